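test_that("the stratified split reproduces per-class rounded counts", {
  labels <- rep(c("SCA", "MCN", "IPMN"), c(76, 40, 48))
  plan <- stratified_split(labels, 0.7, seed = 1)
  counts <- table(labels[plan$train])
  expect_equal(unname(counts[c("SCA", "MCN", "IPMN")]), c(53, 28, 34),
               ignore_attr = TRUE)
  expect_length(intersect(plan$train, plan$validation), 0)
  expect_setequal(c(plan$train, plan$validation), seq_along(labels))

  # determinism and seed sensitivity with invariant counts
  plan2 <- stratified_split(labels, 0.7, seed = 1)
  plan3 <- stratified_split(labels, 0.7, seed = 2)
  expect_identical(plan$train, plan2$train)
  expect_false(identical(plan$train, plan3$train))
  expect_equal(table(labels[plan3$train]), counts)

  expect_length(stratified_split(labels, 1.0, seed = 1)$validation, 0)
  expect_error(stratified_split(c("a", "a", "b"), 0.7), "invalid stratum")
})

test_that("kernel formulas match hand-coded oracles to 1e-12", {
  set.seed(41)
  x <- rnorm(6); y <- rnorm(6)
  p <- list(sigma = 0.7, degree = 3)
  expect_equal(kernel_eval("linear", p, x, y), sum(x * y), tolerance = 1e-12)
  expect_equal(kernel_eval("gaussian", p, x, y),
               exp(-0.7 * sum((x - y)^2)), tolerance = 1e-12)
  expect_equal(kernel_eval("laplacian", p, x, y),
               exp(-0.7 * sqrt(sum((x - y)^2))), tolerance = 1e-12)
  expect_equal(kernel_eval("anova_rbf", p, x, y),
               (sum(exp(-0.7 * (x - y)^2)))^3, tolerance = 1e-12)
  expect_equal(kernel_eval("gaussian", p, x, x), 1)
  expect_equal(kernel_eval("anova_rbf", list(sigma = 1, degree = 1), x, x),
               length(x))
  expect_error(kernel_eval("gaussian", p, x, c(y, 1)), "invalid argument")
})

test_that("SVM separates separable data and standardizes internally", {
  set.seed(42)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(40, mean = 6), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  fit <- train_svm(x, y, kernel = "linear", C = 10)
  expect_equal(mean(predict(fit, x) == y), 1)
  # only training statistics are stored for standardization
  expect_named(fit$standardize, c("mean", "sd"))

  # three 10-SD-separated blobs, gaussian kernel
  x3 <- rbind(matrix(rnorm(60), 30, 2),
              matrix(rnorm(60, mean = 10), 30, 2),
              matrix(rnorm(60, mean = c(10, -10)), 30, 2, byrow = TRUE))
  y3 <- rep(c("a", "b", "c"), each = 30)
  fit3 <- train_svm(x3, y3, kernel = "gaussian", C = 2)
  expect_equal(mean(predict(fit3, x3) == y3), 1)
})

test_that("random forests expose the full OOB trajectory", {
  set.seed(43)
  n <- 90
  y <- rep(c("a", "b", "c"), each = n / 3)
  x <- data.frame(info = as.integer(factor(y)) + rnorm(n, sd = 0.1),
                  junk = rnorm(n))
  fit <- train_rf(x, y, n_trees = 300, mtry = 1)
  expect_equal(nrow(fit$oob), 300)
  expect_true(all(c("OOB", "a", "b", "c") %in% colnames(fit$oob)))
  expect_lt(fit$oob[300, "OOB"], 0.1)  # informative feature drives error down
  expect_error(train_rf(x, y, mtry = 5), "invalid argument")

  # pure-noise features: OOB error near the majority-class error rate
  xn <- data.frame(a = rnorm(n), b = rnorm(n))
  fitn <- train_rf(xn, y, n_trees = 300, mtry = 1)
  expect_lt(abs(fitn$oob[300, "OOB"] - 2 / 3), 0.12)
})

test_that("the neural net solves XOR and responds to weight decay", {
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  xor_y <- factor(c("a", "b", "b", "a"))
  fit <- train_ann(xor_x, xor_y, hidden_units = 2, weight_decay = 0,
                   seed = 2, restarts = 5)
  expect_equal(mean(predict(fit, xor_x) == xor_y), 1)

  set.seed(44)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  # huge decay collapses predictions to the class priors
  fit_big <- train_ann(x, y, hidden_units = 5, weight_decay = 1000, seed = 1)
  pr <- predict(fit_big, x, type = "prob")
  expect_lt(max(apply(pr, 2, function(cc) diff(range(cc)))), 0.05)
  # weight norm is non-increasing in the decay
  norms <- vapply(c(0, 0.1, 1), function(dcy)
    sqrt(sum(train_ann(x, y, hidden_units = 4, weight_decay = dcy,
                       seed = 3)$fit$wts^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("cross-validated selection scores grids and breaks ties as stated", {
  set.seed(45)
  n <- 60
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  x <- cbind(as.integer(y) + rnorm(n, sd = 0.3), rnorm(n))

  one <- cv_select("svm", data.frame(kernel = "linear", C = 3), x, y,
                   seed = 1)
  expect_equal(one$best$C, 3)
  expect_equal(nrow(one$cv_table), 1)

  grid <- data.frame(kernel = rep(c("linear", "gaussian"), each = 2),
                     C = c(1, 2, 1, 2), stringsAsFactors = FALSE)
  sel <- cv_select("svm", grid, x, y, folds = 4, seed = 1)
  expect_equal(nrow(sel$cv_table), 4)
  fold_cols <- paste0("fold", 1:4)
  expect_equal(rowMeans(sel$cv_table[, fold_cols]), sel$cv_table$score,
               tolerance = 1e-12)

  rf_sel <- cv_select("rf", data.frame(n_trees = c(100, 200), mtry = 1),
                      x, y, seed = 1)
  expect_true(rf_sel$best$n_trees %in% c(100, 200))
})

test_that("a radial class structure prefers the gaussian kernel", {
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 60
    r <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
    th <- runif(n, 0, 2 * pi)
    x <- cbind(r * cos(th), r * sin(th))
    y <- factor(rep(c("in", "out"), each = n / 2))
    grid <- data.frame(kernel = c("linear", "gaussian"), C = 2,
                       stringsAsFactors = FALSE)
    sel <- cv_select("svm", grid, x, y, folds = 4, seed = s)
    wins <- wins + (sel$best$kernel == "gaussian")
  }
  expect_gte(wins, 18)
})
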