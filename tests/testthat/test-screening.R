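test_that("ICC(2,1) matches the two-way ANOVA oracle and edge behaviour", {
  # worked 6-patient example, oracle = aov() mean squares
  set.seed(31)
  x <- matrix(rnorm(18, mean = rep(1:6, 3)), 6, 3)
  df <- data.frame(y = as.numeric(x),
                   subj = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 6; k <- 3
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc21(x), expected, tolerance = 1e-12)

  # identical columns: perfect agreement
  y <- rnorm(10)
  expect_equal(icc21(cbind(y, y, y)), 1, tolerance = 1e-12)

  # independent noise at n = 200: near zero
  z <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(icc21(z)), 0.15)
})

test_that("icc_screen keeps reproducible features and drops noisy ones", {
  set.seed(32)
  base <- rnorm(50)
  tabs <- lapply(1:3, function(k) data.frame(
    patient_id = sprintf("P%02d", 1:50),
    stable = base + rnorm(50, sd = 0.05),
    noisy = rnorm(50)))
  res <- icc_screen(tabs, threshold = 0.75)
  expect_true(res$kept[res$feature == "stable"])
  expect_false(res$kept[res$feature == "noisy"])
  expect_identical(res$kept, res$icc > 0.75)
})

test_that("correlation pruning leaves a pairwise-decorrelated survivor set", {
  set.seed(33)
  n <- 60
  # planted collinear block of 3 plus 7 independent features
  block <- rnorm(n)
  tab <- data.frame(
    b1 = block, b2 = block + rnorm(n, sd = 0.1),
    b3 = -block + rnorm(n, sd = 0.1),
    matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("f", 1:7))))
  surv <- correlation_prune(tab, 0.75)
  expect_length(intersect(surv, c("b1", "b2", "b3")), 1)
  expect_true(all(paste0("f", 1:7) %in% surv))
  r <- abs(cor(tab[, surv]))
  diag(r) <- 0
  expect_lte(max(r), 0.75)

  # exact duplicates: exactly one survives
  dup <- data.frame(a = block, b = block)
  expect_length(correlation_prune(dup, 0.75), 1)
  # orthogonal features all survive
  ortho <- data.frame(diag(4))
  expect_length(correlation_prune(ortho, 0.75), 4)
  # constant features have undefined r, treated as uncorrelated
  cst <- data.frame(a = block, b = rep(1, n))
  expect_setequal(correlation_prune(cst, 0.75), c("a", "b"))
})

test_that("Kruskal-Wallis reproduces the hand-ranked H and edge cases", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  # distinct values: H = 12/(N(N+1)) * sum R_c^2/n_c - 3(N+1)
  H <- 12 / (9 * 10) * ((6^2 + 15^2 + 24^2) / 3) - 3 * 10
  res <- kruskal_wallis(v, g)
  expect_equal(res$statistic, H, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(kruskal_wallis(rep(5, 9), g), list(statistic = 0, p_value = 1))
  expect_error(kruskal_wallis(1:4, factor(c("a", "a", "b", "b"),
                                          levels = c("a", "b", "c"))),
               "non-empty")

  # strong planted shift is detected
  set.seed(34)
  vals <- c(rnorm(20), rnorm(20), rnorm(20, mean = 10))
  expect_lt(kruskal_wallis(vals, rep(c("a", "b", "c"), each = 20))$p_value,
            0.001)
})

test_that("categorical tests follow the expected-count selection rule", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r1 <- categorical_test(even)
  expect_equal(r1$test, "chisq")
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)

  # 2x2 with n < 40 and small expected counts: Fisher, checked against an
  # exhaustive hypergeometric tail enumeration
  tab <- matrix(c(6, 2, 1, 8), 2)
  r2 <- categorical_test(tab)
  expect_equal(r2$test, "fisher")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  probs <- vapply(max(0, cs[1] - rs[2]):min(rs[1], cs[1]), function(a)
    dhyper(a, rs[1], rs[2], cs[1]), numeric(1))
  p_exact <- sum(probs[probs <= dhyper(tab[1, 1], rs[1], rs[2], cs[1]) *
                         (1 + 1e-7)])
  expect_equal(r2$p_value, p_exact, tolerance = 1e-10)

  # an expected count below 1 forces the Fisher branch
  tiny <- matrix(c(1, 30, 1, 1), 2)
  expect_equal(categorical_test(tiny)$test, "fisher")

  # large-n 2x2 with an expected count in [1, 5): corrected chi-square
  big <- matrix(c(3, 60, 4, 40), 2)
  ex <- outer(rowSums(big), colSums(big)) / sum(big)
  expect_true(any(ex < 5) && all(ex >= 1) && sum(big) >= 40)
  expect_equal(categorical_test(big)$test, "chisq_corrected")

  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
})

test_that("shadow-attribute selection confirms a perfectly informative feature", {
  set.seed(36)
  n <- 60
  y <- rep(c("A", "B", "C"), each = n / 3)
  tab <- data.frame(oracle = as.integer(factor(y)),
                    matrix(rnorm(n * 6), n, 6,
                           dimnames = list(NULL, paste0("noise", 1:6))))
  res <- boruta_select(tab, y, alpha = 0.01, max_iter = 30,
                       rf_params = list(ntree = 200), seed = 3)
  dec <- res$decision
  expect_equal(dec$status[dec$feature == "oracle"], "confirmed")
  expect_identical(sort(unique(dec$status)) %in%
                     c("confirmed", "rejected", "tentative"),
                   rep(TRUE, length(unique(dec$status))))
  # determinism
  res2 <- boruta_select(tab, y, alpha = 0.01, max_iter = 30,
                        rf_params = list(ntree = 200), seed = 3)
  expect_identical(res$decision, res2$decision)
  expect_error(boruta_select(tab, rep("A", n)), "invalid labels")
})

test_that("the screening pipeline nests survivors and handles the null case", {
  set.seed(37)
  n <- 45
  y <- rep(c("SCA", "MCN", "IPMN"), each = n / 3)
  shift <- rep(c(0, 1.5, 3), each = n / 3)
  shift2 <- rep(c(0, 2, 0), each = n / 3)  # orthogonal class pattern
  base <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    planted1 = shift + rnorm(n, sd = 0.5),
    planted2 = shift2 + rnorm(n, sd = 0.5),
    dup_of_planted1 = NA,
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
    unstable = rnorm(n))
  base$dup_of_planted1 <- base$planted1 + rnorm(n, sd = 0.01)
  tables <- lapply(1:3, function(k) {
    t <- base
    jitter <- rnorm(n, sd = 0.02)
    for (cn in setdiff(colnames(t), c("patient_id", "unstable")))
      t[[cn]] <- t[[cn]] + jitter * 0.01
    t$unstable <- rnorm(n)   # not reproducible across segmentations
    t
  })
  clinical <- data.frame(
    ca199 = exp(rnorm(n, log(10) + shift, 0.4)),
    age = round(rnorm(n, 50 + 5 * shift, 5)),
    filler = rnorm(n))
  rpt <- screen_pipeline(tables, clinical, y, seed = 5)
  expect_false("unstable" %in% rpt$robust)
  expect_true(all(rpt$decorrelated %in% rpt$robust))
  expect_true(all(rpt$significant %in% rpt$decorrelated))
  expect_length(intersect(c("planted1", "dup_of_planted1"),
                          rpt$decorrelated), 1)
  expect_true(all(c("ca199", "age") %in% rpt$significant_clinical))
  expect_false("filler" %in% rpt$significant_clinical)
  expect_true(any(c("planted1", "dup_of_planted1") %in% rpt$selected))
  expect_true("planted2" %in% c(rpt$selected,
                                rpt$boruta$decision$feature))

  # identical class distributions: nothing significant, Boruta skipped
  null_tab <- data.frame(patient_id = sprintf("P%02d", 1:n),
                         f1 = rnorm(n), f2 = rnorm(n))
  null_clin <- data.frame(x = rnorm(n))
  expect_message(
    repn <- screen_pipeline(list(null_tab, null_tab, null_tab),
                            null_clin, y, seed = 6),
    "skipped")
  expect_length(repn$selected, 0)
  expect_null(repn$boruta)
})
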