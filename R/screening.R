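#' Intraclass correlation coefficient, two-way random effects, absolute
#' agreement, single measurement
#'
#' ICC(2,1) from the two-way ANOVA mean squares of an `n x k` matrix
#' (patients x segmentations):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Degenerate inputs (zero between-patient variance) return the computed,
#' possibly non-positive, value rather than failing.
#'
#' @param x numeric matrix, rows = subjects, columns = raters/segmentations.
#' @return ICC estimate.
#' @export
icc21 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  mu <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - mu)^2) / (n - 1)
  msc <- n * sum((col_m - mu)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-300) return(0)
  (msr - mse) / denom
}

#' Screen features for robustness against segmentation perturbation
#'
#' For each feature, computes ICC(2,1) across the feature tables extracted
#' from the original and perturbed segmentations and keeps the feature iff
#' the ICC exceeds the threshold.
#'
#' @param tables list of feature `data.frame`s (same patients, same feature
#'   columns; first column `patient_id` is ignored if present).
#' @param threshold ICC retention threshold (default 0.75).
#' @return `data.frame` with columns `feature`, `icc`, `kept`.
#' @export
icc_screen <- function(tables, threshold = 0.75) {
  stopifnot(length(tables) >= 2)
  feats <- setdiff(colnames(tables[[1]]), "patient_id")
  for (t in tables)
    if (!all(feats %in% colnames(t)))
      stop("feature tables must share feature columns", call. = FALSE)
  icc <- vapply(feats, function(f) {
    icc21(do.call(cbind, lapply(tables, function(t) t[[f]])))
  }, numeric(1))
  data.frame(feature = feats, icc = icc, kept = icc > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Greedy inter-correlation pruning
#'
#' While any feature pair has `|Pearson r|` above the threshold, the pair
#' with the largest `|r|` is found and the member with the larger mean
#' absolute correlation to all remaining features is dropped (ties broken
#' by dropping the lexicographically later name). Constant features have
#' undefined correlations, treated as 0. Survivors are pairwise at or below
#' the threshold by construction.
#'
#' @param table feature `data.frame` (a `patient_id` column is ignored).
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered redundant (default 0.75).
#' @return Character vector of surviving feature names.
#' @export
correlation_prune <- function(table, threshold = 0.75) {
  feats <- setdiff(colnames(table), "patient_id")
  if (length(feats) < 2) return(feats)
  x <- as.matrix(table[, feats, drop = FALSE])
  suppressWarnings(r <- abs(cor(x)))
  r[!is.finite(r)] <- 0  # constant features: undefined r treated as 0
  diag(r) <- 0
  alive <- feats
  while (TRUE) {
    sub <- r[alive, alive, drop = FALSE]
    if (max(sub) <= threshold) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- alive[w[1]]; b <- alive[w[2]]
    mean_a <- mean(sub[a, ]); mean_b <- mean(sub[b, ])
    drop <- if (mean_a > mean_b) a
            else if (mean_b > mean_a) b
            else max(a, b)  # lexicographic tie-break
    alive <- setdiff(alive, drop)
    if (length(alive) < 2) break
  }
  alive
}

#' Kruskal-Wallis test across the three subtypes
#'
#' Thin wrapper over [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-square reference with `groups - 1` df). An all-constant
#' response returns `H = 0, p = 1` instead of a division-by-zero failure.
#'
#' @param values numeric vector.
#' @param groups group labels (coerced to factor).
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("each group must be non-empty", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Categorical association test with the conventional selection rule
#'
#' Plain chi-square when all expected counts are at least 5; Yates
#' continuity-corrected chi-square for 2x2 tables with an expected count in
#' `[1, 5)` and total n >= 40; Fisher's exact test when any expected count
#' is below 1, for 2x2 tables with small expected counts and n < 40, and
#' for larger-than-2x2 tables with expected counts below 5 (where the
#' correction does not apply).
#'
#' @param counts contingency table of non-negative integer counts.
#' @return List with `test` (`"chisq"`, `"chisq_corrected"`, `"fisher"`),
#'   `statistic` (NA for Fisher) and `p_value`.
#' @export
categorical_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  is2x2 <- all(dim(counts) == 2)
  if (any(expected < 1) ||
      (is2x2 && any(expected < 5) && n < 40) ||
      (!is2x2 && any(expected < 5))) {
    ft <- fisher.test(counts)
    list(test = "fisher", statistic = NA_real_, p_value = ft$p.value)
  } else if (is2x2 && any(expected < 5)) {
    ct <- suppressWarnings(chisq.test(counts, correct = TRUE))
    list(test = "chisq_corrected", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    list(test = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  }
}

#' Shadow-attribute (Boruta) all-relevant feature selection
#'
#' Implements the reference shadow-attribute algorithm: at every iteration
#' each remaining feature is copied and its values shuffled across patients
#' ("shadow" attributes, padded to at least five); a random forest is fit
#' on originals plus shadows; a feature scores a hit when its permutation
#' importance (mean decrease in accuracy) exceeds the best shadow
#' importance. Features whose hit counts are extreme under a Binomial(n,
#' 1/2) two-sided test with Bonferroni correction are confirmed or
#' rejected and leave the testing pool; whatever remains at `max_iter` is
#' tentative. Deterministic given `seed`.
#'
#' @param table feature `data.frame` (a `patient_id` column is ignored);
#'   character/logical/factor columns are integer-coded.
#' @param labels class labels (coerced to factor, >= 2 classes).
#' @param alpha significance level of the binomial decisions (default 0.01).
#' @param max_iter maximum number of forest iterations (default 100).
#' @param rf_params list of arguments forwarded to
#'   [randomForest::randomForest()] (default `ntree = 300`).
#' @param seed integer seed.
#' @return An object of class `boruta_result`: `data.frame` `decision`
#'   (feature, status, hits, n_tests, mean_importance) plus `n_iterations`
#'   and `alpha`.
#' @export
boruta_select <- function(table, labels, alpha = 0.01, max_iter = 100L,
                          rf_params = list(ntree = 300L), seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("invalid labels: need at least two classes", call. = FALSE)
  feats <- setdiff(colnames(table), "patient_id")
  if (length(feats) < 2)
    stop("need at least two candidate features", call. = FALSE)
  x <- table[, feats, drop = FALSE]
  for (cn in colnames(x))
    if (!is.numeric(x[[cn]])) x[[cn]] <- as.integer(as.factor(x[[cn]]))
  x <- as.matrix(x)
  m <- length(feats)
  status <- rep("tentative", m)
  hits <- integer(m)
  tests <- 0L
  imp_sum <- numeric(m)
  imp_n <- integer(m)
  names(status) <- names(hits) <- feats
  withr::with_seed(sub_seed(seed, 303L), {
    for (iter in seq_len(max_iter)) {
      undecided <- status == "tentative"
      if (!any(undecided)) break
      active <- status != "rejected"
      xa <- x[, active, drop = FALSE]
      sh <- apply(xa, 2, sample)
      if (ncol(sh) < 5)  # pad shadows for a stable max-shadow reference
        sh <- cbind(sh, apply(x[, sample(m, 5 - ncol(sh), replace = TRUE),
                                drop = FALSE], 2, sample))
      colnames(sh) <- paste0("shadow_", seq_len(ncol(sh)))
      rf <- do.call(randomForest::randomForest,
                    c(list(x = cbind(xa, sh), y = labels,
                           importance = TRUE), rf_params))
      imp <- rf$importance[, "MeanDecreaseAccuracy"]
      shadow_max <- max(imp[colnames(sh)])
      real_imp <- imp[colnames(xa)]
      imp_sum[active] <- imp_sum[active] + real_imp
      imp_n[active] <- imp_n[active] + 1L
      hits[undecided] <- hits[undecided] +
        as.integer(real_imp[feats[undecided]] > shadow_max)
      tests <- tests + 1L
      # two-sided binomial decision with Bonferroni over all features
      p_hi <- pbinom(hits[undecided] - 1L, tests, 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[undecided], tests, 0.5)
      conf <- p_hi < alpha / m
      rej <- p_lo < alpha / m
      status[which(undecided)[conf]] <- "confirmed"
      status[which(undecided)[rej & !conf]] <- "rejected"
    }
    structure(list(
      decision = data.frame(
        feature = feats, status = status, hits = hits, n_tests = tests,
        mean_importance = ifelse(imp_n > 0, imp_sum / pmax(imp_n, 1L), NA),
        row.names = NULL, stringsAsFactors = FALSE),
      n_iterations = tests, alpha = alpha), class = "boruta_result")
  })
}

#' @export
print.boruta_result <- function(x, ...) {
  tb <- table(x$decision$status)
  cat(sprintf("<boruta_result> %d iterations: %s\n", x$n_iterations,
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Full feature-screening pipeline
#'
#' Applies the screening stages in order: (1) ICC robustness against the
#' perturbed segmentations, (2) greedy inter-correlation pruning, (3)
#' Kruskal-Wallis significance of each surviving radiomics feature across
#' the three subtypes (clinical covariates are tested by Kruskal-Wallis if
#' continuous, by chi-square/corrected/Fisher if categorical), and (4)
#' shadow-attribute selection on the pooled significant radiomics features
#' and clinical factors. Survivor sets are nested by construction on the
#' radiomics side. When no feature or factor is significant, the shadow
#' stage is skipped with a notice.
#'
#' @param tables list of >= 2 radiomics feature tables (original first) on
#'   the same patients.
#' @param clinical clinical covariate `data.frame` (any `patient_id` /
#'   `label` columns are ignored as candidates).
#' @param labels subtype labels, one per patient.
#' @param icc_threshold,cor_threshold,kw_alpha,boruta_alpha,boruta_max_iter
#'   stage thresholds.
#' @param rf_params,seed forwarded to [boruta_select()].
#' @return An object of class `screening_report`: per-stage survivor sets,
#'   per-feature statistics, the `boruta_result` (or `NULL` if skipped),
#'   the final selected feature names, and stage counts.
#' @export
screen_pipeline <- function(tables, clinical, labels,
                            icc_threshold = 0.75, cor_threshold = 0.75,
                            kw_alpha = 0.05, boruta_alpha = 0.01,
                            boruta_max_iter = 100L,
                            rf_params = list(ntree = 300L), seed = 1L) {
  labels <- as.factor(labels)
  # stage 1: robustness
  icc <- icc_screen(tables, icc_threshold)
  robust <- icc$feature[icc$kept]
  # stage 2: inter-correlation (on the unperturbed table)
  t1 <- tables[[1]]
  decorrelated <- if (length(robust) >= 2)
    correlation_prune(t1[, robust, drop = FALSE], cor_threshold)
  else robust
  # stage 3: univariate significance
  kw_p <- vapply(decorrelated, function(f)
    kruskal_wallis(t1[[f]], labels)$p_value, numeric(1))
  significant <- decorrelated[kw_p < kw_alpha]
  clin_cols <- setdiff(colnames(clinical), c("patient_id", "label"))
  clin_p <- vapply(clin_cols, function(cn) {
    v <- clinical[[cn]]
    if (is.numeric(v) && length(unique(v)) > 5) {
      kruskal_wallis(v, labels)$p_value
    } else {
      tab <- table(v, labels)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (any(dim(tab) < 2)) 1 else categorical_test(tab)$p_value
    }
  }, numeric(1))
  sig_clinical <- clin_cols[clin_p < kw_alpha]
  # stage 4: shadow-attribute selection on the pooled candidates
  pool <- c(significant, sig_clinical)
  boruta <- NULL
  selected <- character(0)
  notice <- NULL
  if (length(pool) >= 2) {
    pool_tab <- cbind(t1[, significant, drop = FALSE],
                      clinical[, sig_clinical, drop = FALSE])
    boruta <- boruta_select(pool_tab, labels, alpha = boruta_alpha,
                            max_iter = boruta_max_iter,
                            rf_params = rf_params, seed = seed)
    selected <- boruta$decision$feature[boruta$decision$status == "confirmed"]
  } else {
    notice <- "no significant candidates; shadow-attribute stage skipped"
    message(notice)
  }
  structure(list(
    icc = icc,
    robust = robust,
    decorrelated = decorrelated,
    kw_p = kw_p,
    significant = significant,
    clinical_p = clin_p,
    significant_clinical = sig_clinical,
    boruta = boruta,
    selected = selected,
    notice = notice,
    counts = c(total = nrow(icc), robust = length(robust),
               decorrelated = length(decorrelated),
               significant = length(significant),
               significant_clinical = length(sig_clinical),
               selected = length(selected))),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  print(x$counts)
  if (length(x$selected))
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
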