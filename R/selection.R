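# Three-stage feature reduction: one-way ANOVA screen across the three HER2
# groups, greedy Pearson redundancy pruning, and multinomial LASSO.

#' One-way ANOVA screen across HER2 groups
#'
#' Per feature, the F statistic is the between-group over within-group mean
#' square across the three HER2 groups; features with `p < alpha` survive.
#' Features with no variance at all (between and within both zero) are
#' dropped and flagged.
#'
#' @param matrix Numeric matrix, rows = samples.
#' @param labels HER2 labels aligned with rows.
#' @param alpha Significance threshold (default 0.05).
#' @return List: `survivors` (column names), `pvalues`, `fstats` (named, all
#'   columns), `flagged` (degenerate columns).
#' @export
anova_filter <- function(matrix, labels, alpha = 0.05) {
  y <- as_her2_factor(labels)
  if (any(table(y) < 2)) stop("each HER2 class needs >= 2 samples")
  m <- unclass(matrix)
  n <- nrow(m); k <- nlevels(y)
  gm <- colMeans(m)
  ssb <- rep(0, ncol(m)); ssw <- rep(0, ncol(m))
  for (lv in levels(y)) {
    rows <- y == lv
    mu_g <- colMeans(m[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (mu_g - gm)^2
    ssw <- ssw + colSums(sweep(m[rows, , drop = FALSE], 2, mu_g)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssb < .Machine$double.eps * n & ssw < .Machine$double.eps * n
  p[degenerate] <- NA
  f[degenerate] <- NA
  cn <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  names(f) <- names(p) <- cn
  keep <- !is.na(p) & p < alpha
  list(survivors = cn[keep], pvalues = p, fstats = f,
       flagged = cn[degenerate])
}

#' Greedy Pearson redundancy pruning
#'
#' Iterates survivors in `priority` order (typically ascending ANOVA p); a
#' feature is kept iff its absolute Pearson correlation with every
#' already-kept feature is below `r_threshold`. Zero-variance features are
#' dropped and flagged.
#'
#' @param matrix Numeric matrix.
#' @param survivors Candidate column names.
#' @param r_threshold Absolute-correlation cut (default 0.90).
#' @param priority Optional ordering values (lower = higher priority),
#'   named by or aligned with `survivors`.
#' @return List: `survivors`, `flagged`.
#' @export
pearson_redundancy_filter <- function(matrix, survivors, r_threshold = 0.90,
                                      priority = NULL) {
  if (length(survivors) == 0) stop("no surviving features to prune")
  m <- unclass(matrix)[, survivors, drop = FALSE]
  if (!is.null(priority)) {
    pr <- if (!is.null(names(priority))) priority[survivors] else priority
    ord <- order(pr)
  } else {
    ord <- seq_along(survivors)
  }
  sds <- apply(m, 2, pop_sd)
  flagged <- survivors[sds == 0 | !is.finite(sds)]
  kept <- character(0)
  kept_mat <- NULL
  for (i in ord) {
    nm <- survivors[i]
    if (nm %in% flagged) next
    if (length(kept) == 0) {
      kept <- nm; kept_mat <- m[, nm, drop = FALSE]
      next
    }
    r <- suppressWarnings(abs(cor(m[, nm], kept_mat)))
    r[!is.finite(r)] <- 0
    if (all(r < r_threshold)) {
      kept <- c(kept, nm)
      kept_mat <- cbind(kept_mat, m[, nm])
    }
  }
  list(survivors = kept, flagged = flagged)
}

# Stratified fold ids ensuring every fold sees every class.
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fid <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      fid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fid
  })
}

#' Multinomial LASSO feature selection
#'
#' L1-penalized multinomial logistic regression over glmnet's log-spaced
#' lambda path; lambda chosen by stratified cross-validated multinomial
#' deviance (CV minimum). A feature survives iff any class coefficient at
#' the chosen lambda is nonzero.
#'
#' @param matrix Numeric matrix (stage-2 survivors as columns).
#' @param labels HER2 labels.
#' @param n_folds CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return List: `survivors`, `lambda`, `lambda_path`, `cv_deviance`,
#'   `coefficients` (features x classes at the chosen lambda).
#' @export
lasso_select <- function(matrix, labels, n_folds = 10, seed = 1L) {
  y <- as_her2_factor(labels)
  m <- unclass(matrix)
  if (ncol(m) < 2) stop("need >= 2 candidate features for the LASSO stage")
  foldid <- stratified_folds(y, n_folds, derive_seed(seed, "lasso_folds"))
  cvfit <- with_seed(derive_seed(seed, "lasso"), {
    glmnet::cv.glmnet(m, y, family = "multinomial", foldid = foldid,
                      type.measure = "deviance", standardize = FALSE)
  })
  lam <- cvfit$lambda.min
  cf <- stats::coef(cvfit, s = lam)
  beta <- do.call(cbind, lapply(cf, function(b) as.matrix(b)[-1, 1]))
  colnames(beta) <- names(cf)
  nz <- rowSums(abs(beta) > 0) > 0
  list(survivors = rownames(beta)[nz],
       lambda = lam,
       lambda_path = cvfit$lambda,
       cv_deviance = cvfit$cvm,
       coefficients = beta[nz, , drop = FALSE])
}

#' Run the full ANOVA -> Pearson -> LASSO cascade
#'
#' @param matrix Z-scored feature matrix (training rows only).
#' @param labels HER2 labels.
#' @param alpha ANOVA threshold.
#' @param r_threshold Pearson threshold.
#' @param n_folds LASSO CV folds.
#' @param seed RNG seed.
#' @return A `selection_result`: `stage1_survivors`, `stage2_survivors`,
#'   `stage3_survivors`, `anova_pvalues`, `lasso` (path details),
#'   `per_habitat_counts`.
#' @export
select_features <- function(matrix, labels, alpha = 0.05, r_threshold = 0.90,
                            n_folds = 10, seed = 1L) {
  s1 <- anova_filter(matrix, labels, alpha)
  if (length(s1$survivors) == 0) stop("ANOVA stage removed every feature")
  s2 <- pearson_redundancy_filter(matrix, s1$survivors, r_threshold,
                                  priority = s1$pvalues[s1$survivors])
  s3 <- if (length(s2$survivors) >= 2) {
    lasso_select(unclass(matrix)[, s2$survivors, drop = FALSE], labels,
                 n_folds, seed)
  } else {
    list(survivors = s2$survivors, lambda = NA, lambda_path = numeric(0),
         cv_deviance = numeric(0), coefficients = NULL)
  }
  hab <- tryCatch(parse_feature_name(s3$survivors)$habitat,
                  error = function(e) rep(NA_integer_, length(s3$survivors)))
  structure(list(
    stage1_survivors = s1$survivors,
    stage2_survivors = s2$survivors,
    stage3_survivors = s3$survivors,
    anova_pvalues = s1$pvalues,
    anova_flagged = s1$flagged,
    lasso = s3,
    per_habitat_counts = if (!anyNA(hab)) table(factor(hab)) else NULL
  ), class = "selection_result")
}
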