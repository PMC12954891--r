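# Ternary HER2 classification: SMOTE + random-undersampling rebalancing,
# grid-searched gradient-boosted trees (xgboost), one-vs-rest ROC/AUC
# evaluation with stratified bootstrap CIs.

#' SMOTE + random undersampling to class parity
#'
#' Minority classes are raised toward the majority count with SMOTE
#' (synthetic rows interpolated between a minority sample and one of its
#' `k_neighbors` nearest same-class neighbors), then random undersampling
#' trims every class to the exact parity target (default: the majority
#' count, so undersampling is a no-op unless a smaller target is given).
#' Synthetic rows are flagged so cross-validation can verify that they never
#' enter validation folds.
#'
#' @param matrix Numeric matrix.
#' @param labels HER2 labels.
#' @param seed RNG seed.
#' @param k_neighbors SMOTE neighbor count (default 5; lowered with a
#'   warning when a class is too small).
#' @param target Per-class target count (default: majority class size).
#' @return List: `matrix`, `labels` (factor), `synthetic` (logical flag per
#'   output row).
#' @export
rebalance <- function(matrix, labels, seed = 1L, k_neighbors = 5,
                      target = NULL) {
  y <- as_her2_factor(labels)
  m <- unclass(matrix)
  cnt <- table(y)
  if (any(cnt < 2)) stop("SMOTE needs >= 2 samples per class")
  if (is.null(target)) target <- max(cnt)
  out_m <- list(); out_y <- list(); out_s <- list()
  with_seed(derive_seed(seed, "rebalance"), {
    for (lv in levels(y)) {
      rows <- which(y == lv)
      xm <- m[rows, , drop = FALSE]
      syn <- NULL
      need <- max(cnt) - length(rows)
      if (need > 0) {
        kn <- min(k_neighbors, length(rows) - 1)
        if (kn < k_neighbors) {
          warning("class ", lv, ": neighbor count lowered to ", kn)
        }
        d2 <- as.matrix(dist(xm))^2
        diag(d2) <- Inf
        nnm <- t(apply(d2, 1, function(r) order(r)[seq_len(kn)]))
        base_i <- sample.int(length(rows), need, replace = TRUE)
        nb_i <- vapply(base_i, function(b) nnm[b, sample.int(kn, 1)], integer(1))
        gap <- runif(need)
        syn <- xm[base_i, , drop = FALSE] +
          gap * (xm[nb_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
      }
      full <- rbind(xm, syn)
      flag <- c(rep(FALSE, nrow(xm)), rep(TRUE, if (is.null(syn)) 0 else nrow(syn)))
      if (nrow(full) > target) {
        keep <- sample.int(nrow(full), target)
        full <- full[keep, , drop = FALSE]
        flag <- flag[keep]
      }
      out_m[[lv]] <- full; out_s[[lv]] <- flag
      out_y[[lv]] <- rep(lv, nrow(full))
    }
  })
  list(matrix = do.call(rbind, out_m),
       labels = factor(unlist(out_y, use.names = FALSE), levels = her2_levels()),
       synthetic = unlist(out_s, use.names = FALSE))
}

#' Default hyperparameter grid
#'
#' Trees x depth x learning rate x row/column subsampling; includes the
#' combination (100 trees, depth 3, lr 0.01, 0.6, 0.6).
#'
#' @return Data frame of grid points.
#' @export
default_xgb_grid <- function() {
  expand.grid(n_trees = c(100, 300, 500), max_depth = c(3, 5, 7),
              learning_rate = c(0.01, 0.05, 0.1),
              row_subsample = c(0.6, 0.8, 1.0),
              col_subsample = c(0.6, 0.8, 1.0))
}

fit_xgb <- function(x, y, pars, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = 3,
                  max_depth = pars$max_depth, eta = pars$learning_rate,
                  subsample = pars$row_subsample,
                  colsample_bytree = pars$col_subsample,
                  nthread = 1, seed = as.integer(seed)),
    data = dm, nrounds = pars$n_trees, verbose = 0)
}

# Macro one-vs-rest AUC of a probability matrix against true labels.
macro_ovr_auc <- function(probs, y) {
  mean(vapply(seq_len(nlevels(y)), function(c) {
    truth <- as.integer(y) == c
    if (all(truth) || !any(truth)) return(NA_real_)
    auc_mann_whitney(probs[, c], truth)
  }, numeric(1)), na.rm = TRUE)
}

#' Grid-search cross-validated training
#'
#' Stratified CV; rebalancing is applied inside each training fold only
#' (validation folds contain no synthetic rows). Grid points are scored by
#' mean macro one-vs-rest AUC; the best point is refit on the full
#' rebalanced training set.
#'
#' @param matrix Numeric training matrix.
#' @param labels HER2 labels.
#' @param grid Data frame of hyperparameter points (see
#'   [default_xgb_grid()]).
#' @param n_folds CV folds (>= 3, default 5).
#' @param seed RNG seed.
#' @return A `trained_classifier`: `booster`, `best_params`, `cv_table`,
#'   `cv_macro_auc`, `feature_names`, `class_levels`, `seed`,
#'   `validation_synthetic` (always all-FALSE audit flag).
#' @export
grid_search_train <- function(matrix, labels, grid = default_xgb_grid(),
                              n_folds = 5, seed = 1L) {
  if (n_folds < 3) stop("n_folds must be >= 3")
  y <- as_her2_factor(labels)
  m <- unclass(matrix)
  foldid <- stratified_folds(y, n_folds, derive_seed(seed, "cv_folds"))
  cv_scores <- matrix(NA_real_, nrow(grid), n_folds)
  synth_in_validation <- FALSE
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    rb <- rebalance(m[tr, , drop = FALSE], y[tr],
                    seed = derive_seed(seed, paste0("fold", f)))
    va_x <- m[!tr, , drop = FALSE]
    va_y <- y[!tr]
    # validation rows are taken straight from the original matrix; audit
    synth_in_validation <- synth_in_validation ||
      any(!rownames(va_x) %in% rownames(m))
    for (g in seq_len(nrow(grid))) {
      fit <- tryCatch(
        fit_xgb(rb$matrix, rb$labels, grid[g, ], derive_seed(seed, paste0("xgb", f, "_", g))),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr <- predict(fit, xgboost::xgb.DMatrix(va_x))
      cv_scores[g, f] <- macro_ovr_auc(pr, va_y)
    }
  }
  mean_auc <- rowMeans(cv_scores, na.rm = TRUE)
  if (all(is.na(mean_auc))) stop("every grid point failed to train")
  best <- which.max(mean_auc)
  rb_full <- rebalance(m, y, seed = derive_seed(seed, "full_rebalance"))
  booster <- fit_xgb(rb_full$matrix, rb_full$labels, grid[best, ],
                     derive_seed(seed, "final"))
  structure(list(
    booster = booster,
    best_params = as.list(grid[best, ]),
    grid = grid,
    cv_table = cbind(grid, mean_macro_auc = mean_auc),
    cv_macro_auc = mean_auc[best],
    feature_names = colnames(m),
    class_levels = her2_levels(),
    resampling = "SMOTE to majority count + random undersampling to parity",
    seed = seed,
    validation_synthetic = synth_in_validation
  ), class = "trained_classifier")
}

#' Class-probability predictions
#'
#' @param model A `trained_classifier`.
#' @param matrix Matrix with the training columns.
#' @return n x 3 matrix of probabilities (rows sum to 1), columns in
#'   (zero, low, positive) order.
#' @export
predict_proba <- function(model, matrix) {
  if (!inherits(model, "trained_classifier")) stop("model is not trained")
  m <- unclass(matrix)
  if (!is.null(model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(m))
    if (length(missing) > 0) {
      stop("missing feature column(s): ", paste(head(missing, 5), collapse = ", "))
    }
    m <- m[, model$feature_names, drop = FALSE]
  }
  p <- predict(model$booster, xgboost::xgb.DMatrix(m))
  colnames(p) <- model$class_levels
  rownames(p) <- rownames(m)
  p
}

#' AUC as the Mann-Whitney statistic
#'
#' Probability that a positive scores above a random negative, ties counted
#' one half; computed from midranks, identical to exhaustive pair
#' enumeration.
#'
#' @param scores Numeric scores.
#' @param truth Logical (TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 P R / (P + R)`; defined as 0 when both are 0.
#'
#' @param precision,sensitivity Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_from_pr <- function(precision, sensitivity) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(sensitivity >= 0 & sensitivity <= 1))
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' One-vs-rest evaluation report
#'
#' Per class: ROC points, Mann-Whitney AUC with a stratified percentile
#' bootstrap 95% CI; plus the 3x3 confusion matrix (rows = truth) from
#' argmax predictions and per-class OvR-collapsed accuracy, sensitivity,
#' specificity, precision and F1.
#'
#' @param probs n x 3 probability matrix.
#' @param labels True HER2 labels.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @param cohort Optional cohort identifier.
#' @return An `evaluation_report`.
#' @export
evaluate_ovr <- function(probs, labels, n_boot = 2000, seed = 1L,
                         cohort = NA_character_) {
  y <- as_her2_factor(labels)
  stopifnot(nrow(probs) == length(y), ncol(probs) == 3)
  lv <- her2_levels()
  pred <- factor(lv[max.col(probs, ties.method = "first")], levels = lv)
  cm <- table(truth = y, predicted = pred)
  per_class <- list()
  for (c in seq_along(lv)) {
    truth <- y == lv[c]
    sc <- probs[, c]
    if (!any(truth)) {
      per_class[[lv[c]]] <- list(auc = NA_real_, ci = c(NA, NA))
      next
    }
    auc <- auc_mann_whitney(sc, truth)
    boots <- with_seed(derive_seed(seed, paste0("boot", c)), {
      pos <- which(truth); neg <- which(!truth)
      vapply(seq_len(n_boot), function(b) {
        i <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
        auc_mann_whitney(sc[i], truth[i])
      }, numeric(1))
    })
    ci <- quantile(boots, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    # OvR-collapsed 2x2 at argmax predictions
    tp <- sum(pred == lv[c] & truth); fp <- sum(pred == lv[c] & !truth)
    fn <- sum(pred != lv[c] & truth); tn <- sum(pred != lv[c] & !truth)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    o <- order(sc, decreasing = TRUE)
    roc <- data.frame(
      fpr = cumsum(!truth[o]) / max(1, sum(!truth)),
      tpr = cumsum(truth[o]) / max(1, sum(truth))
    )
    per_class[[lv[c]]] <- list(
      auc = auc, ci = ci, roc = roc,
      accuracy = (tp + tn) / length(y),
      sensitivity = sens,
      specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
      precision = prec,
      f1 = f1_from_pr(prec, sens)
    )
  }
  structure(list(
    cohort = cohort,
    confusion = cm,
    per_class = per_class,
    macro_auc = mean(vapply(per_class, function(x) x$auc, numeric(1)), na.rm = TRUE),
    n = length(y), n_boot = n_boot
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", if (!is.na(x$cohort)) x$cohort else "",
      "n =", x$n, "\n")
  for (cl in names(x$per_class)) {
    pc <- x$per_class[[cl]]
    cat(sprintf("  HER2-%-9s AUC %.3f (95%% CI %.3f-%.3f)  acc %.3f sens %.3f spec %.3f prec %.3f F1 %.3f\n",
                cl, pc$auc, pc$ci[1], pc$ci[2], pc$accuracy, pc$sensitivity,
                pc$specificity, pc$precision, pc$f1))
  }
  cat("  macro AUC", round(x$macro_auc, 3), "\n")
  invisible(x)
}
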