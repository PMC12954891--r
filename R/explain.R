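# Shapley-value interpretation of the trained classifier.
#
# Attributions are computed on the margin (log-odds) scale, where tree
# Shapley values are exact and additive; probability-scale numbers shown in
# waterfalls are display transforms through the model's softmax.

#' Exact tree Shapley attributions for every sample and class
#'
#' Uses the tree-path-dependent Shapley algorithm of the boosting library
#' (exact for tree ensembles, margin scale). The per-class base value is the
#' expected margin over the model's training distribution.
#'
#' @param model A `trained_classifier`.
#' @param matrix Matrix with the training columns.
#' @return A `shap_explanation`: `phi` (samples x features x classes),
#'   `base_values` (length 3), `margins`, `probs`, `feature_values`,
#'   `feature_names`, `class_levels`, `scale = "margin"`.
#' @export
compute_shap <- function(model, matrix) {
  if (!inherits(model, "trained_classifier")) stop("model is not trained")
  m <- unclass(matrix)
  missing <- setdiff(model$feature_names, colnames(m))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(head(missing, 5), collapse = ", "))
  }
  m <- m[, model$feature_names, drop = FALSE]
  ts <- booster_treeshap(model$booster, m, model$class_levels)
  phi <- ts$phi
  base <- ts$base
  margins <- ts$margins
  probs <- t(apply(margins, 1, function(z) exp(z - max(z)) / sum(exp(z - max(z)))))
  dimnames(phi) <- list(rownames(m), model$feature_names, model$class_levels)
  colnames(margins) <- colnames(probs) <- model$class_levels
  structure(list(
    phi = phi, base_values = setNames(base, model$class_levels),
    margins = margins, probs = probs,
    feature_values = m, feature_names = model$feature_names,
    class_levels = model$class_levels, scale = "margin"
  ), class = "shap_explanation")
}

#' Global feature-importance summary for one class
#'
#' Ranks features by mean absolute Shapley attribution for the class and
#' returns the per-sample (attribution, feature value) pairs needed for a
#' beeswarm-style summary display.
#'
#' @param explanation A [compute_shap()] result.
#' @param class One of `"zero"`, `"low"`, `"positive"`.
#' @param top_n How many features to return (default 20; capped at the
#'   feature count).
#' @return Data frame ranked by `mean_abs_shap`, with a `scatter` list
#'   column of per-sample (phi, value) matrices.
#' @export
global_summary <- function(explanation, class, top_n = 20) {
  stopifnot(inherits(explanation, "shap_explanation"))
  class <- match.arg(class, explanation$class_levels)
  ph <- explanation$phi[, , class, drop = FALSE][, , 1, drop = TRUE]
  if (is.null(dim(ph))) ph <- matrix(ph, nrow = dim(explanation$phi)[1])
  score <- colMeans(abs(ph))
  top_n <- min(top_n, length(score))
  ord <- order(score, decreasing = TRUE)[seq_len(top_n)]
  out <- data.frame(
    feature = explanation$feature_names[ord],
    mean_abs_shap = unname(score[ord]),
    stringsAsFactors = FALSE
  )
  out$scatter <- lapply(ord, function(j) {
    cbind(phi = ph[, j], value = explanation$feature_values[, j])
  })
  out
}

#' Per-sample waterfall decomposition
#'
#' Features sorted by decreasing |phi| with the cumulative margin path from
#' the class base value to the sample's final margin; `prob_start` /
#' `prob_end` map those endpoints to the probability scale through the
#' model's softmax (matching how such explanations are usually narrated).
#'
#' @param explanation A [compute_shap()] result.
#' @param sample Row index or patient id.
#' @param class HER2 class.
#' @return List: `steps` (data frame feature/phi/cumulative), `base_margin`,
#'   `end_margin`, `prob_start`, `prob_end`.
#' @export
waterfall <- function(explanation, sample, class) {
  stopifnot(inherits(explanation, "shap_explanation"))
  class <- match.arg(class, explanation$class_levels)
  n <- dim(explanation$phi)[1]
  if (is.character(sample)) {
    sample <- match(sample, rownames(explanation$feature_values))
  }
  if (is.na(sample) || sample < 1 || sample > n) stop("invalid sample index")
  ph <- explanation$phi[sample, , class]
  ord <- order(abs(ph), decreasing = TRUE)
  base <- explanation$base_values[class]
  steps <- data.frame(
    feature = explanation$feature_names[ord],
    value = explanation$feature_values[sample, ord],
    phi = unname(ph[ord]),
    stringsAsFactors = FALSE
  )
  steps$cumulative <- base + cumsum(steps$phi)
  softmax <- function(z) exp(z - max(z)) / sum(exp(z - max(z)))
  cls_i <- match(class, explanation$class_levels)
  list(
    steps = steps,
    base_margin = unname(base),
    end_margin = unname(explanation$margins[sample, class]),
    prob_start = unname(softmax(explanation$base_values)[cls_i]),
    prob_end = unname(softmax(explanation$margins[sample, ])[cls_i])
  )
}

#' Brute-force interventional Shapley values (oracle)
#'
#' Enumerates all feature coalitions for an arbitrary scalar prediction
#' function, valuing a coalition S as the mean prediction over background
#' rows with the features in S fixed to the explained sample. Exponential in
#' the feature count; intended as an independent oracle for small toys.
#'
#' @param f Function taking a numeric vector (one sample) and returning a
#'   scalar.
#' @param x Sample to explain (numeric vector).
#' @param background Background matrix (rows = reference samples).
#' @return Numeric vector of attributions, one per feature; attribute
#'   `base` holds the mean background prediction.
#' @export
shapley_brute_force <- function(f, x, background) {
  p <- length(x)
  if (p > 15) stop("brute force is limited to <= 15 features")
  v <- function(S) {
    mean(apply(background, 1, function(z) {
      z[S] <- x[S]
      f(z)
    }))
  }
  phi <- numeric(p)
  subsets <- lapply(0:(2^p - 1), function(b) which(bitwAnd(b, 2^(0:(p - 1))) > 0))
  vs <- vapply(subsets, v, numeric(1))
  key <- vapply(subsets, function(S) sum(2^(S - 1)), numeric(1))
  lookup <- setNames(vs, key)
  for (j in seq_len(p)) {
    for (i in seq_along(subsets)) {
      S <- subsets[[i]]
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w *
        (lookup[[as.character(sum(2^(c(S, j) - 1)))]] - vs[i])
    }
  }
  attr(phi, "base") <- lookup[["0"]]
  phi
}
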