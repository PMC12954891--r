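# Shared fixtures, built in code at test time.

# Small noise-free phantom study with k planted habitats.
make_tiny_study <- function(k = 4, noise_sd = 0, seed = 11, grid = 24,
                            radius = c(5, 7)) {
  mask <- generate_tumor_mask(rep(grid, 3), radius, seed = seed)
  mix <- rep(1 / k, k)
  truth <- plant_habitats(mask, k, mix, seed = seed + 1)
  ph <- simulate_phases(mask, truth, default_signatures(k), noise_sd,
                        seed = seed + 2)
  structure(list(
    patient_id = sprintf("T%03d", seed),
    phase_pre = ph$phase_pre, phase_early = ph$phase_early,
    phase_delayed = ph$phase_delayed,
    tumor_mask = mask, spacing = c(1, 1, 1),
    her2 = "low", truth_habitats = truth
  ), class = "dce_study")
}

# Brute-force silhouette: literal per-point loops over all pairs.
silhouette_brute <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force Davies-Bouldin: literal definition.
db_brute <- function(x, labels) {
  gs <- sort(unique(labels))
  cent <- t(vapply(gs, function(g) colMeans(x[labels == g, , drop = FALSE]),
                   numeric(ncol(x))))
  sprd <- vapply(seq_along(gs), function(gi) {
    m <- x[labels == gs[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(m, 2, cent[gi, ])^2)))
  }, numeric(1))
  mean(vapply(seq_along(gs), function(i) {
    max(vapply(setdiff(seq_along(gs), i), function(j) {
      (sprd[i] + sprd[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# Exhaustive Mann-Whitney AUC over all (positive, negative) pairs.
auc_brute <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small labeled feature matrix with planted class signal in given columns.
make_signal_matrix <- function(n = 90, p = 20, signal_cols = 1:3, effect = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("zero", "low", "positive"), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    for (i in seq_along(signal_cols)) {
      cls <- c("zero", "low", "positive")[(i - 1) %% 3 + 1]
      x[y == cls, signal_cols[i]] <- x[y == cls, signal_cols[i]] + effect
    }
    colnames(x) <- paste0("original_firstorder_F", seq_len(p),
                          "_Habitat", rep_len(1:4, p))
    rownames(x) <- sprintf("S%03d", seq_len(n))
    list(x = x, y = y)
  })
}

digital_ball <- function(r, n = 2 * r + 5) {
  ctr <- (n + 1) / 2
  ax <- seq_len(n)
  d2 <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
  array((d2 <= r^2) * 1L, rep(n, 3))
}
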