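# Double-precision path-dependent tree Shapley values, computed from the
# booster's JSON serialization. The algorithm is the exact polynomial-time
# recursion for tree ensembles (coalition weights from node covers); it is
# carried in double precision end to end so the additivity audit is exact.
# The boosting library's own (float32) contribution predictor serves as an
# independent cross-check in the tests.

# Round doubles to their nearest float32 value (kept as doubles), so split
# comparisons reproduce the booster's single-precision routing exactly.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          size = 4L, n = length(v))
}

# Parse a booster's JSON model into per-tree node lists:
# left/right (1-based child indices, NA at leaves), fidx (1-based feature),
# split (float32-exact threshold), value (leaf value), cover.
parse_booster_trees <- function(booster) {
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(booster, raw_format = "json")),
                          simplifyVector = FALSE)
  mod <- j$learner$gradient_booster$model
  trees <- lapply(mod$trees, function(t) {
    left <- unlist(t$left_children)
    right <- unlist(t$right_children)
    leaf <- left == -1
    list(
      left = ifelse(leaf, NA_integer_, left + 1L),
      right = ifelse(leaf, NA_integer_, right + 1L),
      leaf = leaf,
      fidx = ifelse(leaf, NA_integer_, unlist(t$split_indices) + 1L),
      split = as_float32(unlist(t$split_conditions)),
      value = ifelse(leaf, as_float32(unlist(t$split_conditions)), NA_real_),
      cover = unlist(t$sum_hessian)
    )
  })
  list(trees = trees,
       tree_class = unlist(mod$tree_info) + 1L,
       base_score = as.numeric(j$learner$learner_model_param$base_score))
}

# Cover-weighted expected value of one tree.
tree_expected_value <- function(tr) {
  sum(tr$value[tr$leaf] * tr$cover[tr$leaf]) / tr$cover[1]
}

# Evaluate one tree at sample x (float32-rounded numeric vector).
tree_value <- function(tr, x) {
  i <- 1L
  while (!tr$leaf[i]) {
    i <- if (x[tr$fidx[i]] < tr$split[i]) tr$left[i] else tr$right[i]
  }
  tr$value[i]
}

# Exact path-dependent Shapley recursion for a single tree and sample.
tree_shap_one <- function(tr, x, p) {
  phi <- numeric(p)

  extend <- function(m, pz, po, pi) {
    l <- nrow(m)
    m <- rbind(m, c(pi, pz, po, if (l == 0) 1 else 0))
    if (l > 0) {
      for (i in l:1) {
        m[i + 1, 4] <- m[i + 1, 4] + po * m[i, 4] * i / (l + 1)
        m[i, 4] <- pz * m[i, 4] * (l + 1 - i) / (l + 1)
      }
    }
    m
  }
  unwind <- function(m, i) {
    l <- nrow(m) - 1L
    n <- m[l + 1, 4]
    o <- m[i, 3]; z <- m[i, 2]
    for (j in l:1) {
      if (o != 0) {
        t <- m[j, 4]
        m[j, 4] <- n * (l + 1) / (j * o)
        n <- t - m[j, 4] * z * (l + 1 - j) / (l + 1)
      } else {
        m[j, 4] <- m[j, 4] * (l + 1) / (z * (l + 1 - j))
      }
    }
    if (i <= l) for (j in i:l) {
      m[j, 1] <- m[j + 1, 1]; m[j, 2] <- m[j + 1, 2]; m[j, 3] <- m[j + 1, 3]
    }
    m[seq_len(l), , drop = FALSE]
  }
  unwound_sum <- function(m, i) {
    l <- nrow(m) - 1L
    n <- m[l + 1, 4]
    o <- m[i, 3]; z <- m[i, 2]
    tot <- 0
    for (j in l:1) {
      if (o != 0) {
        t <- n * (l + 1) / (j * o)
        tot <- tot + t
        n <- m[j, 4] - t * z * (l + 1 - j) / (l + 1)
      } else {
        tot <- tot + m[j, 4] * (l + 1) / (z * (l + 1 - j))
      }
    }
    tot
  }

  recurse <- function(node, m, pz, po, pi) {
    m <- extend(m, pz, po, pi)
    if (tr$leaf[node]) {
      if (nrow(m) > 1) {
        for (i in 2:nrow(m)) {
          w <- unwound_sum(m, i)
          fi <- m[i, 1]
          phi[fi] <<- phi[fi] + w * (m[i, 3] - m[i, 2]) * tr$value[node]
        }
      }
      return(invisible(NULL))
    }
    f <- tr$fidx[node]
    hot <- if (x[f] < tr$split[node]) tr$left[node] else tr$right[node]
    cold <- if (hot == tr$left[node]) tr$right[node] else tr$left[node]
    iz <- 1; io <- 1
    if (nrow(m) > 1) {
      prev <- which(m[-1, 1] == f) + 1L
      if (length(prev) > 0) {
        k <- prev[1]
        iz <- m[k, 2]; io <- m[k, 3]
        m <- unwind(m, k)
      }
    }
    rc <- tr$cover[node]
    recurse(hot, m, tr$cover[hot] / rc * iz, io, f)
    recurse(cold, m, tr$cover[cold] / rc * iz, 0, f)
    invisible(NULL)
  }

  m0 <- matrix(numeric(0), 0, 4)
  recurse(1L, m0, 1, 1, 0L)
  phi
}

# Shapley attributions for all samples/classes of a multiclass booster,
# in double precision: phi (n x p x n_class), base values, and margins
# recomputed in double from the tree structure.
booster_treeshap <- function(booster, m, class_levels) {
  m <- matrix(as_float32(m), nrow(m), ncol(m), dimnames = dimnames(m))
  p <- ncol(m); n <- nrow(m)
  parsed <- parse_booster_trees(booster)
  nc <- length(class_levels)
  base <- rep(parsed$base_score, nc)
  phi <- array(0, c(n, p, nc))
  margins <- matrix(parsed$base_score, n, nc)
  for (t in seq_along(parsed$trees)) {
    tr <- parsed$trees[[t]]
    cl <- parsed$tree_class[t]
    base[cl] <- base[cl] + tree_expected_value(tr)
    for (i in seq_len(n)) {
      x <- m[i, ]
      phi[i, , cl] <- phi[i, , cl] + tree_shap_one(tr, x, p)
      margins[i, cl] <- margins[i, cl] + tree_value(tr, x)
    }
  }
  list(phi = phi, base = setNames(base, class_levels), margins = margins)
}
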