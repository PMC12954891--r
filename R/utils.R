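#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate cor dist kmeans median pf predict quantile
#'   rnorm runif sd var setNames
#' @importFrom utils head read.csv write.csv
NULL

# Derive a reproducible child seed from a parent seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 69091 + h * 101 + 17) %% 2147483629)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Population standard deviation (divides by n, not n - 1).
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Canonical HER2 class labels, in fixed order.
her2_levels <- function() c("zero", "low", "positive")

as_her2_factor <- function(x) {
  f <- factor(as.character(x), levels = her2_levels())
  if (anyNA(f)) stop("HER2 labels must be one of: ", paste(her2_levels(), collapse = ", "))
  f
}

# Content hash of an arbitrary R object (via serialization to a temp file).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
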