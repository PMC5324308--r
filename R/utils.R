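# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All user-facing randomized operations take an explicit `seed` and run
#' through this helper, so they are deterministic and never disturb the
#' global RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Keeps independent pipeline stages on independent, reproducible RNG
#' substreams while everything flows from one master seed.
#' @noRd
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629)
}

# Two-sided binomial p-value: twice the smaller tail, capped at 1.
# Vectorized over x/n; used by the differential-island and DE tests.
binom_p_two_sided <- function(x, n, p) {
  lo <- stats::pbinom(x, n, p)
  hi <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
  out <- pmin(1, 2 * pmin(lo, hi))
  out[n == 0] <- 1
  out
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
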