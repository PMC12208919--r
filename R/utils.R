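# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and a label
#'
#' All stochastic stages derive their own seed from one master seed plus a
#' stage/sample label, so reordering samples or stages never changes any
#' individual draw.
#'
#' @param seed master integer seed.
#' @param tag character label of the substream (e.g. a sample id).
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(paste(tag, collapse = "/"))
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 1000003 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  force(expr)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Check a scalar count-ish argument.
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_fmt("`%s` must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}
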