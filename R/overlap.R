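#' Morisita-Horn similarity between two repertoires
#'
#' Abundance-weighted similarity on the union clonotype set: with proportions
#' \eqn{p_i = x_i/X} and \eqn{q_i = y_i/Y},
#' \deqn{C_{MH} = \frac{2\sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}.}
#' The index is 0 for disjoint repertoires, 1 when the proportion vectors are
#' equal, and invariant to rescaling either vector.
#'
#' @param x,y nonnegative numeric vectors of equal length, aligned on the
#'   union of clonotypes (absent clonotype = 0); both must have positive
#'   totals.
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' morisita_horn(c(3, 1, 0), c(1, 3, 0))  # 0.6
morisita_horn <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop_fmt("counts must be nonnegative")
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop_fmt("Morisita-Horn is undefined for an empty sample")
  p <- x / X; q <- y / Y
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

#' All pairwise Morisita-Horn comparisons of an abundance table
#'
#' Computes the full symmetric similarity matrix and partitions the unordered
#' sample pairs into within-group and between-group categories using a sample
#' metadata column (e.g. genotype); a 3+3 design yields 3 + 3 within pairs and
#' 9 between pairs, a 4+4 design 6 + 6 and 16.
#'
#' @param table an [abundance_table()].
#' @param group_by name of the grouping column in `table$samples`
#'   (default `"group"`).
#' @return an object of class `overlap_matrix`: list with `matrix` (unit
#'   diagonal, symmetric), `pairs` (long data frame: sample_a, sample_b,
#'   category, value) and `group_by`.
#' @export
pairwise_overlap <- function(table, group_by = "group") {
  stopifnot(inherits(table, "abundance_table"))
  ids <- table$samples$sample_id
  if (length(ids) < 2L) {
    warn_fmt("fewer than 2 samples: no pairs to compare")
  }
  groups <- table$samples[[group_by]]
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  pairs <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        v <- morisita_horn(table$counts[, i], table$counts[, j])
        m[i, j] <- m[j, i] <- v
        cat_ij <- if (!is.na(groups[i]) && !is.na(groups[j]) &&
                      groups[i] == groups[j]) {
          paste0("within:", groups[i])
        } else "between"
        pairs[[length(pairs) + 1L]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j], category = cat_ij, value = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else {
    data.frame(sample_a = character(), sample_b = character(),
               category = character(), value = numeric())
  }
  structure(list(matrix = m, pairs = pairs, group_by = group_by),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap_matrix: %d samples, %d pairs\n", nrow(x$matrix),
              nrow(x$pairs)))
  if (nrow(x$pairs)) {
    means <- tapply(x$pairs$value, x$pairs$category, mean)
    for (k in names(means)) cat(sprintf("  mean %s = %.4f\n", k, means[k]))
  }
  invisible(x)
}
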