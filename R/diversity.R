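#' Hill-number diversity of an abundance vector
#'
#' Treats each unique cDNA molecule as an individual and each clonotype as a
#' species. For order `q != 1` the effective number of clonotypes is
#' \deqn{{}^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}
#' over nonzero clonotype proportions \eqn{p_i}; at `q = 1` it is the
#' exponential of Shannon entropy, \eqn{\exp(-\sum_i p_i \log p_i)}, the
#' continuous limit. `q = 0` gives richness and `q = 2` the inverse Simpson
#' concentration. `0 log 0` is taken as 0.
#'
#' @param x nonnegative numeric vector of clonotype counts.
#' @param q Hill order, a single nonnegative real (default 1, Shannon
#'   diversity).
#' @return the effective number of clonotypes, a number in `[1, S_obs]`.
#' @export
#' @examples
#' hill_diversity(c(1, 1, 1, 1))      # 4 equally abundant clonotypes
#' hill_diversity(c(2, 1, 1), q = 2)  # inverse Simpson
hill_diversity <- function(x, q = 1) {
  stopifnot(is.numeric(x), is.numeric(q), length(q) == 1L, q >= 0)
  x <- x[!is.na(x) & x > 0]
  n <- sum(x)
  if (length(x) == 0L || n <= 0) {
    stop_fmt("diversity is undefined for an empty abundance vector")
  }
  p <- x / n
  if (abs(q - 1) < 1e-12) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

# Draw one subsample of exactly m molecules without replacement
# (multivariate hypergeometric) and return its per-clonotype counts.
subsample_counts <- function(x, m) {
  idx <- sample.int(sum(x), m)
  breaks <- c(0, cumsum(x))
  tabulate(findInterval(idx, breaks, left.open = TRUE), nbins = length(x))
}

#' Monte-Carlo rarefied diversity at one subsample size
#'
#' Draws `reps` subsamples of exactly `m` molecules without replacement from
#' the observed sample and evaluates [hill_diversity()] on each; used to
#' assess whether sequencing depth saturates diversity. Extrapolation beyond
#' the observed depth is out of scope.
#'
#' @param x nonnegative integer vector of clonotype counts.
#' @param m subsample size, `0 < m <= sum(x)`.
#' @param reps number of Monte-Carlo replicates (default 100).
#' @param seed optional integer seed; the result is deterministic given the
#'   seed and does not disturb the global RNG state.
#' @param q Hill order (default 1).
#' @return list with `mean` and `se` (standard error over replicates).
#' @export
rarefied_diversity <- function(x, m, reps = 100, seed = NULL, q = 1) {
  x <- as.integer(round(x))
  n <- sum(x)
  if (n <= 0) stop_fmt("empty abundance vector")
  assert_count(m, "m", min = 1L)
  if (m > n) stop_fmt("subsample size m = %d exceeds sample size n = %d", m, n)
  assert_count(reps, "reps", min = 1L)
  x <- x[x > 0]
  d <- with_seed(seed, vapply(seq_len(reps), function(i) {
    hill_diversity(subsample_counts(x, m), q = q)
  }, numeric(1)))
  list(mean = mean(d), se = stats::sd(d) / sqrt(reps))
}

#' Rarefaction curve over a grid of subsample sizes
#'
#' @param x nonnegative integer vector of clonotype counts.
#' @param grid increasing vector of subsample sizes, all `<= sum(x)`.
#' @param reps,seed,q as in [rarefied_diversity()]; each grid point uses an
#'   independent, reproducible substream of the seed.
#' @return data frame with columns `m`, `mean`, `se`; when the grid includes
#'   `sum(x)`, that point equals the observed diversity with zero SE.
#' @export
rarefaction_curve <- function(x, grid, reps = 100, seed = NULL, q = 1) {
  if (is.unsorted(grid)) stop_fmt("rarefaction grid must be sorted")
  rows <- lapply(seq_along(grid), function(i) {
    s <- if (is.null(seed)) NULL else substream_seed(seed, sprintf("m=%d", grid[i]))
    r <- rarefied_diversity(x, grid[i], reps = reps, seed = s, q = q)
    data.frame(m = grid[i], mean = r$mean, se = r$se)
  })
  do.call(rbind, rows)
}

#' Good-Turing sample coverage
#'
#' Estimated sample completeness: the fraction of molecules in the sampled
#' community that belong to clonotypes detected in the sample, from the
#' bias-corrected Good-Turing form
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' with \eqn{f_1, f_2} the singleton and doubleton counts. With no singletons
#' the estimate is 1; with singletons but no doubletons it degrades to
#' \eqn{1 - f_1/n}.
#'
#' @param x nonnegative integer vector of clonotype counts.
#' @return coverage estimate in `[0, 1]`.
#' @export
sample_coverage <- function(x) {
  x <- as.integer(round(x))
  x <- x[x > 0]
  n <- sum(x)
  if (n <= 0) stop_fmt("coverage is undefined for an empty sample")
  f1 <- sum(x == 1L)
  f2 <- sum(x == 2L)
  if (f1 == 0L) return(1)
  1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
}

#' Relative diversity against a reference sample set
#'
#' Divides each sample's observed diversity by the mean diversity of a
#' reference sample set (typically the control genotype), giving unit-free
#' summaries once coverage is effectively complete.
#'
#' @param values named numeric vector of per-sample diversities.
#' @param reference_ids names of the reference samples (nonempty subset of
#'   `names(values)`).
#' @return named numeric vector of normalised diversities.
#' @export
relative_diversity <- function(values, reference_ids) {
  stopifnot(!is.null(names(values)))
  if (length(reference_ids) == 0L) stop_fmt("reference set must be nonempty")
  missing <- setdiff(reference_ids, names(values))
  if (length(missing)) {
    stop_fmt("reference sample(s) not found: %s", paste(missing, collapse = ", "))
  }
  ref <- mean(values[reference_ids])
  if (!is.finite(ref) || ref == 0) stop_fmt("reference mean diversity is zero")
  values / ref
}

#' Per-sample diversity summary of an abundance table
#'
#' @param table an [abundance_table()].
#' @param q Hill order (default 1).
#' @param grid optional rarefaction grid; `"auto:k"` gives `k` log-spaced
#'   points up to each sample's depth.
#' @param reps,seed passed to [rarefaction_curve()].
#' @return list with `summary` (data frame: sample_id, n, S_obs, D_obs,
#'   coverage) and `curves` (long data frame of rarefaction points, or NULL).
#' @export
diversity_summary <- function(table, q = 1, grid = NULL, reps = 100,
                              seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- table$samples$sample_id
  summ <- do.call(rbind, lapply(ids, function(id) {
    x <- table$counts[, id]
    data.frame(sample_id = id, n = sum(x), S_obs = sum(x > 0),
               D_obs = hill_diversity(x, q = q),
               coverage = sample_coverage(x), stringsAsFactors = FALSE)
  }))
  curves <- NULL
  if (!is.null(grid)) {
    curves <- do.call(rbind, lapply(ids, function(id) {
      x <- table$counts[, id]
      g <- resolve_grid(grid, sum(x))
      s <- if (is.null(seed)) NULL else substream_seed(seed, id)
      cbind(sample_id = id, rarefaction_curve(x, g, reps = reps, seed = s,
                                              q = q))
    }))
  }
  list(summary = summ, curves = curves)
}

# "auto:k" -> k log-spaced depths up to n; otherwise validate a numeric grid.
resolve_grid <- function(grid, n) {
  if (is.character(grid) && grepl("^auto:\\d+$", grid)) {
    k <- as.integer(sub("^auto:", "", grid))
    unique(pmax(1L, round(exp(seq(log(max(n %/% 50, 1)), log(n),
                                  length.out = k)))))
  } else {
    g <- sort(unique(as.integer(grid)))
    g[g <= n]
  }
}
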