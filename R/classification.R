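# Set-theoretic clonotype classifiers: recurrence, condition dependence,
# natural-CD5 subrepertoires, cross-assignment, top-k expansion, public
# paired clones, subrepertoire diversity.

# Presence matrix: clonotype x sample logicals at a UMI floor.
presence_matrix <- function(table, min_umi = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  assert_count(min_umi, "min_umi", min = 1L)
  table$counts >= min_umi
}

# Resolve sample ids for a group label (or pass through explicit ids).
group_sample_ids <- function(table, group) {
  ids <- table$samples$sample_id
  if (all(group %in% ids)) return(group)
  hit <- ids[!is.na(table$samples$group) & table$samples$group %in% group]
  if (length(hit) == 0L) stop_fmt("no samples match group '%s'",
                                  paste(group, collapse = ","))
  hit
}

#' Recurrent clonotypes
#'
#' A clonotype is recurrent when it is detected (at least `min_umi` molecules)
#' in at least `min_samples` of all samples, regardless of group. The default
#' of 3 matches a design with three replicates per condition, where recurrence
#' demands detection beyond a single replicate set.
#'
#' @param table an [abundance_table()].
#' @param min_samples minimum number of samples with detection (default 3).
#' @param min_umi detection floor in molecules per sample (default 1).
#' @return character vector of recurrent clonotype keys (row names of the
#'   table).
#' @export
recurrent_clonotypes <- function(table, min_samples = 3L, min_umi = 1L) {
  assert_count(min_samples, "min_samples", min = 1L)
  if (ncol(table$counts) < min_samples) {
    stop_fmt("table has %d samples but min_samples = %d", ncol(table$counts),
             min_samples)
  }
  pres <- presence_matrix(table, min_umi)
  rownames(pres)[rowSums(pres) >= min_samples]
}

#' Classify recurrent clonotypes by condition dependence
#'
#' Partitions a recurrent clonotype set into three disjoint classes based on
#' detection across two sample groups: `dependent` clonotypes are detected in
#' at least one group-A sample and in no group-B sample (selected only under
#' condition A), `newcomer` clonotypes show the mirror pattern, and `shared`
#' clonotypes are detected in at least one sample of each group. The partition
#' identity `|A-recurrent| + |B-recurrent| - |shared| = |recurrent|` holds by
#' construction.
#'
#' @param table an [abundance_table()].
#' @param recurrent character vector of clonotype keys (subset of the table's
#'   rows), e.g. from [recurrent_clonotypes()].
#' @param group_a,group_b group labels (matched against `table$samples$group`)
#'   or explicit sample id vectors; must be disjoint and nonempty.
#' @param min_umi detection floor (default 1).
#' @return an object of class `dependence_labels`: list with `labels` (named
#'   factor over `recurrent` with levels dependent/shared/newcomer), `sets`
#'   (the three key sets plus `recurrent_a`, `recurrent_b`), and the group
#'   sample ids.
#' @export
classify_dependence <- function(table, recurrent, group_a, group_b,
                                min_umi = 1L) {
  ids_a <- group_sample_ids(table, group_a)
  ids_b <- group_sample_ids(table, group_b)
  if (length(intersect(ids_a, ids_b))) stop_fmt("groups overlap")
  if (length(ids_a) == 0L || length(ids_b) == 0L) stop_fmt("empty group")
  unknown <- setdiff(recurrent, rownames(table$counts))
  if (length(unknown)) {
    stop_fmt("recurrent set contains %d clonotype(s) absent from the table",
             length(unknown))
  }
  pres <- presence_matrix(table, min_umi)[recurrent, , drop = FALSE]
  in_a <- rowSums(pres[, ids_a, drop = FALSE]) > 0L
  in_b <- rowSums(pres[, ids_b, drop = FALSE]) > 0L
  lab <- ifelse(in_a & !in_b, "dependent",
                ifelse(!in_a & in_b, "newcomer", "shared"))
  labels <- factor(lab, levels = c("dependent", "shared", "newcomer"))
  names(labels) <- recurrent
  structure(list(
    labels = labels,
    sets = list(dependent = recurrent[lab == "dependent"],
                shared = recurrent[lab == "shared"],
                newcomer = recurrent[lab == "newcomer"],
                recurrent = recurrent,
                recurrent_a = recurrent[in_a],
                recurrent_b = recurrent[in_b]),
    group_a = ids_a, group_b = ids_b, min_umi = as.integer(min_umi)
  ), class = "dependence_labels")
}

#' @export
print.dependence_labels <- function(x, ...) {
  n <- vapply(x$sets[c("dependent", "shared", "newcomer")], length, integer(1))
  cat(sprintf(
    "dependence_labels: %d recurrent = %d dependent + %d shared + %d newcomer\n",
    length(x$sets$recurrent), n[1], n[2], n[3]))
  invisible(x)
}

#' Classify natural CD5-extreme clonotypes
#'
#' Given samples sorted from the two extremes of the CD5 spectrum, a clonotype
#' is a natural member of one extreme when it is detected in at least
#' `min_present` samples of that extreme and in none of the other extreme's
#' samples; everything else is unassigned. The two natural classes are
#' disjoint by construction.
#'
#' @param table an [abundance_table()] restricted to the CD5-sorted samples.
#' @param subset_lo,subset_hi subset labels (matched against
#'   `table$samples$subset`) or explicit sample id vectors.
#' @param min_present minimum detections within the home extreme (default 3,
#'   of a 4-replicate design).
#' @param min_umi detection floor (default 1).
#' @return object of class `cd5_labels`: named factor `labels` over all table
#'   clonotypes with levels natural_lo/natural_hi/unassigned, plus the two key
#'   sets.
#' @export
classify_cd5 <- function(table, subset_lo, subset_hi, min_present = 3L,
                         min_umi = 1L) {
  ids <- table$samples$sample_id
  pick <- function(lab) {
    if (all(lab %in% ids)) return(lab)
    hit <- ids[!is.na(table$samples$subset) & table$samples$subset %in% lab]
    if (length(hit) == 0L) stop_fmt("no samples match subset '%s'",
                                    paste(lab, collapse = ","))
    hit
  }
  ids_lo <- pick(subset_lo)
  ids_hi <- pick(subset_hi)
  if (length(intersect(ids_lo, ids_hi))) stop_fmt("subset labels overlap")
  assert_count(min_present, "min_present", min = 1L)
  if (length(ids_lo) < min_present || length(ids_hi) < min_present) {
    stop_fmt("each subset needs >= min_present = %d samples", min_present)
  }
  pres <- presence_matrix(table, min_umi)
  n_lo <- rowSums(pres[, ids_lo, drop = FALSE])
  n_hi <- rowSums(pres[, ids_hi, drop = FALSE])
  lab <- ifelse(n_lo >= min_present & n_hi == 0L, "natural_lo",
                ifelse(n_hi >= min_present & n_lo == 0L, "natural_hi",
                       "unassigned"))
  labels <- factor(lab, levels = c("natural_lo", "natural_hi", "unassigned"))
  names(labels) <- rownames(pres)
  structure(list(labels = labels,
                 sets = list(natural_lo = names(labels)[lab == "natural_lo"],
                             natural_hi = names(labels)[lab == "natural_hi"]),
                 subset_lo = ids_lo, subset_hi = ids_hi),
            class = "cd5_labels")
}

#' Cross-assign a clonotype set against dependence labels
#'
#' Matches query clonotypes (exact key match) into a labelled recurrent
#' inventory and summarises how the matched clones distribute over the
#' dependence classes. Fractions are reported both over matched clones and
#' over all query clones, since either denominator may be of interest when
#' part of the query is absent from the inventory.
#'
#' @param query character vector of clonotype keys (see [clonotype_key()]).
#' @param labels a `dependence_labels` object from [classify_dependence()].
#' @return list with `n_query`, `n_matched`, `n_unmatched`, `counts` (per
#'   class), `fraction_matched` (class counts / matched) and `fraction_all`
#'   (class counts / query size).
#' @export
cross_assign <- function(query, labels) {
  stopifnot(inherits(labels, "dependence_labels"))
  query <- unique(query)
  if (length(query) == 0L) stop_fmt("empty query clonotype set")
  hit <- query[query %in% names(labels$labels)]
  if (length(hit) == 0L) warn_fmt("no query clonotype matched the inventory")
  cls <- labels$labels[hit]
  counts <- table(cls)
  list(n_query = length(query),
       n_matched = length(hit),
       n_unmatched = length(query) - length(hit),
       counts = c(counts),
       fraction_matched = if (length(hit)) c(counts) / length(hit) else
         stats::setNames(rep(NA_real_, nlevels(cls)), levels(cls)),
       fraction_all = c(counts) / length(query))
}

#' Top expanded clonotypes by relative frequency
#'
#' Ranks clonotypes by their mean relative frequency across the table's
#' samples (or by pooled frequency with `pooled = TRUE`) and returns the top
#' `k`. Ties at the cut are broken deterministically by lexicographic
#' clonotype key.
#'
#' @param table an [abundance_table()] of the expanded population.
#' @param k number of clonotypes to return (default 10).
#' @param pooled rank by frequency in the pooled counts instead of the mean of
#'   per-sample frequencies (default FALSE).
#' @return data frame: key, v_gene, j_gene, cdr3_aa, per-sample frequency
#'   columns, `mean_freq`, ordered by rank.
#' @export
top_expanded <- function(table, k = 10L, pooled = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  assert_count(k, "k", min = 1L)
  freqs <- sweep(table$counts, 2, pmax(colSums(table$counts), 1L), "/")
  score <- if (pooled) {
    rowSums(table$counts) / max(sum(table$counts), 1L)
  } else {
    rowMeans(freqs)
  }
  if (k > nrow(freqs)) {
    warn_fmt("k = %d exceeds the %d clonotypes available; returning all", k,
             nrow(freqs))
    k <- nrow(freqs)
  }
  ord <- order(-score, rownames(freqs), method = "radix")
  top <- ord[seq_len(k)]
  out <- cbind(key = rownames(freqs)[top], table$clonotypes[top, ],
               as.data.frame(freqs[top, , drop = FALSE]),
               mean_freq = score[top])
  rownames(out) <- NULL
  out
}

#' Public paired clonotypes shared between two genotypes
#'
#' Intersects the union-over-mice paired clonotype sets of two groups and
#' reports, per shared (public) clonotype, the number of mice of each group in
#' which it was detected.
#'
#' @param sets a `paired_sets` object from [aggregate_paired()].
#' @param group_a,group_b the two group labels in `sets$mice$group`.
#' @return data frame of shared clonotypes with `n_mice_a` and `n_mice_b`
#'   columns (zero rows when the intersection is empty).
#' @export
public_paired <- function(sets, group_a, group_b) {
  stopifnot(inherits(sets, "paired_sets"))
  mice_a <- sets$mice$mouse_id[sets$mice$group == group_a]
  mice_b <- sets$mice$mouse_id[sets$mice$group == group_b]
  if (length(mice_a) == 0L || length(mice_b) == 0L) {
    warn_fmt("a group has no mice; intersection is empty")
  }
  n_a <- rowSums(sets$presence[, mice_a, drop = FALSE])
  n_b <- rowSums(sets$presence[, mice_b, drop = FALSE])
  shared <- which(n_a > 0L & n_b > 0L)
  out <- sets$clonotypes[shared, setdiff(names(sets$clonotypes), "n_mice"),
                         drop = FALSE]
  out$n_mice_a <- n_a[shared]
  out$n_mice_b <- n_b[shared]
  rownames(out) <- NULL
  out
}

#' Per-sample diversity of a clonotype subrepertoire
#'
#' Restricts the abundance table to a clonotype subset (e.g. the dependent
#' clones) and computes each sample's Hill diversity on the restriction.
#' Samples with no molecules in the subset get `NA` (undefined diversity).
#'
#' @param table an [abundance_table()].
#' @param subset nonempty character vector of clonotype keys.
#' @param q Hill order (default 1).
#' @return named numeric vector of per-sample diversities (NA where the
#'   restriction is empty).
#' @export
subrepertoire_diversity <- function(table, subset, q = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(subset) == 0L) stop_fmt("empty clonotype subset")
  keys <- intersect(subset, rownames(table$counts))
  if (length(keys) == 0L) stop_fmt("no subset clonotype is present in the table")
  sub <- table$counts[keys, , drop = FALSE]
  vapply(table$samples$sample_id, function(id) {
    x <- sub[, id]
    if (sum(x) == 0) NA_real_ else hill_diversity(x, q = q)
  }, numeric(1))
}
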