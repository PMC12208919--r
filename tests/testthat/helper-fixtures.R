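# Fixture builders and independent oracles shared across tests.

# Minimal abundance table from a counts matrix; clonotype keys are generated
# as distinct (V, J, CDR3) triples unless supplied.
make_table <- function(counts, groups = NULL, subsets = NULL,
                       clonotypes = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(clonotypes)) {
    clonotypes <- data.frame(
      v_gene = paste0("TRAV", seq_len(n)),
      j_gene = paste0("TRAJ", seq_len(n)),
      cdr3_aa = sprintf("CAAS%02dF", seq_len(n)),
      stringsAsFactors = FALSE
    )
  }
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("s", seq_len(ncol(counts)))
  samples <- data.frame(
    sample_id = ids,
    group = groups %||% rep(NA_character_, ncol(counts)),
    subset = subsets %||% rep(NA_character_, ncol(counts)),
    replicate = seq_len(ncol(counts)),
    stringsAsFactors = FALSE
  )
  abundance_table(counts, clonotypes, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a rearrangement TSV from a data frame of reads (row order preserved).
write_reads_tsv <- function(reads, path = tempfile(fileext = ".tsv")) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

reads_row <- function(sample_id = "s1", umi = "u1", v_call = "TRAV1",
                      j_call = "TRAJ1", junction_aa = "CAASF",
                      productive = "TRUE", ...) {
  data.frame(sample_id = sample_id, umi = umi, v_call = v_call,
             j_call = j_call, junction_aa = junction_aa,
             productive = productive, ..., stringsAsFactors = FALSE)
}

# Exact expected rarefied Hill diversity by exhaustive enumeration of all
# C(n, m) subsamples (feasible for n <= 12). Independent of the package's
# Monte-Carlo path: works on explicit individual labels.
exact_rarefied_diversity <- function(x, m, q = 1) {
  individuals <- rep(seq_along(x), x)
  subs <- combn(length(individuals), m)
  vals <- apply(subs, 2, function(idx) {
    hill_diversity(tabulate(individuals[idx], nbins = length(x)), q = q)
  })
  mean(vals)
}
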