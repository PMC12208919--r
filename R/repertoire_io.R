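#' Canonical clonotype key
#'
#' A bulk TCR-alpha clonotype is the unique combination of a V gene, a J gene
#' and an in-frame CDR3 amino-acid sequence. Equality is exact string equality
#' of the three fields; the key string is used as row identifier throughout.
#'
#' @param v_gene,j_gene,cdr3_aa character vectors (recycled to common length).
#' @return character vector of keys.
#' @export
#' @examples
#' clonotype_key("TRAV14-1", "TRAJ33", "CAASDSNYQLIW")
clonotype_key <- function(v_gene, j_gene, cdr3_aa) {
  paste(v_gene, j_gene, cdr3_aa, sep = "|")
}

# Order consistent with lexicographic order on the (v, j, cdr3) tuple.
order_clonotypes <- function(v_gene, j_gene, cdr3_aa) {
  order(v_gene, j_gene, cdr3_aa, method = "radix")
}

#' Normalise gene call strings
#'
#' Gene calls are upper-cased and allele suffixes are stripped
#' (`"TRAV14-1*01" -> "TRAV14-1"`). Multi-valued calls (comma-separated, as
#' produced for paralog-ambiguous alignments) are de-duplicated and sorted so
#' that the same ambiguity always yields the same key.
#'
#' @param calls character vector of gene call strings, possibly comma-separated.
#' @return character vector of normalised call strings.
#' @export
normalize_gene_calls <- function(calls) {
  vapply(strsplit(toupper(trimws(calls)), ",", fixed = TRUE), function(g) {
    g <- sub("\\*.*$", "", trimws(g))
    paste(sort(unique(g[nzchar(g)])), collapse = ",")
  }, character(1))
}

airr_required_cols <- c("sample_id", "umi", "v_call", "j_call", "junction_aa",
                        "productive")
airr_junction_cols <- c("v_deletions", "j_deletions", "p_additions",
                        "n_additions")

#' Read an AIRR-style rearrangement table
#'
#' Reads a tab-separated rearrangement file with one annotated read per row.
#' Required columns: `sample_id`, `umi`, `v_call`, `j_call`, `junction_aa`
#' (alias `cdr3_aa` accepted), `productive`. Optional junction columns
#' (`v_deletions`, `j_deletions`, `p_additions`, `n_additions`) are carried
#' through when present and reported as `NA` otherwise. The reader does not
#' deduplicate UMIs; collapsing to unique molecules happens in
#' [aggregate_bulk()].
#'
#' @param path path to a TSV file.
#' @return a data frame of annotated reads with normalised gene calls and the
#'   derived columns `n_v_calls` and `paralog_ambiguous`.
#' @seealso [aggregate_bulk()]
#' @export
read_rearrangements <- function(path) {
  if (!file.exists(path)) stop_fmt("rearrangement file not found: %s", path)
  reads <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
  if ("cdr3_aa" %in% names(reads) && !"junction_aa" %in% names(reads)) {
    names(reads)[names(reads) == "cdr3_aa"] <- "junction_aa"
  }
  missing <- setdiff(airr_required_cols, names(reads))
  if (length(missing)) {
    stop_fmt("rearrangement file is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  if (nrow(reads) == 0L) {
    reads <- reads[, union(airr_required_cols, intersect(airr_junction_cols, names(reads))),
                   drop = FALSE]
  }
  bad <- which(!nzchar(reads$umi) | !nzchar(reads$sample_id))
  if (length(bad)) stop_fmt("unreadable row %d: empty sample_id or umi", bad[1])
  prod <- tolower(reads$productive) %in% c("t", "true", "1", "yes")
  out <- data.frame(
    sample_id = reads$sample_id,
    umi = reads$umi,
    v_call = normalize_gene_calls(reads$v_call),
    j_call = normalize_gene_calls(reads$j_call),
    cdr3_aa = toupper(trimws(reads$junction_aa)),
    productive = prod,
    stringsAsFactors = FALSE
  )
  out$n_v_calls <- lengths(strsplit(out$v_call, ",", fixed = TRUE))
  out$paralog_ambiguous <- out$n_v_calls > 1L
  for (col in airr_junction_cols) {
    out[[col]] <- if (col %in% names(reads)) {
      suppressWarnings(as.integer(reads[[col]]))
    } else rep(NA_integer_, nrow(reads))
  }
  out
}

#' Construct a clonotype abundance table
#'
#' Low-level constructor used by [aggregate_bulk()] and [read_abundance()].
#' Rows are clonotypes (keyed by [clonotype_key()]), columns are samples, and
#' entries count unique cDNA molecules (UMIs). All-zero clonotype rows are
#' dropped.
#'
#' @param counts integer matrix, clonotypes x samples.
#' @param clonotypes data frame with columns `v_gene`, `j_gene`, `cdr3_aa`
#'   aligned with the rows of `counts`.
#' @param samples data frame with columns `sample_id` and optionally `group`,
#'   `subset`, `replicate`, aligned with the columns of `counts`.
#' @param paralog_excluded optional named numeric vector: per-sample fraction
#'   of molecules excluded as paralog-ambiguous during aggregation.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, clonotypes, samples,
                            paralog_excluded = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop_fmt("counts must be nonnegative integers")
  }
  stopifnot(nrow(counts) == nrow(clonotypes), ncol(counts) == nrow(samples))
  if (anyDuplicated(samples$sample_id)) stop_fmt("duplicate sample_id")
  samples$sample_id <- as.character(samples$sample_id)
  for (col in c("group", "subset")) {
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
    samples[[col]] <- as.character(samples[[col]])
  }
  if (is.null(samples$replicate)) samples$replicate <- seq_len(nrow(samples))
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  clonotypes <- clonotypes[keep, , drop = FALSE]
  key <- clonotype_key(clonotypes$v_gene, clonotypes$j_gene, clonotypes$cdr3_aa)
  if (anyDuplicated(key)) stop_fmt("duplicate clonotype keys in table")
  ord <- order_clonotypes(clonotypes$v_gene, clonotypes$j_gene,
                          clonotypes$cdr3_aa)
  counts <- counts[ord, , drop = FALSE]
  clonotypes <- clonotypes[ord, , drop = FALSE]
  rownames(counts) <- key[ord]
  colnames(counts) <- samples$sample_id
  rownames(clonotypes) <- NULL
  rownames(samples) <- NULL
  structure(list(counts = counts,
                 clonotypes = clonotypes[, c("v_gene", "j_gene", "cdr3_aa")],
                 samples = samples,
                 paralog_excluded = paralog_excluded),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d clonotypes x %d samples (%d molecules)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  grp <- table(x$samples$group, useNA = "no")
  if (length(grp)) {
    cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Aggregate annotated reads into a clonotype abundance table
#'
#' Reads are first collapsed to unique molecules by exact `(sample_id, umi)`
#' match (one UMI = one cDNA molecule). When reads within a UMI group disagree
#' on the clonotype, the majority clonotype wins and ties break to the
#' lexicographically smallest `(v, j, cdr3)` tuple; the conflict rate is
#' recorded in the `umi_conflict_rate` attribute. Each unique molecule then
#' contributes exactly 1 to one clonotype count.
#'
#' Paralog-ambiguous molecules (more than one V call) are kept by default,
#' keyed by the sorted comma-joined V-call string, and the per-sample excluded
#' fraction is reported when `drop_paralog_ambiguous = TRUE`; downstream
#' gene-position and junction analyses exclude them regardless.
#'
#' @param reads data frame of annotated reads as from [read_rearrangements()].
#' @param samples optional sample metadata data frame (`sample_id`, `group`,
#'   `subset`, `replicate`). When supplied, reads carrying unknown sample ids
#'   are an error; when omitted, metadata is derived from the reads.
#' @param productive_only drop non-productive reads first (default `TRUE`).
#' @param drop_paralog_ambiguous exclude paralog-ambiguous molecules from the
#'   table and report the excluded fraction per sample (default `FALSE`).
#' @return an [abundance_table()].
#' @export
aggregate_bulk <- function(reads, samples = NULL, productive_only = TRUE,
                           drop_paralog_ambiguous = FALSE) {
  stopifnot(is.data.frame(reads))
  if (!is.null(samples)) {
    unknown <- setdiff(unique(reads$sample_id), samples$sample_id)
    if (length(unknown)) {
      stop_fmt("reads reference unknown sample id(s): %s",
               paste(unknown, collapse = ", "))
    }
  }
  if (productive_only) reads <- reads[reads$productive, , drop = FALSE]
  bad <- reads$productive & !nzchar(reads$cdr3_aa)
  if (any(bad)) stop_fmt("productive read with empty cdr3_aa (row %d)",
                         which(bad)[1])
  key <- clonotype_key(reads$v_call, reads$j_call, reads$cdr3_aa)

  # UMI collapse: majority clonotype per (sample, umi), ties to smallest key.
  mol_id <- paste(reads$sample_id, reads$umi, sep = "\r")
  grp <- split(seq_len(nrow(reads)), mol_id)
  n_conflict <- 0L
  pick <- vapply(grp, function(idx) {
    if (length(idx) == 1L) return(idx)
    k <- key[idx]
    if (length(unique(k)) > 1L) n_conflict <<- n_conflict + 1L
    tab <- table(k)
    winners <- names(tab)[tab == max(tab)]
    win <- sort(winners)[1]
    idx[match(win, k)]
  }, integer(1))
  mols <- reads[pick, , drop = FALSE]
  mkey <- key[pick]

  excluded <- c(table(factor(mols$sample_id[mols$paralog_ambiguous],
                             levels = unique(mols$sample_id))))
  totals <- c(table(factor(mols$sample_id, levels = unique(mols$sample_id))))
  if (drop_paralog_ambiguous) {
    keep <- !mols$paralog_ambiguous
    mols <- mols[keep, , drop = FALSE]
    mkey <- mkey[keep]
  }

  if (is.null(samples)) {
    samples <- data.frame(sample_id = unique(reads$sample_id),
                          stringsAsFactors = FALSE)
  }
  ckeys <- sort(unique(mkey))
  counts <- matrix(0L, length(ckeys), nrow(samples),
                   dimnames = list(ckeys, samples$sample_id))
  if (length(mkey)) {
    tab <- table(factor(mkey, levels = ckeys),
                 factor(mols$sample_id, levels = samples$sample_id))
    counts[] <- as.integer(tab)
  }
  parts <- do.call(rbind, strsplit(ckeys, "|", fixed = TRUE))
  clonos <- if (length(ckeys)) {
    data.frame(v_gene = parts[, 1], j_gene = parts[, 2], cdr3_aa = parts[, 3],
               stringsAsFactors = FALSE)
  } else {
    data.frame(v_gene = character(), j_gene = character(),
               cdr3_aa = character())
  }
  frac <- excluded / pmax(totals, 1L)
  tab <- abundance_table(counts, clonos, samples,
                         paralog_excluded = frac[samples$sample_id])
  attr(tab, "umi_conflict_rate") <- n_conflict / max(length(grp), 1L)
  tab
}

#' Write / read an abundance table as TSV
#'
#' The on-disk format is a plain TSV whose first three columns are `v_gene`,
#' `j_gene` and `cdr3_aa`, followed by one integer column per sample. Sample
#' metadata travel in `#`-prefixed header lines (`# group=`, `# subset=`,
#' `# replicate=`), so `read_abundance(write_abundance(x))` is the identity.
#'
#' @param table an [abundance_table()].
#' @param path output/input path.
#' @return `write_abundance` returns `path` invisibly; `read_abundance`
#'   returns an [abundance_table()].
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  s <- table$samples
  hdr <- c(
    sprintf("# group=%s", paste(ifelse(is.na(s$group), "", s$group), collapse = ",")),
    sprintf("# subset=%s", paste(ifelse(is.na(s$subset), "", s$subset), collapse = ",")),
    sprintf("# replicate=%s", paste(s$replicate, collapse = ","))
  )
  body <- cbind(table$clonotypes,
                as.data.frame(table$counts, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop_fmt("abundance file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ([a-z_]+)=.*$", "\\1", h)
    meta[[kv]] <- strsplit(sub("^# [a-z_]+=", "", h), ",", fixed = TRUE)[[1]]
  }
  body <- utils::read.delim(text = lines[!startsWith(lines, "# ")], sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("v_gene", "j_gene", "cdr3_aa")
  if (!all(need %in% names(body))) {
    stop_fmt("abundance file must start with columns v_gene, j_gene, cdr3_aa")
  }
  scols <- setdiff(names(body), need)
  counts <- as.matrix(body[, scols, drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop_fmt("abundance counts must be nonnegative integers")
  }
  n <- length(scols)
  pad <- function(x) {
    x <- as.character(x %||% character())
    length(x) <- n
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    x
  }
  samples <- data.frame(
    sample_id = scols,
    group = pad(meta$group),
    subset = pad(meta$subset),
    replicate = as.integer(pad(meta$replicate %||% seq_len(n))),
    stringsAsFactors = FALSE
  )
  abundance_table(counts, body[, need], samples)
}

#' Aggregate paired single-cell clonotypes per mouse
#'
#' Paired-chain clonotypes are defined at the amino-acid level (V region, CDR3
#' and J region of both chains); only cells with both chains in frame are
#' retained. Within a mouse, duplicate clonotypes collapse to one, so every
#' clonotype is counted once per mouse; the result records, per clonotype, the
#' set of mice (and their genotype groups) where it was seen.
#'
#' @param cells data frame with columns `mouse_id`, `group`, `alpha_v`,
#'   `alpha_cdr3`, `alpha_j`, `beta_v`, `beta_cdr3`, `beta_j`,
#'   `in_frame_alpha`, `in_frame_beta`.
#' @return an object of class `paired_sets`: a list with `clonotypes` (one row
#'   per distinct paired clonotype), `presence` (logical clonotype x mouse
#'   matrix), `mice` (mouse metadata) and `rejected` (excluded cells with
#'   reasons).
#' @export
aggregate_paired <- function(cells) {
  need <- c("mouse_id", "group", "alpha_v", "alpha_cdr3", "alpha_j",
            "beta_v", "beta_cdr3", "beta_j", "in_frame_alpha", "in_frame_beta")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    stop_fmt("paired cell table is missing column(s): %s",
             paste(missing, collapse = ", "))
  }
  ok <- cells$in_frame_alpha & cells$in_frame_beta
  rejected <- cells[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(!rejected$in_frame_alpha & !rejected$in_frame_beta,
                              "both chains out of frame",
                              ifelse(!rejected$in_frame_alpha,
                                     "alpha chain out of frame",
                                     "beta chain out of frame"))
  } else rejected$reason <- character(0)
  cells <- cells[ok, , drop = FALSE]
  akey <- clonotype_key(normalize_gene_calls(cells$alpha_v),
                        normalize_gene_calls(cells$alpha_j),
                        toupper(cells$alpha_cdr3))
  bkey <- clonotype_key(normalize_gene_calls(cells$beta_v),
                        normalize_gene_calls(cells$beta_j),
                        toupper(cells$beta_cdr3))
  pkey <- paste(akey, bkey, sep = "||")
  mice <- unique(cells[, c("mouse_id", "group")])
  mice <- mice[order(mice$mouse_id), , drop = FALSE]
  rownames(mice) <- NULL
  if (anyDuplicated(mice$mouse_id)) {
    stop_fmt("mouse id assigned to more than one group")
  }
  keys <- sort(unique(pkey))
  presence <- matrix(FALSE, length(keys), nrow(mice),
                     dimnames = list(keys, mice$mouse_id))
  if (length(pkey)) {
    presence[cbind(match(pkey, keys), match(cells$mouse_id, mice$mouse_id))] <- TRUE
  }
  first <- cells[!duplicated(pkey), , drop = FALSE]
  first <- first[match(keys, pkey[!duplicated(pkey)]), , drop = FALSE]
  clonos <- data.frame(
    key = keys,
    alpha_v = first$alpha_v, alpha_cdr3 = first$alpha_cdr3,
    alpha_j = first$alpha_j,
    beta_v = first$beta_v, beta_cdr3 = first$beta_cdr3, beta_j = first$beta_j,
    n_mice = rowSums(presence),
    stringsAsFactors = FALSE
  )
  rownames(clonos) <- NULL
  structure(list(clonotypes = clonos, presence = presence, mice = mice,
                 rejected = rejected),
            class = "paired_sets")
}

#' @export
print.paired_sets <- function(x, ...) {
  cat(sprintf("paired_sets: %d clonotypes across %d mice (%d cells rejected)\n",
              nrow(x$clonotypes), nrow(x$mice), nrow(x$rejected)))
  invisible(x)
}
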