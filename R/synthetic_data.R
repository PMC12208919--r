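# Seeded synthetic repertoire generator with planted ground truth. The
# defaults mirror the two-genotype study design the classifiers target:
# 3+3 bulk replicates, 4+4 CD5-sorted replicates, a 1,000-clonotype pool of
# which half is selectable only in condition A ("dependent"), 100 only in
# condition B ("newcomer"), heavy-tailed log-normal clone sizes, Poisson
# junction edits with a newcomer shift, and Poisson-displaced gene positions
# with a newcomer distality shift.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_study()]. Clone sizes are
#' log-normal on the relative-abundance scale (heavy-tailed, as repertoires
#' are); availability labels partition the pool into shared / dependent /
#' newcomer clonotypes; each clonotype carries a fixed latent CD5 class, a
#' junction annotation and V/J positional indices.
#'
#' @param s_shared,s_dependent,s_newcomer pool sizes of the three availability
#'   classes (defaults 400/500/100).
#' @param replicates samples per genotype (default 3).
#' @param reads molecules per sample (default 50000).
#' @param sigma log-normal sdlog of clone sizes (default 1.5).
#' @param include_cd5 also simulate a 4+4 CD5-sorted sample set (default
#'   FALSE).
#' @param cd5_replicates samples per CD5 extreme (default 4).
#' @param cd5_reads molecules per CD5 sample (default `reads`).
#' @param cd5_p_lo probability that a clonotype's latent CD5 class is "lo"
#'   (default 0.5); the class is fixed per clonotype, never per sample.
#' @param lambda_edit Poisson mean of total junction edits (default 4).
#' @param delta_edit additive shift of the edit mean for newcomers (default 2).
#' @param lambda_pos Poisson displacement of V and J positional indices from 1
#'   (default 7).
#' @param delta_pos additive shift of the positional mean for newcomers
#'   (default 2).
#' @param paralog_fraction fraction of clonotypes whose V call is
#'   paralog-ambiguous (default 0.25).
#' @param group_a,group_b genotype labels (defaults "ctrl", "mut").
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(s_shared = 400L, s_dependent = 500L, s_newcomer = 100L,
                       replicates = 3L, reads = 50000L, sigma = 1.5,
                       include_cd5 = FALSE, cd5_replicates = 4L,
                       cd5_reads = reads, cd5_p_lo = 0.5,
                       lambda_edit = 4, delta_edit = 2,
                       lambda_pos = 7, delta_pos = 2,
                       paralog_fraction = 0.25,
                       group_a = "ctrl", group_b = "mut") {
  cfg <- list(s_shared = as.integer(s_shared),
              s_dependent = as.integer(s_dependent),
              s_newcomer = as.integer(s_newcomer),
              replicates = as.integer(replicates),
              reads = as.integer(reads), sigma = sigma,
              include_cd5 = isTRUE(include_cd5),
              cd5_replicates = as.integer(cd5_replicates),
              cd5_reads = as.integer(cd5_reads), cd5_p_lo = cd5_p_lo,
              lambda_edit = lambda_edit, delta_edit = delta_edit,
              lambda_pos = lambda_pos, delta_pos = delta_pos,
              paralog_fraction = paralog_fraction,
              group_a = group_a, group_b = group_b)
  if (any(c(cfg$s_shared, cfg$s_dependent, cfg$s_newcomer) < 0L)) {
    stop_fmt("pool sizes must be >= 0")
  }
  if (cfg$s_shared + cfg$s_dependent + cfg$s_newcomer == 0L) {
    stop_fmt("clonotype pool is empty")
  }
  if (cfg$sigma <= 0) stop_fmt("sigma must be > 0")
  if (cfg$cd5_p_lo < 0 || cfg$cd5_p_lo > 1) stop_fmt("cd5_p_lo must be in [0,1]")
  if (cfg$paralog_fraction < 0 || cfg$paralog_fraction > 1) {
    stop_fmt("paralog_fraction must be in [0,1]")
  }
  if (cfg$replicates < 1L || cfg$reads < 1L) {
    stop_fmt("replicates and reads must be >= 1")
  }
  structure(cfg, class = "sim_config")
}

aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_cdr3 <- function(n, len_min = 8L, len_max = 16L) {
  lens <- sample(seq(len_min, len_max), n, replace = TRUE)
  vapply(lens, function(l) {
    paste0("C", paste(sample(aa_alphabet, l - 2L, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}

# Draw the clonotype pool with per-clonotype truth attributes.
draw_pool <- function(cfg) {
  S <- cfg$s_shared + cfg$s_dependent + cfg$s_newcomer
  label <- rep(c("shared", "dependent", "newcomer"),
               c(cfg$s_shared, cfg$s_dependent, cfg$s_newcomer))
  newc <- label == "newcomer"
  v_index <- 1L + stats::rpois(S, cfg$lambda_pos + ifelse(newc, cfg$delta_pos, 0))
  j_index <- 1L + stats::rpois(S, cfg$lambda_pos + ifelse(newc, cfg$delta_pos, 0))
  ambiguous <- stats::runif(S) < cfg$paralog_fraction
  v_gene <- paste0("TRAV", v_index)
  v_gene[ambiguous] <- paste0(v_gene[ambiguous], ",", v_gene[ambiguous], "D")
  j_gene <- paste0("TRAJ", j_index)
  cdr3 <- random_cdr3(S)
  key <- clonotype_key(v_gene, j_gene, cdr3)
  while (anyDuplicated(key)) {  # astronomically rare; keep keys unique
    dup <- duplicated(key)
    cdr3[dup] <- random_cdr3(sum(dup))
    key <- clonotype_key(v_gene, j_gene, cdr3)
  }
  lam <- cfg$lambda_edit + ifelse(newc, cfg$delta_edit, 0)
  # Four junction fields each Poisson(lambda/4), so the total is Poisson(lambda).
  truth <- data.frame(
    key = key, v_gene = v_gene, j_gene = j_gene, cdr3_aa = cdr3,
    label = label,
    cd5_class = ifelse(stats::runif(S) < cfg$cd5_p_lo, "lo", "hi"),
    weight = stats::rlnorm(S, meanlog = 0, sdlog = cfg$sigma),
    v_index = v_index, j_index = j_index,
    paralog_ambiguous = ambiguous,
    v_deletions = stats::rpois(S, lam / 4),
    j_deletions = stats::rpois(S, lam / 4),
    p_additions = stats::rpois(S, lam / 4),
    n_additions = stats::rpois(S, lam / 4),
    stringsAsFactors = FALSE
  )
  truth$edit_count <- with(truth, v_deletions + j_deletions + p_additions +
                             n_additions)
  truth
}

# Multinomial sample of `reads` molecules from the availability-restricted
# weight vector; returns counts over the full pool (zeros where unavailable).
draw_sample <- function(truth, available, reads, seed) {
  if (!any(available)) stop_fmt("no clonotypes available for this sample")
  p <- truth$weight * available
  counts <- with_seed(seed, stats::rmultinom(1, reads, p / sum(p)))[, 1]
  as.integer(counts)
}

#' Simulate a two-genotype repertoire study with ground truth
#'
#' Draws a clonotype pool with planted availability labels (shared /
#' dependent / newcomer), fixed latent CD5 classes and junction/positional
#' attributes, then samples each replicate as a multinomial draw of `reads`
#' molecules from its genotype's availability-restricted abundance vector.
#' CD5-sorted samples (when configured) draw only from condition-A clonotypes
#' of the matching latent class. All randomness flows from `seed` through
#' named per-sample substreams, so the result is reproducible and insensitive
#' to stage order.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return a list of class `sim_study`: `table` (genotype [abundance_table()]),
#'   `cd5_table` (CD5 [abundance_table()] or NULL), `truth` (per-clonotype
#'   data frame) and `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  truth <- with_seed(substream_seed(seed, "pool"), draw_pool(config))
  avail_a <- truth$label %in% c("shared", "dependent")
  avail_b <- truth$label %in% c("shared", "newcomer")
  ids_a <- sprintf("%s_%d", config$group_a, seq_len(config$replicates))
  ids_b <- sprintf("%s_%d", config$group_b, seq_len(config$replicates))
  cols <- c(
    lapply(ids_a, function(id) draw_sample(truth, avail_a, config$reads,
                                           substream_seed(seed, id))),
    lapply(ids_b, function(id) draw_sample(truth, avail_b, config$reads,
                                           substream_seed(seed, id)))
  )
  counts <- do.call(cbind, cols)
  samples <- data.frame(
    sample_id = c(ids_a, ids_b),
    group = rep(c(config$group_a, config$group_b), each = config$replicates),
    subset = "M2",
    replicate = c(seq_len(config$replicates), seq_len(config$replicates)),
    stringsAsFactors = FALSE
  )
  tab <- abundance_table(counts, truth[, c("v_gene", "j_gene", "cdr3_aa")],
                         samples)
  cd5_tab <- NULL
  if (config$include_cd5) {
    ids_lo <- sprintf("cd5lo_%d", seq_len(config$cd5_replicates))
    ids_hi <- sprintf("cd5hi_%d", seq_len(config$cd5_replicates))
    cols5 <- c(
      lapply(ids_lo, function(id) {
        draw_sample(truth, avail_a & truth$cd5_class == "lo", config$cd5_reads,
                    substream_seed(seed, id))
      }),
      lapply(ids_hi, function(id) {
        draw_sample(truth, avail_a & truth$cd5_class == "hi", config$cd5_reads,
                    substream_seed(seed, id))
      })
    )
    samples5 <- data.frame(
      sample_id = c(ids_lo, ids_hi),
      group = config$group_a,
      subset = rep(c("CD5lo", "CD5hi"), each = config$cd5_replicates),
      replicate = c(seq_len(config$cd5_replicates),
                    seq_len(config$cd5_replicates)),
      stringsAsFactors = FALSE
    )
    cd5_tab <- abundance_table(do.call(cbind, cols5),
                               truth[, c("v_gene", "j_gene", "cdr3_aa")],
                               samples5)
  }
  structure(list(table = tab, cd5_table = cd5_tab, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study (seed %d): pool of %d clonotypes (%s)\n", x$seed,
              nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$label)),
                            table(x$truth$label)), collapse = ", ")))
  print(x$table)
  if (!is.null(x$cd5_table)) print(x$cd5_table)
  invisible(x)
}

#' Simulate paired single-cell clonotypes with planted public clones
#'
#' Builds a paired-clonotype pool split into genotype-private clones and
#' exactly `n_public` public clones, then fills each mouse with cells drawn
#' from its genotype's pool. Every public clone is planted in at least one
#' mouse of each genotype, and private clones never cross genotypes, so
#' [public_paired()] recovers exactly the planted public set.
#'
#' @param n_mice mice per genotype (default 5).
#' @param cells_per_mouse cells sorted per mouse (default 40).
#' @param n_private private paired clonotypes per genotype (default 60).
#' @param n_public planted public clonotypes (default 5).
#' @param group_a,group_b genotype labels.
#' @param seed integer master seed.
#' @return list of class `sim_paired`: `cells` (one row per sorted cell,
#'   consumable by [aggregate_paired()]) and `truth` (clonotype key and
#'   public/private type).
#' @export
simulate_paired <- function(n_mice = 5L, cells_per_mouse = 40L,
                            n_private = 60L, n_public = 5L,
                            group_a = "ctrl", group_b = "mut", seed = 1L) {
  assert_count(n_mice, "n_mice"); assert_count(cells_per_mouse,
                                               "cells_per_mouse")
  assert_count(n_public, "n_public", min = 0L)
  assert_count(n_private, "n_private", min = 0L)
  n_pool <- 2L * n_private + n_public
  if (n_pool == 0L) stop_fmt("empty paired clonotype pool")
  if (n_public > n_mice * cells_per_mouse) {
    stop_fmt("cannot place %d public clones with %d cells per genotype",
             n_public, n_mice * cells_per_mouse)
  }
  with_seed(substream_seed(seed, "paired"), {
    pool <- data.frame(
      alpha_v = paste0("TRAV14-", sample(1:3, n_pool, replace = TRUE)),
      alpha_cdr3 = random_cdr3(n_pool),
      alpha_j = paste0("TRAJ", 1L + stats::rpois(n_pool, 20)),
      beta_v = "TRBV5",
      beta_cdr3 = random_cdr3(n_pool),
      beta_j = paste0("TRBJ", sample(1:2, n_pool, replace = TRUE), "-",
                      sample(1:7, n_pool, replace = TRUE)),
      type = rep(c("private_a", "private_b", "public"),
                 c(n_private, n_private, n_public)),
      stringsAsFactors = FALSE
    )
    pool$key <- paste(
      clonotype_key(pool$alpha_v, pool$alpha_j, pool$alpha_cdr3),
      clonotype_key(pool$beta_v, pool$beta_j, pool$beta_cdr3), sep = "||")
    weight <- stats::rlnorm(n_pool, 0, 1)
    make_cells <- function(group, gtype) {
      idx_pool <- which(pool$type %in% c(gtype, "public"))
      mice <- sprintf("%s_m%d", group, seq_len(n_mice))
      rows <- list()
      # plant each public clone in one mouse of this genotype
      pub <- which(pool$type == "public")
      if (length(pub)) {
        planted <- sample(rep_len(seq_len(n_mice), length(pub)))
        rows[[1]] <- data.frame(mouse_id = mice[planted], idx = pub)
      }
      fill <- cells_per_mouse * n_mice - length(pub)
      if (fill > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = sample(mice, fill, replace = TRUE),
          idx = sample(idx_pool, fill, replace = TRUE,
                       prob = weight[idx_pool]))
      }
      out <- do.call(rbind, rows)
      cbind(out, group = group)
    }
    cells_idx <- rbind(make_cells(group_a, "private_a"),
                       make_cells(group_b, "private_b"))
    cells <- cbind(
      cells_idx[, c("mouse_id", "group")],
      pool[cells_idx$idx, c("alpha_v", "alpha_cdr3", "alpha_j",
                            "beta_v", "beta_cdr3", "beta_j")],
      in_frame_alpha = TRUE, in_frame_beta = TRUE
    )
    rownames(cells) <- NULL
    structure(list(cells = cells, truth = pool[, c("key", "type")],
                   seed = as.integer(seed)),
              class = "sim_paired")
  })
}

#' Write a simulated (or real) study as an AIRR-style rearrangement TSV
#'
#' Expands an abundance table back to one annotated read per molecule, with
#' per-sample sequential UMIs, and writes a single rearrangement TSV that
#' [read_rearrangements()] plus [aggregate_bulk()] reproduce exactly. Junction
#' columns are filled from a truth table when available. `dup_rate` re-emits a
#' fraction of molecules as duplicate reads with the same UMI, exercising the
#' UMI-collapse path without changing the aggregated counts.
#'
#' @param study a `sim_study` from [simulate_study()] or an
#'   [abundance_table()].
#' @param path output TSV path.
#' @param dup_rate fraction of molecules written twice (default 0).
#' @param seed seed used only when `dup_rate > 0`.
#' @return `path`, invisibly.
#' @export
emit_airr <- function(study, path, dup_rate = 0, seed = 1L) {
  tab <- if (inherits(study, "sim_study")) study$table else study
  truth <- if (inherits(study, "sim_study")) study$truth else NULL
  stopifnot(inherits(tab, "abundance_table"))
  if (dup_rate < 0 || dup_rate > 1) stop_fmt("dup_rate must be in [0,1]")
  key <- rownames(tab$counts)
  jmatch <- if (!is.null(truth)) match(key, truth$key) else rep(NA_integer_,
                                                                length(key))
  jcol <- function(col) {
    if (is.null(truth)) rep(NA_integer_, length(key)) else truth[[col]][jmatch]
  }
  vdel <- jcol("v_deletions"); jdel <- jcol("j_deletions")
  padd <- jcol("p_additions"); nadd <- jcol("n_additions")
  rows <- list()
  for (s in seq_len(ncol(tab$counts))) {
    cts <- tab$counts[, s]
    nz <- which(cts > 0L)
    if (length(nz) == 0L) next
    ridx <- rep(nz, cts[nz])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = tab$samples$sample_id[s],
      umi = sprintf("m%06d", seq_along(ridx)),
      v_call = tab$clonotypes$v_gene[ridx],
      j_call = tab$clonotypes$j_gene[ridx],
      junction_aa = tab$clonotypes$cdr3_aa[ridx],
      productive = "TRUE",
      v_deletions = vdel[ridx], j_deletions = jdel[ridx],
      p_additions = padd[ridx], n_additions = nadd[ridx],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    stats::setNames(
      as.data.frame(matrix(character(), 0, 10)),
      c("sample_id", "umi", "v_call", "j_call", "junction_aa", "productive",
        airr_junction_cols))
  }
  if (dup_rate > 0 && nrow(out)) {
    dup <- with_seed(substream_seed(seed, "dup"),
                     which(stats::runif(nrow(out)) < dup_rate))
    out <- rbind(out, out[dup, , drop = FALSE])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
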