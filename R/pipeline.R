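# Pipeline orchestration: validated YAML config -> simulate/ingest ->
# aggregate -> diversity -> overlap -> classify -> junctions -> report bundle.

pipeline_defaults <- list(
  min_samples = 3L, min_umi = 1L, top_k = 10L,
  q = 1, grid = NULL, reps = 100L, n_perm = 1000L, seed = 1L
)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults (`min_samples = 3`,
#' `min_umi = 1`, `top_k = 10`, `q = 1`, `reps = 100`, `n_perm = 1000`,
#' `seed = 1`) and collects all validation errors before failing, so a broken
#' config reports every problem at once. Exactly one of `input` (a
#' rearrangement TSV plus group assignments) or `simulation` (arguments for
#' [sim_config()]) must be present.
#'
#' @param config path to a YAML file or a named list.
#' @return a normalized list of class `pipeline_config`, or an error listing
#'   every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      stop_fmt("config is not parseable YAML: %s", conditionMessage(e))
    })
  }
  stopifnot(is.list(config))
  errors <- character()
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  for (nm in names(pipeline_defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- pipeline_defaults[[nm]]
  }
  for (nm in c("min_samples", "min_umi", "top_k", "reps", "n_perm")) {
    v <- config[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      note("`%s` must be a positive integer (got %s)", nm,
           paste(v, collapse = ","))
    } else config[[nm]] <- as.integer(v)
  }
  if (!is.numeric(config$q) || config$q < 0) note("`q` must be >= 0")

  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input && has_sim) {
    note("`input` and `simulation` are mutually exclusive")
  }
  if (!has_input && !has_sim) note("one of `input` or `simulation` is required")
  if (has_input) {
    if (is.null(config$input$rearrangements) &&
        is.null(config$input$abundance)) {
      note("`input` needs `rearrangements` or `abundance` path")
    }
    for (p in c(config$input$rearrangements, config$input$abundance)) {
      if (!file.exists(p)) note("input file not found: %s", p)
    }
  }
  if (has_sim) {
    sim <- tryCatch(do.call(sim_config, config$simulation),
                    error = function(e) {
                      note("invalid simulation block: %s", conditionMessage(e))
                      NULL
                    })
    config$simulation <- sim
  }
  if (!is.null(config$groups) &&
      (is.null(config$groups$a) || is.null(config$groups$b))) {
    note("`groups` must name `a` and `b`")
  }
  if (length(errors)) {
    stop(paste(c("invalid pipeline config:",
                 paste0("  - ", errors)), collapse = "\n"), call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12, null = "null",
                       pretty = TRUE)
}

#' Run the full repertoire analysis pipeline
#'
#' Executes the configured stages in dependency order: obtain an abundance
#' table (by simulation or ingest), per-sample diversity and coverage,
#' pairwise Morisita-Horn overlap, recurrence and dependence classification
#' (plus CD5 classification and truth-vs-recovered comparison for simulated
#' studies), junction and positional comparisons of the newcomer set, and a
#' machine-readable report. A stage failure aborts with the stage named.
#' Rerunning with the same config and seed reproduces the JSON summary
#' bit-identically (numbers serialised at 12 significant digits).
#'
#' @param config a `pipeline_config` from [validate_config()], a list, or a
#'   YAML path.
#' @param out_dir output directory, created if needed; receives stage TSVs and
#'   `summary.json`.
#' @return the report bundle (named list mirroring `summary.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "ingest"
  bundle <- tryCatch({
    truth <- NULL
    cd5_tab <- NULL
    if (!is.null(config$simulation)) {
      stage <- "simulate"
      study <- simulate_study(config$simulation, seed = config$seed)
      tab <- study$table
      cd5_tab <- study$cd5_table
      truth <- study$truth
      utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      groups <- list(a = config$simulation$group_a,
                     b = config$simulation$group_b)
    } else {
      stage <- "ingest"
      tab <- if (!is.null(config$input$abundance)) {
        read_abundance(config$input$abundance)
      } else {
        reads <- read_rearrangements(config$input$rearrangements)
        aggregate_bulk(reads)
      }
      groups <- config$groups
      if (!is.null(groups)) {
        known <- unique(stats::na.omit(tab$samples$group))
        for (g in c(groups$a, groups$b)) {
          if (!g %in% known && !all(g %in% tab$samples$sample_id)) {
            stop_fmt("group '%s' matches no sample", g)
          }
        }
      }
    }
    write_abundance(tab, file.path(out_dir, "abundance.tsv"))

    stage <- "diversity"
    div <- diversity_summary(tab, q = config$q, grid = config$grid,
                             reps = config$reps,
                             seed = substream_seed(config$seed, "diversity"))
    utils::write.table(div$summary, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(div$curves)) {
      utils::write.table(div$curves, file.path(out_dir, "rarefaction.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "overlap"
    ov <- pairwise_overlap(tab)
    utils::write.table(ov$pairs, file.path(out_dir, "overlap_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ov$matrix, file.path(out_dir, "overlap_matrix.tsv"),
                       sep = "\t", quote = FALSE)

    classification <- NULL
    junctions <- NULL
    recovery <- NULL
    cd5 <- NULL
    if (!is.null(groups)) {
      stage <- "classify"
      rec <- recurrent_clonotypes(tab, min_samples = config$min_samples,
                                  min_umi = config$min_umi)
      dep <- classify_dependence(tab, rec, groups$a, groups$b,
                                 min_umi = config$min_umi)
      lab_df <- data.frame(key = names(dep$labels),
                           class = as.character(dep$labels))
      utils::write.table(lab_df, file.path(out_dir, "dependence_labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      classification <- list(
        n_recurrent = length(dep$sets$recurrent),
        n_dependent = length(dep$sets$dependent),
        n_shared = length(dep$sets$shared),
        n_newcomer = length(dep$sets$newcomer),
        n_recurrent_a = length(dep$sets$recurrent_a),
        n_recurrent_b = length(dep$sets$recurrent_b)
      )
      if (!is.null(truth)) {
        planted <- split(truth$key, truth$label)
        tp <- length(intersect(dep$sets$dependent, planted$dependent))
        recovery <- list(
          planted_dependent = length(planted$dependent %||% character()),
          recovered_dependent = length(dep$sets$dependent),
          true_dependent_recovered = tp,
          false_dependent = length(dep$sets$dependent) - tp,
          recovered_dependent_fraction =
            length(dep$sets$dependent) / length(dep$sets$recurrent)
        )
      }
      if (!is.null(cd5_tab)) {
        cd5l <- classify_cd5(cd5_tab, "CD5lo", "CD5hi",
                             min_present = config$min_samples,
                             min_umi = config$min_umi)
        xa_lo <- cross_assign(cd5l$sets$natural_lo, dep)
        xa_hi <- cross_assign(cd5l$sets$natural_hi, dep)
        cd5 <- list(
          n_natural_lo = length(cd5l$sets$natural_lo),
          n_natural_hi = length(cd5l$sets$natural_hi),
          lo_dependent_fraction_matched =
            unname(xa_lo$fraction_matched["dependent"]),
          hi_dependent_fraction_matched =
            unname(xa_hi$fraction_matched["dependent"])
        )
      }

      stage <- "junctions"
      if (!is.null(truth)) {
        ok <- !truth$paralog_ambiguous
        base <- ok & truth$label != "newcomer" & truth$key %in% rec
        newc <- ok & truth$label == "newcomer" & truth$key %in% rec
        if (any(base) && any(newc)) {
          pos <- compare_positional_bias(
            truth$v_gene[base], truth$v_gene[newc],
            n_perm = config$n_perm,
            seed = substream_seed(config$seed, "pos"))
          edit <- compare_edit_counts(
            truth$edit_count[base], truth$edit_count[newc],
            n_perm = config$n_perm,
            seed = substream_seed(config$seed, "edit"))
          junctions <- list(
            positional_delta = pos$delta, positional_p = pos$p_value,
            edit_delta = edit$delta, edit_p = edit$p_value)
        }
      }
    }

    stage <- "report"
    list(
      package = "clonalholes",
      version = as.character(utils::packageVersion("clonalholes")),
      seed = config$seed,
      config_hash = config_hash(config),
      n_clonotypes = nrow(tab$counts),
      n_samples = ncol(tab$counts),
      diversity = stats::setNames(as.list(div$summary$D_obs),
                                  div$summary$sample_id),
      coverage = stats::setNames(as.list(div$summary$coverage),
                                 div$summary$sample_id),
      overlap_category_means = if (nrow(ov$pairs)) {
        as.list(tapply(ov$pairs$value, ov$pairs$category, mean))
      } else NULL,
      classification = classification,
      cd5 = cd5,
      recovery = recovery,
      junctions = junctions
    )
  }, error = function(e) {
    stop_fmt("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  write_json_summary(bundle, file.path(out_dir, "summary.json"))
  invisible(bundle)
}

# Deterministic short hash of the normalized config (provenance only).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12,
                        null = "null", force = TRUE)
  codes <- utf8ToInt(as.character(s))
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  sprintf("%08x", h)
}
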