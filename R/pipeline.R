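#' Assemble a run configuration
#'
#' One object drives an end-to-end run: the simulation parameters, every
#' analysis threshold, and the root seed from which all per-stage seeds
#' are derived (so identical config + seed gives byte-identical outputs).
#'
#' @param mode one of `"simulate"`, `"analyze"`, `"screen"`, `"assay"`,
#'   `"full"`.
#' @param sim a [sim_config()] (simulate/full modes).
#' @param min_overlap,max_mismatch_frac merger thresholds.
#' @param repeat_max_mismatch Hamming tolerance per repeat occurrence.
#' @param novelty_max_mismatch tolerance for matching ancestral spacers.
#' @param map_max_mismatch tolerance for protospacer mapping (0 = perfect
#'   matches only).
#' @param flank PAM length.
#' @param bin_size bin width of the positional map.
#' @param paths named list of input paths (analyze/screen/assay modes):
#'   `r1`, `r2`, `references`, `ancestral_spacers`, `repeat_seq`,
#'   `contigs`, `representative`, `assay_counts`.
#' @param seed root seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze", "screen",
                                "assay"),
                       sim = sim_config(),
                       min_overlap = 20L, max_mismatch_frac = 0.1,
                       repeat_max_mismatch = 3L,
                       novelty_max_mismatch = 2L,
                       map_max_mismatch = 0L,
                       flank = 7L, bin_size = 100L,
                       paths = list(), seed = sim$seed) {
  mode <- match.arg(mode)
  structure(list(mode = mode, sim = sim, min_overlap = as.integer(min_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 repeat_max_mismatch = as.integer(repeat_max_mismatch),
                 novelty_max_mismatch = as.integer(novelty_max_mismatch),
                 map_max_mismatch = as.integer(map_max_mismatch),
                 flank = as.integer(flank), bin_size = as.integer(bin_size),
                 paths = paths, seed = as.integer(seed)),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the pipeline end to end
#'
#' `full` mode simulates a cohort (seeded from `config$seed`), merges the
#' read pairs, parses arrays and calls acquisition, classifies new spacers
#' and builds the PAM model, and returns a machine-readable report with a
#' provenance block (thresholds, seed, package version). `simulate` stops
#' after generation. Other stages fail fast with the stage name.
#'
#' @param config a [run_config()].
#' @param out_path optional path for a JSON report.
#' @return list report (invisible when written to disk).
#' @export
run_pipeline <- function(config, out_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$sim
  cfg$seed <- config$seed
  cohort <- .stage("synthetic_data", {
    if (config$mode %in% c("full", "simulate")) simulate_cohort(cfg)
    else NULL
  })
  if (config$mode == "analyze") {
    cohort <- .stage("read_merge", {
      pairs <- read_fastq_pairs(config$paths$r1, config$paths$r2)
      if (nrow(pairs) == 0L) stop("no read pairs in input")
      anc <- as.character(
        Biostrings::readDNAStringSet(config$paths$ancestral_spacers))
      list(pairs = pairs, refs = .read_reference_set(config$paths$references),
           ancestral = anc, truth = NULL)
    })
  }
  if (config$mode == "simulate") {
    report <- list(mode = "simulate", n_reads = nrow(cohort$pairs),
                   truth_acquired = mean(cohort$truth$acquired))
    return(.finish_report(report, config, out_path))
  }
  if (config$mode == "screen") {
    report <- .stage("acr_orf", {
      contigs <- Biostrings::readDNAStringSet(config$paths$contigs)
      rep_aa <- as.character(
        Biostrings::readAAStringSet(config$paths$representative))[1]
      orfs <- do.call(rbind, lapply(seq_along(contigs), function(i) {
        find_orfs(as.character(contigs[[i]]),
                  contig_id = sub(" .*", "", names(contigs)[i]))
      }))
      if (is.null(orfs) || nrow(orfs) == 0L) stop("no ORFs found")
      list(mode = "screen", n_orfs = nrow(orfs),
           verdicts = truncation_screen(orfs, rep_aa))
    })
    return(.finish_report(report, config, out_path))
  }
  if (config$mode == "assay") {
    report <- .stage("assay_stats", {
      tab <- utils::read.table(config$paths$assay_counts, header = TRUE,
                               sep = "\t")
      list(mode = "assay",
           loss = lapply(seq_len(nrow(tab)), function(i) {
             loss_fraction(assay_counts(tab$n_total[i], tab$n_lost[i]))
           }))
    })
    return(.finish_report(report, config, out_path))
  }

  merged <- .stage("read_merge", {
    if (nrow(cohort$pairs) == 0L) stop("no read pairs in input")
    merge_pairs(cohort$pairs, config$min_overlap, config$max_mismatch_frac)
  })
  spec <- repeat_spec(cfg$repeat_seq, config$repeat_max_mismatch)
  ancestral <- if (!is.null(cohort$refs$ancestral)) {
    cohort$refs$ancestral$spacers
  } else cohort$ancestral
  detection <- .stage("spacer_detect", {
    detect_acquisition(merged$merged, spec, ancestral,
                       config$novelty_max_mismatch)
  })
  classification <- .stage("target_classify", {
    if (length(detection$spacer_counts)) {
      cls <- classify_spacers(detection$spacer_counts, cohort$refs,
                              config$map_max_mismatch, config$flank)
      pams <- cls$pam[!is.na(cls$pam)]
      wts <- cls$count[!is.na(cls$pam)]
      list(classified = cls,
           abundance = categorize_cohort(cls),
           pam_model = if (length(pams)) build_pam_model(pams, wts) else NULL,
           positions = position_map(cls, "plasmid",
                                    nchar(cohort$refs$sequences[["plasmid"]]),
                                    config$bin_size))
    } else list(classified = NULL, abundance = NULL, pam_model = NULL,
                positions = NULL)
  })

  frac <- detection$fraction
  report <- list(
    mode = config$mode,
    n_pairs = nrow(cohort$pairs),
    n_merged = nrow(merged$merged),
    n_unparseable = length(detection$unparseable),
    acquisition = list(estimate = frac$estimate, lower = frac$lower,
                       upper = frac$upper, n_expanded = frac$n_expanded,
                       n_total = frac$n_total),
    abundance = as.list(classification$abundance),
    pam_consensus = if (!is.null(classification$pam_model)) {
      classification$pam_model$consensus
    } else NA_character_,
    pam_n_sites = if (!is.null(classification$pam_model)) {
      classification$pam_model$n_sites
    } else 0L,
    position_chisq = if (!is.null(classification$positions)) {
      list(statistic = classification$positions$chisq,
           df = classification$positions$df)
    } else NULL,
    truth = if (!is.null(cohort$truth)) {
      list(acquired_fraction = mean(cohort$truth$acquired))
    } else NULL)
  .finish_report(report, config, out_path)
}

.finish_report <- function(report, config, out_path) {
  thresholds <- config[c("min_overlap", "max_mismatch_frac",
                         "repeat_max_mismatch", "novelty_max_mismatch",
                         "map_max_mismatch", "flank", "bin_size")]
  report$provenance <- list(
    seed = config$seed,
    thresholds = thresholds,
    package = "spacerTracer",
    version = as.character(utils::packageVersion("spacerTracer")))
  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}

.read_reference_set <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*", "", names(x))
  circ <- grepl("topology=circular", names(x))
  structure(list(sequences = stats::setNames(as.character(x), ids),
                 circular = stats::setNames(circ, ids)),
            class = "reference_set")
}
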