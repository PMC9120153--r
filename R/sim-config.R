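#' Configuration of the synthetic amplicon cohort
#'
#' Bundles every generative parameter of the simulated CR1 amplicon
#' experiment: the repeat/leader fixture sequences, the per-read probability
#' that the sequenced array carries one newly acquired leader-proximal
#' spacer, the PAM constraint used when sampling protospacers, the read
#' geometry and the substitution error rate.
#'
#' The defaults describe the study conditions the pipeline is validated
#' against: 2 x 250 bp paired-end reads, 30-nt spacers, a 36-nt repeat-like
#' fixture sequence (configurable so a real repeat can be supplied), and
#' protospacers drawn adjacent to an `NNAGAAW` motif with the PAM on the
#' 3' side of the protospacer.
#'
#' @param repeat_seq direct-repeat sequence anchoring the array (DNA).
#' @param spacer_len spacer length in nt.
#' @param n_ancestral_spacers number of ancestral spacers in the amplified
#'   leader-proximal window.
#' @param leader_seq leader-side sequence 5' of the first repeat (includes
#'   the forward primer site).
#' @param trailer_seq sequence 3' of the last repeat (reverse primer side).
#' @param p_acq probability per read that the array carries one newly
#'   acquired spacer.
#' @param pam_pattern IUPAC pattern adjacent to sampled protospacers.
#' @param pam_side which side of the protospacer carries the PAM
#'   (`"three_prime"` or `"five_prime"`).
#' @param error_rate per-base substitution probability of the sequencer.
#' @param read_len read length in nt.
#' @param n_reads number of read pairs to generate.
#' @param seed integer seed controlling the whole cohort.
#' @param target_weights named numeric vector of sampling probabilities for
#'   the protospacer source (`plasmid`, `acr`, `genome`); normalised to 1.
#' @param plasmid_len,acr_len,genome_len reference lengths in nt.
#' @param pam_sites named integer vector: PAM instances planted per
#'   reference.
#' @param plant_pam plant concrete PAM instances into the references; when
#'   `FALSE` only background matches of `pam_pattern` are available and
#'   generation fails if too few exist.
#' @param qual_hi Phred quality at error-free positions.
#' @param qual_err Phred quality written at simulated error positions (the
#'   configurable quality dip; set equal to `qual_hi` to disable).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(repeat_seq = "GTTTTTGTACTCTCAAGATTTAAGTAACTGTACAAC",
                      spacer_len = 30L,
                      n_ancestral_spacers = 2L,
                      leader_seq = "CTGAATCCATGAACGTCTAAGTGATCCGTTAACTGC",
                      trailer_seq = "ACGGTCATCCTCTTGCAGGTTCAACTGGTA",
                      p_acq = 0.33,
                      pam_pattern = "NNAGAAW",
                      pam_side = c("three_prime", "five_prime"),
                      error_rate = 0.001,
                      read_len = 250L,
                      n_reads = 1000L,
                      seed = 1L,
                      target_weights = c(plasmid = 0.8, acr = 0.1,
                                         genome = 0.1),
                      plasmid_len = 3000L,
                      acr_len = 600L,
                      genome_len = 2000L,
                      pam_sites = c(plasmid = 60L, acr = 12L, genome = 40L),
                      plant_pam = TRUE,
                      qual_hi = 38L,
                      qual_err = 20L) {
  pam_side <- match.arg(pam_side)
  cfg <- list(repeat_seq = toupper(repeat_seq),
              spacer_len = as.integer(spacer_len),
              n_ancestral_spacers = as.integer(n_ancestral_spacers),
              leader_seq = toupper(leader_seq),
              trailer_seq = toupper(trailer_seq),
              p_acq = p_acq,
              pam_pattern = toupper(pam_pattern),
              pam_side = pam_side,
              error_rate = error_rate,
              read_len = as.integer(read_len),
              n_reads = as.integer(n_reads),
              seed = as.integer(seed),
              target_weights = target_weights / sum(target_weights),
              plasmid_len = as.integer(plasmid_len),
              acr_len = as.integer(acr_len),
              genome_len = as.integer(genome_len),
              pam_sites = pam_sites,
              plant_pam = isTRUE(plant_pam),
              qual_hi = as.integer(qual_hi),
              qual_err = as.integer(qual_err))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(cfg$p_acq, cfg$error_rate, cfg$target_weights)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$spacer_len < 1L) stop("spacer_len must be >= 1")
  if (!grepl("^[ACGT]+$", cfg$repeat_seq)) {
    stop("repeat_seq must be concrete DNA (ACGT)")
  }
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", cfg$pam_pattern)) {
    stop("pam_pattern must contain only IUPAC DNA codes")
  }
  if (!all(names(cfg$target_weights) %in% c("plasmid", "acr", "genome")) ||
      is.null(names(cfg$target_weights))) {
    stop("target_weights must be named plasmid/acr/genome")
  }
  # The expanded amplicon must be spanned by the pair with usable overlap.
  amp_max <- amplicon_length(cfg, expanded = TRUE)
  if (amp_max > 2L * cfg$read_len - 20L) {
    stop(sprintf(paste0("expanded amplicon (%d nt) too long for 2 x %d nt ",
                        "reads to overlap by >= 20 nt: merging impossible"),
                 amp_max, cfg$read_len))
  }
  cfg
}

# Length of the primer-to-primer amplicon, with or without one acquisition.
amplicon_length <- function(cfg, expanded = FALSE) {
  n_sp <- cfg$n_ancestral_spacers + as.integer(expanded)
  nchar(cfg$leader_seq) + (n_sp + 1L) * nchar(cfg$repeat_seq) +
    n_sp * cfg$spacer_len + nchar(cfg$trailer_seq)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d reads, p_acq = %g, error_rate = %g, PAM %s (%s)",
              x$n_reads, x$p_acq, x$error_rate, x$pam_pattern, x$pam_side),
      "\n")
  cat(sprintf("  repeat %d nt, spacer %d nt, %d ancestral spacers, 2 x %d bp\n",
              nchar(x$repeat_seq), x$spacer_len, x$n_ancestral_spacers,
              x$read_len))
  invisible(x)
}
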