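#' Build the synthetic reference set
#'
#' Generates the three target references the cohort samples protospacers
#' from — a circular plasmid-like sequence, a linear anti-CRISPR (acr) gene
#' segment and a linear host-genome segment — and the ancestral CRISPR
#' array. Concrete instances of `cfg$pam_pattern` are planted on alternating
#' strands at regular spacing so that PAM-constrained protospacer sampling
#' never starves; background (chance) matches remain and are counted too.
#'
#' @param cfg a [sim_config()].
#' @param rng_seed seed for this stage (default derived from `cfg$seed`).
#' @param backbones optional named list of backbone sequences (`plasmid`,
#'   `acr`, `genome`) overriding random generation; lengths override the
#'   configured lengths.
#' @return object of class `reference_set`: list with `sequences` (named
#'   character), `circular` (named logical), `pam_pattern`, and `ancestral`
#'   (ancestral spacers plus the unexpanded amplicon).
#' @export
build_references <- function(cfg, rng_seed = NULL, backbones = NULL) {
  validate_sim_config(cfg)
  if (is.null(rng_seed)) rng_seed <- derive_seed(cfg$seed, "references")
  set.seed(rng_seed)

  lens <- c(plasmid = cfg$plasmid_len, acr = cfg$acr_len,
            genome = cfg$genome_len)
  pam_len <- nchar(cfg$pam_pattern)
  seqs <- character(0)
  for (ref in names(lens)) {
    bb <- if (!is.null(backbones[[ref]])) toupper(backbones[[ref]])
          else random_dna(lens[[ref]])
    if (cfg$plant_pam) {
      bb <- .plant_pam_sites(bb, cfg$pam_pattern,
                             n_sites = cfg$pam_sites[[ref]],
                             margin = cfg$spacer_len + pam_len)
    }
    seqs[[ref]] <- bb
  }

  # post-condition: sampling must not starve (>= 50 plasmid sites, both
  # strands counted; a handful elsewhere)
  counts <- vapply(names(seqs), function(r) {
    nrow(iupac_scan(seqs[[r]], cfg$pam_pattern, both_strands = TRUE))
  }, integer(1))
  need <- c(plasmid = 50L, acr = 3L, genome = 3L)
  short <- counts < need[names(counts)]
  if (any(short)) {
    stop(sprintf("too few %s matches on: %s (found %s, need %s)",
                 cfg$pam_pattern,
                 paste(names(counts)[short], collapse = ", "),
                 paste(counts[short], collapse = ", "),
                 paste(need[names(counts)][short], collapse = ", ")))
  }

  ancestral_spacers <- vapply(seq_len(cfg$n_ancestral_spacers),
                              function(i) random_dna(cfg$spacer_len),
                              character(1))
  refs <- list(sequences = seqs,
               circular = c(plasmid = TRUE, acr = FALSE, genome = FALSE),
               pam_pattern = cfg$pam_pattern,
               pam_site_counts = counts,
               ancestral = list(
                 spacers = ancestral_spacers,
                 amplicon = .array_amplicon(ancestral_spacers, cfg)))
  class(refs) <- "reference_set"
  refs
}

# Overwrite windows of `seq` with concrete draws from an IUPAC pattern,
# alternating strands, evenly spaced, leaving `margin` nt clear at each end.
.plant_pam_sites <- function(seq, pattern, n_sites, margin) {
  L <- nchar(seq)
  m <- nchar(pattern)
  usable <- L - 2L * margin - m
  if (n_sites < 1L) return(seq)
  if (usable < 1L || (n_sites > 1L && usable / (n_sites - 1L) < m + 2L)) {
    stop(sprintf("cannot plant %d '%s' sites into %d nt (margin %d)",
                 n_sites, pattern, L, margin))
  }
  starts <- margin + round(seq(0, usable, length.out = n_sites))
  chars <- strsplit(seq, "")[[1]]
  allowed <- .iupac_bases(strsplit(pattern, "")[[1]])
  for (i in seq_along(starts)) {
    inst <- vapply(allowed, function(b) sample(b, 1L), character(1))
    inst <- paste(inst, collapse = "")
    if (i %% 2L == 0L) inst <- revcomp(inst)
    chars[(starts[i] + 1L):(starts[i] + m)] <- strsplit(inst, "")[[1]]
  }
  paste(chars, collapse = "")
}

# leader + R + (S + R)*k + trailer for an ordered spacer vector
.array_amplicon <- function(spacers, cfg) {
  body <- paste0(cfg$repeat_seq,
                 paste(vapply(spacers, function(s) paste0(s, cfg$repeat_seq),
                              character(1)), collapse = ""))
  paste0(cfg$leader_seq, body, cfg$trailer_seq)
}

# Extract [start, end) (0-based) from a possibly circular sequence.
.ref_window <- function(seq, start, end, circular = FALSE) {
  L <- nchar(seq)
  if (!circular) {
    if (start < 0L || end > L) return(NA_character_)
    return(substr(seq, start + 1L, end))
  }
  idx <- ((start:(end - 1L)) %% L) + 1L
  paste(strsplit(seq, "")[[1]][idx], collapse = "")
}

# All PAM-adjacent protospacer sites of a reference, forward coordinates.
# pam_side "three_prime": the PAM sits immediately 3' of the protospacer on
# the protospacer strand.
.protospacer_sites <- function(ref_seq, circular, cfg) {
  pam_len <- nchar(cfg$pam_pattern)
  sl <- cfg$spacer_len
  L <- nchar(ref_seq)
  pams <- iupac_scan(ref_seq, cfg$pam_pattern, both_strands = TRUE)
  if (nrow(pams) == 0L) return(pams[0, ])
  if (cfg$pam_side == "three_prime") {
    start <- ifelse(pams$strand == "+", pams$start - sl, pams$end)
  } else {
    start <- ifelse(pams$strand == "+", pams$end, pams$start - sl)
  }
  end <- start + sl
  ok <- if (circular) rep(TRUE, length(start)) else start >= 0L & end <= L
  data.frame(start = start[ok], end = end[ok], strand = pams$strand[ok])
}

#' Simulate CRISPR arrays with leader-proximal acquisition
#'
#' Each of `cfg$n_reads` arrays independently carries, with probability
#' `cfg$p_acq`, one newly acquired spacer inserted at the leader-proximal
#' position. New spacers are `spacer_len`-nt protospacers sampled uniformly
#' from PAM-adjacent sites of a reference chosen by `cfg$target_weights`;
#' all other arrays reproduce the ancestral array verbatim.
#'
#' @param cfg a [sim_config()].
#' @param refs a [build_references()] result.
#' @param rng_seed stage seed (default derived from `cfg$seed`).
#' @return list with `arrays` (list of ordered spacer vectors,
#'   leader-proximal first), `amplicons` (character) and `truth`, a
#'   data.frame with one row per read: `read_id`, `acquired`, `spacer`,
#'   `ref`, `start`, `end` (0-based half-open, forward strand), `strand`.
#' @export
simulate_arrays <- function(cfg, refs, rng_seed = NULL) {
  validate_sim_config(cfg)
  stopifnot(inherits(refs, "reference_set"))
  if (is.null(rng_seed)) rng_seed <- derive_seed(cfg$seed, "arrays")
  set.seed(rng_seed)

  sites <- lapply(names(refs$sequences), function(r) {
    .protospacer_sites(refs$sequences[[r]], refs$circular[[r]], cfg)
  })
  names(sites) <- names(refs$sequences)
  starved <- vapply(sites, nrow, integer(1)) == 0L
  active <- names(refs$sequences)[cfg$target_weights[names(refs$sequences)] > 0]
  if (any(starved[active])) {
    stop("no eligible PAM-adjacent protospacer sites on: ",
         paste(names(which(starved[active])), collapse = ", "))
  }

  n <- cfg$n_reads
  ids <- sprintf("read%06d", seq_len(n))
  acquired <- stats::runif(n) < cfg$p_acq
  n_acq <- sum(acquired)

  truth <- data.frame(read_id = ids, acquired = acquired,
                      spacer = NA_character_, ref = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, stringsAsFactors = FALSE)
  arrays <- rep(list(refs$ancestral$spacers), n)

  if (n_acq > 0L) {
    cats <- sample(names(cfg$target_weights), n_acq, replace = TRUE,
                   prob = cfg$target_weights)
    idx_acq <- which(acquired)
    for (k in seq_len(n_acq)) {
      r <- cats[k]
      st <- sites[[r]]
      pick <- st[sample.int(nrow(st), 1L), ]
      raw <- .ref_window(refs$sequences[[r]], pick$start, pick$end,
                         refs$circular[[r]])
      spacer <- if (pick$strand == "+") raw else revcomp(raw)
      i <- idx_acq[k]
      arrays[[i]] <- c(spacer, refs$ancestral$spacers)
      truth$spacer[i] <- spacer
      truth$ref[i] <- r
      truth$start[i] <- pick$start %% nchar(refs$sequences[[r]])
      truth$end[i] <- pick$end
      truth$strand[i] <- pick$strand
    }
  }
  amplicons <- vapply(arrays, .array_amplicon, character(1), cfg = cfg)
  list(arrays = arrays, amplicons = amplicons, truth = truth)
}

# Apply per-base substitution errors; returns seq and 1-based error sites.
.mutate_read <- function(seq, error_rate) {
  L <- nchar(seq)
  if (error_rate <= 0 || L == 0L) return(list(seq = seq, sites = integer(0)))
  n_err <- stats::rbinom(1L, L, error_rate)
  if (n_err == 0L) return(list(seq = seq, sites = integer(0)))
  sites <- sample.int(L, n_err)
  chars <- strsplit(seq, "")[[1]]
  for (s in sites) {
    chars[s] <- sample(setdiff(DNA_BASES, chars[s]), 1L)
  }
  list(seq = paste(chars, collapse = ""), sites = sort(sites))
}

.qual_string <- function(len, sites, qual_hi, qual_err) {
  hi <- rawToChar(as.raw(qual_hi + 33L))
  if (!length(sites)) return(strrep(hi, len))
  q <- rep(hi, len)
  q[sites] <- rawToChar(as.raw(qual_err + 33L))
  paste(q, collapse = "")
}

#' Simulate paired-end amplicon reads
#'
#' The forward read is the first `read_len` nt of the amplicon, the reverse
#' read the reverse complement of the last `read_len` nt (both truncated to
#' the amplicon when it is shorter). Substitution errors are drawn per base
#' at `cfg$error_rate`; qualities are constant `qual_hi` with a dip to
#' `qual_err` at error positions.
#'
#' @param sim a [simulate_arrays()] result (or any list with `amplicons`).
#' @param cfg a [sim_config()].
#' @param rng_seed stage seed (default derived from `cfg$seed`).
#' @return data.frame of class `read_pairs`: `read_id`, `r1`, `q1`, `r2`,
#'   `q2`, `n_err1`, `n_err2`, `amplicon_len`.
#' @export
simulate_read_pairs <- function(sim, cfg, rng_seed = NULL) {
  validate_sim_config(cfg)
  if (is.null(rng_seed)) rng_seed <- derive_seed(cfg$seed, "reads")
  set.seed(rng_seed)
  amps <- sim$amplicons
  too_long <- nchar(amps) >= 2L * cfg$read_len
  if (any(too_long)) {
    stop(sprintf("%d amplicon(s) of length >= %d cannot be spanned by 2 x %d reads",
                 sum(too_long), min(nchar(amps[too_long])), cfg$read_len))
  }
  n <- length(amps)
  r1 <- q1 <- r2 <- q2 <- character(n)
  e1 <- e2 <- integer(n)
  for (i in seq_len(n)) {
    L <- nchar(amps[i])
    rl <- min(cfg$read_len, L)
    fwd <- substr(amps[i], 1L, rl)
    rev <- revcomp(substr(amps[i], L - rl + 1L, L))
    m1 <- .mutate_read(fwd, cfg$error_rate)
    m2 <- .mutate_read(rev, cfg$error_rate)
    r1[i] <- m1$seq; e1[i] <- length(m1$sites)
    r2[i] <- m2$seq; e2[i] <- length(m2$sites)
    q1[i] <- .qual_string(rl, m1$sites, cfg$qual_hi, cfg$qual_err)
    q2[i] <- .qual_string(rl, m2$sites, cfg$qual_hi, cfg$qual_err)
  }
  out <- data.frame(read_id = if (!is.null(sim$truth)) sim$truth$read_id
                              else sprintf("read%06d", seq_len(n)),
                    r1 = r1, q1 = q1, r2 = r2, q2 = q2,
                    n_err1 = e1, n_err2 = e2,
                    amplicon_len = nchar(amps),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Simulate plasmid-loss colony screens
#'
#' Each screen plates `n_colonies` colonies on permissive and selective
#' medium; a colony growing only without antibiotic has lost the plasmid.
#' Lost counts are Binomial(`n_colonies`, `p_loss`).
#'
#' @param n_colonies colonies screened per replicate.
#' @param p_loss per-colony probability of plasmid loss.
#' @param rng_seed seed.
#' @param n_screens number of replicate screens.
#' @return for `n_screens = 1` an `assay_counts` object; otherwise a
#'   data.frame with `screen`, `n_total`, `n_lost`.
#' @export
simulate_colony_screen <- function(n_colonies, p_loss, rng_seed = 1L,
                                   n_screens = 1L) {
  stopifnot(n_colonies >= 1L, p_loss >= 0, p_loss <= 1)
  set.seed(rng_seed)
  lost <- stats::rbinom(n_screens, n_colonies, p_loss)
  if (n_screens == 1L) return(assay_counts(n_colonies, lost))
  data.frame(screen = seq_len(n_screens), n_total = n_colonies,
             n_lost = lost)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [build_references()], [simulate_arrays()]
#' and [simulate_read_pairs()] under per-stage seeds derived from
#' `cfg$seed`, so the whole cohort is reproducible from the config alone.
#'
#' @param cfg a [sim_config()].
#' @return list with `refs`, `arrays`, `amplicons`, `truth`, `pairs`.
#' @export
simulate_cohort <- function(cfg) {
  refs <- build_references(cfg)
  sim <- simulate_arrays(cfg, refs)
  pairs <- simulate_read_pairs(sim, cfg)
  list(refs = refs, arrays = sim$arrays, amplicons = sim$amplicons,
       truth = sim$truth, pairs = pairs)
}
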