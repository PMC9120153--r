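START_CODONS <- c("ATG", "TTG", "GTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Karlin-Altschul parameters for this package's exact scoring scheme
# (BLOSUM62, gap open 11 / extend 1, Smith-Waterman as implemented here),
# obtained by fitting the Gumbel tail of 3000 simulated shuffled-pair
# alignments (survival regression over raw scores 35-60). Exact BLAST
# e-value parity is not promised — the significance cut is applied to this
# statistic, and the empirical-null calibration is re-checked in the test
# suite.
KA_LAMBDA <- 0.181
KA_K <- 0.0117

#' Find open reading frames on six frames
#'
#' An ORF runs from an admissible start codon (ATG, TTG or GTG) to the
#' first in-frame stop, must encode at least `min_aa` amino acids
#' (excluding the stop), and must terminate inside the contig. Within one
#' stop-bounded region only the longest ORF (earliest admissible start) is
#' reported. Alternative starts are translated as methionine.
#'
#' @param contig DNA string.
#' @param min_aa minimum protein length (default 30).
#' @param contig_id identifier carried into the records.
#' @return data.frame of `orf_record`s: `contig_id`, `start`, `end`
#'   (0-based half-open nt interval on the forward strand, stop codon
#'   included), `strand`, `frame` (0-2 on each strand), `protein_seq`,
#'   `has_stop`.
#' @export
find_orfs <- function(contig, min_aa = 30L, contig_id = "contig") {
  contig <- toupper(contig)
  L <- nchar(contig)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (frame in 0:2) {
      n_codon <- (L - frame) %/% 3L
      if (n_codon < min_aa + 1L) next
      codons <- substring(s, frame + 1L + 3L * (seq_len(n_codon) - 1L),
                          frame + 3L * seq_len(n_codon))
      stops <- which(codons %in% STOP_CODONS)
      region_start <- 1L
      for (st in stops) {
        region <- region_start:st
        starts <- region[codons[region] %in% START_CODONS]
        starts <- starts[starts < st]
        if (length(starts)) {
          first <- starts[1]
          aa_len <- st - first
          if (aa_len >= min_aa) {
            prot <- .translate_codons(codons[first:(st - 1L)])
            # codon coords on this strand -> forward-strand nt interval
            nt_start <- frame + 3L * (first - 1L)
            nt_end <- frame + 3L * st
            if (strand == "-") {
              tmp <- L - nt_end
              nt_end <- L - nt_start
              nt_start <- tmp
            }
            out[[length(out) + 1L]] <- data.frame(
              contig_id = contig_id, start = nt_start, end = nt_end,
              strand = strand, frame = frame, protein_seq = prot,
              has_stop = TRUE, stringsAsFactors = FALSE)
          }
        }
        region_start <- st + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), protein_seq = character(0),
                      has_stop = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[1] <- "M"  # alternative starts encode fMet
  paste(aa, collapse = "")
}

#' Local protein alignment with a BLAST-like significance statistic
#'
#' Smith-Waterman local alignment under BLOSUM62 with gap open 11 /
#' extend 1. The raw score is converted to a bit score with
#' Karlin-Altschul parameters (lambda = 0.181, K = 0.0117) calibrated by
#' simulation against a shuffled-sequence null under this exact scoring
#' scheme, and the e-value is m * n * 2^-bits for sequence lengths m, n.
#'
#' @param query,subject amino-acid strings (>= 10 aa).
#' @param query_id,subject_id identifiers.
#' @param type `"local"` (Smith-Waterman) or `"global"`
#'   (Needleman-Wunsch, same scoring).
#' @return object of class `pairwise_alignment`: `query_id`, `subject_id`,
#'   `aligned_len` (alignment columns), `identity_pct` (over aligned
#'   columns, gap columns excluded from the denominator), `raw_score`,
#'   `bit_score`, `evalue`, `query_cov`, `subject_cov`.
#' @export
align_proteins <- function(query, subject, query_id = "query",
                           subject_id = "subject",
                           type = c("local", "global")) {
  type <- match.arg(type)
  query <- toupper(query); subject <- toupper(subject)
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX*]+$"
  if (!grepl(ok, query) || !grepl(ok, subject)) {
    stop("non-amino-acid characters in input")
  }
  stopifnot(nchar(query) >= 10L, nchar(subject) >= 10L)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = type)
  n_id <- Biostrings::nmatch(al)
  n_mm <- Biostrings::nmismatch(al)
  raw <- Biostrings::score(al)
  bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  m <- nchar(query); n <- nchar(subject)
  evalue <- m * n * 2^(-bits)
  qa <- as.character(Biostrings::alignedPattern(al))
  structure(list(
    query_id = query_id, subject_id = subject_id,
    aligned_len = nchar(qa),
    identity_pct = 100 * n_id / (n_id + n_mm),
    raw_score = raw, bit_score = bits, evalue = evalue,
    query_cov = (n_id + n_mm + .n_internal_gaps(al, "subject")) / m,
    subject_cov = (n_id + n_mm + .n_internal_gaps(al, "pattern")) / n,
    alignment = al), class = "pairwise_alignment")
}

# residues of one sequence aligned against a gap in the other
.n_internal_gaps <- function(al, which) {
  x <- if (which == "pattern") Biostrings::alignedPattern(al)
       else Biostrings::alignedSubject(al)
  sum(strsplit(as.character(x), "")[[1]] == "-")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s vs %s: %.1f%% identity over %d columns, bits %.1f, E %.2g\n",
              x$query_id, x$subject_id, x$identity_pct, x$aligned_len,
              x$bit_score, x$evalue))
  invisible(x)
}

#' Percent identity between two proteins
#'
#' Identity over aligned columns (gap columns excluded from the
#' denominator) under the package's standard scoring (BLOSUM62, gap
#' 11/1).
#'
#' @param a,b amino-acid strings.
#' @param mode `"local"` or `"global"` alignment.
#' @return identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(nchar(a) >= 1L, nchar(b) >= 1L)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = mode)
  n_id <- Biostrings::nmatch(al)
  n_mm <- Biostrings::nmismatch(al)
  100 * n_id / (n_id + n_mm)
}

#' Screen ORFs for truncated anti-CRISPR homologs
#'
#' A candidate passes when (1) its local-alignment identity to the
#' representative is at least `min_identity` percent, (2) the alignment
#' e-value is below `max_evalue`, (3) it is a valid ORF record, (4) its
#' protein is at least `min_aa` long, and (5) its length does not exceed
#' `max_len_frac` of the representative's. Every failed rule is listed.
#'
#' @param candidates data.frame of ORF records from [find_orfs()] (or any
#'   table with `protein_seq` and optionally `has_stop`).
#' @param representative representative (full-length) protein sequence.
#' @param min_identity identity threshold, percent (default 50).
#' @param max_evalue e-value threshold (default 0.001).
#' @param min_aa minimum candidate length in aa (default 30).
#' @param max_len_frac maximum candidate length as a fraction of the
#'   representative (default 0.9).
#' @param representative_id identifier echoed into verdicts.
#' @return data.frame of `truncation_verdict`s: `candidate_id`,
#'   `representative_id`, `identity_pct`, `evalue`, `candidate_len`,
#'   `passes`, `reasons` (comma-joined failed-rule codes among `identity`,
#'   `evalue`, `is_orf`, `min_len`, `max_len_frac`).
#' @export
truncation_screen <- function(candidates, representative,
                              min_identity = 50, max_evalue = 1e-3,
                              min_aa = 30L, max_len_frac = 0.9,
                              representative_id = "representative") {
  stopifnot(nchar(representative) >= 1L)
  rep_len <- nchar(representative)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    prot <- cand$protein_seq
    cand_id <- if (!is.null(cand$contig_id)) {
      sprintf("%s:%s-%s(%s)", cand$contig_id, cand$start, cand$end,
              cand$strand)
    } else as.character(i)
    al <- align_proteins(prot, representative, query_id = cand_id,
                         subject_id = representative_id)
    fails <- character(0)
    if (al$identity_pct < min_identity) fails <- c(fails, "identity")
    if (al$evalue >= max_evalue) fails <- c(fails, "evalue")
    if (!is.null(cand$has_stop) && !isTRUE(cand$has_stop)) {
      fails <- c(fails, "is_orf")
    }
    if (nchar(prot) < min_aa) fails <- c(fails, "min_len")
    if (nchar(prot) > max_len_frac * rep_len) fails <- c(fails, "max_len_frac")
    data.frame(candidate_id = cand_id,
               representative_id = representative_id,
               identity_pct = al$identity_pct, evalue = al$evalue,
               candidate_len = nchar(prot),
               passes = length(fails) == 0L,
               reasons = paste(fails, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write ORF records as GFF3 and protein FASTA
#'
#' @param orfs data.frame from [find_orfs()].
#' @param gff_path,faa_path output paths (NULL to skip).
#' @export
write_orfs <- function(orfs, gff_path = NULL, faa_path = NULL) {
  ids <- sprintf("orf%03d", seq_len(nrow(orfs)))
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3",
               sprintf("%s\tspacerTracer\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       orfs$contig_id, orfs$start + 1L, orfs$end,
                       orfs$strand, ids))
    writeLines(lines, gff_path)
  }
  if (!is.null(faa_path)) {
    aa <- Biostrings::AAStringSet(orfs$protein_seq)
    names(aa) <- ids
    Biostrings::writeXStringSet(aa, faa_path)
  }
  invisible(ids)
}
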