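#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#' @importFrom Biostrings BStringSet reverseComplement readDNAStringSet
#' @importFrom Biostrings readAAStringSet writeXStringSet
#' @importFrom Biostrings IUPAC_CODE_MAP GENETIC_CODE pairwiseAlignment
#' @importFrom Biostrings score nmatch nmismatch alignedPattern alignedSubject
#' @importFrom S4Vectors mcols
#' @importFrom stats rbinom runif setNames chisq.test qnorm
#' @importFrom utils write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (ACGT plus IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(reverseComplement(DNAStringSet(x)))
}

# Integer codes of a DNA string, for vectorised per-position comparison.
.dna_int <- function(seq) utf8ToInt(seq)

#' Hamming-distance sliding-window scan
#'
#' Finds every window of `seq` within Hamming distance `max_mismatch` of
#' `pattern` (substitutions only, forward orientation). This is the anchoring
#' primitive for repeat detection and protospacer mapping.
#'
#' @param seq DNA string to scan.
#' @param pattern DNA string (exact bases, no ambiguity codes).
#' @param max_mismatch maximum substitutions tolerated per window.
#' @return data.frame with 0-based half-open `start`, `end` and `mismatches`,
#'   ordered by position.
#' @export
hamming_scan <- function(seq, pattern, max_mismatch = 0L) {
  m <- nchar(pattern)
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0))
  if (L < m || m == 0L) return(empty)
  s <- .dna_int(seq)
  p <- .dna_int(pattern)
  n_off <- L - m + 1L
  mm <- integer(n_off)
  for (j in seq_len(m)) {
    mm <- mm + (s[j:(j + n_off - 1L)] != p[j])
  }
  keep <- which(mm <= max_mismatch)
  data.frame(start = keep - 1L, end = keep - 1L + m,
             mismatches = mm[keep])
}

# IUPAC code -> set of concrete bases
.iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  expanded <- map[toupper(code)]
  if (anyNA(expanded)) {
    stop("invalid IUPAC code(s): ",
         paste(unique(code[is.na(expanded)]), collapse = ", "))
  }
  strsplit(unname(expanded), "")
}

#' Scan a sequence for matches to an IUPAC pattern
#'
#' Sliding-window scan where each pattern position may be any IUPAC ambiguity
#' code; a window matches when every base falls in the allowed set. Used to
#' locate plantable PAM sites and to validate extracted PAMs.
#'
#' @param seq DNA string (concrete bases).
#' @param pattern IUPAC DNA string, e.g. `"NNAGAAW"`.
#' @param both_strands also scan the reverse complement; minus-strand matches
#'   are reported in forward coordinates with `strand == "-"`.
#' @return data.frame with 0-based half-open `start`, `end`, `strand`.
#' @export
iupac_scan <- function(seq, pattern, both_strands = FALSE) {
  m <- nchar(pattern)
  L <- nchar(seq)
  scan_one <- function(s_chr) {
    if (L < m || m == 0L) return(integer(0))
    s <- .dna_int(s_chr)
    allowed <- .iupac_bases(strsplit(pattern, "")[[1]])
    n_off <- L - m + 1L
    ok <- rep(TRUE, n_off)
    for (j in seq_len(m)) {
      ok <- ok & (s[j:(j + n_off - 1L)] %in% utf8ToInt(paste(allowed[[j]],
                                                             collapse = "")))
    }
    which(ok) - 1L
  }
  fwd <- scan_one(seq)
  out <- data.frame(start = fwd, end = fwd + m,
                    strand = rep("+", length(fwd)))
  if (both_strands) {
    rev_hits <- scan_one(revcomp(seq))
    if (length(rev_hits)) {
      # window [s, s+m) on the reverse strand maps to [L-s-m, L-s) forward
      fs <- L - rev_hits - m
      out <- rbind(out, data.frame(start = fs, end = fs + m,
                                   strand = rep("-", length(fs))))
    }
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p,
       lower = max(0, centre - half),
       upper = min(1, centre + half))
}

# Derive a per-stage 32-bit seed from a root seed so stages are independently
# reproducible. Stage names hash by character codes.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Random DNA of length n under the current RNG state.
random_dna <- function(n, bases = DNA_BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
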