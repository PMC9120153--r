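# Independent reference implementations used to cross-check the package.
# These deliberately use different mechanisms (regex, per-window substring
# comparison, per-position codon walks) from the vectorised production code.

# Count overlapping IUPAC-pattern matches by regex lookahead.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  classes <- vapply(strsplit(pattern, "")[[1]], function(code) {
    paste0("[", map[[code]], "]")
  }, character(1))
  paste(classes, collapse = "")
}

oracle_iupac_count <- function(seq, pattern, both_strands = TRUE) {
  rx <- sprintf("(?=%s)", iupac_regex(pattern))
  count_one <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    sum(m > 0)
  }
  n <- count_one(seq)
  if (both_strands) n <- n + count_one(spacerTracer::revcomp(seq))
  n
}

oracle_iupac_matches <- function(seq, pattern) {
  rx <- sprintf("(?=%s)", iupac_regex(pattern))
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (all(m < 0)) integer(0) else as.integer(m) - 1L  # 0-based starts
}

# All windows within Hamming distance k, one substring comparison at a time.
oracle_hamming_scan <- function(seq, pattern, max_mm) {
  m <- nchar(pattern)
  L <- nchar(seq)
  p <- strsplit(pattern, "")[[1]]
  out <- data.frame(start = integer(0), end = integer(0),
                    mismatches = integer(0))
  if (L < m) return(out)
  for (s in 0:(L - m)) {
    w <- strsplit(substr(seq, s + 1L, s + m), "")[[1]]
    mm <- sum(w != p)
    if (mm <= max_mm) {
      out <- rbind(out, data.frame(start = s, end = s + m, mismatches = mm))
    }
  }
  out
}

# Greedy left-to-right non-overlap resolution applied to an interval table.
oracle_greedy <- function(hits) {
  keep <- logical(nrow(hits))
  cur <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= cur) {
      keep[i] <- TRUE
      cur <- hits$end[i]
    }
  }
  hits[keep, , drop = FALSE]
}

# Brute-force overlap scorer for the merger: best (mismatches, overlap).
oracle_best_overlap <- function(r1, r2, min_overlap) {
  rc2 <- spacerTracer::revcomp(r2)
  l1 <- nchar(r1); l2 <- nchar(rc2)
  best <- NULL
  if (min(l1, l2) < min_overlap) return(NULL)
  for (o in min_overlap:min(l1, l2)) {
    t1 <- strsplit(substr(r1, l1 - o + 1L, l1), "")[[1]]
    h2 <- strsplit(substr(rc2, 1L, o), "")[[1]]
    mm <- sum(t1 != h2)
    if (is.null(best) || mm < best$mm || (mm == best$mm && o > best$o)) {
      best <- list(o = o, mm = mm)
    }
  }
  best
}

# Per-position codon walk over six frames; longest ORF per stop kept.
oracle_orfs <- function(contig, min_aa) {
  starts <- c("ATG", "TTG", "GTG")
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(contig)
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else spacerTracer::revcomp(contig)
    for (i in seq_len(L - 2L)) {
      if (!substr(s, i, i + 2L) %in% starts) next
      j <- i
      stop_at <- NA
      while (j + 2L <= L) {
        if (substr(s, j, j + 2L) %in% stops) { stop_at <- j; break }
        j <- j + 3L
      }
      if (is.na(stop_at)) next
      aa_len <- (stop_at - i) / 3L
      if (aa_len < min_aa) next
      found[[length(found) + 1L]] <- data.frame(
        strand = strand, start_on_strand = i - 1L,
        stop_on_strand = stop_at - 1L, aa_len = aa_len)
    }
  }
  if (!length(found)) {
    return(data.frame(strand = character(0), start_on_strand = integer(0),
                      stop_on_strand = integer(0), aa_len = integer(0)))
  }
  all <- do.call(rbind, found)
  # longest ORF per (strand, stop)
  keep <- unlist(lapply(split(seq_len(nrow(all)),
                              paste(all$strand, all$stop_on_strand)),
                        function(idx) idx[which.max(all$aa_len[idx])]))
  res <- all[sort(keep), , drop = FALSE]
  rownames(res) <- NULL
  res
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
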