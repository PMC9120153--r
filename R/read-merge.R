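#' Merge one overlapping read pair
#'
#' Reverse-complements the reverse read, scores every candidate overlap of
#' at least `min_overlap` nt by mismatch count, and keeps the overlap with
#' the fewest mismatches (ties broken by the longest overlap). The pair is
#' accepted when the mismatch fraction in the chosen overlap is at most
#' `max_mismatch_frac`; at disagreeing overlap positions the base with the
#' higher Phred quality wins, ties going to read 1.
#'
#' @param r1,r2 forward and reverse read sequences (reverse read in raw
#'   sequencer orientation).
#' @param q1,q2 optional Phred+33 quality strings; when absent, read 1 wins
#'   all overlap disagreements.
#' @param min_overlap smallest admissible overlap (>= 8 nt).
#' @param max_mismatch_frac largest tolerated mismatch fraction in the
#'   overlap.
#' @param id1,id2 read identifiers carried into the result.
#' @return list of class `merged_read` with `sequence`, `overlap_len`,
#'   `mismatches_in_overlap`, `source_ids`, `status = "merged"` — or of
#'   class `merge_rejection` with `status = "rejected"` and a `reason` code
#'   (`"no_admissible_overlap"` or `"mismatch_fraction"`).
#' @export
merge_pair <- function(r1, r2, q1 = NULL, q2 = NULL,
                       min_overlap = 20L, max_mismatch_frac = 0.1,
                       id1 = "r1", id2 = "r2") {
  stopifnot(nchar(r1) > 0L, nchar(r2) > 0L, min_overlap >= 8L)
  rc2 <- revcomp(r2)
  qc2 <- if (!is.null(q2)) .reverse_chars(q2) else NULL
  l1 <- nchar(r1); l2 <- nchar(rc2)
  max_o <- min(l1, l2)
  if (max_o < min_overlap) {
    return(.merge_reject(id1, id2, "no_admissible_overlap"))
  }
  a <- .dna_int(r1)
  b <- .dna_int(rc2)
  best_o <- NA_integer_; best_mm <- Inf
  for (o in min_overlap:max_o) {
    mm <- sum(a[(l1 - o + 1L):l1] != b[1:o])
    if (mm < best_mm || (mm == best_mm && o > best_o)) {
      best_mm <- mm; best_o <- o
    }
  }
  if (best_mm / best_o > max_mismatch_frac) {
    return(.merge_reject(id1, id2, "mismatch_fraction",
                         overlap_len = best_o, mismatches = best_mm))
  }
  ov1 <- (l1 - best_o + 1L):l1
  ov2 <- 1:best_o
  cons <- a[ov1]
  if (best_mm > 0L) {
    diff <- which(a[ov1] != b[ov2])
    if (!is.null(q1) && !is.null(qc2)) {
      qa <- utf8ToInt(q1)[ov1][diff]
      qb <- utf8ToInt(qc2)[ov2][diff]
      take2 <- qb > qa
      cons[diff[take2]] <- b[ov2][diff[take2]]
    }
  }
  merged <- paste0(substr(r1, 1L, l1 - best_o),
                   intToUtf8(cons),
                   substr(rc2, best_o + 1L, l2))
  structure(list(sequence = merged, overlap_len = best_o,
                 mismatches_in_overlap = best_mm,
                 source_ids = c(id1, id2), status = "merged"),
            class = "merged_read")
}

.reverse_chars <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

.merge_reject <- function(id1, id2, reason, overlap_len = NA_integer_,
                          mismatches = NA_integer_) {
  structure(list(sequence = NA_character_, overlap_len = overlap_len,
                 mismatches_in_overlap = mismatches,
                 source_ids = c(id1, id2), status = "rejected",
                 reason = reason),
            class = "merge_rejection")
}

#' Merge a cohort of read pairs
#'
#' Applies [merge_pair()] to every row of a `read_pairs` table; unmerged
#' pairs are dropped from downstream analysis but counted in the report.
#'
#' @param pairs `read_pairs` data.frame (columns `read_id`, `r1`, `q1`,
#'   `r2`, `q2`).
#' @inheritParams merge_pair
#' @return list with `merged` (data.frame: `read_id`, `sequence`,
#'   `overlap_len`, `mismatches`) and `report` (per-read `status`, `reason`).
#' @export
merge_pairs <- function(pairs, min_overlap = 20L, max_mismatch_frac = 0.1) {
  n <- nrow(pairs)
  status <- reason <- character(n)
  seqs <- character(n); ov <- mm <- integer(n)
  has_q <- all(c("q1", "q2") %in% names(pairs))
  for (i in seq_len(n)) {
    m <- merge_pair(pairs$r1[i], pairs$r2[i],
                    q1 = if (has_q) pairs$q1[i],
                    q2 = if (has_q) pairs$q2[i],
                    min_overlap = min_overlap,
                    max_mismatch_frac = max_mismatch_frac,
                    id1 = pairs$read_id[i], id2 = pairs$read_id[i])
    status[i] <- m$status
    reason[i] <- if (m$status == "rejected") m$reason else ""
    seqs[i] <- if (m$status == "merged") m$sequence else NA_character_
    ov[i] <- if (!is.na(m$overlap_len)) m$overlap_len else NA_integer_
    mm[i] <- if (!is.na(m$mismatches_in_overlap)) m$mismatches_in_overlap
             else NA_integer_
  }
  keep <- status == "merged"
  list(merged = data.frame(read_id = pairs$read_id[keep],
                           sequence = seqs[keep],
                           overlap_len = ov[keep], mismatches = mm[keep],
                           stringsAsFactors = FALSE),
       report = data.frame(read_id = pairs$read_id, status = status,
                           reason = reason, stringsAsFactors = FALSE))
}
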