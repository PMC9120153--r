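#' Repeat specification for array parsing
#'
#' @param sequence direct-repeat sequence (DNA).
#' @param max_mismatch Hamming tolerance per repeat occurrence; must not
#'   exceed a quarter of the repeat length.
#' @return object of class `repeat_spec`.
#' @export
repeat_spec <- function(sequence, max_mismatch = 3L) {
  sequence <- toupper(sequence)
  stopifnot(grepl("^[ACGT]+$", sequence))
  max_mismatch <- as.integer(max_mismatch)
  if (max_mismatch < 0L || max_mismatch > nchar(sequence) / 4) {
    stop("max_mismatch must lie in [0, len(repeat)/4]")
  }
  structure(list(sequence = sequence, max_mismatch = max_mismatch),
            class = "repeat_spec")
}

#' Locate direct-repeat occurrences in a merged read
#'
#' Mismatch-tolerant (substitution-only) scan for the repeat in forward
#' orientation; amplicons are primer-oriented so no reverse search is
#' needed. Overlapping candidate windows are resolved greedily left to
#' right: the leftmost window is accepted and scanning resumes at its end.
#'
#' @param seq merged-read sequence.
#' @param spec a [repeat_spec()].
#' @return data.frame of 0-based half-open intervals (`start`, `end`,
#'   `mismatches`), non-overlapping, ordered by position.
#' @export
find_repeats <- function(seq, spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  hits <- hamming_scan(seq, spec$sequence, spec$max_mismatch)
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(nrow(hits))
  cur_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= cur_end) {
      keep[i] <- TRUE
      cur_end <- hits$end[i]
    }
  }
  hits[keep, , drop = FALSE]
}

#' Parse a merged read into repeat/spacer structure
#'
#' Spacers are the inter-repeat segments, reported leader-proximal first
#' (the amplicon's forward orientation). Segments shorter than 15 nt or
#' longer than 60 nt are kept but flagged atypical.
#'
#' @param seq merged-read sequence.
#' @param spec a [repeat_spec()].
#' @param source_id identifier carried into the result.
#' @return object of class `crispr_array`: `spacers` (character),
#'   `atypical` (logical flags), `repeat_positions` (interval data.frame),
#'   `source_id`, `seq` (the parsed segment).
#' @export
parse_array <- function(seq, spec, source_id = NA_character_) {
  reps <- find_repeats(seq, spec)
  if (nrow(reps) < 2L) {
    stop("unparseable: fewer than 2 repeat occurrences found",
         call. = FALSE)
  }
  n_sp <- nrow(reps) - 1L
  spacers <- character(n_sp)
  for (i in seq_len(n_sp)) {
    spacers[i] <- substr(seq, reps$end[i] + 1L, reps$start[i + 1L])
  }
  lens <- nchar(spacers)
  structure(list(spacers = spacers,
                 atypical = lens < 15L | lens > 60L,
                 repeat_positions = reps,
                 source_id = source_id,
                 seq = seq),
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("crispr_array: %d repeats, %d spacers (%s)\n",
              nrow(x$repeat_positions), length(x$spacers),
              paste(nchar(x$spacers), collapse = "/")))
  invisible(x)
}

#' Serialise a parsed array back to sequence
#'
#' Concatenates the parsed segment's repeats and spacers in reported order;
#' by construction this reconstructs `seq` between the first and last
#' repeat exactly.
#'
#' @param array a `crispr_array`.
#' @param repeat_seq repeat sequence to interleave (defaults to the exact
#'   windows observed in the parsed read).
#' @return DNA string.
#' @export
serialize_array <- function(array, repeat_seq = NULL) {
  reps <- array$repeat_positions
  windows <- if (is.null(repeat_seq)) {
    vapply(seq_len(nrow(reps)), function(i) {
      substr(array$seq, reps$start[i] + 1L, reps$end[i])
    }, character(1))
  } else rep(repeat_seq, nrow(reps))
  out <- windows[1]
  for (i in seq_along(array$spacers)) {
    out <- paste0(out, array$spacers[i], windows[i + 1L])
  }
  out
}

# Hamming distance between equal-length strings; Inf on length mismatch.
.spacer_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(.dna_int(a) != .dna_int(b))
}

#' Call spacer acquisition for one parsed array
#'
#' A spacer is *new* when its Hamming distance to every ancestral spacer
#' exceeds `novelty_max_mismatch` (length-mismatched comparisons count as
#' distance infinity). The array is *expanded* when it shows more
#' repeat-spacer units than the ancestral amplified window or contains at
#' least one new spacer; both conditions are recorded separately.
#'
#' @param array a `crispr_array` from [parse_array()].
#' @param ancestral ancestral spacers: a character vector or a
#'   `crispr_array`.
#' @param novelty_max_mismatch Hamming tolerance for matching an ancestral
#'   spacer.
#' @return object of class `acquisition_call`: `read_id`, `expanded`,
#'   `expanded_by_count`, `expanded_by_novelty`, `new_spacers`, `n_units`.
#' @export
call_acquisition <- function(array, ancestral, novelty_max_mismatch = 2L) {
  anc <- if (inherits(ancestral, "crispr_array")) ancestral$spacers
         else as.character(ancestral)
  stopifnot(length(anc) >= 1L)
  is_new <- vapply(array$spacers, function(s) {
    all(vapply(anc, .spacer_dist, numeric(1), a = s) > novelty_max_mismatch)
  }, logical(1), USE.NAMES = FALSE)
  n_units <- length(array$spacers)
  by_count <- n_units > length(anc)
  by_novelty <- any(is_new)
  structure(list(read_id = array$source_id,
                 expanded = by_count || by_novelty,
                 expanded_by_count = by_count,
                 expanded_by_novelty = by_novelty,
                 new_spacers = array$spacers[is_new],
                 n_units = n_units),
            class = "acquisition_call")
}

#' Acquisition fraction with Wilson 95% interval
#'
#' Point estimate is expanded reads over parseable reads; the interval is
#' the Wilson score interval.
#'
#' @param calls list of `acquisition_call` objects, or a logical vector of
#'   expanded flags.
#' @param conf confidence level.
#' @return list with `estimate`, `lower`, `upper`, `n_expanded`, `n_total`.
#' @export
acquisition_fraction <- function(calls, conf = 0.95) {
  expanded <- if (is.logical(calls)) calls
              else vapply(calls, function(c) isTRUE(c$expanded), logical(1))
  n <- length(expanded)
  stopifnot(n >= 1L)
  ci <- wilson_ci(sum(expanded), n, conf)
  c(ci, list(n_expanded = sum(expanded), n_total = n))
}

#' Detect acquisition across a merged cohort
#'
#' Parses every merged read and calls acquisition against the ancestral
#' spacer set. Reads whose array cannot be parsed (fewer than two repeat
#' hits) are excluded from the denominator and reported.
#'
#' @param merged data.frame with `read_id`, `sequence` (from
#'   [merge_pairs()]).
#' @param spec a [repeat_spec()].
#' @param ancestral ancestral spacers (character vector).
#' @param novelty_max_mismatch see [call_acquisition()].
#' @return list with `calls` (data.frame: `read_id`, `expanded`,
#'   `expanded_by_count`, `expanded_by_novelty`, `n_units`, `new_spacers`
#'   comma-joined), `unparseable` (read ids), `fraction`
#'   (from [acquisition_fraction()]), and `spacer_counts` (named counts of
#'   unique new spacers).
#' @export
detect_acquisition <- function(merged, spec, ancestral,
                               novelty_max_mismatch = 2L) {
  n <- nrow(merged)
  ok <- logical(n)
  rows <- vector("list", n)
  new_pool <- character(0)
  for (i in seq_len(n)) {
    arr <- tryCatch(parse_array(merged$sequence[i], spec,
                                source_id = merged$read_id[i]),
                    error = function(e) NULL)
    if (is.null(arr)) next
    ok[i] <- TRUE
    call <- call_acquisition(arr, ancestral, novelty_max_mismatch)
    rows[[i]] <- data.frame(read_id = call$read_id,
                            expanded = call$expanded,
                            expanded_by_count = call$expanded_by_count,
                            expanded_by_novelty = call$expanded_by_novelty,
                            n_units = call$n_units,
                            new_spacers = paste(call$new_spacers,
                                                collapse = ","),
                            stringsAsFactors = FALSE)
    new_pool <- c(new_pool, call$new_spacers)
  }
  calls <- do.call(rbind, rows[ok])
  if (is.null(calls)) {
    stop("no parseable reads in cohort", call. = FALSE)
  }
  counts <- sort(table(new_pool), decreasing = TRUE)
  list(calls = calls,
       unparseable = merged$read_id[!ok],
       fraction = acquisition_fraction(calls$expanded),
       spacer_counts = stats::setNames(as.integer(counts), names(counts)))
}
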