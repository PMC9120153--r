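REF_PRIORITY <- c("plasmid", "acr", "genome")

#' Map a spacer to the reference set
#'
#' Exhaustive substitution-only search for the spacer on both strands of
#' every reference, reporting all positions within `max_mismatch`. The
#' plasmid reference is treated as circular: windows may wrap the origin
#' (reported with `start < ref length <= end`). The spacer-level category
#' is taken from the best hit, with ties across reference categories
#' reported as `"ambiguous"` and no hit at all as `"unmapped"`.
#'
#' @param spacer spacer sequence (>= 15 nt).
#' @param refs a `reference_set` (or list with `sequences` and `circular`).
#' @param max_mismatch Hamming tolerance (default 0: perfect matches only,
#'   the convention used for target classification).
#' @return data.frame of hits — `spacer_seq`, `ref_id`, `start`, `end`
#'   (0-based half-open, forward strand), `strand`, `mismatches`,
#'   `category` — sorted by mismatches, then reference priority
#'   (plasmid, acr, genome), then position; the spacer-level call is in
#'   `attr(, "category")`.
#' @export
map_spacer <- function(spacer, refs, max_mismatch = 0L) {
  stopifnot(nchar(spacer) >= 15L)
  m <- nchar(spacer)
  rc <- revcomp(spacer)
  out <- list()
  for (ref in names(refs$sequences)) {
    s <- refs$sequences[[ref]]
    L <- nchar(s)
    circ <- isTRUE(refs$circular[[ref]])
    scan_seq <- if (circ) paste0(s, substr(s, 1L, m - 1L)) else s
    for (strand in c("+", "-")) {
      qry <- if (strand == "+") spacer else rc
      h <- hamming_scan(scan_seq, qry, max_mismatch)
      if (circ) h <- h[h$start < L, , drop = FALSE]
      if (nrow(h) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        spacer_seq = spacer, ref_id = ref,
        start = h$start, end = h$start + m, strand = strand,
        mismatches = h$mismatches, category = ref,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out)
          else data.frame(spacer_seq = character(0), ref_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), mismatches = integer(0),
                          category = character(0))
  if (nrow(hits)) {
    prio <- match(hits$ref_id, REF_PRIORITY, nomatch = length(REF_PRIORITY) + 1L)
    hits <- hits[order(hits$mismatches, prio, hits$start, hits$strand), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    best <- hits$mismatches == hits$mismatches[1]
    cats <- unique(hits$category[best])
    attr(hits, "category") <- if (length(cats) > 1L) "ambiguous" else cats
  } else {
    attr(hits, "category") <- "unmapped"
  }
  hits
}

#' Classify a set of unique spacers with read counts
#'
#' Maps every unique spacer, assigns its category, and extracts the PAM of
#' the best hit when that hit is unique and mismatch-free.
#'
#' @param spacer_counts named integer vector: unique spacer -> read count
#'   (e.g. `spacer_counts` from [detect_acquisition()]).
#' @param refs a `reference_set`.
#' @param max_mismatch Hamming tolerance for mapping.
#' @param flank PAM length to extract.
#' @return data.frame: `spacer`, `count`, `category`, `ref_id`, `start`,
#'   `end`, `strand`, `mismatches`, `pam` (NA when unavailable).
#' @export
classify_spacers <- function(spacer_counts, refs, max_mismatch = 0L,
                             flank = 7L) {
  spacers <- names(spacer_counts)
  rows <- lapply(seq_along(spacers), function(i) {
    hits <- map_spacer(spacers[i], refs, max_mismatch)
    cat <- attr(hits, "category")
    row <- data.frame(spacer = spacers[i],
                      count = as.integer(spacer_counts[[i]]),
                      category = cat, ref_id = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      strand = NA_character_, mismatches = NA_integer_,
                      pam = NA_character_, stringsAsFactors = FALSE)
    if (nrow(hits) && !cat %in% c("ambiguous", "unmapped")) {
      best <- hits[1, ]
      row$ref_id <- best$ref_id
      row$start <- best$start; row$end <- best$end
      row$strand <- best$strand; row$mismatches <- best$mismatches
      if (best$mismatches == 0L) {
        row$pam <- extract_pam(best, refs, flank)
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Relative target abundance of a spacer cohort
#'
#' Read-count-weighted relative abundance per category, including
#' `unmapped` and `ambiguous`; abundances sum to 1.
#'
#' @param classified data.frame from [classify_spacers()] (needs `category`
#'   and `count`).
#' @return named numeric vector of abundances.
#' @export
categorize_cohort <- function(classified) {
  cats <- c(REF_PRIORITY, "unmapped", "ambiguous")
  if (nrow(classified) == 0L) {
    return(stats::setNames(rep(0, length(cats)), cats))
  }
  tot <- tapply(classified$count, factor(classified$category, levels = cats),
                sum, default = 0L)
  out <- as.numeric(tot) / sum(classified$count)
  stats::setNames(out, cats)
}

#' Positional distribution of protospacer starts
#'
#' Bins hit start positions along one reference, per strand, and reports a
#' chi-square statistic for uniformity over bins (statistic and degrees of
#' freedom only; no automatic verdict).
#'
#' @param classified data.frame with `ref_id`, `start`, `strand`, `count`.
#' @param ref_id reference to map.
#' @param ref_len reference length in nt.
#' @param bin_size bin width in nt (>= 1).
#' @return list with `bins` (data.frame `bin_start`, `bin_end`, `plus`,
#'   `minus`), `chisq`, `df`, `p_value` (NA when no hits).
#' @export
position_map <- function(classified, ref_id, ref_len, bin_size = 100L) {
  stopifnot(bin_size >= 1L)
  sel <- classified[!is.na(classified$ref_id) &
                    classified$ref_id == ref_id, , drop = FALSE]
  breaks <- seq(0L, ref_len + bin_size - 1L, by = bin_size)
  if (breaks[length(breaks)] < ref_len) breaks <- c(breaks, ref_len)
  nb <- length(breaks) - 1L
  bins <- data.frame(bin_start = breaks[-length(breaks)],
                     bin_end = pmin(breaks[-1], ref_len),
                     plus = integer(nb), minus = integer(nb))
  if (nrow(sel)) {
    idx <- findInterval(sel$start %% ref_len, breaks,
                        rightmost.closed = TRUE)
    for (i in seq_len(nrow(sel))) {
      col <- if (sel$strand[i] == "+") "plus" else "minus"
      bins[idx[i], col] <- bins[idx[i], col] + sel$count[i]
    }
  }
  total <- bins$plus + bins$minus
  if (sum(total) == 0L) {
    return(list(bins = bins, chisq = NA_real_, df = nb - 1L,
                p_value = NA_real_))
  }
  widths <- bins$bin_end - bins$bin_start
  test <- suppressWarnings(stats::chisq.test(total, p = widths / sum(widths)))
  list(bins = bins, chisq = unname(test$statistic),
       df = unname(test$parameter), p_value = unname(test$p.value))
}

#' Extract the PAM adjacent to a protospacer hit
#'
#' Returns the `flank` nucleotides immediately 3' of the protospacer on the
#' protospacer strand: reference `[end, end + flank)` for `+` hits and the
#' reverse complement of `[start - flank, start)` for `-` hits. Wrapping is
#' allowed on circular references; `NA` when the flank runs off a linear
#' reference. PAMs are only meaningful for mismatch-free hits.
#'
#' @param hit one hit row from [map_spacer()] (fields `ref_id`, `start`,
#'   `end`, `strand`, `mismatches`).
#' @param refs a `reference_set`.
#' @param flank PAM length (default 7).
#' @return DNA string or `NA_character_`.
#' @export
extract_pam <- function(hit, refs, flank = 7L) {
  stopifnot(hit$mismatches == 0L)
  s <- refs$sequences[[hit$ref_id]]
  circ <- isTRUE(refs$circular[[hit$ref_id]])
  if (hit$strand == "+") {
    .ref_window(s, hit$end, hit$end + flank, circ)
  } else {
    w <- .ref_window(s, hit$start - flank, hit$start, circ)
    if (is.na(w)) NA_character_ else revcomp(w)
  }
}

#' Position frequency model of extracted PAMs
#'
#' Builds the 4 x L position count matrix over extracted PAMs, the
#' per-position information content (2 + sum p log2 p, in bits, with
#' 0 log 0 = 0), and an IUPAC consensus: at each position the smallest
#' IUPAC degeneracy class whose member frequencies sum to at least
#' `consensus_threshold`, `N` otherwise; ties go to the class with the
#' larger frequency mass.
#'
#' @param pams character vector of equal-length PAMs (NAs dropped).
#' @param weights optional read-count weights, one per PAM.
#' @param consensus_threshold frequency mass a degeneracy class must reach.
#' @return object of class `pam_matrix`: `counts` (4 x L), `n_sites`,
#'   `freqs`, `information` (bits per position), `consensus`.
#' @export
build_pam_model <- function(pams, weights = NULL,
                            consensus_threshold = 0.9) {
  keep <- !is.na(pams)
  pams <- pams[keep]
  if (!is.null(weights)) weights <- weights[keep] else
    weights <- rep(1L, length(pams))
  stopifnot(length(pams) >= 1L,
            length(unique(nchar(pams))) == 1L)
  L <- nchar(pams[1])
  counts <- matrix(0L, nrow = 4L, ncol = L,
                   dimnames = list(DNA_BASES, seq_len(L)))
  mat <- do.call(rbind, strsplit(pams, ""))
  for (j in seq_len(L)) {
    t <- tapply(weights, factor(mat[, j], levels = DNA_BASES), sum,
                default = 0)
    counts[, j] <- as.integer(t)
  }
  n_sites <- sum(weights)
  freqs <- counts / n_sites
  info <- apply(freqs, 2, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  consensus <- paste(vapply(seq_len(L), function(j) {
    .iupac_consensus(freqs[, j], consensus_threshold)
  }, character(1)), collapse = "")
  structure(list(counts = counts, n_sites = n_sites, freqs = freqs,
                 information = info, consensus = consensus),
            class = "pam_matrix")
}

# Smallest IUPAC class reaching the frequency threshold at one position.
.iupac_consensus <- function(p, threshold) {
  map <- Biostrings::IUPAC_CODE_MAP
  sizes <- nchar(map)
  mass <- vapply(names(map), function(code) {
    sum(p[strsplit(map[[code]], "")[[1]]])
  }, numeric(1))
  ord <- order(sizes, -mass, names(map))
  for (i in ord) {
    if (mass[i] >= threshold) return(names(map)[i])
  }
  "N"
}

#' @export
print.pam_matrix <- function(x, ...) {
  cat(sprintf("pam_matrix: %d sites, consensus %s\n", x$n_sites,
              x$consensus))
  cat("information (bits):",
      paste(sprintf("%.2f", x$information), collapse = " "), "\n")
  invisible(x)
}

#' Write PAM model outputs
#'
#' Writes the count matrix and the logo-ready per-position frequency table
#' as TSV.
#'
#' @param model a `pam_matrix`.
#' @param counts_path,freqs_path output paths (NULL to skip).
#' @export
write_pam_model <- function(model, counts_path = NULL, freqs_path = NULL) {
  if (!is.null(counts_path)) {
    utils::write.table(model$counts, counts_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(freqs_path)) {
    utils::write.table(t(model$freqs), freqs_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(model$consensus)
}
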