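#' Write a simulated cohort to disk
#'
#' Standard interchange formats: paired FASTQ (Phred+33), references as
#' multi-FASTA, truth table as TSV (0-based half-open coordinates), config
#' as JSON.
#'
#' @param pairs a `read_pairs` data.frame.
#' @param r1_path,r2_path output FASTQ paths.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  .write_fastq(pairs$read_id, pairs$r1, pairs$q1, r1_path)
  .write_fastq(pairs$read_id, pairs$r2, pairs$q2, r2_path)
  invisible(c(r1_path, r2_path))
}

.write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
}

#' @rdname write_fastq_pairs
#' @param r1_path,r2_path FASTQ paths to read.
#' @return `read_fastq_pairs`: a `read_pairs` data.frame (without error
#'   bookkeeping columns).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  f <- Biostrings::readDNAStringSet(r1_path, format = "fastq",
                                    with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(r2_path, format = "fastq",
                                    with.qualities = TRUE)
  stopifnot(length(f) == length(r))
  out <- data.frame(
    read_id = sub(" .*", "", names(f)),
    r1 = as.character(f), q1 = as.character(S4Vectors::mcols(f)$qualities),
    r2 = as.character(r), q2 = as.character(S4Vectors::mcols(r)$qualities),
    stringsAsFactors = FALSE)
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' @rdname write_fastq_pairs
#' @param refs a `reference_set`.
#' @param path output path.
#' @export
write_references <- function(refs, path) {
  x <- Biostrings::DNAStringSet(refs$sequences)
  names(x) <- sprintf("%s topology=%s", names(refs$sequences),
                      ifelse(refs$circular[names(refs$sequences)],
                             "circular", "linear"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fastq_pairs
#' @param truth truth data.frame from [simulate_arrays()].
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fastq_pairs
#' @param x any list-like object (e.g. a `sim_config`) to serialise.
#' @export
write_config_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
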