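#' Construct a short RNA reference set
#'
#' A reference set maps unique feature identifiers to short RNA sequences
#' (e.g. an equimolar synthetic miRNA pool of ~1006 sequences of 20-25 nt)
#' with a class label and the per-entry G-content, the sequence covariate
#' most associated with capture/detection bias in ligation-based protocols.
#'
#' @param feature_id character vector of unique feature ids.
#' @param sequence character vector of non-empty uppercase DNA sequences;
#'   `N` bases are rejected (reference sequences are fully determined).
#' @param class_label RNA class per entry (default `"miRNA"`).
#' @return A `data.frame` of class `reference_set` with columns
#'   `feature_id`, `sequence`, `class_label`, `g_content`.
#' @export
reference_set <- function(feature_id, sequence,
                          class_label = rep("miRNA", length(feature_id))) {
  stopifnot(length(feature_id) == length(sequence))
  dup <- unique(feature_id[duplicated(feature_id)])
  if (length(dup) > 0L) {
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop("reference sequences must be non-empty")
  if (any(grepl("[^ACGT]", sequence))) {
    stop("reference sequences must be A/C/G/T only (N not permitted)")
  }
  g <- vapply(strsplit(sequence, ""), function(b) sum(b == "G"), numeric(1))
  df <- data.frame(feature_id = as.character(feature_id),
                   sequence = as.character(sequence),
                   class_label = as.character(class_label),
                   g_content = g / nchar(sequence),
                   stringsAsFactors = FALSE)
  class(df) <- c("reference_set", "data.frame")
  df
}

#' Read a FASTA reference into a reference set
#'
#' Entries are keyed by the first whitespace-delimited header token.
#'
#' @param path path to a FASTA file with unique headers.
#' @param class_label class assigned to every entry (default `"miRNA"`).
#' @return A `reference_set`.
#' @export
read_fasta_reference <- function(path, class_label = "miRNA") {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  reference_set(ids, as.character(seqs),
                class_label = rep(class_label, length(ids)))
}

#' Write a reference set to FASTA
#'
#' @param refs a `reference_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_reference <- function(refs, path) {
  x <- Biostrings::DNAStringSet(refs$sequence)
  names(x) <- refs$feature_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
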