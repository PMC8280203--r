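#' RNA class priority order for hierarchical assignment
#'
#' Reads overlapping several annotated classes are assigned to exactly one
#' class by priority. The order runs from small RNA classes of interest down
#' to protein-coding genes; absence of any qualifying overlap is reported as
#' `"intergenic"`, which is never stored in an annotation track.
#'
#' @return Character vector of the 18 class labels, highest priority first.
#' @export
rna_class_priority <- function() {
  c("miRNA", "miRNA_primary_transcript", "GtRNAdb", "Mt_tRNA", "rRNA",
    "Mt_rRNA", "snoRNA", "snRNA", "sRNA", "scaRNA", "scRNA", "piRBase",
    "misc_RNA", "ribozyme", "coding_exon", "lncRNA", "ncRNA",
    "protein_coding")
}

#' Construct an annotation track
#'
#' Intervals use the 0-based half-open convention internally: an interval
#' `(contig, 10, 20)` contains positions 10..19. Strand is carried but
#' ignored by class assignment.
#'
#' @param contig,start,end,strand,class_label,feature_id parallel vectors
#'   describing one interval per element. `start < end` must hold and every
#'   `class_label` must be one of [rna_class_priority()].
#' @return A `data.frame` of class `annotation_track`.
#' @export
annotation_track <- function(contig, start, end, strand, class_label,
                             feature_id) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(start >= end)) stop("annotation intervals require start < end")
  unknown <- setdiff(unique(class_label), rna_class_priority())
  if (length(unknown) > 0L) {
    stop("unknown annotation class label(s): ",
         paste(unknown, collapse = ", "))
  }
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   class_label = as.character(class_label),
                   feature_id = as.character(feature_id),
                   stringsAsFactors = FALSE)
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read an annotation track from GFF3 or BED
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention on read; BED is adopted as-is. The class
#' label is taken from the GFF3 `type` column or the BED name's
#' `<class>:<feature>` prefix.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @return An `annotation_track`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  start0 <- GenomicRanges::start(gr) - 1L   # GRanges is 1-based inclusive
  end0 <- GenomicRanges::end(gr)
  meta <- S4Vectors::mcols(gr)
  if (!is.null(meta$type)) {               # GFF3
    cls <- as.character(meta$type)
    fid <- if (!is.null(meta$ID)) as.character(meta$ID) else
      paste0("feat", seq_along(gr))
  } else {                                 # BED with name "<class>:<id>"
    nm <- as.character(meta$name)
    cls <- sub(":.*$", "", nm)
    fid <- sub("^[^:]*:", "", nm)
  }
  annotation_track(as.character(GenomicRanges::seqnames(gr)), start0, end0,
                   as.character(GenomicRanges::strand(gr)), cls, fid)
}

#' Write an annotation track to GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention on write.
#'
#' @param track an `annotation_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$contig,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    strand = track$strand)
  S4Vectors::mcols(gr)$type <- track$class_label
  S4Vectors::mcols(gr)$ID <- track$feature_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
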