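#' Map trimmed reads to a short RNA reference set
#'
#' Each read is aligned end-to-end against reference sequences by unit-cost
#' edit distance with free end gaps on the reference only (reads are
#' trimmed inserts; references are full-length). A hit requires
#' `identity = 1 - errors / read_length >= min_identity` (the benchmark
#' threshold is 0.80). Per read exactly one best hit is flagged for
#' counting; identity ties resolve to the lexicographically smallest
#' feature id.
#'
#' With `best_only = TRUE` (default) only the best hit per read is
#' computed, using an exact-sequence fast path plus a length-prefiltered
#' scan for inexact reads. With `best_only = FALSE` every read x reference
#' pair at or above the threshold is reported (quadratic; for small
#' inputs).
#'
#' @param records a `smallrna_records` table of kept (trimmed) reads.
#' @param refs a non-empty `reference_set`.
#' @param min_identity identity threshold in `(0, 1]` (default 0.80).
#' @param best_only compute only the best hit per read (default `TRUE`).
#' @return A data frame of hits with columns `read_id`, `feature_id`,
#'   `identity`, `errors`, `is_best`.
#' @export
map_to_reference <- function(records, refs, min_identity = 0.80,
                             best_only = TRUE) {
  if (!inherits(refs, "reference_set") || nrow(refs) == 0L) {
    stop("empty reference set")
  }
  stopifnot(min_identity > 0, min_identity <= 1)
  ord <- order(refs$feature_id)
  refs_sorted <- refs[ord, , drop = FALSE]
  if (best_only) {
    m <- cpp_map_best(records$sequence, refs_sorted$sequence, min_identity)
    hit <- which(!is.na(m$ref_idx))
    return(data.frame(
      read_id = records$read_id[hit],
      feature_id = refs_sorted$feature_id[m$ref_idx[hit]],
      identity = m$identity[hit], errors = m$errors[hit],
      is_best = rep(TRUE, length(hit)), stringsAsFactors = FALSE))
  }
  m <- cpp_map_all(records$sequence, refs_sorted$sequence, min_identity)
  if (nrow(m) == 0L) {
    return(data.frame(read_id = character(), feature_id = character(),
                      identity = numeric(), errors = integer(),
                      is_best = logical(), stringsAsFactors = FALSE))
  }
  hits <- data.frame(read_id = records$read_id[m$read_idx],
                     feature_id = refs_sorted$feature_id[m$ref_idx],
                     identity = m$identity, errors = m$errors,
                     stringsAsFactors = FALSE)
  # best per read: max identity, tie -> lexicographically smallest feature
  o <- order(hits$read_id, -hits$identity, hits$feature_id)
  hits <- hits[o, , drop = FALSE]
  hits$is_best <- !duplicated(hits$read_id)
  rownames(hits) <- NULL
  hits
}

#' Hierarchically assign mapped reads to RNA classes
#'
#' For each read, every annotation interval covering at least
#' `min_overlap` of the read length (over all the read's alignments;
#' multi-mapped reads contribute all loci) nominates its class; the
#' highest-priority class under [rna_class_priority()] wins. Reads with no
#' qualifying overlap are `"intergenic"`. Strand is ignored.
#'
#' @param alignments data frame with columns `read_id`, `contig`, `start`,
#'   `end` (0-based half-open read alignment intervals).
#' @param track an `annotation_track`.
#' @param min_overlap minimum covered fraction of the read (default 0.90).
#' @return A data frame with `read_id` and `assigned_class`.
#' @export
assign_class <- function(alignments, track, min_overlap = 0.90) {
  stopifnot(min_overlap > 0, min_overlap <= 1)
  if (!inherits(track, "annotation_track")) {
    track <- do.call(annotation_track, as.list(track))  # validates labels
  }
  reads <- unique(alignments$read_id)
  if (nrow(alignments) == 0L) {
    return(data.frame(read_id = character(), assigned_class = character(),
                      stringsAsFactors = FALSE))
  }
  qry <- GenomicRanges::GRanges(
    alignments$contig,
    IRanges::IRanges(start = alignments$start + 1L, end = alignments$end))
  sbj <- GenomicRanges::GRanges(
    track$contig,
    IRanges::IRanges(start = track$start + 1L, end = track$end))
  ov <- GenomicRanges::findOverlaps(qry, sbj, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  inter <- pmin(alignments$end[q], track$end[s]) -
    pmax(alignments$start[q], track$start[s])
  rlen <- alignments$end[q] - alignments$start[q]
  ok <- inter / rlen >= min_overlap
  prio <- match(track$class_label[s[ok]], rna_class_priority())
  best <- tapply(prio, alignments$read_id[q[ok]], min)
  cls <- rep("intergenic", length(reads))
  names(cls) <- reads
  cls[names(best)] <- rna_class_priority()[best]
  data.frame(read_id = reads, assigned_class = unname(cls[reads]),
             stringsAsFactors = FALSE)
}

#' Aggregate best hits into a raw count layer
#'
#' `count[f, s]` is the number of reads in sample `s` whose best hit is
#' feature `f`; unmapped reads are excluded. The full feature universe of
#' the reference is kept as rows so equimolar accuracy statistics see
#' undetected features as zeros.
#'
#' @param hits a hit table from [map_to_reference()] with an added
#'   `sample_id` column (or a named list of per-sample hit tables).
#' @param refs the `reference_set` defining the feature universe.
#' @return An integer matrix features x samples.
#' @export
count_features <- function(hits, refs) {
  if (is.list(hits) && !is.data.frame(hits)) {
    hits <- do.call(rbind, Map(function(h, s) {
      if (nrow(h) > 0L) h$sample_id <- s
      h
    }, hits, names(hits)))
  }
  stopifnot("sample_id" %in% names(hits) || nrow(hits) == 0L)
  samples <- if (nrow(hits) > 0L) unique(hits$sample_id) else character()
  best <- hits[hits$is_best, , drop = FALSE]
  m <- matrix(0L, nrow = nrow(refs), ncol = length(samples),
              dimnames = list(refs$feature_id, samples))
  if (nrow(best) > 0L) {
    tab <- table(factor(best$feature_id, levels = refs$feature_id),
                 factor(best$sample_id, levels = samples))
    m[] <- as.integer(tab)
  }
  m
}

#' Reads-per-million-mapped normalization
#'
#' Scales each sample column to a total of one million over mapped
#' features: `value = raw * 1e6 / column_sum`. All-zero columns are left
#' at zero with a warning.
#'
#' @param raw numeric matrix of raw counts (features x samples).
#' @return The RPMM matrix.
#' @export
rpmm_normalize <- function(raw) {
  cs <- colSums(raw)
  zero <- cs == 0
  if (any(zero)) {
    warning("column(s) with no mapped reads left at zero: ",
            paste(colnames(raw)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  sweep(raw, 2L, cs, "/") * 1e6
}

#' Detection calls at a count threshold
#'
#' A feature is detected in a sample iff its raw count is at least
#' `threshold` (the benchmark uses a count of at least 1).
#'
#' @param raw numeric matrix of raw counts.
#' @param threshold minimum count (>= 1, default 1).
#' @return A list with `detected` (logical matrix), `per_sample`
#'   (detected-feature counts) and `per_feature` (detection rate, the
#'   fraction of samples where the feature is detected).
#' @export
detection_calls <- function(raw, threshold = 1L) {
  stopifnot(threshold >= 1L)
  det <- raw >= threshold
  list(detected = det,
       per_sample = colSums(det),
       per_feature = rowMeans(det))
}
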