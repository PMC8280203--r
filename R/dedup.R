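#' Hamming distance between two equal-length strings
#'
#' @param u1,u2 strings of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(u1, u2) {
  if (nchar(u1) != nchar(u2)) stop("hamming distance requires equal lengths")
  sum(strsplit(u1, "")[[1]] != strsplit(u2, "")[[1]])
}

#' Build per-(sample, feature) UMI read-count tables
#'
#' UMIs containing N are dropped at construction (Hamming semantics are
#' undefined for N) and the dropped read count is recorded in the
#' `dropped_n` attribute.
#'
#' @param hits best-hit table (see [map_to_reference()]) carrying
#'   `read_id`, `feature_id` and a `sample_id` column.
#' @param records the `smallrna_records` the hits refer to (source of each
#'   read's UMI); alternatively a `umi` column already present in `hits`.
#' @param group_by_length also partition UMI groups by trimmed read length
#'   (default `TRUE`), mirroring read-length-aware deduplication.
#' @return A data frame with columns `sample_id`, `feature_id`,
#'   `read_length` (-1 when `group_by_length = FALSE`), `umi`, `reads`,
#'   of class `umi_table`.
#' @export
umi_table <- function(hits, records = NULL, group_by_length = TRUE) {
  h <- hits[hits$is_best, , drop = FALSE]
  if (!"umi" %in% names(h)) {
    stopifnot(!is.null(records))
    h$umi <- records$umi[match(h$read_id, records$read_id)]
    if (group_by_length) {
      h$read_length <-
        nchar(records$sequence[match(h$read_id, records$read_id)])
    }
  }
  if (!group_by_length) h$read_length <- -1L
  if (!"read_length" %in% names(h)) h$read_length <- -1L
  dropped <- sum(grepl("N", h$umi, fixed = TRUE) | !nzchar(h$umi))
  h <- h[!grepl("N", h$umi, fixed = TRUE) & nzchar(h$umi), , drop = FALSE]
  if (nrow(h) == 0L) {
    agg <- data.frame(sample_id = character(), feature_id = character(),
                      read_length = integer(), umi = character(),
                      reads = integer(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(reads = rep(1L, nrow(h))),
                            by = list(sample_id = h$sample_id,
                                      feature_id = h$feature_id,
                                      read_length = h$read_length,
                                      umi = h$umi),
                            FUN = sum)
    agg <- agg[order(agg$sample_id, agg$feature_id, agg$read_length,
                     agg$umi), , drop = FALSE]
    rownames(agg) <- NULL
  }
  attr(agg, "dropped_n") <- dropped
  class(agg) <- c("umi_table", "data.frame")
  agg
}

#' Deduplicate one UMI set with the adjacency network method
#'
#' Builds a graph with an edge between UMIs at Hamming distance exactly 1,
#' then repeatedly selects the unassigned UMI with the highest read count
#' (ties to the lexicographically smallest UMI) and groups it with all its
#' unassigned direct neighbors until every UMI is assigned. The molecule
#' count is the number of groups. The lexicographic tie-break makes the
#' result deterministic.
#'
#' @param counts named integer vector: UMI -> read count (counts >= 1,
#'   equal-length UMIs).
#' @return A list with `n_molecules` and `groups`, each group a list with
#'   `representative`, `members`, `reads`.
#' @export
adjacency_dedup <- function(counts) {
  stopifnot(length(counts) > 0L, all(counts >= 1L))
  umis <- names(counts)
  stopifnot(!is.null(umis), length(unique(nchar(umis))) == 1L)
  n <- length(umis)
  # adjacency at Hamming distance exactly 1
  mat <- do.call(rbind, strsplit(umis, ""))
  adj <- vector("list", n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      di <- colSums(t(mat[(i + 1L):n, , drop = FALSE]) != mat[i, ])
      nb <- which(di == 1L) + i
      adj[[i]] <- c(adj[[i]], nb)
      for (j in nb) adj[[j]] <- c(adj[[j]], i)
    }
  }
  ord <- order(-counts, umis)
  assigned <- rep(FALSE, n)
  groups <- list()
  for (i in ord) {
    if (assigned[i]) next
    members <- c(i, adj[[i]][!assigned[adj[[i]]]])
    assigned[members] <- TRUE
    groups[[length(groups) + 1L]] <-
      list(representative = umis[i],
           members = sort(umis[members]),
           reads = sum(counts[members]))
  }
  list(n_molecules = length(groups), groups = groups)
}

#' UMI-deduplicated molecule counts per (sample, feature)
#'
#' Runs [adjacency_dedup()] within each (sample, feature[, read length])
#' stratum and sums molecule counts over read-length strata.
#'
#' @param table a `umi_table`.
#' @param refs the `reference_set` defining the feature universe.
#' @param sample_ids sample universe for the output columns (default: the
#'   samples present).
#' @return An integer matrix features x samples of molecule counts.
#' @export
dedup_counts <- function(table, refs, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(table$sample_id)
  m <- matrix(0L, nrow = nrow(refs), ncol = length(sample_ids),
              dimnames = list(refs$feature_id, sample_ids))
  if (nrow(table) == 0L) return(m)
  key <- paste(table$sample_id, table$feature_id, table$read_length,
               sep = "\r")
  for (k in unique(key)) {
    rows <- which(key == k)
    counts <- table$reads[rows]
    names(counts) <- table$umi[rows]
    res <- adjacency_dedup(counts)
    m[table$feature_id[rows[1L]], table$sample_id[rows[1L]]] <-
      m[table$feature_id[rows[1L]], table$sample_id[rows[1L]]] +
      res$n_molecules
  }
  m
}

#' Reads-per-UMI statistics
#'
#' PCR duplication depth: per (sample, feature), total reads divided by
#' distinct UMIs; per sample, the mean over features; and the cohort mean
#' and SD over samples.
#'
#' @param table a `umi_table`.
#' @return A list with `per_feature` (data frame `sample_id`, `feature_id`,
#'   `reads_per_umi`), `per_sample` (named means) and `cohort`
#'   (`mean`, `sd`).
#' @export
reads_per_umi <- function(table) {
  if (nrow(table) == 0L) {
    return(list(per_feature = data.frame(sample_id = character(),
                                         feature_id = character(),
                                         reads_per_umi = numeric()),
                per_sample = numeric(), cohort = list(mean = NaN, sd = NA)))
  }
  agg <- stats::aggregate(
    cbind(reads = table$reads, umis = rep(1L, nrow(table))),
    by = list(sample_id = table$sample_id, feature_id = table$feature_id),
    FUN = sum)
  agg$reads_per_umi <- agg$reads / agg$umis
  per_sample <- tapply(agg$reads_per_umi, agg$sample_id, mean)
  list(per_feature = agg[, c("sample_id", "feature_id", "reads_per_umi")],
       per_sample = per_sample,
       cohort = list(mean = mean(per_sample), sd = stats::sd(per_sample)))
}

#' Total molecules per cell over miRNA features
#'
#' @param molecules molecule-count matrix from [dedup_counts()].
#' @param refs the `reference_set` (used to restrict to miRNA-class
#'   features).
#' @return Named numeric vector of per-sample molecule totals.
#' @export
molecules_per_cell <- function(molecules, refs) {
  keep <- refs$feature_id[refs$class_label == "miRNA"]
  colSums(molecules[rownames(molecules) %in% keep, , drop = FALSE])
}
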