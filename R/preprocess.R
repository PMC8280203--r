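#' Trimming configuration
#'
#' Defaults follow the benchmarked pipeline: 3' quality cutoff 20, adapter
#' error rate 10%, up to three trimming rounds per read, at most 2 N bases,
#' minimum kept length 18 nt, and reads with fewer than 4 bases remaining
#' after trimming classified as adapter dimers. PolyA/polyG tails are
#' modelled as 10-nt homopolymer adapters subject to the same error rule.
#'
#' @param adapters3 character vector of 3' adapters to remove (3' adapter,
#'   PCR primer, ...).
#' @param polyA,polyG include homopolymer-tail adapters (default `TRUE`).
#' @param homopolymer_len length of the homopolymer adapters (default 10).
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param max_error_rate adapter match error rate (default 0.10).
#' @param max_rounds maximum adapter removal rounds per read (default 3).
#' @param max_n maximum N bases in a kept read (default 2).
#' @param min_len minimum kept read length (default 18).
#' @param dimer_max_len maximum post-trim length classified as adapter
#'   dimer (default 3, i.e. "fewer than four bases remaining").
#' @param min_overlap minimum adapter-prefix overlap for 3'-terminal
#'   partial matches (default 10). Short inserts frequently end in the
#'   first few bases of an adapter or in short A/G runs by chance; with a
#'   small overlap such coincidences are trimmed in later rounds and can
#'   push genuine inserts below the length floor, so the default demands
#'   10 bases of evidence before a partial 3' match is removed. Full
#'   adapter occurrences are unaffected.
#' @param flank_clip bases clipped from each end of a kept read (4N-family
#'   random flanks; default 0).
#' @return A list of class `trim_config`.
#' @export
trim_config <- function(adapters3, polyA = TRUE, polyG = TRUE,
                        homopolymer_len = 10L, quality_cutoff = 20L,
                        max_error_rate = 0.10, max_rounds = 3L, max_n = 2L,
                        min_len = 18L, dimer_max_len = 3L, min_overlap = 10L,
                        flank_clip = 0L) {
  stopifnot(length(adapters3) >= 1L, all(nzchar(adapters3)),
            max_error_rate > 0, max_error_rate < 1,
            dimer_max_len < min_len)
  ad <- adapters3
  kinds <- rep("adapter", length(ad))
  if (isTRUE(polyA)) {
    ad <- c(ad, strrep("A", homopolymer_len))
    kinds <- c(kinds, "polyA")
  }
  if (isTRUE(polyG)) {
    ad <- c(ad, strrep("G", homopolymer_len))
    kinds <- c(kinds, "polyG")
  }
  structure(list(adapters = ad, adapter_kinds = kinds,
                 quality_cutoff = as.integer(quality_cutoff),
                 max_error_rate = max_error_rate,
                 max_rounds = as.integer(max_rounds),
                 max_n = as.integer(max_n), min_len = as.integer(min_len),
                 dimer_max_len = as.integer(dimer_max_len),
                 min_overlap = as.integer(min_overlap),
                 flank_clip = as.integer(flank_clip)),
            class = "trim_config")
}

#' Trimming configuration matching a protocol architecture
#'
#' @param arch a `protocol_architecture`.
#' @param ... overrides passed to [trim_config()].
#' @return A `trim_config` with the architecture's 3' adapter and PCR
#'   primer, and `flank_clip` set from its 4N flank length.
#' @export
trim_config_for <- function(arch, ...) {
  trim_config(adapters3 = c(arch$adapter3, arch$pcr_primer),
              flank_clip = arch$flank4n_len, ...)
}

#' Extract the UMI from the 5' end of each read
#'
#' The first `umi_len` bases are moved from the sequence (and qualities)
#' into the record's `umi` field — the in-memory analogue of copying the
#' UMI into the read header. `umi_len = 0` is the identity. UMIs containing
#' N are stored verbatim and flagged (`umi_has_n` attribute) for the
#' deduplication step to drop; reads shorter than the UMI are flagged
#' (`umi_short`) and fail QC downstream.
#'
#' @param records a `smallrna_records` table.
#' @param umi_len UMI length in bases.
#' @return The records with `umi` filled and sequences shortened; logical
#'   attributes `umi_has_n` and `umi_short` mark problem reads.
#' @export
extract_umi <- function(records, umi_len) {
  umi_len <- as.integer(umi_len)
  if (umi_len == 0L) {
    attr(records, "umi_short") <- rep(FALSE, nrow(records))
    attr(records, "umi_has_n") <- rep(FALSE, nrow(records))
    return(records)
  }
  short <- nchar(records$sequence) <= umi_len
  umi <- substr(records$sequence, 1L, umi_len)
  umi[short] <- ""
  records$umi <- umi
  records$sequence[!short] <- substring(records$sequence[!short],
                                        umi_len + 1L)
  records$quality[!short] <- substring(records$quality[!short],
                                       umi_len + 1L)
  attr(records, "umi_short") <- short
  attr(records, "umi_has_n") <- grepl("N", umi, fixed = TRUE)
  records
}

#' 3' quality trimming with the running-sum rule
#'
#' From the 3' end, accumulate `(cutoff - q_i)` and cut at the position
#' minimizing the running sum (the BWA/cutadapt rule). Reads whose
#' qualities all exceed the cutoff are unchanged.
#'
#' @param records a `smallrna_records` table.
#' @param cutoff Phred cutoff (default 20).
#' @return The records with 3' low-quality tails removed.
#' @export
quality_trim_3prime <- function(records, cutoff = 20L) {
  keep <- cpp_quality_cut(records$quality, as.integer(cutoff),
                          phred_offset(records))
  records$sequence <- substr(records$sequence, 1L, keep)
  records$quality <- substr(records$quality, 1L, keep)
  records
}

#' Locate a 3' adapter in a read sequence
#'
#' Semi-global search for the adapter, either in full anywhere in the read
#' or as a 3'-terminal prefix of length at least `min_overlap`.
#' Substitutions and indels each cost one error; a candidate is accepted
#' iff `errors / matched_adapter_length <= max_error_rate`. Among
#' acceptable candidates the smallest error count wins, ties broken by the
#' leftmost start.
#'
#' @param sequence a single read sequence.
#' @param adapter non-empty adapter sequence.
#' @param max_error_rate maximum error fraction (default 0.10).
#' @param min_overlap minimum matched prefix length (default 3).
#' @return `NULL` when absent, else a list with `start` (1-based start of
#'   the occurrence; trimming keeps `substr(sequence, 1, start - 1)`),
#'   `errors` and `match_length`.
#' @export
find_adapter <- function(sequence, adapter, max_error_rate = 0.10,
                         min_overlap = 3L) {
  stopifnot(length(sequence) == 1L, nzchar(adapter))
  m <- cpp_find_adapter(sequence, adapter, max_error_rate,
                        as.integer(min_overlap))
  if (!m$found[1L]) return(NULL)
  list(start = m$start[1L] + 1L, errors = m$errors[1L],
       match_length = m$match_length[1L])
}

TRIM_STATUS <- c("kept", "adapter_dimer", "too_short", "quality_fail")

#' Trim reads and classify their outcome
#'
#' Per read: one 3' quality trim, then up to `max_rounds` rounds each
#' removing the earliest-starting acceptable adapter/homopolymer
#' occurrence, then classification on the post-trim length with precedence
#' adapter dimer (< 4 bases) > too short (< `min_len`) > quality fail
#' (> `max_n` N bases); everything else is kept. Kept reads finally lose
#' `flank_clip` bases from each end (4N random flanks). The UMI must have
#' been extracted beforehand and is never altered.
#'
#' @param records a `smallrna_records` table (after [extract_umi()]).
#' @param cfg a `trim_config`.
#' @return A list with `records` (trimmed `smallrna_records` of all reads),
#'   `status` (factor over kept/adapter_dimer/too_short/quality_fail),
#'   `removed` (per-read `kind=segment` strings) and `summary` (counts and
#'   fractions per status).
#' @export
trim_reads <- function(records, cfg) {
  stopifnot(inherits(cfg, "trim_config"))
  force_fail <- attr(records, "umi_short")
  if (is.null(force_fail)) force_fail <- rep(FALSE, nrow(records))
  res <- cpp_trim_batch(records$sequence, records$quality, cfg$adapters,
                        cfg$adapter_kinds, cfg$quality_cutoff,
                        phred_offset(records), cfg$max_error_rate,
                        cfg$min_overlap, cfg$max_rounds, cfg$dimer_max_len,
                        cfg$min_len, cfg$max_n, force_fail)
  status <- factor(TRIM_STATUS[res$status + 1L], levels = TRIM_STATUS)
  seqs <- res$sequence
  quals <- res$quality
  if (cfg$flank_clip > 0L) {
    kept <- which(status == "kept")
    seqs[kept] <- substr(seqs[kept], cfg$flank_clip + 1L,
                         nchar(seqs[kept]) - cfg$flank_clip)
    quals[kept] <- substr(quals[kept], cfg$flank_clip + 1L,
                          nchar(quals[kept]) - cfg$flank_clip)
  }
  out <- records
  out$sequence <- seqs
  out$quality <- quals
  counts <- table(status)
  summary <- data.frame(status = names(counts),
                        n = as.integer(counts),
                        fraction = as.numeric(counts) / max(1L, nrow(records)),
                        stringsAsFactors = FALSE)
  list(records = out, status = status, removed = res$removed,
       summary = summary)
}

#' Trim a single read to a full outcome record
#'
#' Single-read convenience around [trim_reads()] returning the status, the
#' trimmed record and the removed segments as `(kind, sequence)` pairs.
#'
#' @param record a one-row `smallrna_records` table.
#' @param cfg a `trim_config`.
#' @return A list with `status`, `trimmed` and `removed_segments`.
#' @export
trim_read <- function(record, cfg) {
  res <- trim_reads(record, cfg)
  segs <- strsplit(res$removed[1L], ";", fixed = TRUE)[[1L]]
  segs <- segs[nzchar(segs)]
  removed <- lapply(segs, function(s) {
    kv <- strsplit(s, "=", fixed = TRUE)[[1L]]
    list(kind = kv[1L], sequence = ifelse(length(kv) > 1L, kv[2L], ""))
  })
  list(status = as.character(res$status[1L]),
       trimmed = res$records[1L, , drop = FALSE],
       removed_segments = removed)
}

#' Deterministic uniform subsampling of reads
#'
#' Draws exactly `min(n, total)` reads uniformly without replacement,
#' preserving the original order; deterministic given `seed`. The selection
#' is reproducible within this package but not bit-compatible with external
#' subsampling tools, whose RNGs differ.
#'
#' @param records a `smallrna_records` table.
#' @param n number of reads to keep (the benchmark uses 300,000).
#' @param seed RNG seed (the benchmark uses 42).
#' @return The subsampled `smallrna_records`.
#' @export
subsample_reads <- function(records, n, seed = 42L) {
  stopifnot(n >= 0L)
  total <- nrow(records)
  if (n >= total) return(records)
  set.seed(seed)
  idx <- sort(sample.int(total, n))
  out <- records[idx, , drop = FALSE]
  attr(out, "phred_offset") <- phred_offset(records)
  class(out) <- c("smallrna_records", "data.frame")
  out
}
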