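#' Construct a table of small RNA sequencing reads
#'
#' Reads are held as a plain `data.frame` with one row per read and columns
#' `read_id`, `sequence`, `quality` (Phred string at a fixed offset) and
#' `umi` (empty string when no UMI has been extracted). The quality string
#' always has the same length as the sequence, the sequence alphabet is
#' restricted to `A`, `C`, `G`, `T`, `N`, and a UMI, once extracted, is never
#' altered by downstream trimming.
#'
#' @param read_id character vector of unique read identifiers.
#' @param sequence character vector of uppercase DNA sequences.
#' @param quality character vector of Phred quality strings, same lengths as
#'   `sequence`.
#' @param umi character vector of extracted UMIs (default: none).
#' @param phred_offset integer Phred encoding offset (default 33, modern
#'   Illumina).
#' @return A `data.frame` of class `smallrna_records`.
#' @export
smallrna_records <- function(read_id, sequence, quality,
                             umi = rep("", length(read_id)),
                             phred_offset = 33L) {
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality),
            length(umi) == length(read_id))
  bad_len <- which(nchar(sequence) != nchar(quality))
  if (length(bad_len) > 0L) {
    stop("sequence/quality length mismatch at record(s) ",
         paste(utils::head(bad_len, 5L), collapse = ", "))
  }
  if (any(grepl("[^ACGTN]", sequence))) {
    stop("sequence alphabet must be A/C/G/T/N")
  }
  df <- data.frame(read_id = as.character(read_id),
                   sequence = as.character(sequence),
                   quality = as.character(quality),
                   umi = as.character(umi),
                   stringsAsFactors = FALSE)
  attr(df, "phred_offset") <- as.integer(phred_offset)
  class(df) <- c("smallrna_records", "data.frame")
  df
}

#' Decode Phred qualities to integers
#'
#' @param records a `smallrna_records` table.
#' @return A list of integer vectors, one per read.
#' @export
quality_ints <- function(records) {
  off <- phred_offset(records)
  lapply(records$quality, function(q) utf8ToInt(q) - off)
}

phred_offset <- function(records) {
  off <- attr(records, "phred_offset")
  if (is.null(off)) 33L else as.integer(off)
}

#' Read a FASTQ file into a read table
#'
#' Records must be 4-line FASTQ; gzip-compressed files are handled
#' transparently. If a header carries a `UMI=<seq>` comment token (as written
#' by [write_fastq()] after UMI extraction) the UMI is restored into the
#' `umi` column.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @param phred_offset integer Phred offset used to interpret qualities
#'   (default 33).
#' @return A `smallrna_records` table in file order.
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(smallrna_records(character(), character(), character(),
                            phred_offset = phred_offset))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record ",
         length(lines) %/% 4L, ")")
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record ", bad[1L] - 1L, ": header missing '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record ", bad[1L] - 1L, ": separator missing '+'")
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record ", bad[1L] - 1L,
         ": quality length differs from sequence length")
  }
  hdr <- sub("^@", "", hdr)
  read_id <- sub("\\s.*$", "", hdr)
  umi <- rep("", length(hdr))
  has_umi <- grepl("\\bUMI=", hdr)
  umi[has_umi] <- sub("^.*\\bUMI=(\\S*).*$", "\\1", hdr[has_umi])
  smallrna_records(read_id, seqs, qual, umi, phred_offset = phred_offset)
}

#' Write a read table to FASTQ
#'
#' Extracted UMIs are carried in the header comment as `UMI=<seq>` so that
#' `read_fastq(write_fastq(x))` round-trips the full record including the
#' UMI; records without UMIs round-trip byte-identically.
#'
#' @param records a `smallrna_records` table.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  hdr <- paste0("@", records$read_id,
                ifelse(nzchar(records$umi), paste0(" UMI=", records$umi), ""))
  out <- as.vector(rbind(hdr, records$sequence, "+", records$quality))
  if (length(out) == 0L) out <- character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
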