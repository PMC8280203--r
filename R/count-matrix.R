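#' Build a count container from named layers
#'
#' The count container is a [SummarizedExperiment::SummarizedExperiment]:
#' assays hold the named layers (e.g. `raw` reads, `molecules` after UMI
#' deduplication, `rpmm`, `lognorm`), `colData` holds per-sample metadata
#' (protocol, patient, stage labels). All layers share dimensions; raw
#' layers are non-negative integers; an `rpmm` layer has columns summing to
#' 1e6 wherever any read mapped.
#'
#' @param layers named list of numeric matrices (features x samples) with
#'   identical dimnames.
#' @param metadata optional `data.frame` keyed by sample id (rownames or a
#'   `sample_id` column).
#' @return A `SummarizedExperiment`.
#' @export
make_count_matrix <- function(layers, metadata = NULL) {
  stopifnot(is.list(layers), length(layers) > 0L,
            !is.null(names(layers)), all(nzchar(names(layers))))
  dims <- lapply(layers, dim)
  if (length(unique(dims)) != 1L) stop("all layers must share dimensions")
  ref <- layers[[1L]]
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    stop("layers need feature rownames and sample colnames")
  }
  cd <- if (is.null(metadata)) {
    S4Vectors::DataFrame(row.names = colnames(ref))
  } else {
    md <- as.data.frame(metadata)
    if ("sample_id" %in% names(md)) rownames(md) <- md$sample_id
    S4Vectors::DataFrame(md[colnames(ref), , drop = FALSE])
  }
  SummarizedExperiment::SummarizedExperiment(assays = layers, colData = cd)
}

#' Write a count container to TSV files
#'
#' One `<layer>.tsv` per assay (feature rows, sample columns) plus a
#' `samples.tsv` metadata sidecar are written under `dir`.
#'
#' @param se a `SummarizedExperiment` from [make_count_matrix()].
#' @param dir output directory (created if missing).
#' @param layers layers to write; default all.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(se, dir, layers = NULL) {
  if (is.null(layers)) layers <- SummarizedExperiment::assayNames(se)
  missing_layers <- setdiff(layers, SummarizedExperiment::assayNames(se))
  if (length(missing_layers) > 0L) {
    stop("unknown layer(s): ", paste(missing_layers, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in layers) {
    m <- SummarizedExperiment::assay(se, ly)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, paste0(ly, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  md <- as.data.frame(SummarizedExperiment::colData(se))
  md <- data.frame(sample_id = colnames(se), md, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(md, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count container written by [write_count_matrix()]
#'
#' @param dir directory holding `<layer>.tsv` files and optionally a
#'   `samples.tsv` sidecar; a missing sidecar yields empty metadata with a
#'   warning.
#' @return A `SummarizedExperiment`.
#' @export
read_count_matrix <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  layer_files <- files[basename(files) != "samples.tsv"]
  if (length(layer_files) == 0L) stop("no layer TSVs found in ", dir)
  layers <- list()
  for (f in layer_files) {
    df <- utils::read.table(f, sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$feature_id
    layers[[sub("\\.tsv$", "", basename(f))]] <- m
  }
  md_file <- file.path(dir, "samples.tsv")
  md <- NULL
  if (file.exists(md_file)) {
    md <- utils::read.table(md_file, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    rownames(md) <- md$sample_id
  } else {
    warning("no samples.tsv metadata sidecar in ", dir,
            "; loading with empty metadata")
  }
  make_count_matrix(layers, metadata = md)
}
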