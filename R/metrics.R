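#' Coefficient of variation of spike-in expression
#'
#' Quantification-accuracy statistic for an equimolar pool: the sample
#' (n - 1) standard deviation divided by the mean, computed over ALL
#' reference features of one sample's expression column — zeros included,
#' because the equimolar truth expects every feature present. A perfectly
#' accurate equimolar measurement has CV 0; sequence-dependent capture
#' bias inflates it.
#'
#' @param expression numeric vector: one (typically RPMM) expression
#'   column restricted to the spike-in features, length >= 2.
#' @param detected_only drop zero features first (alternative mode whose
#'   absolute values differ; default `FALSE`).
#' @return The coefficient of variation.
#' @export
coefficient_of_variation <- function(expression, detected_only = FALSE) {
  if (detected_only) expression <- expression[expression > 0]
  if (length(expression) < 2L) stop("need at least two features")
  m <- mean(expression)
  if (m == 0) stop("mean expression is zero; CV undefined")
  stats::sd(expression) / m
}

#' Within- and between-group reproducibility distances
#'
#' Euclidean distance on `log2(value + pseudocount)` between every
#' unordered sample pair, partitioned into within-group (replicates of the
#' same protocol) and between-group pairs. Each pair appears once.
#'
#' @param mat expression matrix (features x samples).
#' @param groups named character vector mapping every sample to its
#'   protocol/group.
#' @param pseudocount added before log2 (default 1).
#' @return A list with `pairs` (data frame `sample_a`, `sample_b`,
#'   `distance`, `type`), `within` and `between` (numeric distance sets).
#' @export
reproducibility_distances <- function(mat, groups, pseudocount = 1) {
  missing_groups <- setdiff(colnames(mat), names(groups))
  if (length(missing_groups) > 0L) {
    stop("no group label for sample(s): ",
         paste(missing_groups, collapse = ", "))
  }
  if (ncol(mat) < 2L) stop("need at least two samples")
  lg <- t(log2(mat + pseudocount))
  d <- as.matrix(stats::dist(lg))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(
    sample_a = colnames(mat)[idx[, 1L]],
    sample_b = colnames(mat)[idx[, 2L]],
    distance = d[idx], stringsAsFactors = FALSE)
  pairs$type <- ifelse(groups[pairs$sample_a] == groups[pairs$sample_b],
                       "within", "between")
  list(pairs = pairs,
       within = pairs$distance[pairs$type == "within"],
       between = pairs$distance[pairs$type == "between"])
}

#' Association between detection rate and G-content
#'
#' Spearman rank correlation (average ranks for ties, large-sample p)
#' between per-feature detection rates and reference G-content — the
#' signature of G-content-dependent capture bias: a positive rho means
#' G-richer sequences are detected more often.
#'
#' @param refs a `reference_set` (>= 10 features).
#' @param detection_rates named numeric vector of per-feature detection
#'   rates (see [detection_calls()]).
#' @return A list with `rho` and `p_value`; `rho` is `NA` with a warning
#'   when either vector is constant.
#' @export
gcontent_detection_association <- function(refs, detection_rates) {
  stopifnot(nrow(refs) >= 10L)
  x <- refs$g_content
  y <- detection_rates[refs$feature_id]
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    warning("constant vector; Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Filter cells by molecule totals
#'
#' Low-quality cells are excluded by requiring a minimum number of
#' detected miRNA molecules (the benchmark threshold is 50; its empty
#' negative controls yielded only 7 and 14 molecules).
#'
#' @param molecule_totals named numeric vector of per-sample miRNA
#'   molecule totals (see [molecules_per_cell()]).
#' @param min_molecules minimum total (default 50).
#' @return Character vector of kept sample ids (empty with a warning when
#'   nothing passes).
#' @export
filter_cells <- function(molecule_totals, min_molecules = 50L) {
  stopifnot(min_molecules >= 0L)
  kept <- names(molecule_totals)[molecule_totals >= min_molecules]
  if (length(kept) == 0L) warning("no sample passes the molecule filter")
  kept
}

#' Library-size log-normalization
#'
#' `ln(1 + raw * scale / column_sum)` with a scaling factor of 10,000 —
#' the standard single-cell normalization (natural log). Zero-sum columns
#' are zeroed with a warning.
#'
#' @param raw counts matrix (features x samples).
#' @param scale scaling factor (default 1e4).
#' @return The normalized matrix.
#' @export
lognormalize <- function(raw, scale = 1e4) {
  cs <- colSums(raw)
  zero <- cs == 0
  if (any(zero)) {
    warning("zero library size; column(s) zeroed: ",
            paste(colnames(raw)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  log1p(sweep(raw, 2L, cs, "/") * scale)
}

#' Variance-stabilizing variable-feature selection
#'
#' The "vst" ranking: expected log10 variance is fitted as a local
#' regression (span 0.3) on log10 mean over features with positive
#' variance; raw counts are standardized by the predicted standard
#' deviation, clipped at `sqrt(n_samples)`, and features are ranked by the
#' variance of the standardized values.
#'
#' @param raw counts matrix (features x samples, >= 3 samples).
#' @param n number of top features to return.
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @return Character vector of the top `n` feature ids, most variable
#'   first; features beyond those with positive variance rank last (all
#'   returned with a warning when fewer than `n` are usable).
#' @export
variable_features <- function(raw, n, loess_span = 0.3) {
  mu <- rowMeans(raw)
  v <- apply(raw, 1L, stats::var)
  usable <- mu > 0 & v > 0
  std_var <- rep(0, nrow(raw))
  names(std_var) <- rownames(raw)
  if (sum(usable) >= 2L) {
    lv <- log10(v[usable])
    lm_ <- log10(mu[usable])
    # the local-regression trend needs enough features; degenerate inputs
    # fall back to a log-linear mean-variance trend
    fitted_lv <- if (sum(usable) >= 10L) {
      tryCatch(stats::fitted(stats::loess(lv ~ lm_, span = loess_span)),
               error = function(e) stats::fitted(stats::lm(lv ~ lm_)))
    } else {
      stats::fitted(stats::lm(lv ~ lm_))
    }
    sd_exp <- sqrt(10^fitted_lv)
    clip <- sqrt(ncol(raw))
    z <- sweep(raw[usable, , drop = FALSE], 1L, mu[usable], "-")
    z <- sweep(z, 1L, sd_exp, "/")
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    std_var[usable] <- apply(z, 1L, stats::var)
  }
  if (sum(usable) < n) {
    warning("only ", sum(usable), " features with nonzero variance; ",
            "returning all features ranked")
    n <- min(n, nrow(raw))
  }
  names(sort(std_var, decreasing = TRUE))[seq_len(n)]
}

#' Clustering/embedding configuration
#'
#' Stage-specific settings of the single-cell analysis: number of variable
#' features, principal components (20 or 15 in the benchmark), UMAP
#' neighbors (9/12/12/15 per stage), Louvain resolution (1.4, or 1.05 for
#' the patient subset), shared-nearest-neighbor `k` (default 20, shrunk to
#' `n - 1` for small sample sets) and the seed.
#'
#' @param n_variable_features number of vst-selected features (`NULL` for
#'   all).
#' @param n_pcs principal components retained.
#' @param umap_neighbors UMAP neighborhood size.
#' @param louvain_resolution Louvain resolution parameter.
#' @param snn_k neighbors for the SNN graph.
#' @param seed RNG seed; mandatory.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(n_variable_features = NULL, n_pcs = 15L,
                           umap_neighbors = 15L, louvain_resolution = 1.4,
                           snn_k = 20L, seed) {
  if (missing(seed)) stop("a seed is mandatory for embedding/clustering")
  structure(list(n_variable_features = n_variable_features,
                 n_pcs = as.integer(n_pcs),
                 umap_neighbors = as.integer(umap_neighbors),
                 louvain_resolution = louvain_resolution,
                 snn_k = as.integer(snn_k), seed = as.integer(seed)),
            class = "cluster_config")
}

snn_graph <- function(pcs, k) {
  n <- nrow(pcs)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pcs))
  # neighbor sets include the point itself
  nb <- lapply(seq_len(n), function(i) {
    c(i, order(d[i, ])[seq_len(k + 1L)][-1L][seq_len(k)])
  })
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inter <- length(intersect(nb[[i]], nb[[j]]))
      if (inter > 0L) {
        w[i, j] <- w[j, i] <- inter / length(union(nb[[i]], nb[[j]]))
      }
    }
  }
  w[w < 1 / 15] <- 0  # prune weak shared-neighbor edges
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' PCA, SNN-Louvain clustering and UMAP embedding
#'
#' Samples are embedded and clustered from a normalized expression layer:
#' optional vst feature selection, per-feature centering/scaling, PCA,
#' a Jaccard-weighted shared-nearest-neighbor graph on the retained PCs,
#' Louvain community detection at the configured resolution, and a 2-D
#' UMAP on the same PCs. Deterministic given `cfg$seed`.
#'
#' @param normalized normalized matrix (features x samples).
#' @param cfg a `cluster_config`.
#' @param raw optional raw counts for vst feature selection (required if
#'   `cfg$n_variable_features` is set).
#' @return A list with `embedding` (samples x 2), `clusters` (integer
#'   labels named by sample), `pca` (retained PC scores) and `features`
#'   (features used).
#' @export
embed_and_cluster <- function(normalized, cfg, raw = NULL) {
  stopifnot(inherits(cfg, "cluster_config"))
  n <- ncol(normalized)
  if (n < 3L) stop("too few samples to embed and cluster")
  feats <- rownames(normalized)
  if (!is.null(cfg$n_variable_features)) {
    if (is.null(raw)) stop("raw counts needed for vst feature selection")
    feats <- variable_features(raw, cfg$n_variable_features)
  }
  x <- normalized[feats, , drop = FALSE]
  keep <- apply(x, 1L, stats::sd) > 0
  x <- x[keep, , drop = FALSE]
  xs <- t(scale(t(x)))
  n_pcs <- min(cfg$n_pcs, n - 1L, nrow(xs))
  set.seed(cfg$seed)
  pca <- stats::prcomp(t(xs), rank. = n_pcs)
  pcs <- pca$x[, seq_len(n_pcs), drop = FALSE]
  g <- snn_graph(pcs, cfg$snn_k)
  cl <- igraph::cluster_louvain(g, resolution = cfg$louvain_resolution)
  clusters <- igraph::membership(cl)
  names(clusters) <- colnames(normalized)
  nn <- min(cfg$umap_neighbors, n - 1L)
  emb <- uwot::umap(pcs, n_neighbors = nn, n_threads = 1,
                    n_sgd_threads = 1, init = if (n <= 20L) "pca" else
                      "spectral")
  rownames(emb) <- colnames(normalized)
  list(embedding = emb, clusters = as.integer(clusters),
       pca = pcs, features = rownames(x), sample_ids = colnames(normalized))
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement between two clusterings:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])` with the exact
#' hypergeometric expected mutual information and arithmetic-mean
#' normalization. Permutation-invariant; identical labelings give 1,
#' independent ones about 0.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return The AMI value.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1L, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      for (nij in lo:hi) {
        # hypergeometric probability of nij via log factorials
        lp <- lgamma(a[i] + 1) + lgamma(b[j] + 1) + lgamma(n - a[i] + 1) +
          lgamma(n - b[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
          lgamma(a[i] - nij + 1) - lgamma(b[j] - nij + 1) -
          lgamma(n - a[i] - b[j] + nij + 1)
        emi <- emi + nij / n * log(n * nij / (a[i] * b[j])) * exp(lp)
      }
    }
  }
  h <- function(x) {
    p <- x / n
    -sum(ifelse(p > 0, p * log(p), 0))
  }
  denom <- (h(a) + h(b)) / 2 - emi
  if (denom == 0) return(if (abs(mi - emi) < 1e-12) 1 else 0)
  unname((mi - emi) / denom)
}
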