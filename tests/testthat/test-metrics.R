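test_that("coefficient of variation matches hand arithmetic", {
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)  # sd 1, mean 2
  expect_error(coefficient_of_variation(c(0, 0, 0)), "mean")
  expect_error(coefficient_of_variation(5), "two features")
  # detected-only mode drops zeros first
  expect_equal(coefficient_of_variation(c(0, 0, 1, 2, 3),
                                        detected_only = TRUE), 0.5)
})

test_that("reproducibility distances partition sample pairs once", {
  mat <- matrix(c(0, 3, 3, 0, 0, 3), nrow = 2,
                dimnames = list(c("f1", "f2"), c("a1", "a2", "b1")))
  groups <- c(a1 = "A", a2 = "A", b1 = "B")
  d <- reproducibility_distances(mat, groups, pseudocount = 1)
  # columns (0,3) vs (3,0): sqrt((0-2)^2 + (2-0)^2) with log2(4) = 2
  expect_equal(d$within, sqrt(8))
  expect_equal(sort(d$between), c(0, sqrt(8)))
  expect_equal(nrow(d$pairs), 3L)  # each unordered pair once
  expect_error(reproducibility_distances(mat, c(a1 = "A"), 1), "group")
  same <- matrix(c(1, 2, 1, 2), nrow = 2,
                 dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(reproducibility_distances(same, c(s1 = "A", s2 = "A"),
                                         1)$within, 0)
  # triangle inequality on a random fixture
  set.seed(3)
  m <- matrix(rpois(30, 20), nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  dd <- reproducibility_distances(m, stats::setNames(rep("A", 6),
                                                     colnames(m)), 1)
  dm <- matrix(0, 6, 6, dimnames = list(colnames(m), colnames(m)))
  for (r in seq_len(nrow(dd$pairs))) {
    dm[dd$pairs$sample_a[r], dd$pairs$sample_b[r]] <- dd$pairs$distance[r]
    dm[dd$pairs$sample_b[r], dd$pairs$sample_a[r]] <- dd$pairs$distance[r]
  }
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
  }
})

test_that("G-content association is a Spearman correlation", {
  refs <- generate_reference(50, seed = 8)
  rates <- stats::setNames(rank(refs$g_content) / 50, refs$feature_id)
  up <- gcontent_detection_association(refs, rates)
  expect_equal(up$rho, 1)
  down <- gcontent_detection_association(refs, 1 - rates)
  expect_equal(down$rho, -1)
  expect_warning(
    flat <- gcontent_detection_association(
      refs, stats::setNames(rep(1, 50), refs$feature_id)),
    "constant")
  expect_true(is.na(flat$rho))
})

test_that("cell filtering applies the molecule threshold monotonically", {
  totals <- c(neg1 = 7, neg2 = 14, cell1 = 60)
  expect_equal(filter_cells(totals, 50), "cell1")
  expect_equal(filter_cells(totals, 0), names(totals))
  expect_warning(none <- filter_cells(totals, 100), "no sample")
  expect_equal(length(none), 0L)
  for (th in c(0, 5, 10, 20, 60, 100)) {
    expect_true(all(suppressWarnings(filter_cells(totals, th)) %in%
                      suppressWarnings(filter_cells(totals, max(0, th - 5)))))
  }
})

test_that("log-normalization uses natural log at scale 10,000", {
  raw <- matrix(c(5, 0), ncol = 1, dimnames = list(c("f1", "f2"), "s1"))
  ln <- lognormalize(raw)
  expect_equal(ln["f1", 1], log(10001))
  expect_equal(ln["f2", 1], 0)
  m <- matrix(rpois(40, 10), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  out <- lognormalize(m, scale = 1e4)
  expect_equal(unname(colSums(exp(out) - 1)), rep(1e4, 4))
  expect_warning(lognormalize(matrix(0, 2, 1,
    dimnames = list(c("a", "b"), "s"))), "zero library")
})

test_that("vst variable features rank a spiked bimodal feature first", {
  set.seed(10)
  n_feat <- 100
  n_samp <- 24
  raw <- matrix(rpois(n_feat * n_samp, lambda = rep(exp(rnorm(n_feat, 3,
    0.8)), n_samp)), nrow = n_feat,
    dimnames = list(sprintf("f%03d", 1:n_feat), paste0("s", 1:n_samp)))
  raw["f001", ] <- rep(c(5L, 50L), each = n_samp / 2)  # 10-fold bimodal
  raw["f002", ] <- 7L                                  # zero variance
  top <- suppressWarnings(variable_features(raw, 6))
  expect_equal(top[1], "f001")
  all_ranked <- suppressWarnings(variable_features(raw, n_feat))
  expect_equal(length(all_ranked), n_feat)
  expect_true(which(all_ranked == "f002") > n_feat - 10)
  expect_warning(variable_features(raw[1:4, ], 10), "returning all")
})

test_that("vst ranking agrees with the Seurat reference implementation", {
  set.seed(12)
  raw <- matrix(rpois(2400, lambda = rep(exp(rnorm(100, 2.5, 1)), 24)),
                nrow = 100,
                dimnames = list(sprintf("f%03d", 1:100), paste0("s", 1:24)))
  top <- variable_features(raw, 10)
  sv <- suppressWarnings(Seurat::FindVariableFeatures(
    raw, selection.method = "vst", verbose = FALSE))
  seurat_top <- rownames(sv)[order(sv$variance.standardized,
                                   decreasing = TRUE)][1:10]
  expect_gte(length(intersect(top, seurat_top)), 9L)
})

test_that("adjusted mutual information matches the formula oracle", {
  expect_equal(adjusted_mutual_information(c(1, 1, 2, 2), c("a", "a", "b",
                                                            "b")), 1)
  expect_equal(adjusted_mutual_information(c(1, 2, 1, 2), rep("x", 4)), 0)
  expect_error(adjusted_mutual_information(1:3, 1:4), "equal length")
  a <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 1, 2, 3)
  b <- c("x", "x", "y", "y", "y", "z", "z", "z", "x", "z", "x", "y")
  expect_equal(adjusted_mutual_information(a, b), oracle_ami(a, b))
  set.seed(9)
  for (i in 1:10) {
    aa <- sample(1:3, 12, TRUE)
    bb <- sample(letters[1:4], 12, TRUE)
    expect_equal(adjusted_mutual_information(aa, bb), oracle_ami(aa, bb))
    # permutation invariance of the labels
    relab <- c(b = 1, a = 2, d = 3, c = 4)[bb]
    expect_equal(adjusted_mutual_information(aa, relab),
                 adjusted_mutual_information(aa, bb))
  }
})

test_that("embedding and clustering are deterministic and order-stable", {
  set.seed(4)
  base <- matrix(rpois(200 * 12, 20), nrow = 200,
                 dimnames = list(sprintf("f%03d", 1:200),
                                 paste0("s", 1:12)))
  base[1:50, 7:12] <- base[1:50, 7:12] + 60L  # two clear groups
  norm <- lognormalize(base)
  cfg <- cluster_config(n_pcs = 5, umap_neighbors = 4,
                        louvain_resolution = 1.0, snn_k = 5, seed = 42)
  e1 <- suppressWarnings(embed_and_cluster(norm, cfg))
  e2 <- suppressWarnings(embed_and_cluster(norm, cfg))
  expect_identical(e1$clusters, e2$clusters)
  expect_identical(e1$embedding, e2$embedding)
  expect_equal(length(unique(e1$clusters)), 2L)
  expect_equal(adjusted_mutual_information(e1$clusters,
                                           rep(1:2, each = 6)), 1)
  # feature order must not change the labels
  e3 <- suppressWarnings(embed_and_cluster(norm[sample(nrow(norm)), ], cfg))
  expect_equal(adjusted_mutual_information(e3$clusters, e1$clusters), 1)
  # identical samples collapse into one cluster
  flat <- matrix(rep(c(3, 8, 1, 9), 6), nrow = 4,
                 dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  flat <- flat + matrix(stats::rnorm(24, sd = 1e-3), nrow = 4)
  ef <- suppressWarnings(embed_and_cluster(lognormalize(abs(flat)),
    cluster_config(n_pcs = 2, umap_neighbors = 3, louvain_resolution = 1,
                   snn_k = 3, seed = 1)))
  expect_equal(length(unique(ef$clusters)), 1L)
})

test_that("dedup lowers the spike-in CV when duplication dominates", {
  refs <- generate_reference(300, seed = 41)
  arch <- protocol_presets()$SBN_CL
  cfg <- library_sim_config(n_reads = 40000, frac_dimer = 0,
                            frac_other_rna = 0, frac_junk = 0,
                            bias_beta_g = 0, bias_sigma = 0,
                            pcr_mean_reads_per_molecule = 6,
                            pcr_dispersion = 0.3, seq_error_rate = 0,
                            low_quality_tail_frac = 0, seed = 42)
  sim <- simulate_library(refs, arch, cfg, sample_id = "s1")
  q <- quantify_sim(sim, refs, arch, "s1")
  raw <- count_features(q$hits, refs)
  mol <- dedup_counts(umi_table(q$hits, q$kept), refs, sample_ids = "s1")
  cv_raw <- coefficient_of_variation(rpmm_normalize(raw)[, 1])
  cv_mol <- coefficient_of_variation(rpmm_normalize(mol)[, 1])
  expect_lt(cv_mol, cv_raw)
})
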