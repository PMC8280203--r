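mk_records <- function(seqs, prefix = "r") {
  smallrna_records(sprintf("%s%03d", prefix, seq_along(seqs)), seqs,
                   strrep("I", nchar(seqs)))
}

test_that("identity-threshold mapping follows the 80% rule", {
  ref <- "ACGTACGTACGTACGTACGTAC"  # 22 nt
  refs <- reference_set("m1", ref)
  mutate <- function(s, k) {
    for (p in seq_len(k)) {
      substr(s, p * 4L, p * 4L) <- if (substr(s, p * 4L, p * 4L) == "A")
        "C" else "A"
    }
    s
  }
  recs <- mk_records(c(ref, mutate(ref, 4L), mutate(ref, 5L)))
  hits <- map_to_reference(recs, refs, min_identity = 0.80)
  expect_equal(hits$read_id, c("r001", "r002"))
  expect_equal(hits$identity, c(1, 18 / 22))
  expect_equal(hits$errors, c(0L, 4L))  # 5 substitutions: 17/22 < 0.8
  expect_error(map_to_reference(recs, refs[0, ], 0.8), "empty reference")
})

test_that("mapping matches the R dynamic-programming oracle", {
  set.seed(21)
  refs <- generate_reference(20, len_range = c(20, 25), seed = 21)
  # reads: exact copies, mutated copies, prefixes, random junk
  seqs <- c(refs$sequence[1:5],
            vapply(refs$sequence[6:10], function(s) {
              substr(s, 3, 3) <- "A"; substr(s, 9, 9) <- "T"; s
            }, character(1), USE.NAMES = FALSE),
            substr(refs$sequence[11:13], 1, 19),
            replicate(5, paste(sample(c("A", "C", "G", "T"), 22, TRUE),
                               collapse = "")))
  recs <- mk_records(seqs)
  hits <- map_to_reference(recs, refs, 0.80, best_only = FALSE)
  for (i in seq_along(seqs)) {
    maxe <- floor(0.2 * nchar(seqs[i]))
    want <- vapply(refs$sequence, oracle_semiglobal_errors,
                   numeric(1), read = seqs[i], USE.NAMES = FALSE)
    want_hits <- refs$feature_id[want <= maxe]
    got <- hits[hits$read_id == recs$read_id[i], ]
    expect_setequal(got$feature_id, want_hits)
    if (nrow(got) > 0) {
      expect_equal(got$errors[order(got$feature_id)],
                   as.integer(want[want <= maxe]))
    }
    # the fast best-only path agrees with the full scan
    best_fast <- map_to_reference(recs[i, , drop = FALSE], refs, 0.80)
    if (length(want_hits) == 0) {
      expect_equal(nrow(best_fast), 0L)
    } else {
      emin <- min(want[want <= maxe])
      cands <- refs$feature_id[want == emin]
      expect_equal(best_fast$feature_id, min(cands))  # lexicographic tie
      expect_equal(best_fast$errors, as.integer(emin))
    }
  }
})

test_that("identity ties resolve to the lexicographically smallest id", {
  seqs <- c(zz = "ACGTACGTACGTACGTACGTAC", aa = "ACGTACGTACGTACGTACGTAC")
  refs <- reference_set(names(seqs), unname(seqs))
  hits <- map_to_reference(mk_records(seqs[1]), refs, 0.8)
  expect_equal(hits$feature_id, "aa")
})

test_that("class assignment is hierarchical over all alignments", {
  track <- annotation_track(
    contig = rep("c1", 3),
    start = c(100L, 100L, 500L), end = c(200L, 200L, 600L),
    strand = c("+", "+", "+"),
    class_label = c("miRNA", "protein_coding", "lncRNA"),
    feature_id = c("mir1", "pc1", "lnc1"))
  aln <- data.frame(
    read_id = c("r1", "r1", "r2", "r3", "r4"),
    contig = "c1",
    start = c(110L, 110L, 174L, 400L, 510L),
    end = c(140L, 140L, 204L, 430L, 540L))
  out <- assign_class(aln, track, min_overlap = 0.90)
  out <- out[order(out$read_id), ]
  # r1 overlaps miRNA and protein_coding fully -> miRNA wins
  # r2 overlaps 26/30 = 86.7% -> intergenic
  # r3 hits nothing; r4 sits in the lncRNA
  expect_equal(out$assigned_class, c("miRNA", "intergenic", "intergenic",
                                     "lncRNA"))
  # multi-mapped read contributes all loci: alignment at miRNA OR lncRNA
  aln2 <- data.frame(read_id = c("rx", "rx"), contig = "c1",
                     start = c(510L, 110L), end = c(540L, 140L))
  expect_equal(assign_class(aln2, track, 0.9)$assigned_class, "miRNA")
  # permuting the priority candidates never changes the result
  out2 <- assign_class(aln[sample(nrow(aln)), ], track, 0.9)
  expect_equal(out2$assigned_class[order(out2$read_id)],
               out$assigned_class)
})

test_that("counting, RPMM and detection behave arithmetically", {
  refs <- reference_set(c("m1", "m2", "m3"),
                        c("ACGTACGTACGTACGTACGT",
                          "TTTTCCCCGGGGAAAATTTT",
                          "GACTGACTGACTGACTGACT"))
  hits <- data.frame(read_id = paste0("r", 1:4),
                     feature_id = c("m1", "m1", "m1", "m2"),
                     identity = 1, errors = 0L, is_best = TRUE,
                     sample_id = "s1", stringsAsFactors = FALSE)
  cnt <- count_features(hits, refs)
  expect_equal(unname(cnt[, "s1"]), c(3L, 1L, 0L))
  rp <- rpmm_normalize(matrix(c(10, 30, 60), ncol = 1,
                              dimnames = list(refs$feature_id, "s1")))
  expect_equal(unname(rp[, 1]), c(1e5, 3e5, 6e5))
  expect_equal(rpmm_normalize(rp), rp)  # idempotent on normalized columns
  single <- rpmm_normalize(matrix(c(0, 5, 0), ncol = 1,
                                  dimnames = list(refs$feature_id, "s1")))
  expect_equal(unname(single[2, 1]), 1e6)
  expect_warning(z <- rpmm_normalize(matrix(0, 3, 1,
    dimnames = list(refs$feature_id, "s1"))), "no mapped reads")
  expect_true(all(z == 0))
  det <- detection_calls(matrix(c(0, 1, 5), ncol = 1,
                                dimnames = list(refs$feature_id, "s1")))
  expect_equal(unname(det$detected[, 1]), c(FALSE, TRUE, TRUE))
  expect_equal(unname(det$per_sample), 2)
  multi <- matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0), nrow = 3)
  rownames(multi) <- refs$feature_id
  colnames(multi) <- paste0("s", 1:4)
  expect_equal(unname(detection_calls(multi)$per_feature),
               c(1, 0.75, 0))
})

test_that("simulated counts at zero error equal ground-truth reads", {
  refs <- generate_reference(60, seed = 13)
  arch <- protocol_presets()$SBN_CL
  cfg <- library_sim_config(n_reads = 6000, frac_dimer = 0.1,
                            frac_other_rna = 0, frac_junk = 0,
                            seq_error_rate = 0, low_quality_tail_frac = 0,
                            seed = 14)
  sim <- simulate_library(refs, arch, cfg)
  q <- quantify_sim(sim, refs, arch, "s1")
  cnt <- count_features(q$hits, refs)
  truth <- sim$truth[sim$truth$origin_class == "mirna", ]
  want <- table(factor(truth$origin_feature, levels = refs$feature_id))
  expect_equal(unname(cnt[, 1]), as.integer(want))
  # conservation: mapped + unmapped best-hit reads partition the kept set
  expect_equal(nrow(q$hits) + (nrow(q$kept) - nrow(q$hits)), nrow(q$kept))
  expect_lte(nrow(q$hits), nrow(q$kept))
})
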