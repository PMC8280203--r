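adapter3 <- protocol_presets()$SBN_CL$adapter3

test_that("UMI extraction moves leading bases into the UMI field", {
  rec <- smallrna_records("r1", "AACCGGTTACGTACGTACGTACGTACGT",
                          strrep("I", 28))
  out <- extract_umi(rec, 8L)
  expect_equal(out$umi, "AACCGGTT")
  expect_equal(out$sequence, "ACGTACGTACGTACGTACGT")
  expect_equal(nchar(out$quality), 20L)
  expect_identical(extract_umi(rec, 0L)$sequence, rec$sequence)
  # N-containing UMIs are stored verbatim but flagged
  rec_n <- smallrna_records("r2", "AANCGGTTACGTACGTACGT", strrep("I", 20))
  out_n <- extract_umi(rec_n, 8L)
  expect_equal(out_n$umi, "AANCGGTT")
  expect_true(attr(out_n, "umi_has_n"))
  # reads shorter than the UMI are flagged and later fail QC
  rec_s <- smallrna_records("r3", "ACGT", "IIII")
  out_s <- extract_umi(rec_s, 8L)
  expect_true(attr(out_s, "umi_short"))
  tr <- trim_reads(out_s, trim_config(adapter3, min_len = 2L,
                                      dimer_max_len = 0L))
  expect_equal(as.character(tr$status), "quality_fail")
})

test_that("3' quality trimming minimizes the running sum", {
  mk <- function(quals) {
    smallrna_records("r", strrep("A", length(quals)),
                     intToUtf8(quals + 33L))
  }
  high <- quality_trim_3prime(mk(rep(40, 10)), 20)
  expect_equal(nchar(high$sequence), 10L)
  low <- quality_trim_3prime(mk(rep(2, 6)), 20)
  expect_equal(nchar(low$sequence), 0L)
  mixed <- quality_trim_3prime(mk(c(40, 40, 40, 2, 2)), 20)
  expect_equal(nchar(mixed$sequence), 3L)
  # brute-force oracle: the cut minimizing the partial sum from the 3' end
  set.seed(42)
  for (i in 1:50) {
    q <- sample(2:41, sample(5:30, 1), replace = TRUE)
    sums <- rev(cumsum(rev(q - 20)))
    # ties resolve to the rightmost minimizing cut (keep the longer read)
    cut <- if (min(sums) < 0) max(which(sums == min(sums))) - 1L else
      length(q)
    got <- quality_trim_3prime(mk(q), 20)
    expect_equal(nchar(got$sequence), cut)
  }
})

test_that("adapter search honors the error-rate threshold", {
  insert <- "ACGTACGTACGTACGTACGTAC"  # 22 nt
  ad <- "TGGAATTCTCGGGTGCCAAG"        # 20 nt
  m <- find_adapter(paste0(insert, ad), ad, 0.10)
  expect_equal(m$start, 23L)  # first adapter base after the 22-nt insert
  expect_equal(m$errors, 0L)
  # 2 substitutions in 20 = 10% is accepted
  ad2 <- ad
  substr(ad2, 3, 3) <- "A"; substr(ad2, 10, 10) <- "A"
  m2 <- find_adapter(paste0(insert, ad2), ad, 0.10)
  expect_equal(m2$start, 23L)
  expect_equal(m2$errors, 2L)
  # 3 substitutions in 20 = 15% is rejected
  ad3 <- ad2
  substr(ad3, 15, 15) <- "C"
  expect_null(find_adapter(paste0(insert, ad3), ad, 0.10))
})

test_that("adapter search equals the exhaustive adist oracle", {
  set.seed(11)
  ad <- "TGGAATTCTCGG"
  for (i in 1:150) {
    len <- sample(5:40, 1)
    read <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    if (runif(1) < 0.5) {  # embed a mutated adapter copy
      pos <- sample.int(max(1, len - 5), 1)
      frag <- substr(ad, 1, min(nchar(ad), len - pos + 1))
      substr(read, pos, pos + nchar(frag) - 1L) <- frag
    }
    got <- find_adapter(read, ad, 0.10, min_overlap = 3L)
    want <- oracle_find_adapter(read, ad, 0.10, min_overlap = 3L)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$start, want$start, label = read)
      expect_equal(got$errors, want$errors, label = read)
    }
  }
})

test_that("trimming classifies reads with dimer precedence", {
  cfg <- trim_config(adapter3)
  pad <- function(s) smallrna_records("r", s, strrep("I", nchar(s)))
  # adapter-only read: everything trimmed -> dimer
  out <- trim_read(pad(paste0(adapter3, "ATCTCGTATGCCGTCTTCTGCTTG")), cfg)
  expect_equal(out$status, "adapter_dimer")
  expect_equal(out$removed_segments[[1]]$kind, "adapter")
  # 22-nt insert + adapter -> kept at 22
  ins22 <- "ACGTACGTACGTACGTACGTAC"
  out <- trim_read(pad(paste0(ins22, adapter3)), cfg)
  expect_equal(out$status, "kept")
  expect_equal(out$trimmed$sequence, ins22)
  # 16-nt insert + adapter -> too_short
  out <- trim_read(pad(paste0("ACGTACGTACGTACGT", adapter3)), cfg)
  expect_equal(out$status, "too_short")
  # kept-length read with 3 Ns -> quality_fail
  out <- trim_read(pad(paste0("ACGTNNNACGTACGTACGTAC", adapter3)), cfg)
  expect_equal(out$status, "quality_fail")
  # a 2-nt remnant with an N is a dimer, not a quality failure
  out <- trim_read(pad(paste0("NA", adapter3)), cfg)
  expect_equal(out$status, "adapter_dimer")
})

test_that("every read gets exactly one status and kept output is stable", {
  refs <- generate_reference(80, seed = 3)
  arch <- protocol_presets()$SBN_CL
  cfg <- library_sim_config(n_reads = 4000, seed = 5)
  sim <- simulate_library(refs, arch, cfg)
  rec <- extract_umi(sim$records, arch$umi_len)
  tcfg <- trim_config_for(arch)
  tr <- trim_reads(rec, tcfg)
  expect_equal(length(tr$status), 4000L)
  expect_equal(sum(tr$summary$n), 4000L)
  expect_false(any(is.na(tr$status)))
  # idempotence: re-trimming kept reads changes nothing
  kept <- tr$records[tr$status == "kept", , drop = FALSE]
  class(kept) <- c("smallrna_records", "data.frame")
  tr2 <- trim_reads(kept, tcfg)
  expect_true(all(tr2$status == "kept"))
  expect_equal(tr2$records$sequence, kept$sequence)
})

test_that("4N flanks are clipped from kept reads only", {
  arch <- protocol_presets()$SB_4N
  ins <- "ACGTACGTACGTACGTACGTAC"
  read <- paste0("TTTT", ins, "CCCC", arch$adapter3)
  rec <- smallrna_records("r", read, strrep("I", nchar(read)))
  out <- trim_reads(rec, trim_config_for(arch))
  expect_equal(as.character(out$status), "kept")
  expect_equal(out$records$sequence, ins)
})

test_that("subsampling is exact, order-preserving and deterministic", {
  rec <- random_records(5000, seed = 8)
  sub <- subsample_reads(rec, 3000, seed = 42)
  expect_equal(nrow(sub), 3000L)
  expect_identical(sub$read_id, sort(sub$read_id))  # original order kept
  sub2 <- subsample_reads(rec, 3000, seed = 42)
  expect_identical(sub$read_id, sub2$read_id)
  expect_equal(nrow(subsample_reads(rec, 10000, seed = 42)), 5000L)
})
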