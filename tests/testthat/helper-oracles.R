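# Independent oracles and small pipeline helpers used across the suite.
# Each oracle deliberately re-derives its quantity through a different
# route than the package implementation.

# --- edit distance of read vs reference, free end gaps on the reference,
#     plain R dynamic programming (oracle for map_to_reference)
oracle_semiglobal_errors <- function(read, ref) {
  r <- strsplit(read, "")[[1]]
  f <- strsplit(ref, "")[[1]]
  n <- length(r)
  m <- length(f)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0L  # free leading reference overhang
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (r[i] != f[j]),
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  min(D[n + 1L, ])  # free trailing reference overhang
}

# --- exhaustive adapter-occurrence search using base adist (oracle for
#     find_adapter): full adapter against every read substring, or every
#     adapter prefix (>= min_overlap) against every read suffix
oracle_find_adapter <- function(read, adapter, max_error_rate = 0.1,
                                min_overlap = 3L) {
  rlen <- nchar(read)
  alen <- nchar(adapter)
  cand <- list()
  if (rlen >= 1L) {
    starts <- rep(seq_len(rlen), times = rlen - seq_len(rlen) + 1L)
    ends <- unlist(lapply(seq_len(rlen), function(s) s:rlen))
    subs <- substring(read, starts, ends)
    errs <- as.integer(adist(adapter, subs))
    ok <- errs <= max_error_rate * alen
    if (any(ok)) {
      cand[[length(cand) + 1L]] <-
        data.frame(start = starts[ok], errors = errs[ok], mlen = alen)
    }
  }
  js <- seq.int(min_overlap, alen)
  for (j in js) {
    pre <- substr(adapter, 1L, j)
    suf_starts <- c(seq_len(rlen), rlen + 1L)  # include empty suffix
    sufs <- substring(read, suf_starts, rlen)
    errs <- as.integer(adist(pre, sufs))
    ok <- errs <= max_error_rate * j
    if (any(ok)) {
      cand[[length(cand) + 1L]] <-
        data.frame(start = suf_starts[ok], errors = errs[ok], mlen = j)
    }
  }
  if (length(cand) == 0L) return(NULL)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$errors, cand$start), , drop = FALSE]
  list(start = cand$start[1L], errors = cand$errors[1L])
}

# --- adjacency deduplication re-implemented independently: character-code
#     Hamming distances, neighbor sets recomputed at every step
oracle_adjacency_dedup <- function(counts) {
  umis <- names(counts)
  codes <- lapply(umis, utf8ToInt)
  ham <- function(i, j) sum(codes[[i]] != codes[[j]])
  unassigned <- seq_along(umis)
  groups <- 0L
  while (length(unassigned) > 0L) {
    cc <- counts[unassigned]
    top <- unassigned[cc == max(cc)]
    pick <- top[order(umis[top])][1L]
    nb <- unassigned[vapply(unassigned,
                            function(j) j != pick && ham(pick, j) == 1L,
                            logical(1))]
    unassigned <- setdiff(unassigned, c(pick, nb))
    groups <- groups + 1L
  }
  groups
}

# --- adjusted mutual information from the textbook formula, coded with
#     choose() hypergeometric terms rather than log-gamma
oracle_ami <- function(a, b) {
  n <- length(a)
  tab <- unclass(table(a, b))
  ai <- rowSums(tab)
  bj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    if (tab[i, j] > 0) {
      mi <- mi + tab[i, j] / n * log((tab[i, j] * n) / (ai[i] * bj[j]))
    }
  }
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    for (nij in max(1, ai[i] + bj[j] - n):min(ai[i], bj[j])) {
      p <- choose(bj[j], nij) * choose(n - bj[j], ai[i] - nij) /
        choose(n, ai[i])
      emi <- emi + p * nij / n * log((nij * n) / (ai[i] * bj[j]))
    }
  }
  ent <- function(x) -sum((x / n) * log(x / n))
  unname((mi - emi) / ((ent(ai) + ent(bj)) / 2 - emi))
}

# --- shared fixtures -------------------------------------------------------

random_records <- function(n, len = 30L, seed = 1L, prefix = "r") {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  smallrna_records(sprintf("%s%04d", prefix, seq_len(n)), seqs,
                   rep(strrep("I", len), n))
}

# run one simulated library through extract/trim/map with the trimmer
# matched to the generator's artifact content (no homopolymer tails are
# simulated)
quantify_sim <- function(sim, refs, arch, sample_id) {
  rec <- extract_umi(sim$records, arch$umi_len)
  tr <- trim_reads(rec, trim_config_for(arch, polyA = FALSE, polyG = FALSE))
  kept <- tr$records[tr$status == "kept", , drop = FALSE]
  class(kept) <- c("smallrna_records", "data.frame")
  h <- map_to_reference(kept, refs)
  h$sample_id <- rep(sample_id, nrow(h))
  list(hits = h, trim = tr, kept = kept)
}
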