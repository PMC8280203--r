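#' Protocol architecture of a small RNA library
#'
#' Describes how a sequenced read is laid out for a given library protocol
#' family: 3' and 5' adapter sequences, the UMI length carried at the start
#' of the read (8 nt for the SB/SBN/CL families, 6 nt for the shortened-UMI
#' variants, 0 when absent), the length of random-nucleotide flanks at the
#' ligation sites (4 for the 4N family, else 0) and the instrument read
#' length (75 bp single-end).
#'
#' @param name protocol name.
#' @param adapter3,adapter5 non-empty DNA adapter sequences.
#' @param umi_len UMI length, one of 0, 6, 8.
#' @param flank4n_len random-flank length per ligation site, 0 or 4.
#' @param read_len instrument read length (default 75).
#' @param pcr_primer PCR primer sequence appearing on 3' read-through
#'   (also used as a trimmable adapter).
#' @return A list of class `protocol_architecture`.
#' @export
protocol_architecture <- function(name, adapter3, adapter5, umi_len = 8L,
                                  flank4n_len = 0L, read_len = 75L,
                                  pcr_primer = "ATCTCGTATGCCGTCTTCTGCTTG") {
  stopifnot(nzchar(adapter3), nzchar(adapter5),
            umi_len %in% c(0L, 6L, 8L), flank4n_len %in% c(0L, 4L))
  if (read_len < umi_len + 4L) {
    stop("read_len must be at least umi_len + 4")
  }
  structure(list(name = name, adapter3 = adapter3, adapter5 = adapter5,
                 umi_len = as.integer(umi_len),
                 flank4n_len = as.integer(flank4n_len),
                 read_len = as.integer(read_len), pcr_primer = pcr_primer),
            class = "protocol_architecture")
}

#' Built-in protocol architecture presets
#'
#' Presets for the benchmarked ligation protocol families, built on the
#' standard Illumina small RNA adapter/primer sequences those protocols
#' derive from. `SB`/`SBN` carry an 8-nt UMI in the 5' adapter; `*_CL`
#' variants use the chemically modified adapter chemistry (same trimmable
#' sequence); `*_UMI6` shortens the UMI to 6 nt; `4N` variants add 4 random
#' nucleotides at each ligation site (and protocol `4N` itself has no UMI).
#'
#' @return Named list of `protocol_architecture` objects.
#' @export
protocol_presets <- function() {
  ra3 <- "TGGAATTCTCGGGTGCCAAGG"
  ra5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  list(
    SB      = protocol_architecture("SB", ra3, ra5, umi_len = 8L),
    SBN     = protocol_architecture("SBN", ra3, ra5, umi_len = 8L),
    SBN_CL  = protocol_architecture("SBN_CL", ra3, ra5, umi_len = 8L),
    CL      = protocol_architecture("CL", ra3, ra5, umi_len = 8L),
    CL_UMI6 = protocol_architecture("CL_UMI6", ra3, ra5, umi_len = 6L),
    SB_4N   = protocol_architecture("SB_4N", ra3, ra5, umi_len = 8L,
                                    flank4n_len = 4L),
    `4N`    = protocol_architecture("4N", ra3, ra5, umi_len = 0L,
                                    flank4n_len = 4L)
  )
}

#' Configuration of one simulated library
#'
#' Defines the mixture and noise structure of a synthetic single-cell small
#' RNA library: the adapter-dimer, non-miRNA-RNA and junk-read load, the
#' G-content capture-bias model (log-odds slope `bias_beta_g` plus lognormal
#' per-feature noise `bias_sigma`), PCR duplication (shifted negative
#' binomial reads per molecule), base-call substitution errors and
#' low-quality 3' tails. The remainder of the read mixture after dimers,
#' other RNA and junk is miRNA-insert reads.
#'
#' @param n_reads total reads to emit.
#' @param frac_dimer,frac_other_rna,frac_junk mixture fractions in `[0,1]`,
#'   summing to at most 1.
#' @param bias_beta_g log-odds slope of capture probability on G-content.
#' @param bias_sigma standard deviation of lognormal per-feature capture
#'   noise.
#' @param pcr_mean_reads_per_molecule mean reads per molecule (>= 1); the
#'   default targets the duplication depth observed in single-cell
#'   libraries (4.74 reads per UMI).
#' @param pcr_dispersion negative binomial size parameter (> 0).
#' @param seq_error_rate per-base substitution probability.
#' @param low_quality_tail_frac fraction of reads receiving a 3' tail of
#'   sub-Q20 qualities.
#' @param seed integer RNG seed; mandatory, the generator is fully
#'   deterministic given the configuration.
#' @param unique_umis if `TRUE`, molecule UMIs within a feature are drawn
#'   from a parity code with pairwise Hamming distance >= 2, so that UMI
#'   groups map one-to-one onto molecules (used for exact molecule-recovery
#'   checks); default `FALSE` (uniform random UMIs).
#' @return A list of class `library_sim_config`.
#' @export
library_sim_config <- function(n_reads = 50000L, frac_dimer = 0.30,
                               frac_other_rna = 0.15, frac_junk = 0.05,
                               bias_beta_g = 1.5, bias_sigma = 1.0,
                               pcr_mean_reads_per_molecule = 4.74,
                               pcr_dispersion = 2.0, seq_error_rate = 0.002,
                               low_quality_tail_frac = 0.05, seed,
                               unique_umis = FALSE) {
  if (missing(seed)) stop("a seed is mandatory for simulation")
  stopifnot(n_reads >= 1L, frac_dimer >= 0, frac_other_rna >= 0,
            frac_junk >= 0, frac_dimer + frac_other_rna + frac_junk <= 1,
            pcr_mean_reads_per_molecule >= 1, pcr_dispersion > 0,
            seq_error_rate >= 0, seq_error_rate <= 1,
            low_quality_tail_frac >= 0, low_quality_tail_frac <= 1,
            bias_sigma >= 0)
  structure(list(n_reads = as.integer(n_reads), frac_dimer = frac_dimer,
                 frac_other_rna = frac_other_rna, frac_junk = frac_junk,
                 bias_beta_g = bias_beta_g, bias_sigma = bias_sigma,
                 pcr_mean_reads_per_molecule = pcr_mean_reads_per_molecule,
                 pcr_dispersion = pcr_dispersion,
                 seq_error_rate = seq_error_rate,
                 low_quality_tail_frac = low_quality_tail_frac,
                 seed = as.integer(seed),
                 unique_umis = isTRUE(unique_umis)),
            class = "library_sim_config")
}

rand_dna <- function(n, len, prob_g = 0.25) {
  if (n == 0L) return(character())
  probs <- c((1 - prob_g) / 3, (1 - prob_g) / 3, prob_g, (1 - prob_g) / 3)
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE,
                     prob = probs), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a synthetic equimolar short RNA reference
#'
#' Emulates an equimolar spike-in pool: `n_seqs` unique sequences with
#' lengths in `len_range` and a per-sequence G-content drawn from a Beta
#' distribution matched to `gc_profile` (so the pool spans a realistic
#' G-content spread for bias modelling). The pool is substring-free: no
#' sequence is contained in another, so every member is identifiable under
#' end-gap-tolerant mapping — the property that makes an equimolar pool
#' usable as quantification ground truth. Deterministic given `seed`.
#'
#' @param n_seqs number of sequences (>= 1).
#' @param len_range integer length range within `[15, 30]`.
#' @param gc_profile list with `mean` and `sd` of the per-sequence
#'   G-content distribution.
#' @param seed integer RNG seed.
#' @return A `reference_set` with ids `synmiR-0001`, ...
#' @export
generate_reference <- function(n_seqs = 1006L, len_range = c(20L, 25L),
                               gc_profile = list(mean = 0.25, sd = 0.08),
                               seed) {
  stopifnot(n_seqs >= 1L, len_range[1] >= 15L, len_range[2] <= 30L,
            len_range[1] <= len_range[2])
  if (missing(seed)) stop("a seed is mandatory for simulation")
  set.seed(seed)
  m <- gc_profile$mean
  s <- gc_profile$sd
  pg <- if (s > 0) {
    v <- s^2
    a <- m * (m * (1 - m) / v - 1)
    b <- (1 - m) * (m * (1 - m) / v - 1)
    stats::rbeta(n_seqs, a, b)
  } else rep(m, n_seqs)
  lens <- sample(seq(len_range[1], len_range[2]), n_seqs, replace = TRUE)
  seqs <- character(n_seqs)
  seen <- new.env(hash = TRUE)   # all length >= len_range[1] substrings seen
  pool <- ""                     # accepted sequences, "|"-separated
  for (i in seq_len(n_seqs)) {
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      cand <- rand_dna(1L, lens[i], prob_g = pg[i])
      # reject candidates contained in an accepted sequence ...
      if (grepl(cand, pool, fixed = TRUE)) next
      # ... or containing an accepted sequence
      subs <- unique(unlist(lapply(len_range[1]:nchar(cand), function(w) {
        substring(cand, 1:(nchar(cand) - w + 1L), w:nchar(cand))
      })))
      if (any(vapply(subs, function(s) !is.null(seen[[s]]), logical(1)))) {
        next
      }
      for (s in subs) seen[[s]] <- TRUE
      pool <- paste0(pool, "|", cand)
      seqs[i] <- cand
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("failed to draw a unique sequence after 1000 attempts")
    }
  }
  reference_set(sprintf("synmiR-%04d", seq_len(n_seqs)), seqs)
}

#' Capture probabilities under G-content bias
#'
#' Formalizes sequence-dependent capture bias as
#' `p_i` proportional to `exp(beta_g * g_i + eps_i)` with
#' `eps_i ~ Normal(0, sigma^2)`, normalized to sum to 1. With
#' `beta_g = 0` and `sigma = 0` the pool is captured uniformly.
#'
#' @param refs a `reference_set`.
#' @param beta_g log-odds slope on G-content.
#' @param sigma standard deviation of the lognormal per-feature noise.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as inside [simulate_library()]).
#' @return Named numeric vector of probabilities summing to 1.
#' @export
capture_probabilities <- function(refs, beta_g, sigma, seed = NULL) {
  stopifnot(nrow(refs) > 0L)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (sigma > 0) stats::rnorm(nrow(refs), 0, sigma) else
    rep(0, nrow(refs))
  w <- exp(beta_g * refs$g_content + eps)
  p <- w / sum(w)
  names(p) <- refs$feature_id
  p
}

#' Generate a synthetic genome with annotated non-miRNA features
#'
#' Builds a random contig and places non-overlapping annotated features
#' (rRNA, snoRNA, snRNA, misc RNA, lncRNA, protein-coding) plus a few
#' miRNA loci, providing realistic competitors for hierarchical class
#' assignment and the source of "other RNA" inserts.
#'
#' @param genome_len contig length in bp.
#' @param n_features number of non-miRNA features.
#' @param n_mirna number of miRNA loci.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return List with `genome` (single DNA string), `track`
#'   (`annotation_track`) and `contig` name.
#' @export
generate_genome_annotation <- function(genome_len = 20000L, n_features = 30L,
                                       n_mirna = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- rand_dna(1L, genome_len)
  classes <- sample(c("rRNA", "snoRNA", "snRNA", "misc_RNA", "lncRNA",
                      "protein_coding"), n_features, replace = TRUE)
  widths <- ifelse(classes %in% c("lncRNA", "protein_coding"),
                   sample(200:1000, n_features, replace = TRUE),
                   sample(80:300, n_features, replace = TRUE))
  widths <- c(widths, rep(22L, n_mirna))
  classes <- c(classes, rep("miRNA", n_mirna))
  n_all <- length(widths)
  # lay features left to right with random gaps; stop if the contig fills up
  starts <- integer(0)
  pos <- 0L
  keep <- logical(n_all)
  for (i in seq_len(n_all)) {
    gap <- sample(10:200, 1L)
    s <- pos + gap
    if (s + widths[i] > genome_len) break
    starts <- c(starts, s)
    keep[i] <- TRUE
    pos <- s + widths[i]
  }
  classes <- classes[keep]
  widths <- widths[keep]
  track <- annotation_track(
    contig = rep("synchr1", length(starts)), start = starts,
    end = starts + widths, strand = rep("+", length(starts)),
    class_label = classes,
    feature_id = sprintf("%s-%03d", sub("_", "", classes),
                         seq_along(starts)))
  list(genome = genome, track = track, contig = "synchr1")
}

parity_umi <- function(k, umi_len) {
  # single-parity-check code over GF(4): any two codewords differ in >= 2
  # positions, so UMI groups cannot merge under distance-1 adjacency
  bases <- c("A", "C", "G", "T")
  digits <- integer(umi_len - 1L)
  x <- k
  for (i in seq_len(umi_len - 1L)) {
    digits[i] <- x %% 4L
    x <- x %/% 4L
  }
  if (x > 0L) stop("too many molecules for a distance-2 UMI code")
  paste(c(bases[digits + 1L], bases[(sum(digits) %% 4L) + 1L]),
        collapse = "")
}

#' Simulate one small RNA library with per-read ground truth
#'
#' Emits exactly `cfg$n_reads` reads laid out as
#' `[UMI][5' 4N flank][insert][3' 4N flank][3' adapter][PCR primer][polyA]`
#' truncated to the read length. Adapter-dimer reads carry an empty insert.
#' miRNA molecule counts per feature are multinomial under
#' [capture_probabilities()]; reads per molecule follow a shifted negative
#' binomial; substitution errors and sub-Q20 3' tails are applied last.
#' One global RNG is seeded once from `cfg$seed` and consumed in a fixed
#' order (mixture, capture bias, molecules, duplication, sequence assembly,
#' errors, qualities), making the output byte-deterministic.
#'
#' @param refs a `reference_set` of miRNA-like features.
#' @param arch a `protocol_architecture`.
#' @param cfg a `library_sim_config`.
#' @param sample_id prefix for read ids (default `"S1"`).
#' @param genome optional result of [generate_genome_annotation()] used to
#'   draw "other RNA" inserts; generated on the fly when needed.
#' @param capture_probs optional fixed capture-probability vector (as from
#'   [capture_probabilities()]); when given, the per-library bias draw is
#'   skipped so replicates can share one protocol-specific bias profile.
#' @return List with `records` (`smallrna_records`), `truth` (data frame
#'   with `read_id`, `origin_class`, `origin_feature`, `true_umi`,
#'   `molecule_id`) and `capture_probs`.
#' @export
simulate_library <- function(refs, arch, cfg, sample_id = "S1",
                             genome = NULL, capture_probs = NULL) {
  stopifnot(inherits(arch, "protocol_architecture"),
            inherits(cfg, "library_sim_config"))
  if (arch$read_len < arch$umi_len + 4L) {
    stop("read_len shorter than umi_len + 4")
  }
  set.seed(cfg$seed)
  n <- cfg$n_reads
  # 1. mixture: per-read origin class counts
  cls_p <- c(mirna = 1 - cfg$frac_dimer - cfg$frac_other_rna - cfg$frac_junk,
             dimer = cfg$frac_dimer, other_rna = cfg$frac_other_rna,
             junk = cfg$frac_junk)
  cls_n <- as.integer(stats::rmultinom(1L, n, cls_p))
  names(cls_n) <- names(cls_p)
  # 2. capture bias (unless a shared profile was supplied)
  p <- if (is.null(capture_probs)) {
    capture_probabilities(refs, cfg$bias_beta_g, cfg$bias_sigma)
  } else {
    stopifnot(length(capture_probs) == nrow(refs))
    capture_probs
  }
  # 3. miRNA molecules and PCR duplication
  n_mirna <- cls_n[["mirna"]]
  mol_feature <- integer(0)
  mol_reads <- integer(0)
  while (sum(mol_reads) < n_mirna) {
    need <- n_mirna - sum(mol_reads)
    batch <- max(16L, ceiling(need / cfg$pcr_mean_reads_per_molecule))
    f <- sample.int(nrow(refs), batch, replace = TRUE, prob = p)
    d <- if (cfg$pcr_mean_reads_per_molecule > 1) {
      1L + stats::rnbinom(batch, size = cfg$pcr_dispersion,
                          mu = cfg$pcr_mean_reads_per_molecule - 1)
    } else rep(1L, batch)
    mol_feature <- c(mol_feature, f)
    mol_reads <- c(mol_reads, d)
  }
  extra <- sum(mol_reads) - n_mirna
  if (extra > 0L) {  # truncate the last molecule to hit n_mirna exactly
    last <- length(mol_reads)
    while (extra > 0L && last > 0L) {
      cut <- min(extra, mol_reads[last] - 0L)
      if (mol_reads[last] <= extra) {
        extra <- extra - mol_reads[last]
        mol_feature <- mol_feature[-last]
        mol_reads <- mol_reads[-last]
        last <- last - 1L
      } else {
        mol_reads[last] <- mol_reads[last] - extra
        extra <- 0L
      }
    }
  }
  n_mol <- length(mol_reads)
  # per-molecule UMIs
  umi_len <- arch$umi_len
  mol_umi <- if (umi_len == 0L) {
    rep("", n_mol)
  } else if (cfg$unique_umis) {
    idx <- stats::ave(seq_len(n_mol), mol_feature, FUN = seq_along) - 1L
    vapply(idx, parity_umi, character(1), umi_len = umi_len)
  } else {
    rand_dna(n_mol, umi_len)
  }
  mol_id <- sprintf("%s_mol%06d", sample_id, seq_len(n_mol))
  # 4. assemble inserts per read
  mirna_mol_of_read <- rep(seq_len(n_mol), mol_reads)
  mirna_insert <- refs$sequence[mol_feature][mirna_mol_of_read]
  n_other <- cls_n[["other_rna"]]
  if (n_other > 0L && is.null(genome)) {
    genome <- generate_genome_annotation()
  }
  other_insert <- character(0)
  other_feature <- character(0)
  if (n_other > 0L) {
    tr <- genome$track
    cand <- which(tr$class_label != "miRNA")
    pick <- sample(cand, n_other, replace = TRUE)
    w <- pmin(sample(30:70, n_other, replace = TRUE),
              tr$end[pick] - tr$start[pick])
    off <- floor(stats::runif(n_other) *
                   (tr$end[pick] - tr$start[pick] - w + 1))
    other_insert <- substring(genome$genome, tr$start[pick] + off + 1,
                              tr$start[pick] + off + w)
    other_feature <- tr$feature_id[pick]
  }
  n_junk <- cls_n[["junk"]]
  junk_insert <- character(0)
  if (n_junk > 0L) {
    short <- stats::runif(n_junk) < 0.5
    junk_insert <- character(n_junk)
    if (any(short)) {  # too-short inserts (trigger the length filter)
      k <- sum(short)
      junk_insert[short] <- substr(rand_dna(k, 17L), 1L,
                                   sample(4:17, k, replace = TRUE))
    }
    if (any(!short)) {  # N-rich inserts (trigger the max-N filter)
      k <- sum(!short)
      lens <- sample(18:30, k, replace = TRUE)
      s <- substr(rand_dna(k, 30L), 1L, lens)
      p <- sample.int(10L, k, replace = TRUE)  # 3 Ns at p, p+3, p+6 <= 16
      for (off in c(0L, 3L, 6L)) substr(s, p + off, p + off) <- "N"
      junk_insert[!short] <- s
    }
  }
  n_dimer <- cls_n[["dimer"]]
  origin_class <- rep(c("mirna", "dimer", "other_rna", "junk"),
                      c(n_mirna, n_dimer, n_other, n_junk))
  insert <- c(mirna_insert, rep("", n_dimer), other_insert, junk_insert)
  origin_feature <- c(refs$feature_id[mol_feature][mirna_mol_of_read],
                      rep("", n_dimer), other_feature, rep("", n_junk))
  n_total <- length(insert)
  read_umi <- c(mol_umi[mirna_mol_of_read],
                if (umi_len > 0L) rand_dna(n_total - n_mirna, umi_len) else
                  rep("", n_total - n_mirna))
  molecule_id <- c(mol_id[mirna_mol_of_read],
                   sprintf("%s_aux%06d", sample_id,
                           seq_len(n_total - n_mirna)))
  fl <- arch$flank4n_len
  flank5 <- if (fl > 0L) rand_dna(n_total, fl) else rep("", n_total)
  flank3 <- if (fl > 0L) rand_dna(n_total, fl) else rep("", n_total)
  pad <- strrep("A", arch$read_len)
  full <- paste0(read_umi, flank5, insert, flank3, arch$adapter3,
                 arch$pcr_primer, pad)
  seqs <- substr(full, 1L, arch$read_len)
  # 5. substitution errors (vectorized: one pass per error rank)
  if (cfg$seq_error_rate > 0) {
    n_err <- stats::rbinom(n_total, arch$read_len, cfg$seq_error_rate)
    bases <- c("A", "C", "G", "T")
    rank_max <- if (length(n_err) > 0L) max(n_err) else 0L
    for (rk in seq_len(rank_max)) {
      idx <- which(n_err >= rk)
      pos <- sample.int(arch$read_len, length(idx), replace = TRUE)
      cur <- match(substr(seqs[idx], pos, pos), bases)
      ok <- !is.na(cur)  # leave N bases untouched
      new_base <- bases[(cur[ok] - 1L +
                           sample.int(3L, sum(ok), replace = TRUE)) %% 4L + 1L]
      tgt <- idx[ok]
      x <- seqs[tgt]
      substr(x, pos[ok], pos[ok]) <- new_base
      seqs[tgt] <- x
    }
  }
  # 6. qualities: Q37 base, a sub-Q20 3' tail for a fraction of reads
  qual <- rep(strrep(intToUtf8(37L + 33L), arch$read_len), n_total)
  if (cfg$low_quality_tail_frac > 0) {
    low <- which(stats::runif(n_total) < cfg$low_quality_tail_frac)
    if (length(low) > 0L) {
      tail_len <- sample(5:15, length(low), replace = TRUE)
      tail_q <- sample(2:10, length(low), replace = TRUE)
      qual[low] <- paste0(substr(qual[low], 1L,
                                 arch$read_len - tail_len),
                          strrep(vapply(tail_q + 33L, intToUtf8,
                                        character(1)), tail_len))
    }
  }
  read_id <- sprintf("%s_r%07d", sample_id, seq_len(n_total))
  records <- smallrna_records(read_id, seqs, qual)
  truth <- data.frame(read_id = read_id, origin_class = origin_class,
                      origin_feature = origin_feature, true_umi = read_umi,
                      molecule_id = molecule_id, stringsAsFactors = FALSE)
  list(records = records, truth = truth, capture_probs = p)
}

#' Simulate several libraries with per-sample seeds
#'
#' Convenience wrapper running [simulate_library()] once per sample with
#' seeds `cfg$seed + 0 .. n-1`.
#'
#' @param refs,arch,cfg as for [simulate_library()].
#' @param sample_ids character vector of sample names.
#' @param genome optional shared synthetic genome.
#' @param capture_probs optional shared bias profile for all samples.
#' @return Named list of [simulate_library()] results.
#' @export
simulate_samples <- function(refs, arch, cfg, sample_ids, genome = NULL,
                             capture_probs = NULL) {
  out <- vector("list", length(sample_ids))
  names(out) <- sample_ids
  for (i in seq_along(sample_ids)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    out[[i]] <- simulate_library(refs, arch, cfg_i,
                                 sample_id = sample_ids[i], genome = genome,
                                 capture_probs = capture_probs)
  }
  out
}
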