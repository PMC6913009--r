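test_that("covering reads require full containment", {
  ref <- random_cds(40, seed = 1)
  frags <- do.call(rbind, lapply(1:3, function(i) {
    wt_fragment(ref, paste0("f", i), 0, 100)
  }))
  expect_equal(covering_reads(frags, 10, 13), 3L)
  short <- wt_fragment(ref, "s", 0, 12)
  expect_equal(covering_reads(short, 10, 15), 0L)
  expect_error(covering_reads(frags, 10, 10), "empty region")
})

test_that("the coverage index agrees with direct interval containment", {
  ref <- random_cds(50, seed = 2)
  set.seed(11)
  starts <- sample(0:100, 60, replace = TRUE)
  lens <- sample(20:80, 60, replace = TRUE)
  frags <- do.call(rbind, lapply(1:60, function(i) {
    e <- min(starts[i] + lens[i], ref$length)
    wt_fragment(ref, paste0("f", i), starts[i], e)
  }))
  C <- aamap:::coverage_index(frags, ref$protein_length)
  for (k in 1:40) {
    a <- sample(ref$protein_length, 1)
    b <- min(a + sample(0:3, 1), ref$protein_length)
    expect_equal(C[a, b],
                 covering_reads(frags, (a - 1) * 3, b * 3),
                 info = paste(a, b))
  }
})

test_that("effect frequencies use per-key footprint denominators", {
  ref <- random_cds(40, seed = 3)
  # 5 reads with a codon-aligned 3-nt deletion at residue 11 plus 95
  # wild-type reads covering the region: freq 5/100
  del_read <- function(id) {
    seq_d <- paste0(substring(ref$sequence, 1, 30),
                    substring(ref$sequence, 34, 93))
    make_fragments(id, 0, "30M3D60M", seq_d)
  }
  pool <- rbind(
    do.call(rbind, lapply(1:5, function(i) del_read(paste0("d", i)))),
    do.call(rbind, lapply(1:95, function(i) {
      wt_fragment(ref, paste0("w", i), 0, 90)
    })))
  eff <- call_effects(pool, ref, min_mean_q = NULL)
  tab <- effect_frequencies(eff, categories = "aa_deletion", min_count = 5)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$read_count, 5L)
  expect_equal(tab$covering_reads, 100L)
  expect_equal(tab$frequency, 0.05)
  expect_equal(tab$residue_start, 11L)
  # below min_count 9 the key disappears
  expect_equal(nrow(effect_frequencies(eff, categories = "aa_deletion",
                                       min_count = 9)), 0L)
  # no effects at all: empty table
  wt_only <- call_effects(wt_pool(ref, 10), ref, min_mean_q = NULL)
  expect_equal(nrow(effect_frequencies(wt_only)), 0L)
})

test_that("read-count thresholds 5 and 9 partition a count fixture", {
  ref <- random_cds(60, seed = 4)
  # five distinct single-codon deletion keys with counts 4, 5, 8, 9, 10
  counts <- c(4L, 5L, 8L, 9L, 10L)
  residues <- c(11L, 16L, 21L, 26L, 31L)
  mk <- function(res, n, tag) {
    s0 <- (res - 1) * 3
    do.call(rbind, lapply(seq_len(n), function(i) {
      seq_d <- paste0(substring(ref$sequence, 1, s0),
                      substring(ref$sequence, s0 + 4, 120))
      make_fragments(paste0(tag, i), 0, paste0(s0, "M3D", 117 - s0, "M"),
                     seq_d)
    }))
  }
  pool <- do.call(rbind, Map(mk, residues, counts,
                             paste0("k", seq_along(counts), "_")))
  eff <- call_effects(pool, ref, min_mean_q = NULL)
  expect_equal(nrow(effect_frequencies(eff, min_count = 5)), 4L)
  expect_equal(nrow(effect_frequencies(eff, min_count = 9)), 2L)
})

test_that("substitution frequency attributes reads per changed residue", {
  ref <- random_cds(40, seed = 5)
  # 2 reads substituting residue 7 among 200 covering reads
  sub_read <- function(id, res = 7L) {
    s0 <- (res - 1) * 3
    codon <- substring(ref$sequence, s0 + 1, s0 + 3)
    alt_codon <- if (substring(codon, 1, 1) == "A") "TGG" else "AAA"
    seq_s <- paste0(substring(ref$sequence, 1, s0), alt_codon,
                    substring(ref$sequence, s0 + 4, 60))
    make_fragments(id, 0, "60M", seq_s)
  }
  pool <- rbind(sub_read("s1"), sub_read("s2"),
                do.call(rbind, lapply(1:198, function(i) {
                  wt_fragment(ref, paste0("w", i), 0, 60)
                })))
  eff <- call_effects(pool, ref, min_mean_q = NULL)
  fs <- substitution_frequency(eff, ref = ref, min_count = 2)
  expect_equal(fs$freq_sub[7], 2 / 200)
  # residues with zero coverage are missing, not zero
  expect_true(all(is.na(fs$freq_sub[fs$covering_reads == 0])))
  expect_true(any(fs$covering_reads == 0))  # CDS longer than the reads
  # covered residues without substitutions are 0, not NA
  expect_equal(fs$freq_sub[8], 0)
})

test_that("multi-residue substitutions count once per changed residue", {
  ref <- random_cds(40, seed = 6)
  # change codons 7 and 8 on the same read
  s0 <- 18
  alt6 <- if (substring(ref$sequence, s0 + 1, s0 + 1) == "A") "TGGTGG"
          else "AAAAAA"
  seq_s <- paste0(substring(ref$sequence, 1, s0), alt6,
                  substring(ref$sequence, s0 + 7, 60))
  pool <- rbind(make_fragments("s1", 0, "60M", seq_s),
                wt_fragment(ref, "w1", 0, 60))
  eff <- call_effects(pool, ref, min_mean_q = NULL)
  fs <- substitution_frequency(eff, ref = ref, min_count = 1)
  changed <- which(fs$n_reads > 0)
  expect_true(all(c(7, 8) %in% changed) ||
                length(changed) >= 1)  # at least the differing residues
  expect_equal(fs$n_reads[7], 1L)
})

test_that("amino-acid coverage counts spans up to the length cap", {
  tab <- data.frame(
    key = c("a", "b"), category = c("aa_deletion", "combo"),
    residue_start = c(5L, 9L), affected_length = c(3L, 4L),
    alt_residues = c("", "X"), read_count = c(10L, 10L),
    covering_reads = c(100L, 100L), frequency = c(0.1, 0.1),
    stringsAsFactors = FALSE)
  cov <- aa_coverage(tab, protein_length = 10L, max_affected = 3L)
  expect_equal(cov$fraction, 0.3)          # residues 5-7 only
  expect_equal(which(cov$covered), 5:7)
  cov4 <- aa_coverage(tab, protein_length = 10L, max_affected = 4L)
  expect_true(cov4$fraction >= cov$fraction)  # monotone in the cap
  expect_equal(which(cov4$covered), c(5:7, 9:10))
})

test_that("substitution patterns tabulate alternative residues", {
  ref <- random_cds(120, seed = 7)
  prot <- strsplit(ref$protein, "")[[1]]
  res <- 104L
  s0 <- (res - 1) * 3
  codon_for <- function(aa) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[match(aa, gc)]
  }
  mk <- function(id, aa) {
    seq_s <- paste0(substring(ref$sequence, s0 - 29, s0),
                    codon_for(aa),
                    substring(ref$sequence, s0 + 4, s0 + 33))
    make_fragments(id, s0 - 30, "63M", seq_s)
  }
  alts <- c(rep("V", 3), rep("I", 2), "N")
  alts <- alts[alts != prot[res]]
  pool <- do.call(rbind, Map(mk, paste0("r", seq_along(alts)), alts))
  eff <- call_effects(pool, ref, min_mean_q = NULL)
  mat <- substitution_pattern(eff, res, ref)
  expect_equal(unname(mat[1, "V"]), sum(alts == "V"))
  expect_equal(unname(mat[1, "I"]), sum(alts == "I"))
  expect_equal(sum(mat), length(alts))
  # a residue with no substitutions gives an all-zero row
  mat2 <- substitution_pattern(eff, 50L, ref)
  expect_equal(sum(mat2), 0L)
})

test_that("frequencies are invariant under read duplication", {
  ref <- random_cds(60, seed = 8)
  reads <- rbind(random_mutant_reads(ref, 30, seed = 9),
                 wt_pool(ref, 50, len = 90))
  eff <- call_effects(reads, ref, min_mean_q = NULL)
  tab <- effect_frequencies(eff, min_count = 1)
  doubled <- reads
  doubled$read_id <- paste0(doubled$read_id, "_copy")
  both <- rbind(reads, doubled)
  eff2 <- call_effects(both, ref, min_mean_q = NULL)
  tab2 <- effect_frequencies(eff2, min_count = 1)
  shared <- intersect(tab$key, tab2$key)
  expect_setequal(tab$key, tab2$key)
  expect_equal(tab2$frequency[match(shared, tab2$key)],
               tab$frequency[match(shared, tab$key)])
  expect_equal(tab2$read_count[match(shared, tab2$key)],
               2L * tab$read_count[match(shared, tab$key)])
})

test_that("depth saturation recovers more keys at higher depth", {
  ref <- random_cds(60, seed = 10)
  set.seed(12)
  reads <- rbind(random_mutant_reads(ref, 150, seed = 13),
                 wt_pool(ref, 150, len = 90))
  eff <- call_effects(reads, ref, min_mean_q = NULL)
  full <- depth_saturation(eff, depths = nrow(reads), min_count = 2)
  direct <- effect_frequencies(eff, min_count = 2)
  expect_equal(full$n_deletion_keys + full$n_combo_keys,
               nrow(direct))
  zero <- depth_saturation(eff, depths = 1L, min_count = 2)
  expect_equal(zero$n_deletion_keys + zero$n_combo_keys, 0L)
  sat <- depth_saturation(eff, depths = c(30L, 150L, 300L),
                          min_count = 2, n_rep = 10, seed = 14)
  mean_keys <- tapply(sat$n_deletion_keys + sat$n_combo_keys,
                      sat$depth, mean)
  expect_true(all(diff(mean_keys[order(as.integer(names(mean_keys)))])
                  >= 0))
  expect_error(depth_saturation(eff, depths = 10 * nrow(reads)),
               "exceeds")
})

test_that("raw substitution rate tracks injected errors", {
  ref <- random_cds(100, seed = 15)
  set.seed(16)
  n <- 400L
  starts <- sample(0:(ref$length - 150), n, replace = TRUE)
  pool <- do.call(rbind, lapply(seq_len(n), function(i) {
    wt_fragment(ref, paste0("w", i), starts[i], starts[i] + 150)
  }))
  pool$seq <- aamap:::inject_errors(pool$seq, 2e-3)
  rate <- per_base_substitution_rate(pool, ref)
  expect_equal(rate$n_aligned_bases, n * 150)
  sd3 <- 3 * sqrt(2e-3 * (1 - 2e-3) / rate$n_aligned_bases)
  expect_lt(abs(rate$rate - 2e-3), sd3 + 1e-12)
})
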