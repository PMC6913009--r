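test_that("SAM records map to fragments with 0-based coordinates", {
  ref <- toy_ref()
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:toy\tLN:12",
    "r1\t0\ttoy\t1\t60\t12M\t*\t0\t0\tATGGCTGGTTAA\tIIIIIIIIIIII",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tATGGCTGGTTAA\tIIIIIIIIIIII",
    "r3\t0\ttoy\t1\t60\t5M3D4M\t*\t0\t0\tATGGCTTAA\tIIIIIIIII"
  ), sam)
  frags <- read_alignments(sam, ref)
  expect_equal(nrow(frags), 2L)
  expect_equal(frags$cds_start[frags$read_id == "r1"], 0L)
  expect_equal(frags$ref_end[frags$read_id == "r1"], 12L)
  expect_equal(frags$ref_end[frags$read_id == "r3"], 12L)
  expect_equal(unname(attr(frags, "skipped")["unmapped"]), 1L)

  other <- cds_reference("ATGGCTGGTTAA", "other")
  expect_error(read_alignments(sam, other), "other")
})

test_that("quality filter applies the mean-quality rule", {
  ref <- toy_ref()
  q40 <- strrep("I", 12)                       # Q40
  q20 <- strrep("5", 12)                       # Q20
  q_mix <- paste0(strrep("I", 6), strrep("7", 6))  # mean (40+22)/2 = 31
  frags <- rbind(
    make_fragments("keep40", 0, "12M", "ATGGCTGGTTAA", q40),
    make_fragments("drop20", 0, "12M", "ATGGCTGGTTAA", q20),
    make_fragments("keep31", 0, "12M", "ATGGCTGGTTAA", q_mix))
  kept <- quality_filter(frags, min_q = 30)
  expect_setequal(kept$read_id, c("keep40", "keep31"))
  expect_equal(attr(kept, "n_dropped_quality"), 1L)
  # per-base-minimum mode drops the mixed read too
  kept_min <- quality_filter(frags, min_q = 30, mode = "min")
  expect_setequal(kept_min$read_id, "keep40")
  # missing qualities pass with a warning by default
  frags$qual[1] <- "*"
  frags$mean_q[1] <- NA
  expect_warning(kept <- quality_filter(frags, 30), "lack")
  expect_true("keep40" %in% kept$read_id)
})

test_that("variant extraction emits substitutions, deletions, insertions", {
  ref <- random_cds(20, seed = 1)
  # perfect match
  ev <- extract_variants(wt_fragment(ref, "wt", 0, 24), ref)
  expect_equal(nrow(ev$variants), 0L)
  expect_equal(ev$per_read$frame_class, "wildtype")

  # single D op: 6M3D6M from 0
  seq_d <- paste0(substring(ref$sequence, 1, 6),
                  substring(ref$sequence, 10, 15))
  ev <- extract_variants(make_fragments("d1", 0, "6M3D6M", seq_d), ref)
  expect_equal(ev$variants$kind, "deletion")
  expect_equal(ev$variants$ref_start, 6L)
  expect_equal(ev$variants$ref_length, 3L)

  # single mismatch inside an M block at CDS position 4
  s <- ref$sequence
  old <- substring(s, 5, 5)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  seq_m <- paste0(substring(s, 1, 4), new, substring(s, 6, 12))
  ev <- extract_variants(make_fragments("m1", 0, "12M", seq_m), ref)
  expect_equal(ev$variants$kind, "substitution")
  expect_equal(ev$variants$ref_start, 4L)
  expect_equal(ev$variants$alt, new)

  # consecutive mismatches merge into one multi-nt substitution
  seq_mm <- paste0(substring(s, 1, 4), chartr("ACGT", "GTAC",
                                              substring(s, 5, 7)),
                   substring(s, 8, 12))
  ev <- extract_variants(make_fragments("mm", 0, "12M", seq_mm), ref)
  expect_equal(nrow(ev$variants), 1L)
  expect_equal(ev$variants$ref_length, 3L)

  # insertion consumes query only
  seq_i <- paste0(substring(s, 1, 6), "TTT", substring(s, 7, 12))
  ev <- extract_variants(make_fragments("i1", 0, "6M3I6M", seq_i), ref)
  expect_equal(ev$variants$kind, "insertion")
  expect_equal(ev$variants$ref_start, 6L)
  expect_equal(ev$variants$alt, "TTT")

  # unsupported CIGAR op rejected
  bad <- make_fragments("n1", 0, "6M3N6M", substring(s, 1, 12))
  expect_error(extract_variants(bad, ref), "CIGAR")
})

test_that("soft clips are ignored, not treated as variants", {
  ref <- random_cds(20, seed = 2)
  core <- substring(ref$sequence, 7, 30)
  clipped <- paste0("GGGG", core)
  ev <- extract_variants(make_fragments("s1", 6, "4S24M", clipped), ref)
  expect_equal(nrow(ev$variants), 0L)
})

test_that("frame classification follows net indel length mod 3", {
  ref <- random_cds(40, seed = 3)
  # exhaustive single-deletion lengths 1..12
  for (len in 1:12) {
    seq_d <- paste0(substring(ref$sequence, 1, 30),
                    substring(ref$sequence, 31 + len, 60 + len))
    frag <- make_fragments("d", 0, paste0("30M", len, "D30M"), seq_d)
    eff <- call_effects(frag, ref, min_mean_q = NULL)
    if (len %% 3 == 0) {
      expect_false(eff$category == "frameshift", info = len)
    } else {
      expect_equal(eff$category, "frameshift", info = len)
    }
  }
  # deletion 4 + insertion 2: net -2, frameshift
  v <- data.frame(kind = c("deletion", "insertion"),
                  ref_start = c(10L, 30L), ref_length = c(4L, 0L),
                  alt = c("", "AT"), stringsAsFactors = FALSE)
  expect_equal(classify_frame(v), "frameshift")
  v$ref_length[1] <- 3L
  expect_equal(classify_frame(v), "frameshift")  # net -1
  v$alt[2] <- "ATG"                              # net 0
  expect_equal(classify_frame(v), "in_frame_indel")
})

test_that("effect translation reproduces hand-worked examples", {
  # codon-aligned single-codon deletion: M[A]G -> deletes A
  ref <- toy_ref()
  v <- data.frame(kind = "deletion", ref_start = 3L, ref_length = 3L,
                  alt = "", stringsAsFactors = FALSE)
  eff <- translate_effect(v, ref)
  expect_equal(eff$category, "aa_deletion")
  expect_equal(eff$residue_start, 2L)
  expect_equal(eff$affected_length, 1L)
  expect_equal(eff$alt_residues, "")

  # M K P: delete nt [4,7) -> M T: combo replacing KP with T
  ref2 <- mkp_ref()
  v <- data.frame(kind = "deletion", ref_start = 4L, ref_length = 3L,
                  alt = "", stringsAsFactors = FALSE)
  eff <- translate_effect(v, ref2)
  expect_equal(eff$category, "combo")
  expect_equal(eff$residue_start, 2L)
  expect_equal(eff$affected_length, 2L)
  expect_equal(eff$alt_residues, "T")

  # substitution at nt 4: GCT -> GAT (A -> D missense)
  v <- data.frame(kind = "substitution", ref_start = 4L, ref_length = 1L,
                  alt = "A", stringsAsFactors = FALSE)
  eff <- translate_effect(v, ref)
  expect_equal(eff$category, "substitution")
  expect_equal(eff$residue_start, 2L)
  expect_equal(eff$alt_residues, "D")

  # synonymous change is silent: GCT -> GCC (both Ala)
  v <- data.frame(kind = "substitution", ref_start = 5L, ref_length = 1L,
                  alt = "C", stringsAsFactors = FALSE)
  expect_equal(translate_effect(v, ref)$category, "silent")

  # in-frame change creating a stop is nonsense: AAA -> TAA
  v <- data.frame(kind = "substitution", ref_start = 3L, ref_length = 1L,
                  alt = "T", stringsAsFactors = FALSE)
  expect_equal(translate_effect(v, ref2)$category, "nonsense")

  # out-of-frame input is a contract violation
  v <- data.frame(kind = "deletion", ref_start = 3L, ref_length = 2L,
                  alt = "", stringsAsFactors = FALSE)
  expect_error(translate_effect(v, ref), "out-of-frame")
})

test_that("effects are idempotent under flank padding", {
  ref <- random_cds(60, seed = 8)
  reads <- random_mutant_reads(ref, 25, seed = 9)
  eff <- call_effects(reads, ref, min_mean_q = NULL)
  # re-emit every read with 9 nt of extra matching flank on both sides
  padded <- reads
  for (i in seq_len(nrow(padded))) {
    lead <- substring(ref$sequence, padded$cds_start[i] - 8,
                      padded$cds_start[i])
    tail_ <- substring(ref$sequence, padded$ref_end[i] + 1,
                       padded$ref_end[i] + 9)
    padded$seq[i] <- paste0(lead, padded$seq[i], tail_)
    padded$cds_start[i] <- padded$cds_start[i] - nchar(lead)
    padded$ref_end[i] <- padded$ref_end[i] + nchar(tail_)
    padded$cigar[i] <- sub("^([0-9]+)M",
                           paste0("\\1+", nchar(lead), "M"),
                           padded$cigar[i])
    padded$cigar[i] <- sub("([0-9]+)M$",
                           paste0("\\1+", nchar(tail_), "M"),
                           padded$cigar[i])
    # evaluate the small sums written into the CIGAR
    while (grepl("[0-9]+\\+[0-9]+", padded$cigar[i])) {
      m <- regmatches(padded$cigar[i],
                      regexpr("[0-9]+\\+[0-9]+", padded$cigar[i]))
      padded$cigar[i] <- sub("[0-9]+\\+[0-9]+",
                             sum(as.integer(strsplit(m, "\\+")[[1]])),
                             padded$cigar[i])
    }
    padded$qual[i] <- strrep("I", nchar(padded$seq[i]))
  }
  eff_p <- call_effects(padded, ref, min_mean_q = NULL)
  expect_equal(eff_p$category, eff$category)
  expect_equal(eff_p$residue_start, eff$residue_start)
  expect_equal(eff_p$affected_length, eff$affected_length)
  expect_equal(eff_p$alt_residues, eff$alt_residues)
})

test_that("effect footprints contain their source variants", {
  ref <- random_cds(80, seed = 4)
  reads <- random_mutant_reads(ref, 40, seed = 5)
  eff <- call_effects(reads, ref, min_mean_q = NULL)
  ev <- extract_variants(reads, ref)
  scored <- eff[eff$callable, ]
  for (i in seq_len(nrow(scored))) {
    v <- ev$variants[ev$variants$read_id == scored$read_id[i], ]
    # the codon-extended footprint must cover the protein-level change;
    # nucleotide variants can sit slightly outside after trimming shifts
    # a repeated residue, so check the residue interval is inside the
    # read span instead
    expect_true(scored$footprint_start0[i] >=
                  reads$cds_start[match(scored$read_id[i], reads$read_id)])
    expect_true(scored$footprint_end0[i] <=
                  reads$ref_end[match(scored$read_id[i], reads$read_id)])
    expect_true(nrow(v) >= 1)
  }
})

test_that("window profile downsampled counts honour the threshold", {
  ref <- random_cds(40, seed = 6)
  cut <- 45L
  del3 <- function(id) {
    seq_d <- paste0(substring(ref$sequence, 16, cut),
                    substring(ref$sequence, cut + 4, 75))
    make_fragments(id, 15, "30M3D27M", seq_d)
  }
  sub1 <- function(id) {
    s <- ref$sequence
    old <- substring(s, cut, cut)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    seq_s <- paste0(substring(s, 16, cut - 1), new,
                    substring(s, cut + 1, 75))
    make_fragments(id, 15, "60M", seq_s)
  }
  # wild-type reads only: empty profile
  prof <- mutagenesis_window_profile(wt_pool(ref, 10), ref, cut)
  expect_equal(nrow(prof), 0L)
  # 100 identical in-frame deletions: one signature
  pool <- do.call(rbind, lapply(1:100, function(i) del3(paste0("d", i))))
  prof <- mutagenesis_window_profile(pool, ref, cut, min_count = 5)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$count, 100L)
  expect_true(prof$in_frame)
  # 4 of type A and 6 of type B at min_count 5: only B retained
  pool <- rbind(
    do.call(rbind, lapply(1:4, function(i) del3(paste0("a", i)))),
    do.call(rbind, lapply(1:6, function(i) sub1(paste0("b", i)))))
  prof <- mutagenesis_window_profile(pool, ref, cut, min_count = 5)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$count, 6L)
  # variants outside the +/-20 nt window are ignored
  far <- sub1("far")
  ev <- extract_variants(far, ref)
  prof <- mutagenesis_window_profile(far, ref, cut_site = 100L,
                                     min_count = 1)
  expect_equal(nrow(prof), 0L)
})
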