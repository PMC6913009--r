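# Independent oracles used to cross-check the implementation. These are
# deliberately written with different machinery than the package:
# alignment via Biostrings' affine-gap dynamic programming, translation
# via a plain codon loop, trimming via while loops.

# Count sgRNA windows by direct dinucleotide inspection at PAM positions
# (positions >= 21 of each 23-nt window) on both strands.
oracle_pam_scan <- function(sequence, allowed = c("GG", "AG")) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  count_one <- function(s) {
    n <- 0L
    if (nchar(s) < 23) return(0L)
    for (p in 1:(nchar(s) - 22)) {
      if (substring(s, p + 21, p + 22) %in% allowed) n <- n + 1L
    }
    n
  }
  count_one(sequence) + count_one(revcomp(sequence))
}

# Plain-loop translation (independent of translate / GENETIC_CODE vector
# indexing in the implementation path).
oracle_translate <- function(seq) {
  gc <- Biostrings::GENETIC_CODE
  out <- character(0)
  i <- 1
  while (i + 2 <= nchar(seq)) {
    out <- c(out, gc[[substring(seq, i, i + 2)]])
    i <- i + 3
  }
  paste(out, collapse = "")
}

# While-loop prefix/suffix trim at residue level (prefix first).
oracle_trim <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  p <- 0
  while (p < min(length(av), length(bv)) && av[p + 1] == bv[p + 1]) {
    p <- p + 1
  }
  s <- 0
  while (s < min(length(av), length(bv)) - p &&
         av[length(av) - s] == bv[length(bv) - s]) {
    s <- s + 1
  }
  list(residue_start = p + 1,
       ref_mid = paste(av[seq_len(length(av) - s)][-seq_len(p)],
                       collapse = ""),
       alt_mid = paste(bv[seq_len(length(bv) - s)][-seq_len(p)],
                       collapse = ""))
}

# Full read-level oracle: realign the mutant read to the CDS with an
# affine-gap DP aligner, splice the read into the reference over the
# aligned span, translate both and trim. Returns the effect fields.
oracle_effect <- function(read_seq, ref) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read_seq),
    subject = Biostrings::DNAString(ref$sequence),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 6, gapExtension = 1)
  s <- Biostrings::start(Biostrings::subject(aln))
  e <- Biostrings::end(Biostrings::subject(aln))
  mutant <- paste0(substring(ref$sequence, 1, s - 1), read_seq,
                   substring(ref$sequence, e + 1, nchar(ref$sequence)))
  net <- nchar(mutant) - nchar(ref$sequence)
  if (net %% 3 != 0) {
    return(list(category = "frameshift", residue_start = NA,
                affected_length = NA, alt_residues = NA))
  }
  rp <- oracle_translate(ref$sequence)
  mp <- oracle_translate(mutant)
  rp <- sub("\\*$", "", rp)
  mp <- sub("\\*$", "", mp)
  d <- oracle_trim(rp, mp)
  cat <- if (nchar(d$ref_mid) == 0 && nchar(d$alt_mid) == 0) {
    "silent"
  } else if (grepl("*", d$alt_mid, fixed = TRUE)) {
    "nonsense"
  } else if (nchar(d$alt_mid) == 0) {
    "aa_deletion"
  } else if (net != 0) {
    "combo"
  } else if (d$ref_mid == d$alt_mid) {
    "silent"
  } else {
    "substitution"
  }
  list(category = cat, residue_start = d$residue_start,
       affected_length = nchar(d$ref_mid), alt_residues = d$alt_mid)
}

# Random mutant reads with known alignments for oracle-equivalence
# tests: each read carries one planted variant with generous matching
# flanks, so both the truth CIGAR and the realignment are unambiguous.
random_mutant_reads <- function(ref, n, seed) {
  set.seed(seed)
  L <- ref$length
  bases <- c("A", "C", "G", "T")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    type <- sample(c("del3", "del6", "del9", "ins3", "sub1", "sub2",
                     "del1", "del2", "ins1"), 1)
    pos <- sample(seq(30, L - 45), 1)  # 0-based variant anchor
    if (grepl("^del", type)) {
      len <- as.integer(sub("del", "", type))
      kind <- "deletion"; rl <- len; alt <- ""
    } else if (grepl("^ins", type)) {
      len <- as.integer(sub("ins", "", type))
      kind <- "insertion"; rl <- 0L
      alt <- paste(sample(bases, len, replace = TRUE), collapse = "")
    } else {
      len <- as.integer(sub("sub", "", type))
      kind <- "substitution"; rl <- len
      refslice <- substring(ref$sequence, pos + 1, pos + len)
      repeat {
        alt <- paste(sample(bases, len, replace = TRUE), collapse = "")
        if (alt != refslice) break
      }
    }
    fs <- pos - sample(15:28, 1)            # fragment start, 0-based
    fe <- pos + rl + sample(15:28, 1)       # fragment end on reference
    frag_ref <- substring(ref$sequence, fs + 1, fe)
    read_seq <- splice_seq(frag_ref, kind, pos - fs, rl, alt)
    cigar <- if (kind == "deletion") {
      paste0(pos - fs, "M", rl, "D", fe - pos - rl, "M")
    } else if (kind == "insertion") {
      paste0(pos - fs, "M", nchar(alt), "I", fe - pos, "M")
    } else {
      paste0(fe - fs, "M")
    }
    out[[i]] <- list(read_id = paste0("r", i), cds_start = fs,
                     cigar = cigar, seq = read_seq)
  }
  do.call(rbind, lapply(out, function(x) {
    make_fragments(x$read_id, x$cds_start, x$cigar, x$seq)
  }))
}
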