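# Shared fixtures: hand-built fragment tables and tiny references.

toy_ref <- function() cds_reference("ATGGCTGGTTAA", "toy")

# ATG AAA CCC TAA = M K P *
mkp_ref <- function() cds_reference("ATGAAACCCTAA", "mkp")

# Fragment table row(s) built from explicit alignments; ref_end derived
# from the CIGAR, mean quality from the quality string.
make_fragments <- function(read_id, cds_start, cigar, seq,
                           qual = strrep("I", nchar(seq))) {
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  data.frame(
    read_id = read_id,
    cds_start = as.integer(cds_start),
    ref_end = as.integer(cds_start + width),
    cigar = cigar,
    seq = seq,
    qual = qual,
    mean_q = vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# A fragment that is a faithful copy of the reference over [start, end).
wt_fragment <- function(ref, read_id, start, end) {
  make_fragments(read_id, start, paste0(end - start, "M"),
                 substring(ref$sequence, start + 1, end))
}

# n wild-type fragments tiling the CDS (systematic starts).
wt_pool <- function(ref, n, len = min(60L, ref$length)) {
  starts <- (seq_len(n) - 1L) %% max(ref$length - len + 1L, 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    wt_fragment(ref, paste0("wt", i), starts[i], starts[i] + len)
  }))
}

# Random CDS of given residue count (ATG + non-stop codons + TAA).
random_cds <- function(n_res, seed, gene_id = "rnd") {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  cds_reference(paste(c("ATG", sample(nonstop, n_res - 1, replace = TRUE),
                        "TAA"), collapse = ""), gene_id)
}

# Apply a variant table to a sequence string (independent of the package
# internals: simple cumulative splicing).
splice_seq <- function(sequence, kind, ref_start, ref_length, alt) {
  o <- order(ref_start)
  kind <- kind[o]; ref_start <- ref_start[o]
  ref_length <- ref_length[o]; alt <- alt[o]
  out <- ""
  pos <- 0
  for (i in seq_along(kind)) {
    out <- paste0(out, substring(sequence, pos + 1, ref_start[i]), alt[i])
    pos <- ref_start[i] + ref_length[i]
  }
  paste0(out, substring(sequence, pos + 1, nchar(sequence)))
}
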