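#' Count sgRNA spacers in barcode reads
#'
#' Matches 20-nt spacers exactly (no mismatch tolerance) at a position
#' located either by a fixed offset or by a 5' flanking anchor sequence.
#' Reads where the anchor occurs more than once, or where the extracted
#' 20-mer is not in the library, are left unassigned.
#'
#' @param fastq Path to a FASTQ of barcode reads.
#' @param library Data.frame with a `spacer` column (e.g. from
#'   [design_sgrnas()]); duplicated spacers are collapsed with a warning.
#' @param locate `"fixed_offset"` or `"flank_anchor"`.
#' @param offset 0-based position of the spacer within the read
#'   (fixed-offset mode).
#' @param anchor 5' flanking sequence immediately preceding the spacer
#'   (flank-anchor mode); required there.
#' @return A data.frame `spacer`, `count`, with attributes `unassigned`
#'   and `total`.
#' @export
count_spacers <- function(fastq, library,
                          locate = c("flank_anchor", "fixed_offset"),
                          offset = 0L, anchor = NULL) {
  locate <- match.arg(locate)
  spacers <- unique(library$spacer)
  if (length(spacers) < nrow(library)) {
    warning("duplicated spacers in library collapsed (",
            nrow(library) - length(spacers), ")")
  }
  reads <- as.character(Biostrings::readDNAStringSet(fastq,
                                                     format = "fastq"))
  n <- length(reads)
  if (n == 0L) {
    out <- data.frame(spacer = spacers, count = 0L,
                      stringsAsFactors = FALSE)
    attr(out, "unassigned") <- 0L
    attr(out, "total") <- 0L
    return(out)
  }
  if (locate == "fixed_offset") {
    cand <- substr(reads, offset + 1L, offset + 20L)
  } else {
    if (is.null(anchor) || !nzchar(anchor)) {
      stop("flank_anchor mode requires a non-empty 'anchor'")
    }
    hits <- gregexpr(anchor, reads, fixed = TRUE)
    pos <- vapply(hits, function(h) {
      if (length(h) == 1L && h[1L] > 0L) as.integer(h[1L]) else NA_integer_
    }, integer(1))
    cand <- ifelse(is.na(pos), NA_character_,
                   substr(reads, pos + nchar(anchor),
                          pos + nchar(anchor) + 19L))
  }
  m <- match(cand, spacers)
  counts <- tabulate(m, nbins = length(spacers))
  out <- data.frame(spacer = spacers, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "unassigned") <- sum(is.na(m))
  attr(out, "total") <- n
  out
}

#' Per-sgRNA normalized log2 fold change between conditions
#'
#' `log2fc = log2((count_after + 1) / total_after) -
#'  log2((count_before + 1) / total_before)` with totals taken over
#' assigned reads.
#'
#' @param before,after Count tables from [count_spacers()] over the same
#'   library.
#' @return A data.frame `spacer`, `count_before`, `count_after`, `log2fc`.
#' @export
sgrna_log2fc <- function(before, after) {
  stopifnot(identical(sort(before$spacer), sort(after$spacer)))
  a <- after$count[match(before$spacer, after$spacer)]
  tot_b <- max(sum(before$count), 1L)
  tot_a <- max(sum(a), 1L)
  data.frame(
    spacer = before$spacer,
    count_before = before$count,
    count_after = a,
    log2fc = log2((a + 1) / tot_a) - log2((before$count + 1) / tot_b),
    stringsAsFactors = FALSE
  )
}

#' Map sgRNA fold changes onto residues
#'
#' Assigns each sgRNA's log2 fold change to the residue containing its cut
#' site; residues targeted by several sgRNAs take the mean, untargeted
#' residues are `NA`.
#'
#' @param fc_table Output of [sgrna_log2fc()].
#' @param sgrnas sgRNA design table with `spacer` and `residue` columns.
#' @param protein_length Number of residues.
#' @return Numeric vector of length `protein_length`.
#' @export
sgrna_profile <- function(fc_table, sgrnas, protein_length) {
  res <- sgrnas$residue[match(fc_table$spacer, sgrnas$spacer)]
  ok <- !is.na(res) & res >= 1L & res <= protein_length
  track <- rep(NA_real_, protein_length)
  if (any(ok)) {
    agg <- tapply(fc_table$log2fc[ok], res[ok], mean)
    track[as.integer(names(agg))] <- as.numeric(agg)
  }
  track
}

#' Pearson correlation of replicate sgRNA fold changes
#'
#' @param table_rep1,table_rep2 Fold-change tables from [sgrna_log2fc()].
#' @return Pearson r over sgRNAs present in both tables.
#' @export
replicate_correlation <- function(table_rep1, table_rep2) {
  shared <- intersect(table_rep1$spacer, table_rep2$spacer)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared sgRNAs between replicates")
  }
  stats::cor(table_rep1$log2fc[match(shared, table_rep1$spacer)],
             table_rep2$log2fc[match(shared, table_rep2$spacer)])
}
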