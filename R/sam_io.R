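#' Read aligned cDNA fragments from SAM/BAM
#'
#' Loads primary alignments against the target CDS into the package's
#' fragment table. SAM input is converted to BAM on the fly with
#' [Rsamtools::asBam()]. Unmapped, secondary and supplementary records are
#' skipped and counted, as are records whose CIGAR contains an operation
#' outside M/=/X/I/D/S.
#'
#' @param path SAM or BAM file; the reference name must match
#'   `ref$gene_id` (or `rname_map` must translate it).
#' @param ref A [cds_reference()].
#' @param offset Integer added to alignment positions, for reads aligned to
#'   an amplicon sub-reference rather than the full CDS.
#' @param rname_map Optional named character vector mapping SAM reference
#'   names to `gene_id`.
#' @return A `data.frame` of fragments with columns `read_id`, `cds_start`
#'   (0-based), `ref_end` (0-based exclusive), `cigar`, `seq`, `qual`,
#'   `mean_q`, and an attribute `skipped` (named counts of dropped records).
#' @export
read_alignments <- function(path, ref, offset = 0L, rname_map = NULL) {
  stopifnot(inherits(ref, "cds_reference"))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- suppressMessages(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE))
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual")))[[1L]]
  n <- length(res$qname)
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  keep <- !(unmapped | secondary | supplementary)
  rname <- as.character(res$rname)
  if (!is.null(rname_map)) {
    mapped <- rname_map[rname]
    rname <- ifelse(is.na(mapped), rname, mapped)
  }
  bad_ref <- keep & rname != ref$gene_id
  if (any(bad_ref, na.rm = TRUE)) {
    stop("alignments reference '",
         paste(unique(rname[which(bad_ref)]), collapse = "', '"),
         "' but the loaded CDS is '", ref$gene_id, "'")
  }
  cigar <- res$cigar
  bad_op <- keep & grepl("[^0-9MIDS=X]", cigar)
  keep <- keep & !bad_op
  idx <- which(keep)
  cds_start <- res$pos[idx] - 1L + as.integer(offset)
  cig <- cigar[idx]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  qual <- as.character(res$qual)[idx]
  frags <- data.frame(
    read_id = res$qname[idx],
    cds_start = cds_start,
    ref_end = cds_start + width,
    cigar = cig,
    seq = as.character(res$seq)[idx],
    qual = qual,
    mean_q = mean_phred(qual),
    stringsAsFactors = FALSE
  )
  if (any(frags$ref_end > ref$length)) {
    stop("alignment extends past the CDS end (", ref$length, " nt)")
  }
  attr(frags, "skipped") <- c(
    unmapped = sum(unmapped), secondary = sum(secondary),
    supplementary = sum(supplementary), bad_cigar_op = sum(bad_op)
  )
  frags
}

## Mean Phred score per quality string; NA for missing ("*" or empty).
mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || q == "*" || nchar(q) == 0L) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

min_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || q == "*" || nchar(q) == 0L) return(NA_real_)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter fragments on base quality
#'
#' Keeps fragments whose mean (default) or minimum base quality is at least
#' `min_q`. Fragments without quality strings pass with a warning by
#' default, mirroring aligners that emit `*`.
#'
#' @param fragments Fragment table from [read_alignments()].
#' @param min_q Phred threshold (default 30).
#' @param mode `"mean"` (drop iff mean quality < `min_q`) or `"min"`
#'   (drop iff any base < `min_q`).
#' @param missing_qual `"pass"` or `"drop"` for fragments lacking qualities.
#' @return Filtered fragment table; attribute `n_dropped_quality` records
#'   the number removed.
#' @export
quality_filter <- function(fragments, min_q = 30,
                           mode = c("mean", "min"),
                           missing_qual = c("pass", "drop")) {
  mode <- match.arg(mode)
  missing_qual <- match.arg(missing_qual)
  q <- if (mode == "mean") fragments$mean_q else min_phred(fragments$qual)
  miss <- is.na(q)
  if (any(miss) && missing_qual == "pass") {
    warning(sum(miss), " fragment(s) lack base qualities; kept")
  }
  keep <- ifelse(miss, missing_qual == "pass", q >= min_q)
  out <- fragments[keep, , drop = FALSE]
  attr(out, "n_dropped_quality") <- sum(!keep)
  attr(out, "skipped") <- attr(fragments, "skipped")
  out
}

#' Write a fragment table as SAM
#'
#' Emits single-end primary alignments with the fragment's position and
#' CIGAR against the CDS reference, suitable for re-reading with
#' [read_alignments()].
#'
#' @param fragments Fragment table (`read_id`, `cds_start`, `cigar`, `seq`,
#'   `qual`).
#' @param ref The `cds_reference` the fragments are aligned to.
#' @param path Output SAM path.
#' @export
write_sam <- function(fragments, ref, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref$gene_id, "\tLN:", ref$length))
  qual <- fragments$qual
  qual[is.na(qual) | qual == ""] <- "*"
  body <- paste(fragments$read_id, 0L, ref$gene_id,
                fragments$cds_start + 1L, 60L, fragments$cigar,
                "*", 0L, 0L, fragments$seq, qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write reads as FASTQ
#' @param ids,seqs,quals Character vectors of equal length.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}
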