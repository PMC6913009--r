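#' Coding-sequence reference with codon/residue coordinate mapping
#'
#' Validates a coding sequence and precomputes its translation. The sequence
#' must be an uppercase ACGT string whose length is a multiple of 3, with no
#' internal stop codon. A terminal stop codon is allowed and excluded from
#' `protein_length`.
#'
#' Coordinates are 0-based half-open at the nucleotide level throughout the
#' package; residues are numbered 1-based in all outputs.
#'
#' @param sequence Character scalar, the CDS from start codon onward.
#' @param gene_id Identifier used in outputs and as the SAM reference name.
#' @return An object of class `cds_reference`: a list with elements
#'   `gene_id`, `sequence`, `length`, `protein` (translation without the
#'   terminal stop) and `protein_length`.
#' @examples
#' ref <- cds_reference("ATGGCTGGTTAA", "toy")
#' ref$protein_length  # 3
#' @export
cds_reference <- function(sequence, gene_id = "gene") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0L) {
    stop("non-ACGT character '", substr(sequence, bad, bad),
         "' at position ", bad, " of CDS '", gene_id, "'")
  }
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length (", n, ") is not a positive multiple of 3 for '",
         gene_id, "'")
  }
  prot <- translate_nt(sequence)
  stops <- which(strsplit(prot, "")[[1]] == "*")
  if (any(stops < nchar(prot))) {
    stop("internal stop at codon ", stops[stops < nchar(prot)][1L],
         " of CDS '", gene_id, "'")
  }
  protein <- sub("\\*$", "", prot)
  structure(
    list(gene_id = gene_id, sequence = sequence, length = n,
         protein = protein, protein_length = nchar(protein)),
    class = "cds_reference"
  )
}

#' @export
print.cds_reference <- function(x, ...) {
  cat("cds_reference '", x$gene_id, "': ", x$length, " nt, ",
      x$protein_length, " residues\n", sep = "")
  invisible(x)
}

#' Load a CDS reference from a FASTA file
#'
#' Reads the first record (or the record named `gene_id`) and validates it
#' with [cds_reference()].
#'
#' @param fasta_path Path to a FASTA file with at least one record.
#' @param gene_id Optional record name to select; defaults to the first
#'   record. The record name (first word of the header) becomes the
#'   reference's `gene_id`.
#' @return A `cds_reference`.
#' @export
load_cds <- function(fasta_path, gene_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("no FASTA records in ", fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(gene_id)) {
    idx <- 1L
  } else {
    idx <- match(gene_id, ids)
    if (is.na(idx)) {
      stop("record '", gene_id, "' not found in ", fasta_path,
           "; available: ", paste(ids, collapse = ", "))
    }
  }
  cds_reference(as.character(seqs[[idx]]), ids[idx])
}

## Translate an in-frame nucleotide string using the standard genetic code.
## Incomplete trailing bases (< 3 nt) are ignored.
translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  i <- seq_len(n)
  codons <- substring(seq, 3L * i - 2L, 3L * i)
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Map a 0-based CDS nucleotide position to its 1-based residue index
#' @param pos0 Integer vector of 0-based nucleotide positions.
#' @return Integer vector of 1-based residue indices.
#' @export
nt_to_residue <- function(pos0) as.integer(pos0 %/% 3L + 1L)

#' Nucleotide range of a residue
#'
#' @param residue Integer vector of 1-based residue indices.
#' @return A matrix with columns `start0` and `end0` giving the 0-based
#'   half-open nucleotide interval of each codon.
#' @export
residue_to_nt_range <- function(residue) {
  residue <- as.integer(residue)
  cbind(start0 = (residue - 1L) * 3L, end0 = residue * 3L)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Enumerate tiling sgRNAs over a CDS
#'
#' Scans both strands of the coding sequence for every 23-nt window whose
#' final 3 nt match one of the allowed PAMs (default NGG and NAG). The cut
#' site follows the blunt-cut convention 3 bp 5' of the PAM (between spacer
#' positions 17 and 18) and is reported as the 0-based CDS coordinate of the
#' first base 3' of the cut on the plus strand; minus-strand cut sites are
#' mirrored into plus-strand coordinates.
#'
#' Only windows fully inside the CDS are considered; spacers occurring at
#' more than one position are retained and flagged via `duplicate_spacer`.
#'
#' @param ref A `cds_reference`.
#' @param pams Character vector of allowed PAMs among `"NGG"` and `"NAG"`.
#' @return A data.frame with columns `gene_id`, `spacer`, `pam`, `strand`,
#'   `cut_site` (0-based CDS coordinate), `residue` (1-based residue
#'   containing the cut site) and `duplicate_spacer`.
#' @export
design_sgrnas <- function(ref, pams = c("NGG", "NAG")) {
  stopifnot(inherits(ref, "cds_reference"))
  pams <- match.arg(pams, c("NGG", "NAG"), several.ok = TRUE)
  allowed <- sub("^N", "", pams)
  L <- ref$length
  if (L < 23L) {
    warning("CDS shorter than 23 nt; no sgRNAs can be designed")
    return(empty_sgrna_table())
  }
  scan_one <- function(seq) {
    p <- 0:(nchar(seq) - 23L)
    pam <- substring(seq, p + 21L, p + 23L)
    keep <- substring(pam, 2L, 3L) %in% allowed
    data.frame(pos = p[keep],
               spacer = substring(seq, p + 1L, p + 20L)[keep],
               pam = pam[keep], stringsAsFactors = FALSE)
  }
  fwd <- scan_one(ref$sequence)
  rev <- scan_one(reverse_complement(ref$sequence))
  res <- rbind(
    if (nrow(fwd)) data.frame(fwd, strand = "+", cut_site = fwd$pos + 17L),
    if (nrow(rev)) data.frame(rev, strand = "-", cut_site = L - (rev$pos + 17L))
  )
  if (is.null(res) || nrow(res) == 0L) return(empty_sgrna_table())
  res <- res[order(res$cut_site, res$strand), , drop = FALSE]
  out <- data.frame(
    gene_id = ref$gene_id,
    spacer = res$spacer,
    pam = res$pam,
    strand = res$strand,
    cut_site = as.integer(res$cut_site),
    residue = pmin(nt_to_residue(pmin(res$cut_site, L - 1L)),
                   ref$protein_length),
    duplicate_spacer = res$spacer %in% res$spacer[duplicated(res$spacer)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_sgrna_table <- function() {
  data.frame(gene_id = character(), spacer = character(), pam = character(),
             strand = character(), cut_site = integer(), residue = integer(),
             duplicate_spacer = logical(), stringsAsFactors = FALSE)
}

#' Write an sgRNA library table as TSV
#' @param sgrnas Data.frame from [design_sgrnas()].
#' @param path Output file.
#' @export
write_sgrna_library <- function(sgrnas, path) {
  utils::write.table(sgrnas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
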