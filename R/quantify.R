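#' Count reads fully covering a reference interval
#'
#' A fragment counts only if its aligned reference span contains the whole
#' interval; partial overlaps are excluded, since they cannot establish the
#' presence or absence of an event spanning the interval.
#'
#' @param fragments Fragment table.
#' @param start0,end0 0-based half-open CDS interval.
#' @return Integer count.
#' @export
covering_reads <- function(fragments, start0, end0) {
  if (end0 <= start0) stop("empty region [", start0, ",", end0, ")")
  sum(fragments$cds_start <= start0 & fragments$ref_end >= end0)
}

## 2-D coverage index: C[a, b] (a <= b) = number of fragments whose
## aligned span fully contains residues a..b. Built in O(n + L^2) from
## each fragment's fully-covered codon range.
coverage_index <- function(fragments, protein_length) {
  pl <- protein_length
  rlo <- (fragments$cds_start + 2L) %/% 3L + 1L   # first full codon
  rhi <- fragments$ref_end %/% 3L                 # last full codon
  ok <- rlo <= rhi & rlo <= pl & rhi >= 1L
  rlo <- pmax(rlo[ok], 1L)
  rhi <- pmin(rhi[ok], pl)
  M <- matrix(tabulate((rhi - 1L) * pl + rlo, pl * pl), pl, pl)
  M <- apply(M, 2L, cumsum)                       # rlo <= a
  t(apply(M, 1L, function(x) rev(cumsum(rev(x))))) # rhi >= b
}

## Vector of covering-read counts for every residue 1..protein_length.
residue_coverage <- function(fragments, protein_length) {
  C <- coverage_index(fragments, protein_length)
  as.integer(diag(C))
}

#' Per-effect-type frequencies with coverage denominators
#'
#' For every retained effect key (an identical amino-acid-level event), the
#' frequency is the number of supporting reads divided by the number of
#' reads fully covering that key's codon-extended nucleotide footprint.
#' Keys with fewer than `min_count` supporting reads are dropped.
#'
#' @param effects Per-read effect table from [call_effects()].
#' @param fragments Fragment table the effects were called from (defaults
#'   to the table attached to `effects`).
#' @param categories Effect categories to tabulate.
#' @param min_count Minimum supporting reads per key (default 9).
#' @return A data.frame `key`, `category`, `residue_start`,
#'   `affected_length`, `alt_residues`, `read_count`, `covering_reads`,
#'   `frequency`.
#' @export
effect_frequencies <- function(effects, fragments = attr(effects, "fragments"),
                               categories = c("aa_deletion", "combo"),
                               min_count = 9L) {
  sel <- effects$callable & effects$category %in% categories
  e <- effects[sel, , drop = FALSE]
  if (nrow(e) == 0L) return(empty_effect_table())
  counts <- table(e$key)
  counts <- counts[counts >= min_count]
  if (length(counts) == 0L) return(empty_effect_table())
  first <- e[match(names(counts), e$key), , drop = FALSE]
  pl <- max(first$residue_start + pmax(first$affected_length, 1L)) - 1L
  C <- coverage_index(fragments, pl)
  cov <- C[cbind(first$footprint_start0 %/% 3L + 1L,
                 first$footprint_end0 %/% 3L)]
  out <- data.frame(
    key = names(counts),
    category = first$category,
    residue_start = first$residue_start,
    affected_length = first$affected_length,
    alt_residues = first$alt_residues,
    read_count = as.integer(counts),
    covering_reads = as.integer(cov),
    stringsAsFactors = FALSE
  )
  if (any(out$covering_reads == 0L)) {
    warning("dropping ", sum(out$covering_reads == 0L),
            " key(s) with zero covering reads")
    out <- out[out$covering_reads > 0L, , drop = FALSE]
  }
  out$frequency <- out$read_count / out$covering_reads
  out <- out[order(out$residue_start, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_effect_table <- function() {
  data.frame(key = character(), category = character(),
             residue_start = integer(), affected_length = integer(),
             alt_residues = character(), read_count = integer(),
             covering_reads = integer(), frequency = numeric(),
             stringsAsFactors = FALSE)
}

#' Per-residue substitution frequency
#'
#' For residue i the numerator is the number of reads whose substitution
#' effect changes residue i (a multi-residue substitution contributes once
#' to every residue it changes), and the denominator is the number of
#' reads fully covering codon i. Residues with zero coverage are reported
#' as `NA`, never as 0, so downstream statistics skip them. Substitution
#' keys below `min_count` supporting reads are removed first.
#'
#' @param effects Per-read effect table.
#' @param fragments Fragment table (defaults to the attached one).
#' @param ref A `cds_reference`.
#' @param min_count Minimum reads per substitution key (default 9).
#' @return A data.frame `residue`, `ref_aa`, `n_reads`, `covering_reads`,
#'   `freq_sub`.
#' @export
substitution_frequency <- function(effects,
                                   fragments = attr(effects, "fragments"),
                                   ref, min_count = 9L) {
  pl <- ref$protein_length
  cov <- residue_coverage(fragments, pl)
  n_sub <- integer(pl)
  sel <- effects$callable & effects$category == "substitution"
  e <- effects[sel, , drop = FALSE]
  if (nrow(e)) {
    counts <- table(e$key)
    keep_keys <- names(counts)[counts >= min_count]
    e <- e[e$key %in% keep_keys, , drop = FALSE]
  }
  if (nrow(e)) {
    uk <- e[match(unique(e$key), e$key), , drop = FALSE]
    kc <- table(e$key)
    prot <- strsplit(ref$protein, "")[[1L]]
    for (i in seq_len(nrow(uk))) {
      rs <- uk$residue_start[i]
      alt <- strsplit(uk$alt_residues[i], "")[[1L]]
      res <- rs + seq_along(alt) - 1L
      changed <- res[alt != prot[res]]
      n_sub[changed] <- n_sub[changed] + as.integer(kc[[uk$key[i]]])
    }
  }
  data.frame(
    residue = seq_len(pl),
    ref_aa = strsplit(ref$protein, "")[[1L]],
    n_reads = n_sub,
    covering_reads = cov,
    freq_sub = ifelse(cov > 0L, n_sub / cov, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Fraction of residues covered by retained deletion/combo keys
#'
#' A residue counts as covered when at least one retained `aa_deletion` or
#' `combo` key with `affected_length <= max_affected` (and >= 1) spans it.
#'
#' @param effect_table Output of [effect_frequencies()] on the
#'   before-selection library.
#' @param protein_length Number of residues.
#' @param max_affected Maximum affected length counted (default 3).
#' @return A list with `fraction` and the per-residue logical `covered`.
#' @export
aa_coverage <- function(effect_table, protein_length, max_affected = 3L) {
  covered <- logical(protein_length)
  t <- effect_table[effect_table$category %in% c("aa_deletion", "combo") &
                      effect_table$affected_length >= 1L &
                      effect_table$affected_length <= max_affected, ,
                    drop = FALSE]
  for (i in seq_len(nrow(t))) {
    span <- t$residue_start[i]:(t$residue_start[i] + t$affected_length[i] - 1L)
    covered[span[span <= protein_length]] <- TRUE
  }
  list(fraction = mean(covered), covered = covered)
}

#' Substitution pattern matrix for selected residues
#'
#' Counts supporting reads per alternative amino acid for each listed
#' residue; substitutions identical to the reference residue are excluded
#' by construction of the effect call.
#'
#' @param effects Per-read effect table (typically after selection).
#' @param residues 1-based residue indices (matrix rows).
#' @param ref A `cds_reference`.
#' @return An integer matrix `length(residues)` x 20 with amino-acid
#'   columns and `"<ref_aa><residue>"` row names.
#' @export
substitution_pattern <- function(effects, residues, ref) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  prot <- strsplit(ref$protein, "")[[1L]]
  mat <- matrix(0L, nrow = length(residues), ncol = length(aas),
                dimnames = list(paste0(prot[residues], residues), aas))
  e <- effects[effects$callable & effects$category == "substitution", ,
               drop = FALSE]
  for (i in seq_len(nrow(e))) {
    alt <- strsplit(e$alt_residues[i], "")[[1L]]
    res <- e$residue_start[i] + seq_along(alt) - 1L
    for (j in seq_along(res)) {
      r <- match(res[j], residues)
      if (!is.na(r) && alt[j] != prot[res[j]] && alt[j] %in% aas) {
        mat[r, alt[j]] <- mat[r, alt[j]] + 1L
      }
    }
  }
  mat
}

#' Retained effect keys under read subsampling
#'
#' Subsamples the read pool without replacement at each depth (seeded) and
#' reports how many deletion and combo keys remain above `min_count`,
#' emulating a depth-saturation analysis.
#'
#' @param effects Per-read effect table over the full pool (all reads,
#'   including wild type, define the sampling frame).
#' @param depths Integer vector of subsample sizes (<= number of reads).
#' @param seed Seed for subsampling.
#' @param min_count Minimum reads per key (default 9).
#' @param n_rep Subsamples per depth (default 1).
#' @return A data.frame `depth`, `rep`, `n_deletion_keys`, `n_combo_keys`.
#' @export
depth_saturation <- function(effects, depths, seed = 1L, min_count = 9L,
                             n_rep = 1L) {
  n <- nrow(effects)
  if (any(depths > n)) stop("depth exceeds available reads (", n, ")")
  set.seed(seed)
  grid <- expand.grid(rep = seq_len(n_rep), depth = depths)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    d <- grid$depth[g]
    idx <- if (d == n) seq_len(n) else sample.int(n, d)
    e <- effects[idx, , drop = FALSE]
    e <- e[e$callable & e$category %in% c("aa_deletion", "combo"), ,
           drop = FALSE]
    counts <- table(e$key)
    counts <- counts[counts >= min_count]
    cats <- e$category[match(names(counts), e$key)]
    data.frame(depth = d, rep = grid$rep[g],
               n_deletion_keys = sum(cats == "aa_deletion"),
               n_combo_keys = sum(cats == "combo"))
  })
  do.call(rbind, res)
}

#' Raw per-base substitution rate of a fragment pool
#'
#' Substituted bases divided by aligned (M/=/X) bases, before any
#' count-based filtering; used to characterise sequencing/PCR error
#' background in mock libraries.
#'
#' @param fragments Fragment table.
#' @param ref A `cds_reference`.
#' @return A list with `rate`, `n_sub_bases` and `n_aligned_bases`.
#' @export
per_base_substitution_rate <- function(fragments, ref) {
  ev <- extract_variants(fragments, ref)
  v <- ev$variants
  n_sub <- if (nrow(v)) sum(v$ref_length[v$kind == "substitution"]) else 0L
  aligned <- sum(fragments$ref_end - fragments$cds_start) -
    (if (nrow(v)) sum(v$ref_length[v$kind == "deletion"]) else 0L)
  list(rate = n_sub / aligned, n_sub_bases = n_sub,
       n_aligned_bases = aligned)
}
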