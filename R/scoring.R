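#' Fold changes of effect keys between selection conditions
#'
#' Keys retained in the before-selection table get
#' `fc = frequency_after / frequency_before`; keys absent from the
#' after table are kept with `fc = 0` (depleted). Keys that appear only
#' after selection have no valid denominator and are excluded (recorded in
#' the `excluded_keys` attribute).
#'
#' @param before,after Effect tables from [effect_frequencies()] for the
#'   same gene and categories.
#' @return A data.frame `key`, `category`, `residue_start`,
#'   `affected_length`, `fc`, `freq_before`, `freq_after`.
#' @export
fold_changes <- function(before, after) {
  after_freq <- after$frequency[match(before$key, after$key)]
  after_freq[is.na(after_freq)] <- 0
  out <- data.frame(
    key = before$key,
    category = before$category,
    residue_start = before$residue_start,
    affected_length = before$affected_length,
    fc = after_freq / before$frequency,
    freq_before = before$frequency,
    freq_after = after_freq,
    stringsAsFactors = FALSE
  )
  attr(out, "excluded_keys") <- setdiff(after$key, before$key)
  out
}

## Shared residue-level aggregation: each key contributes fc / len^2 to
## every residue in its span; optionally single-residue keys contribute
## w * fc instead (the deletion rule).
aggregate_fc <- function(fcs, protein_length, w = NULL, max_affected = 3L) {
  out <- numeric(protein_length)
  if (nrow(fcs) == 0L) return(out)
  fcs <- fcs[pmax(fcs$affected_length, 1L) <= max_affected, , drop = FALSE]
  for (i in seq_len(nrow(fcs))) {
    len <- max(fcs$affected_length[i], 1L)
    span <- fcs$residue_start[i]:(fcs$residue_start[i] + len - 1L)
    span <- span[span >= 1L & span <= protein_length]
    contrib <- if (!is.null(w) && fcs$affected_length[i] == 1L) {
      w * fcs$fc[i]
    } else {
      fcs$fc[i] / len^2
    }
    out[span] <- out[span] + contrib
  }
  out
}

#' Aggregate deletion fold changes per residue
#'
#' Single-residue deletion keys contribute `w * fc` to their residue
#' (default full weight, w = 1); multi-residue keys contribute
#' `fc / affected_length^2` to every residue they span. Keys affecting
#' more than `max_affected` residues are skipped.
#'
#' @param fcs Fold-change table restricted to `aa_deletion` keys (other
#'   categories are ignored).
#' @param protein_length Number of residues.
#' @param w Weight for single-residue deletions (default 1).
#' @param max_affected Maximum affected length (default 3).
#' @return Numeric vector of per-residue aggregated deletion fold change.
#' @export
aggregate_deletion_fc <- function(fcs, protein_length, w = 1,
                                  max_affected = 3L) {
  fcs <- fcs[fcs$category == "aa_deletion", , drop = FALSE]
  aggregate_fc(fcs, protein_length, w = w, max_affected = max_affected)
}

#' Aggregate combo-mutation fold changes per residue
#'
#' Every combo key contributes `fc / affected_length^2` to each residue it
#' spans (single-residue combo keys included; pure insertions with
#' `affected_length` 0 are treated as length 1).
#'
#' @inheritParams aggregate_deletion_fc
#' @return Numeric vector of per-residue aggregated combo fold change.
#' @export
aggregate_combo_fc <- function(fcs, protein_length, max_affected = 3L) {
  fcs <- fcs[fcs$category == "combo", , drop = FALSE]
  aggregate_fc(fcs, protein_length, w = NULL, max_affected = max_affected)
}

#' Qualitative substitution cutoff and scores
#'
#' The cutoff is `mean + 3 * SD` of `log10` substitution frequencies over
#' residues with positive frequency (sample SD, n-1). A residue scores 2
#' when its `log10` frequency strictly exceeds the cutoff, else 0; missing
#' or zero frequencies score 0.
#'
#' @param freq_sub Numeric vector of per-residue substitution frequencies
#'   (NA for uncovered residues).
#' @param k_sd Number of SDs above the mean (default 3).
#' @return A list with `cutoff` (on the log10 scale) and the integer
#'   vector `sf_score`.
#' @export
substitution_cutoff <- function(freq_sub, k_sd = 3) {
  sf <- integer(length(freq_sub))
  pos <- which(!is.na(freq_sub) & freq_sub > 0)
  if (length(pos) < 2L) {
    warning("fewer than 2 positive substitution frequencies; ",
            "all sf_score set to 0")
    return(list(cutoff = NA_real_, sf_score = sf))
  }
  lf <- log10(freq_sub[pos])
  cutoff <- mean(lf) + k_sd * stats::sd(lf)
  sf[pos[lf > cutoff]] <- 2L
  list(cutoff = cutoff, sf_score = sf)
}

#' Per-residue essential scores
#'
#' Sums the aggregated deletion and combo fold changes per residue,
#' z-scores `log10` of the sum over residues with a positive sum, converts
#' the z to an upper-tail standard-normal probability, and adds the
#' qualitative substitution score:
#' `essential_score = -log10(p) + sf_score`. Residues with zero aggregate
#' get a quantitative part of 0 and `p = NA`. Ranks are assigned by
#' descending score, ties broken by residue index.
#'
#' @param dfc_aa,cmfc_aa Numeric vectors from [aggregate_deletion_fc()]
#'   and [aggregate_combo_fc()].
#' @param sf_score Integer vector from [substitution_cutoff()].
#' @param freq_sub Optional per-residue substitution frequencies, carried
#'   into the output.
#' @param ref Optional `cds_reference` supplying `ref_aa`.
#' @return A data.frame `residue`, `ref_aa`, `dfc_aa`, `cmfc_aa`,
#'   `freq_sub`, `sf_score`, `z`, `p`, `essential_score`, `rank`.
#' @export
essential_scores <- function(dfc_aa, cmfc_aa, sf_score,
                             freq_sub = NULL, ref = NULL) {
  n <- length(dfc_aa)
  stopifnot(length(cmfc_aa) == n, length(sf_score) == n)
  s <- dfc_aa + cmfc_aa
  z <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  quant <- numeric(n)
  pos <- which(s > 0)
  if (length(pos)) {
    ls <- log10(s[pos])
    sdev <- stats::sd(ls)
    if (length(pos) < 2L || is.na(sdev) || sdev == 0) {
      warning("degenerate aggregate fold changes; all z set to 0")
      z[pos] <- 0
    } else {
      z[pos] <- (ls - mean(ls)) / sdev
    }
    p[pos] <- stats::pnorm(z[pos], lower.tail = FALSE)
    quant[pos] <- -log10(p[pos])
  }
  score <- quant + sf_score
  out <- data.frame(
    residue = seq_len(n),
    ref_aa = if (!is.null(ref)) strsplit(ref$protein, "")[[1L]][seq_len(n)]
             else NA_character_,
    dfc_aa = dfc_aa, cmfc_aa = cmfc_aa,
    freq_sub = if (!is.null(freq_sub)) freq_sub else NA_real_,
    sf_score = as.integer(sf_score),
    z = z, p = p,
    essential_score = score,
    stringsAsFactors = FALSE
  )
  out$rank <- integer(n)
  out$rank[order(-out$essential_score, out$residue)] <- seq_len(n)
  out
}

#' Essential-score cutoff and hit list
#'
#' Cutoff is `mean + k_sd * SD` of the essential scores; hits are residues
#' strictly above it (ties at the cutoff are non-hits).
#'
#' @param scores Per-residue score table from [essential_scores()], or a
#'   numeric vector of scores.
#' @param k_sd Number of SDs (default 3).
#' @return A list with `cutoff` and integer vector `hits` (residues).
#' @export
score_cutoff <- function(scores, k_sd = 3) {
  v <- if (is.data.frame(scores)) scores$essential_score else scores
  if (length(v) < 2L) stop("need at least 2 scored residues")
  cutoff <- mean(v) + k_sd * stats::sd(v)
  list(cutoff = cutoff, hits = which(v > cutoff))
}

#' Score a screen from per-read effects of two conditions
#'
#' Convenience driver: computes deletion/combo frequencies before and
#' after selection, their fold changes, per-residue aggregation, the
#' substitution cutoff on the after library, essential scores and the
#' score cutoff.
#'
#' @param effects_before,effects_after Per-read effect tables from
#'   [call_effects()] (with attached fragment tables).
#' @param ref A `cds_reference`.
#' @param min_count Minimum reads per key (default 9).
#' @param max_affected Maximum affected residues per key (default 3).
#' @param w Single-residue deletion weight (default 1).
#' @param k_sd SD multiplier for the essential-score cutoff (default 3).
#' @return A list: `scores` (per-residue table with `above_cutoff`),
#'   `cutoff`, `fold_changes`, `table_before`, `table_after`,
#'   `freq_sub`, `sub_cutoff`.
#' @export
score_screen <- function(effects_before, effects_after, ref,
                         min_count = 9L, max_affected = 3L, w = 1,
                         k_sd = 3) {
  tb <- effect_frequencies(effects_before, min_count = min_count)
  ta <- effect_frequencies(effects_after, min_count = min_count)
  fcs <- fold_changes(tb, ta)
  dfc_aa <- aggregate_deletion_fc(fcs, ref$protein_length, w = w,
                                  max_affected = max_affected)
  cmfc_aa <- aggregate_combo_fc(fcs, ref$protein_length,
                                max_affected = max_affected)
  fs <- substitution_frequency(effects_after, ref = ref,
                               min_count = min_count)
  sub <- suppressWarnings(substitution_cutoff(fs$freq_sub))
  sc <- essential_scores(dfc_aa, cmfc_aa, sub$sf_score,
                         freq_sub = fs$freq_sub, ref = ref)
  cut <- score_cutoff(sc, k_sd = k_sd)
  sc$above_cutoff <- sc$residue %in% cut$hits
  list(scores = sc, cutoff = cut$cutoff, fold_changes = fcs,
       table_before = tb, table_after = ta, freq_sub = fs,
       sub_cutoff = sub$cutoff)
}

#' Average replicate score tables into one ranking
#'
#' Per-residue essential scores are averaged across replicates and ranks
#' recomputed; `pooled` mode instead expects the caller to pool reads
#' upstream, so only `average` is implemented here.
#'
#' @param score_tables List of per-residue score tables from
#'   [essential_scores()] over the same protein.
#' @return A combined score table with recomputed ranks.
#' @export
combine_replicate_scores <- function(score_tables) {
  stopifnot(length(score_tables) >= 1L)
  n <- nrow(score_tables[[1L]])
  score <- rowMeans(vapply(score_tables, `[[`, numeric(n),
                           "essential_score"))
  out <- score_tables[[1L]]
  out$essential_score <- score
  out$rank[order(-out$essential_score, out$residue)] <- seq_len(n)
  out
}
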