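#' Extract nucleotide variants from aligned fragments
#'
#' Walks each fragment's CIGAR against the CDS. Matched blocks (M/=/X) are
#' compared base-by-base and maximal runs of consecutive mismatches are
#' merged into a single substitution variant; I and D operations yield
#' insertion and deletion variants. Soft-clipped bases are ignored.
#'
#' Fragments whose aligned sequence equals the reference slice are
#' short-circuited without a per-base walk, which keeps large wild-type
#' dominated pools fast.
#'
#' @param fragments Fragment table from [read_alignments()].
#' @param ref A `cds_reference`.
#' @return A list with `variants` (data.frame `read_id`, `kind`,
#'   `ref_start` 0-based, `ref_length`, `alt`) and `per_read` (data.frame
#'   `read_id`, `n_variants`, `n_indel`, `net_nt`, `frame_class`).
#' @export
extract_variants <- function(fragments, ref) {
  stopifnot(inherits(ref, "cds_reference"))
  n <- nrow(fragments)
  if (n == 0L) {
    return(list(variants = empty_variant_table(),
                per_read = empty_per_read_table()))
  }
  if (any(grepl("[^0-9MIDS=X]", fragments$cigar))) {
    stop("unsupported CIGAR operation (allowed: M, =, X, I, D, S)")
  }
  ref_slice <- substring(ref$sequence, fragments$cds_start + 1L,
                         fragments$ref_end)

  ## Fast path: single-block nM alignments (the bulk of any real pool)
  ## need no CIGAR decomposition; identical ones need no walk at all.
  pure_m <- grepl("^[0-9]+M$", fragments$cigar)
  clean <- pure_m & fragments$seq == ref_slice
  complex_idx <- which(!pure_m)
  ops <- lens <- NULL
  if (length(complex_idx)) {
    ops <- GenomicAlignments::explodeCigarOps(
      fragments$cigar[complex_idx])
    lens <- GenomicAlignments::explodeCigarOpLengths(
      fragments$cigar[complex_idx])
    aligned_ok <- vapply(seq_along(complex_idx), function(j) {
      !any(ops[[j]] == "I" | ops[[j]] == "D")
    }, logical(1))
    if (any(aligned_ok)) {
      # match-only with soft clips: strip clips and compare directly
      jj <- which(aligned_ok)
      for (j in jj) {
        i <- complex_idx[j]
        lead <- if (ops[[j]][1L] == "S") lens[[j]][1L] else 0L
        k <- length(ops[[j]])
        trail <- if (ops[[j]][k] == "S") lens[[j]][k] else 0L
        if (substr(fragments$seq[i], lead + 1L,
                   nchar(fragments$seq[i]) - trail) == ref_slice[i]) {
          clean[i] <- TRUE
        }
      }
    }
  }

  ## Mismatch runs of all pure-M reads in one vectorised pass over the
  ## concatenated read/reference bytes.
  mm_idx <- which(pure_m & !clean)
  batch <- if (length(mm_idx)) {
    m_block_batch(fragments$read_id[mm_idx], fragments$cds_start[mm_idx],
                  fragments$seq[mm_idx], ref_slice[mm_idx])
  } else list()

  todo <- which(!clean & !pure_m)
  var_list <- vector("list", length(todo))
  pos_in_complex <- match(todo, complex_idx)
  for (j in seq_along(todo)) {
    i <- todo[j]
    ci <- pos_in_complex[j]
    var_list[[j]] <- walk_cigar(fragments$read_id[i],
                                fragments$cds_start[i],
                                ops[[ci]], lens[[ci]],
                                fragments$seq[i], ref_slice[i])
  }
  var_list <- c(list(batch), var_list)
  var_list <- var_list[lengths(var_list) > 0L]
  variants <- if (length(var_list)) {
    data.frame(
      read_id = unlist(lapply(var_list, `[[`, "read_id"),
                       use.names = FALSE),
      kind = unlist(lapply(var_list, `[[`, "kind"), use.names = FALSE),
      ref_start = unlist(lapply(var_list, `[[`, "ref_start"),
                         use.names = FALSE),
      ref_length = unlist(lapply(var_list, `[[`, "ref_length"),
                          use.names = FALSE),
      alt = unlist(lapply(var_list, `[[`, "alt"), use.names = FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    empty_variant_table()
  }
  per_read <- summarize_per_read(fragments$read_id, variants)
  list(variants = variants, per_read = per_read)
}

empty_variant_table <- function() {
  data.frame(read_id = character(), kind = character(),
             ref_start = integer(), ref_length = integer(),
             alt = character(), stringsAsFactors = FALSE)
}

empty_per_read_table <- function() {
  data.frame(read_id = character(), n_variants = integer(),
             n_indel = integer(), net_nt = integer(),
             frame_class = character(), stringsAsFactors = FALSE)
}

## Mismatch runs for a batch of full-length match-block reads, found in
## one pass over the concatenated query/reference bytes (chunked to
## bound memory).
m_block_batch <- function(read_ids, cds_starts, qseqs, ref_slices,
                          chunk_bases = 8e6) {
  lens <- nchar(qseqs)
  cl <- cumsum(as.numeric(lens))
  chunk_of <- cl %/% chunk_bases
  out <- lapply(split(seq_along(qseqs), chunk_of), function(ii) {
    qcat <- paste(qseqs[ii], collapse = "")
    rcat <- paste(ref_slices[ii], collapse = "")
    qv <- utf8ToInt(qcat)
    rv <- utf8ToInt(rcat)
    ends <- cumsum(lens[ii])
    starts <- ends - lens[ii] + 1L
    mm <- which(qv != rv)
    if (length(mm) == 0L) return(list())
    read_of <- findInterval(mm - 1L, ends) + 1L
    newrun <- c(TRUE, diff(mm) != 1L | diff(read_of) != 0L)
    r_start <- mm[newrun]
    r_end <- mm[which(c(newrun[-1L], TRUE))]
    r_read <- read_of[newrun]
    local <- r_start - starts[r_read]
    list(read_id = read_ids[ii][r_read],
         kind = rep("substitution", length(r_start)),
         ref_start = cds_starts[ii][r_read] + local,
         ref_length = r_end - r_start + 1L,
         alt = substring(qcat, r_start, r_end))
  })
  out <- out[lengths(out) > 0L]
  if (length(out) == 0L) return(list())
  list(read_id = unlist(lapply(out, `[[`, "read_id"), use.names = FALSE),
       kind = unlist(lapply(out, `[[`, "kind"), use.names = FALSE),
       ref_start = unlist(lapply(out, `[[`, "ref_start"),
                          use.names = FALSE),
       ref_length = unlist(lapply(out, `[[`, "ref_length"),
                           use.names = FALSE),
       alt = unlist(lapply(out, `[[`, "alt"), use.names = FALSE))
}

## Per-read CIGAR walk emitting variants as parallel vectors (cheap to
## bind across many reads). ref_slice is the reference sequence over the
## fragment's aligned span (saves repeated substring).
walk_cigar <- function(read_id, cds_start, ops, lens, qseq, ref_slice) {
  qpos <- 0L   # consumed query bases
  rpos <- 0L   # consumed reference bases within the slice
  kind <- character(0)
  rstart <- rlen <- integer(0)
  alt <- character(0)
  for (i in seq_along(ops)) {
    op <- ops[i]
    len <- lens[i]
    if (op == "S") {
      qpos <- qpos + len
    } else if (op == "I") {
      kind <- c(kind, "insertion")
      rstart <- c(rstart, cds_start + rpos)
      rlen <- c(rlen, 0L)
      alt <- c(alt, substr(qseq, qpos + 1L, qpos + len))
      qpos <- qpos + len
    } else if (op == "D") {
      kind <- c(kind, "deletion")
      rstart <- c(rstart, cds_start + rpos)
      rlen <- c(rlen, len)
      alt <- c(alt, "")
      rpos <- rpos + len
    } else { # M, =, X: compare (string equality first, bytes only on hit)
      qs <- substr(qseq, qpos + 1L, qpos + len)
      rs <- substr(ref_slice, rpos + 1L, rpos + len)
      if (qs != rs) {
        q <- utf8ToInt(qs)
        r <- utf8ToInt(rs)
        mm <- q != r
        runs <- rle(mm)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        hit <- which(runs$values)
        kind <- c(kind, rep("substitution", length(hit)))
        rstart <- c(rstart, cds_start + rpos + starts[hit] - 1L)
        rlen <- c(rlen, runs$lengths[hit])
        alt <- c(alt, substring(qseq, qpos + starts[hit],
                                qpos + ends[hit]))
      }
      qpos <- qpos + len
      rpos <- rpos + len
    }
  }
  if (length(kind) == 0L) return(list())
  list(read_id = rep(read_id, length(kind)), kind = kind,
       ref_start = rstart, ref_length = rlen, alt = alt)
}

summarize_per_read <- function(read_ids, variants) {
  net <- n_var <- n_ind <- integer(length(read_ids))
  names(net) <- NULL
  if (nrow(variants)) {
    idx <- match(variants$read_id, read_ids)
    signed <- ifelse(variants$kind == "insertion", nchar(variants$alt),
                     ifelse(variants$kind == "deletion",
                            -variants$ref_length, 0L))
    is_ind <- variants$kind != "substitution"
    net <- as.integer(rowsum_vec(signed, idx, length(read_ids)))
    n_var <- as.integer(rowsum_vec(rep(1L, nrow(variants)), idx,
                                   length(read_ids)))
    n_ind <- as.integer(rowsum_vec(as.integer(is_ind), idx,
                                   length(read_ids)))
  }
  data.frame(read_id = read_ids, n_variants = n_var, n_indel = n_ind,
             net_nt = net,
             frame_class = classify_frame_vec(n_var, n_ind, net),
             stringsAsFactors = FALSE)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Classify the reading-frame consequence of a read's variants
#'
#' `frameshift` iff the net indel length is not a multiple of 3;
#' `in_frame_indel` iff the net is a multiple of 3 with at least one indel;
#' `sub_only` for substitution-only reads; `wildtype` for none.
#'
#' @param variants Variant table for a single read (columns `kind`,
#'   `ref_length`, `alt`).
#' @return One of `"wildtype"`, `"sub_only"`, `"in_frame_indel"`,
#'   `"frameshift"`.
#' @export
classify_frame <- function(variants) {
  n_var <- nrow(variants)
  n_ind <- sum(variants$kind != "substitution")
  net <- sum(ifelse(variants$kind == "insertion", nchar(variants$alt),
                    ifelse(variants$kind == "deletion",
                           -variants$ref_length, 0L)))
  classify_frame_vec(n_var, n_ind, net)
}

classify_frame_vec <- function(n_var, n_ind, net) {
  ifelse(n_var == 0L, "wildtype",
         ifelse(net %% 3L != 0L, "frameshift",
                ifelse(n_ind > 0L, "in_frame_indel", "sub_only")))
}

#' Translate a read's variants into an amino-acid-level effect
#'
#' Applies the variants to the CDS, translates reference and mutant, and
#' trims the longest common prefix then the longest common suffix at the
#' residue level. The remaining reference interval defines the affected
#' residues and the remaining mutant residues the replacement. Categories:
#' `aa_deletion` (residues lost, nothing gained), `combo` (net length
#' change with replacement residues, including pure in-frame insertions),
#' `substitution` (same length, >=1 differing residue), `silent`, and
#' `nonsense` for any in-frame change whose replacement introduces a
#' premature stop codon -- such truncation alleles are phenotypically
#' null and are excluded from deletion/combo/substitution scoring.
#'
#' @param variants Variant table for one read, sorted by `ref_start`, with
#'   net indel length a multiple of 3.
#' @param ref A `cds_reference`.
#' @return A one-row data.frame: `category`, `residue_start` (1-based),
#'   `affected_length`, `alt_residues`, `net_nt`.
#' @export
translate_effect <- function(variants, ref) {
  net <- sum(ifelse(variants$kind == "insertion", nchar(variants$alt),
                    ifelse(variants$kind == "deletion",
                           -variants$ref_length, 0L)))
  if (net %% 3L != 0L) {
    stop("translate_effect called on an out-of-frame variant set")
  }
  mutant <- apply_variants(ref$sequence, variants)
  mut_prot <- sub("\\*$", "", translate_nt(mutant))
  diff <- trim_protein_diff(ref$protein, mut_prot)
  data.frame(
    category = effect_category(diff$ref_mid, diff$alt_mid, net),
    residue_start = diff$residue_start,
    affected_length = nchar(diff$ref_mid),
    alt_residues = diff$alt_mid,
    net_nt = as.integer(net),
    stringsAsFactors = FALSE
  )
}

## Batched translate_effect over a list of per-read variant tables: all
## mutant CDSs are built, translated in one Biostrings call, and trimmed.
translate_effect_batch <- function(v_list, ref) {
  n <- length(v_list)
  if (n == 0L) {
    return(data.frame(category = character(), residue_start = integer(),
                      affected_length = integer(),
                      alt_residues = character(), net_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  nets <- vapply(v_list, function(vv) {
    as.integer(sum(ifelse(vv$kind == "insertion", nchar(vv$alt),
                          ifelse(vv$kind == "deletion",
                                 -vv$ref_length, 0L))))
  }, integer(1))
  if (any(nets %% 3L != 0L)) {
    stop("translate_effect called on an out-of-frame variant set")
  }
  mutants <- vapply(v_list, function(vv) apply_variants(ref$sequence, vv),
                    character(1))
  prots <- sub("\\*$", "", as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(mutants),
                          if.fuzzy.codon = "X"))))
  category <- character(n)
  residue_start <- affected_length <- integer(n)
  alt_residues <- character(n)
  for (i in seq_len(n)) {
    d <- trim_protein_diff(ref$protein, prots[i])
    category[i] <- effect_category(d$ref_mid, d$alt_mid, nets[i])
    residue_start[i] <- d$residue_start
    affected_length[i] <- nchar(d$ref_mid)
    alt_residues[i] <- d$alt_mid
  }
  data.frame(category = category, residue_start = residue_start,
             affected_length = affected_length,
             alt_residues = alt_residues, net_nt = nets,
             stringsAsFactors = FALSE)
}

## Splice a sorted, non-overlapping variant set into a reference string.
apply_variants <- function(sequence, variants) {
  if (nrow(variants) == 0L) return(sequence)
  o <- order(variants$ref_start)
  variants <- variants[o, , drop = FALSE]
  pieces <- character(2L * nrow(variants) + 1L)
  pos <- 0L
  for (i in seq_len(nrow(variants))) {
    pieces[2L * i - 1L] <- substring(sequence, pos + 1L,
                                     variants$ref_start[i])
    pieces[2L * i] <- variants$alt[i]
    pos <- variants$ref_start[i] + variants$ref_length[i]
  }
  pieces[length(pieces)] <- substring(sequence, pos + 1L, nchar(sequence))
  paste(pieces, collapse = "")
}

## Residue-level prefix/suffix trim; prefix trimmed first (tie-break).
trim_protein_diff <- function(ref_prot, mut_prot) {
  a <- utf8ToInt(ref_prot)
  b <- utf8ToInt(mut_prot)
  la <- length(a); lb <- length(b)
  m <- min(la, lb)
  p <- 0L
  if (m > 0L) {
    neq <- which(a[seq_len(m)] != b[seq_len(m)])
    p <- if (length(neq)) neq[1L] - 1L else m
  }
  ms <- min(la, lb) - p
  s <- 0L
  if (ms > 0L) {
    neq <- which(a[la - seq_len(ms) + 1L] != b[lb - seq_len(ms) + 1L])
    s <- if (length(neq)) neq[1L] - 1L else ms
  }
  list(
    residue_start = p + 1L,
    ref_mid = substr(ref_prot, p + 1L, la - s),
    alt_mid = substr(mut_prot, p + 1L, lb - s)
  )
}

effect_category <- function(ref_mid, alt_mid, net) {
  nr <- nchar(ref_mid); na <- nchar(alt_mid)
  if (nr == 0L && na == 0L) return("silent")
  ## a premature stop truncates the protein: phenotypically a null
  ## allele, not an amino-acid-level deletion/combo/substitution
  if (grepl("*", alt_mid, fixed = TRUE)) return("nonsense")
  if (na == 0L) return("aa_deletion")
  if (net != 0L) return("combo")
  if (ref_mid == alt_mid) return("silent")
  "substitution"
}

#' Call per-read amino-acid effects for a fragment pool
#'
#' Runs quality filtering, variant extraction, frame classification and
#' effect translation for every read. Translation is memoised over unique
#' variant signatures, so pools dominated by recurrent alleles and
#' wild-type reads stay fast.
#'
#' Effects whose codon-extended reference footprint is not fully contained
#' in the read's aligned span cannot be translated unambiguously; they are
#' kept but flagged `callable = FALSE` and excluded from quantification.
#'
#' @param fragments Fragment table.
#' @param ref A `cds_reference`.
#' @param min_mean_q Mean base-quality threshold; `NULL` skips filtering.
#' @param quality_mode Passed to [quality_filter()].
#' @return A data.frame with one row per retained read: `read_id`,
#'   `frame_class`, `category` (`wildtype`, `silent`, `frameshift`,
#'   `nonsense`, `aa_deletion`, `combo`, `substitution`), `residue_start`,
#'   `affected_length`, `alt_residues`, `net_nt`, `n_variants`, `key`,
#'   `footprint_start0`, `footprint_end0`, `callable`. Attributes carry the
#'   filtered fragment table (`fragments`) and stage accounting
#'   (`accounting`).
#' @export
call_effects <- function(fragments, ref, min_mean_q = 30,
                         quality_mode = c("mean", "min")) {
  quality_mode <- match.arg(quality_mode)
  n_in <- nrow(fragments)
  if (!is.null(min_mean_q)) {
    fragments <- quality_filter(fragments, min_q = min_mean_q,
                                mode = quality_mode)
  }
  ev <- extract_variants(fragments, ref)
  pr <- ev$per_read
  eff <- data.frame(
    read_id = pr$read_id,
    frame_class = pr$frame_class,
    category = ifelse(pr$frame_class == "wildtype", "wildtype",
                      ifelse(pr$frame_class == "frameshift",
                             "frameshift", NA_character_)),
    residue_start = NA_integer_, affected_length = NA_integer_,
    alt_residues = NA_character_, net_nt = pr$net_nt,
    n_variants = pr$n_variants, key = NA_character_,
    footprint_start0 = NA_integer_, footprint_end0 = NA_integer_,
    callable = FALSE, stringsAsFactors = FALSE
  )

  translatable <- pr$frame_class %in% c("sub_only", "in_frame_indel")
  if (any(translatable)) {
    v <- ev$variants
    sig_row <- paste(v$kind, v$ref_start, v$ref_length, v$alt, sep = ":")
    ## collapse signatures per read; reads with a single variant (the
    ## bulk) take their row signature directly
    ridx <- match(v$read_id, pr$read_id)
    sig_by_read <- character(nrow(pr))
    single <- which(pr$n_variants == 1L)
    sig_by_read[ridx] <- sig_row          # last write wins; fix multis next
    multi <- which(pr$n_variants > 1L)
    if (length(multi)) {
      vm <- which(ridx %in% multi)
      sig_by_read[multi] <- vapply(
        split(sig_row[vm], factor(ridx[vm], levels = multi)),
        paste, character(1), collapse = ";")
    }
    idx_t <- which(translatable)
    sigs_t <- sig_by_read[idx_t]
    uniq <- !duplicated(sigs_t)
    uniq_sigs <- sigs_t[uniq]
    uniq_reads <- pr$read_id[idx_t][uniq]
    v_rep <- v[v$read_id %in% uniq_reads, , drop = FALSE]
    v_split <- split(v_rep, factor(v_rep$read_id, levels = uniq_reads))
    trans <- translate_effect_batch(v_split, ref)
    row_of <- match(sigs_t, uniq_sigs)
    eff$category[idx_t] <- trans$category[row_of]
    eff$residue_start[idx_t] <- trans$residue_start[row_of]
    eff$affected_length[idx_t] <- trans$affected_length[row_of]
    eff$alt_residues[idx_t] <- trans$alt_residues[row_of]

    scored <- eff$category[idx_t] %in% c("aa_deletion", "combo",
                                         "substitution")
    rs <- eff$residue_start[idx_t]
    al <- pmax(eff$affected_length[idx_t], 1L)
    fs <- (rs - 1L) * 3L
    fe <- (rs + al - 1L) * 3L
    eff$footprint_start0[idx_t] <- ifelse(scored, fs, NA_integer_)
    eff$footprint_end0[idx_t] <- ifelse(scored, fe, NA_integer_)
    eff$key[idx_t] <- ifelse(
      scored,
      paste0(eff$category[idx_t], ":", rs, ":",
             eff$affected_length[idx_t], ":", eff$alt_residues[idx_t]),
      NA_character_)
    span_ok <- fragments$cds_start[idx_t] <= fs &
      fragments$ref_end[idx_t] >= fe
    eff$callable[idx_t] <- scored & span_ok
  }
  attr(eff, "fragments") <- fragments
  attr(eff, "accounting") <- c(
    input = n_in,
    dropped_quality = n_in - nrow(fragments),
    wildtype = sum(eff$category == "wildtype", na.rm = TRUE),
    frameshift = sum(eff$category == "frameshift", na.rm = TRUE),
    silent = sum(eff$category == "silent", na.rm = TRUE),
    nonsense = sum(eff$category == "nonsense", na.rm = TRUE),
    uncallable = sum(!eff$callable &
                       eff$category %in% c("aa_deletion", "combo",
                                           "substitution"))
  )
  eff
}

#' Profile mutation variety around a cut site
#'
#' Downsamples the pool to `downsample_to` reads (without replacement,
#' seeded), restricts variants to a +/- `window_nt` window around the cut
#' site, groups reads by variant signature within the window, and drops
#' signatures supported by fewer than `min_count` reads.
#'
#' @param fragments Fragment table.
#' @param ref A `cds_reference`.
#' @param cut_site 0-based CDS coordinate of the cut.
#' @param window_nt Half-window in nt (default 20).
#' @param downsample_to Target read count (default 1e5).
#' @param min_count Minimum reads per signature (default 5).
#' @param seed Seed for the downsampling.
#' @return A data.frame `signature`, `count`, `in_frame`, `n_indel`,
#'   sorted by decreasing count; wild-type (empty) signatures are omitted.
#' @export
mutagenesis_window_profile <- function(fragments, ref, cut_site,
                                       window_nt = 20L,
                                       downsample_to = 100000L,
                                       min_count = 5L, seed = 1L) {
  if (nrow(fragments) > downsample_to) {
    set.seed(seed)
    fragments <- fragments[sample.int(nrow(fragments), downsample_to), ,
                           drop = FALSE]
  }
  ev <- extract_variants(fragments, ref)
  v <- ev$variants
  if (nrow(v)) {
    v_end <- v$ref_start + pmax(v$ref_length, 1L)
    keep <- v$ref_start <= cut_site + window_nt &
      v_end >= cut_site - window_nt
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) == 0L) {
    return(data.frame(signature = character(), count = integer(),
                      in_frame = logical(), n_indel = integer(),
                      stringsAsFactors = FALSE))
  }
  sig_row <- paste(v$kind, v$ref_start, v$ref_length, v$alt, sep = ":")
  sig <- vapply(split(sig_row, v$read_id), paste, character(1),
                collapse = ";")
  tab <- table(sig)
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) {
    return(data.frame(signature = character(), count = integer(),
                      in_frame = logical(), n_indel = integer(),
                      stringsAsFactors = FALSE))
  }
  sigs <- names(tab)
  rep_read <- names(sig)[match(sigs, sig)]
  v_by_read <- split(v, v$read_id)
  info <- lapply(rep_read, function(rid) {
    vv <- v_by_read[[rid]]
    net <- sum(ifelse(vv$kind == "insertion", nchar(vv$alt),
                      ifelse(vv$kind == "deletion", -vv$ref_length, 0L)))
    c(in_frame = net %% 3L == 0L,
      n_indel = sum(vv$kind != "substitution"))
  })
  out <- data.frame(
    signature = sigs,
    count = as.integer(tab),
    in_frame = vapply(info, `[[`, numeric(1), "in_frame") > 0,
    n_indel = as.integer(vapply(info, `[[`, numeric(1), "n_indel")),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
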