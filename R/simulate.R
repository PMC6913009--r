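#' Configuration for a synthetic tiling-mutagenesis screen
#'
#' Bundles and validates the parameters of the generative model: a cell
#' population carrying one tiling sgRNA each, per-allele CRISPR editing at
#' the sgRNA cut site, allele-level genotype-to-phenotype rules for
#' recessive or dominant selection, growth advantage for resistant cells,
#' random ~250 bp transcript fragmentation and per-base sequencing error.
#'
#' @param protein_length Residues in the simulated protein (default 200).
#' @param ploidy Alleles per cell (default 2).
#' @param gene_essential If `TRUE`, cells whose alleles are all null die
#'   and null-allele transcripts are excluded after selection.
#' @param inheritance `"recessive"` or `"dominant"`.
#' @param critical_residues 1-based indices of planted critical residues.
#' @param n_cells Cells in the population (default 20000).
#' @param edit_rate Per-allele probability of an edit (default 0.5).
#' @param indel_length_distribution Named probability vector over signed
#'   indel lengths (negative = deletion); default: deletions of 1-12 nt
#'   with probability proportional to 0.7^len (90% mass) plus 1-2 nt
#'   insertions (10% mass).
#' @param missense_rate Probability an edit resolves as a 1-nt
#'   substitution instead of an indel (default 0.1).
#' @param enrichment Selection advantage multiplier for resistant cells
#'   (default 50).
#' @param fragment_length_mean,fragment_length_sd Fragment length model in
#'   nt (default 250 +/- 25).
#' @param seq_error_rate Per-base substitution error rate (default 1e-3).
#' @param depth Reads per condition (default 2e5).
#' @param seed RNG seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(protein_length = 200L, ploidy = 2L,
                              gene_essential = FALSE,
                              inheritance = c("recessive", "dominant"),
                              critical_residues = integer(0),
                              n_cells = 20000L, edit_rate = 0.5,
                              indel_length_distribution =
                                default_indel_distribution(),
                              missense_rate = 0.1, enrichment = 50,
                              fragment_length_mean = 250,
                              fragment_length_sd = 25,
                              seq_error_rate = 1e-3, depth = 200000L,
                              seed = 1L) {
  inheritance <- match.arg(inheritance)
  probs <- c(edit_rate, missense_rate, seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (depth <= 0L) stop("depth must be positive")
  if (length(critical_residues) &&
      (any(critical_residues < 1L) || any(critical_residues > protein_length))) {
    stop("critical_residues outside 1..protein_length")
  }
  d <- indel_length_distribution
  if (is.null(names(d)) || abs(sum(d) - 1) > 1e-8 || any(d < 0)) {
    stop("indel_length_distribution must be a named probability vector")
  }
  structure(list(
    protein_length = as.integer(protein_length), ploidy = as.integer(ploidy),
    gene_essential = isTRUE(gene_essential), inheritance = inheritance,
    critical_residues = as.integer(critical_residues),
    n_cells = as.integer(n_cells), edit_rate = edit_rate,
    indel_length_distribution = d, missense_rate = missense_rate,
    enrichment = enrichment, fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    seq_error_rate = seq_error_rate, depth = as.integer(depth),
    seed = as.integer(seed)), class = "simulation_config")
}

#' Default signed indel-length distribution
#'
#' Deletions of 1-12 nt with probability proportional to 0.7^length (90%
#' of the mass), plus 1 and 2 nt insertions at 5% each: a deletion-skewed,
#' frameshift-dominated repair spectrum.
#' @return Named probability vector (negative names are deletions).
#' @export
default_indel_distribution <- function() {
  del <- 0.7^(1:12)
  del <- 0.9 * del / sum(del)
  ins <- c(0.05, 0.05)
  stats::setNames(c(del, ins), c(paste0("-", 1:12), "1", "2"))
}

#' Simulate a random CDS
#'
#' ATG followed by random non-stop codons and a TAA stop, so the reference
#' always satisfies the CDS invariants.
#'
#' @param protein_length Number of residues (including the leading M).
#' @param gene_id Identifier.
#' @param seed RNG seed.
#' @return A `cds_reference`.
#' @export
simulate_cds <- function(protein_length, gene_id = "synthgene", seed = 1L) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  nonstop <- names(gc)[gc != "*"]
  codons <- sample(nonstop, protein_length - 1L, replace = TRUE)
  cds_reference(paste(c("ATG", codons, "TAA"), collapse = ""), gene_id)
}

#' Classify a cell's resistance from its allele classes
#'
#' Allele classes are `"functional"` (wild type, silent, or in-frame away
#' from critical residues), `"altered"` (in-frame change touching a
#' critical residue) and `"null"` (frameshift or nonsense). Under
#' recessive inheritance a cell is resistant when no functional allele
#' remains (all null, or altered alleles with the rest null); under
#' dominant inheritance a single altered allele suffices. For essential
#' genes the all-null genotype is not viable and is removed from the
#' population before selection.
#'
#' @param classes Character vector of allele classes for one cell.
#' @param inheritance `"recessive"` or `"dominant"`.
#' @param gene_essential Logical.
#' @return Logical: resistant. Attribute `viable` reports cell viability.
#' @export
classify_resistance <- function(classes,
                                inheritance = c("recessive", "dominant"),
                                gene_essential = FALSE) {
  inheritance <- match.arg(inheritance)
  stopifnot(all(classes %in% c("functional", "altered", "null")))
  viable <- !(gene_essential && all(classes == "null"))
  resistant <- if (inheritance == "dominant") {
    any(classes == "altered")
  } else {
    viable && !any(classes == "functional")
  }
  structure(resistant, viable = viable)
}

## Functional class of a single-variant allele.
allele_class <- function(kind, ref_start, ref_length, alt, ref,
                         critical_residues) {
  net <- if (kind == "insertion") nchar(alt)
         else if (kind == "deletion") -ref_length else 0L
  if (net %% 3L != 0L) return("null")
  v <- data.frame(kind = kind, ref_start = ref_start,
                  ref_length = ref_length, alt = alt,
                  stringsAsFactors = FALSE)
  eff <- translate_effect(v, ref)
  if (eff$category == "silent") return("functional")
  if (eff$category == "nonsense") return("null")  # truncation
  span <- eff$residue_start:(eff$residue_start +
                               max(eff$affected_length, 1L) - 1L)
  if (any(span %in% critical_residues)) "altered" else "functional"
}

#' Simulate the edited cell population
#'
#' Each cell receives one sgRNA uniformly at random; each of its alleles
#' is independently edited with probability `edit_rate` at that sgRNA's
#' cut site. An edit resolves as a 1-nt substitution with probability
#' `missense_rate`, otherwise as an indel drawn from
#' `indel_length_distribution`; deletions are centred on the cut site
#' (mimicking bidirectional resection) and insertions are placed at the
#' cut. Allele classes and per-cell resistance/viability follow
#' [classify_resistance()].
#'
#' @param config A `simulation_config`.
#' @param ref A `cds_reference` with `protein_length` matching the config.
#' @param sgrnas Design table from [design_sgrnas()] on `ref`.
#' @return A list (`truth_table`): `cells` (data.frame `cell`, `sgrna`,
#'   `resistant`, `viable`), `allele_variant` (n_cells x ploidy matrix of
#'   variant ids, 0 = unedited), `variants` (data.frame per distinct
#'   variant: id, kind, ref_start, ref_length, alt, net_nt, class,
#'   category, residue_start, affected_length), `critical_residues`.
#' @export
simulate_population <- function(config, ref, sgrnas) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ref, "cds_reference"), nrow(sgrnas) > 0L)
  if (ref$protein_length != config$protein_length) {
    stop("reference protein length does not match the configuration")
  }
  set.seed(config$seed)
  L <- ref$length
  nc <- config$n_cells
  pl <- config$ploidy
  sg <- sample.int(nrow(sgrnas), nc, replace = TRUE)
  cut <- pmin(pmax(sgrnas$cut_site[sg], 0L), L - 1L)

  n_alleles <- nc * pl
  edited <- stats::runif(n_alleles) < config$edit_rate
  is_sub <- edited & stats::runif(n_alleles) < config$missense_rate
  dist <- config$indel_length_distribution
  signed <- as.integer(names(dist))
  draw <- signed[sample.int(length(dist), n_alleles, replace = TRUE,
                            prob = dist)]
  allele_cell <- rep(seq_len(nc), times = pl)
  acut <- cut[allele_cell]

  kind <- rep(NA_character_, n_alleles)
  ref_start <- ref_length <- rep(NA_integer_, n_alleles)
  alt <- rep(NA_character_, n_alleles)
  bases <- c("A", "C", "G", "T")

  si <- which(is_sub)
  if (length(si)) {
    pos <- acut[si]
    refb <- substring(ref$sequence, pos + 1L, pos + 1L)
    altb <- vapply(refb, function(b) sample(setdiff(bases, b), 1L),
                   character(1), USE.NAMES = FALSE)
    kind[si] <- "substitution"
    ref_start[si] <- pos
    ref_length[si] <- 1L
    alt[si] <- altb
  }
  ii <- which(edited & !is_sub)
  if (length(ii)) {
    len <- draw[ii]
    del <- len < 0L
    dl <- -len[del]
    ## deletions are centred on the cut, so resection removes bases on
    ## both sides of the break; one canonical placement per (cut, length)
    ## keeps per-variant-type read counts at realistic library depths
    dstart <- pmin(pmax(acut[ii][del] - dl %/% 2L, 0L), L - dl)
    kind[ii[del]] <- "deletion"
    ref_start[ii[del]] <- dstart
    ref_length[ii[del]] <- dl
    alt[ii[del]] <- ""
    insv <- !del
    if (any(insv)) {
      il <- len[insv]
      kind[ii[insv]] <- "insertion"
      ref_start[ii[insv]] <- acut[ii][insv]
      ref_length[ii[insv]] <- 0L
      alt[ii[insv]] <- vapply(il, function(k)
        paste(sample(bases, k, replace = TRUE), collapse = ""),
        character(1))
    }
  }

  sig <- ifelse(edited,
                paste(kind, ref_start, ref_length, alt, sep = ":"),
                NA_character_)
  uniq <- unique(sig[edited])
  var_id <- integer(n_alleles)
  var_id[edited] <- match(sig[edited], uniq)

  first <- match(uniq, sig)
  variants <- data.frame(
    id = seq_along(uniq),
    kind = kind[first], ref_start = ref_start[first],
    ref_length = ref_length[first], alt = alt[first],
    stringsAsFactors = FALSE
  )
  variants$net_nt <- ifelse(variants$kind == "insertion",
                            nchar(variants$alt),
                            ifelse(variants$kind == "deletion",
                                   -variants$ref_length, 0L))
  cls <- character(nrow(variants))
  cat <- rep(NA_character_, nrow(variants))
  rs <- al <- rep(NA_integer_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    if (variants$net_nt[i] %% 3L != 0L) {
      cls[i] <- "null"
      next
    }
    v <- variants[i, , drop = FALSE]
    eff <- translate_effect(
      data.frame(kind = v$kind, ref_start = v$ref_start,
                 ref_length = v$ref_length, alt = v$alt,
                 stringsAsFactors = FALSE), ref)
    cat[i] <- eff$category
    rs[i] <- eff$residue_start
    al[i] <- eff$affected_length
    cls[i] <- allele_class(v$kind, v$ref_start, v$ref_length, v$alt, ref,
                           config$critical_residues)
  }
  variants$class <- cls
  variants$category <- cat
  variants$residue_start <- rs
  variants$affected_length <- al

  avm <- matrix(var_id, nrow = nc, ncol = pl)
  class_of <- c("functional", variants$class)  # index by var_id + 1
  ## vectorised form of classify_resistance over the whole population
  ## (agreement with the per-cell rule is property-tested)
  clsm <- matrix(class_of[avm + 1L], nrow = nc)
  n_fun <- rowSums(clsm == "functional")
  n_alt <- rowSums(clsm == "altered")
  n_null <- rowSums(clsm == "null")
  viable <- !(config$gene_essential & n_null == pl)
  resistant <- if (config$inheritance == "dominant") {
    n_alt > 0L
  } else {
    viable & n_fun == 0L
  }
  list(
    cells = data.frame(cell = seq_len(nc), sgrna = sg,
                       resistant = resistant, viable = viable),
    allele_variant = avm,
    variants = variants,
    critical_residues = config$critical_residues,
    config = config
  )
}

## Mutant transcript for one variant row (or the reference for NULL).
variant_sequence <- function(variant, ref) {
  if (is.null(variant)) return(ref$sequence)
  apply_variants(ref$sequence,
                 data.frame(kind = variant$kind,
                            ref_start = variant$ref_start,
                            ref_length = variant$ref_length,
                            alt = variant$alt, stringsAsFactors = FALSE))
}

## Fragments for n reads drawn from one (possibly wild-type) allele.
## Returns cds_start/ref_end/cigar/seq for truth alignments.
fragment_allele <- function(n, variant, ref, config, id_prefix) {
  L <- ref$length
  mut <- variant_sequence(variant, ref)
  L2 <- nchar(mut)
  flen <- pmax(30L, pmin(L2, as.integer(round(
    stats::rnorm(n, config$fragment_length_mean,
                 config$fragment_length_sd)))))
  start <- as.integer(floor(stats::runif(n) * (L2 - flen + 1L)))
  end <- start + flen
  seqs <- substring(mut, start + 1L, end)

  if (is.null(variant) || variant$kind == "substitution") {
    cds_start <- start
    cigar <- paste0(flen, "M")
    ref_end <- end
  } else if (variant$kind == "deletion") {
    d <- variant$ref_start
    dl <- variant$ref_length
    before <- end <= d
    after <- start >= d
    spans <- !before & !after
    cds_start <- ifelse(after, start + dl, start)
    ref_end <- ifelse(before, end, ifelse(after, end + dl, end + dl))
    cigar <- character(n)
    cigar[!spans] <- paste0(flen[!spans], "M")
    cigar[spans] <- paste0(d - start[spans], "M", dl, "D",
                           end[spans] - d, "M")
  } else { # insertion of il at reference point d (mutant block [d, d+il))
    d <- variant$ref_start
    il <- nchar(variant$alt)
    cds_start <- integer(n)
    ref_end <- integer(n)
    cigar <- character(n)
    before <- end <= d
    after <- start >= d + il
    cds_start[before] <- start[before]
    ref_end[before] <- end[before]
    cigar[before] <- paste0(flen[before], "M")
    cds_start[after] <- start[after] - il
    ref_end[after] <- end[after] - il
    cigar[after] <- paste0(flen[after], "M")
    rest <- which(!before & !after)
    for (j in rest) {
      s <- start[j]; e <- end[j]
      if (s < d && e >= d + il) {
        lead <- d - s
        tail_m <- e - d - il
        cds_start[j] <- s
        ref_end[j] <- e - il
        cigar[j] <- if (tail_m > 0L) {
          paste0(lead, "M", il, "I", tail_m, "M")
        } else paste0(lead, "M", il, "I")
      } else if (s < d) {          # ends inside the inserted block
        lead <- d - s
        clip <- e - d
        cds_start[j] <- s
        ref_end[j] <- d
        cigar[j] <- paste0(lead, "M", clip, "S")
      } else {                     # starts inside the inserted block
        clip <- d + il - s
        cds_start[j] <- d
        ref_end[j] <- e - il
        cigar[j] <- paste0(clip, "S", e - d - il, "M")
      }
    }
  }
  list(
    read_id = paste0(id_prefix, seq_len(n)),
    cds_start = as.integer(cds_start),
    ref_end = as.integer(ref_end),
    cigar = cigar,
    seq = seqs
  )
}

## Inject per-base substitution errors into read sequences: one draw of
## error sites over the concatenated pool, edited at the byte level.
inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(as.numeric(lens))
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  offs <- sample.int(total, n_err)
  raw <- charToRaw(paste(seqs, collapse = ""))
  base_raw <- charToRaw("ACGT")
  ## row = current base, column = which of its 3 alternatives
  alt_tab <- matrix(c(charToRaw("CGT"), charToRaw("AGT"),
                      charToRaw("ACT"), charToRaw("ACG")),
                    nrow = 4L, byrow = TRUE)
  cur <- match(raw[offs], base_raw)
  raw[offs] <- alt_tab[cbind(cur, sample.int(3L, n_err, replace = TRUE))]
  ends <- cumsum(lens)
  substring(rawToChar(raw), ends - lens + 1L, ends)
}

#' Sample sequencing libraries from a simulated population
#'
#' Draws `depth` fragments per condition. The before library samples
#' transcripts uniformly from viable cells; the after library weights
#' cells by `enrichment^resistant`; the mock library is pure wild type.
#' For essential genes, null-allele transcripts are excluded from
#' after-library sampling. Fragments carry truth alignments (correct
#' POS/CIGAR for the planted variants), so the extraction module can be
#' exercised without an external aligner; per-base substitution errors are
#' injected at `seq_error_rate`.
#'
#' @param truth Output of [simulate_population()].
#' @param ref The simulated `cds_reference`.
#' @param config The `simulation_config` (defaults to the one in `truth`).
#' @param conditions Subset of `c("before", "after", "mock")`.
#' @return Named list of fragment tables (compatible with
#'   [call_effects()]), each with a `qual`/`mean_q` column (constant Q40).
#' @export
select_and_sequence <- function(truth, ref, config = truth$config,
                                conditions = c("before", "after", "mock")) {
  set.seed(config$seed + 1L)
  cells <- truth$cells
  avm <- truth$allele_variant
  viable <- which(cells$viable)
  out <- list()
  for (cond in conditions) {
    if (cond == "mock") {
      var_of_read <- rep(0L, config$depth)
    } else {
      wts <- if (cond == "after") {
        config$enrichment^cells$resistant[viable]
      } else rep(1, length(viable))
      cell_idx <- viable[sample.int(length(viable), config$depth,
                                    replace = TRUE, prob = wts)]
      allele <- sample.int(config$ploidy, config$depth, replace = TRUE)
      var_of_read <- avm[cbind(cell_idx, allele)]
      if (cond == "after" && config$gene_essential) {
        cls <- c("functional", truth$variants$class)[var_of_read + 1L]
        for (i in which(cls == "null")) {
          av <- avm[cell_idx[i], ]
          ok <- av[c("functional",
                     truth$variants$class)[av + 1L] != "null"]
          var_of_read[i] <- ok[sample.int(length(ok), 1L)]
        }
      }
    }
    groups <- split(seq_len(config$depth), var_of_read)
    frag_list <- lapply(names(groups), function(vid) {
      v <- as.integer(vid)
      variant <- if (v == 0L) NULL else truth$variants[v, , drop = FALSE]
      fragment_allele(length(groups[[vid]]), variant, ref, config,
                      id_prefix = paste0(cond, "_v", vid, "_"))
    })
    pull <- function(field) unlist(lapply(frag_list, `[[`, field),
                                   use.names = FALSE)
    frags <- data.frame(
      read_id = pull("read_id"), cds_start = pull("cds_start"),
      ref_end = pull("ref_end"), cigar = pull("cigar"),
      seq = pull("seq"), stringsAsFactors = FALSE)
    frags$seq <- inject_errors(frags$seq, config$seq_error_rate)
    flen <- nchar(frags$seq)
    frags$qual <- strrep("I", seq_len(max(flen)))[flen]
    frags$mean_q <- 40
    rownames(frags) <- NULL
    out[[cond]] <- frags
  }
  out
}

#' Run a complete synthetic screen
#'
#' Simulates the CDS, designs the tiling sgRNA library, edits the
#' population, and samples before/after/mock sequencing libraries plus
#' per-condition sgRNA barcode counts.
#'
#' @param config A `simulation_config`.
#' @param conditions Conditions to sequence.
#' @return A list: `ref`, `sgrnas`, `truth`, `libraries` (fragment tables
#'   per condition), `sgrna_counts` (data.frame `spacer`, `count_before`,
#'   `count_after`).
#' @export
simulate_screen <- function(config,
                            conditions = c("before", "after", "mock")) {
  ref <- simulate_cds(config$protein_length, seed = config$seed)
  sgrnas <- design_sgrnas(ref)
  truth <- simulate_population(config, ref, sgrnas)
  libs <- select_and_sequence(truth, ref, config, conditions)
  cells <- truth$cells
  viable <- cells[cells$viable, , drop = FALSE]
  cb <- tabulate(viable$sgrna, nbins = nrow(sgrnas))
  wt <- config$enrichment^viable$resistant
  ca <- vapply(seq_len(nrow(sgrnas)), function(i)
    sum(wt[viable$sgrna == i]), numeric(1))
  ca <- round(ca / sum(ca) * sum(cb))
  counts <- data.frame(spacer = sgrnas$spacer, count_before = cb,
                       count_after = as.integer(ca),
                       stringsAsFactors = FALSE)
  list(ref = ref, sgrnas = sgrnas, truth = truth, libraries = libs,
       sgrna_counts = counts)
}

#' Residues reachable by in-frame mutagenesis of a tiling library
#'
#' A residue can only acquire in-frame deletion/combo signal if cut sites
#' fall close enough that an in-frame deletion spanning a cut can overlap
#' its codon. This reports, per residue, the number of cut sites within
#' `reach_nt` of the codon and a logical `assayable` flag (at least
#' `min_cuts` such sites). Useful for interpreting gaps in a functional
#' map and for planting benchmark residues where the library can in
#' principle detect them.
#'
#' @param ref A `cds_reference`.
#' @param sgrnas Design table from [design_sgrnas()].
#' @param reach_nt Maximum distance (nt) between a cut site and the codon
#'   for a centred in-frame deletion to plausibly cover both (default 4,
#'   the reach of the common 3-6 nt deletions).
#' @param min_cuts Minimum nearby cut sites for `assayable` (default 2).
#' @return A data.frame `residue`, `n_cuts`, `phase_cut` (a cut site sits
#'   at the codon's second base, so a centred 3-nt deletion excises
#'   exactly this codon and yields a full-weight single-residue deletion
#'   key), and `assayable` (`n_cuts >= min_cuts` and `phase_cut`).
#' @export
assayable_residues <- function(ref, sgrnas, reach_nt = 4L, min_cuts = 2L) {
  pl <- ref$protein_length
  cuts <- sgrnas$cut_site
  n_cuts <- vapply(seq_len(pl), function(r) {
    lo <- (r - 1L) * 3L - reach_nt
    hi <- r * 3L + reach_nt
    sum(cuts >= lo & cuts <= hi)
  }, integer(1))
  phase_cut <- (3L * seq_len(pl) - 2L) %in% cuts
  data.frame(residue = seq_len(pl), n_cuts = n_cuts,
             phase_cut = phase_cut,
             assayable = n_cuts >= min_cuts & phase_cut)
}

#' Write a simulated screen to disk
#'
#' Emits the reference FASTA, sgRNA library TSV, per-condition SAM and
#' FASTQ, a truth table TSV (per-cell resistance plus planted residues)
#' and the configuration as YAML.
#'
#' @param sim Output of [simulate_screen()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_screen <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ref <- sim$ref
  paths <- c(fasta = file.path(outdir, "reference.fa"),
             library = file.path(outdir, "sgrna_library.tsv"),
             truth = file.path(outdir, "truth_cells.tsv"),
             critical = file.path(outdir, "truth_critical_residues.tsv"),
             config = file.path(outdir, "config.yaml"))
  writeLines(c(paste0(">", ref$gene_id), ref$sequence), paths["fasta"])
  write_sgrna_library(sim$sgrnas, paths["library"])
  utils::write.table(sim$truth$cells, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(residue = seq_len(ref$protein_length),
               planted_critical = seq_len(ref$protein_length) %in%
                 sim$truth$critical_residues),
    paths["critical"], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$truth$config
  yaml::write_yaml(cfg[setdiff(names(cfg), "indel_length_distribution")],
                   paths["config"])
  for (cond in names(sim$libraries)) {
    frags <- sim$libraries[[cond]]
    sam <- file.path(outdir, paste0(cond, ".sam"))
    fq <- file.path(outdir, paste0(cond, ".fastq"))
    write_sam(frags, ref, sam)
    write_fastq(frags$read_id, frags$seq, frags$qual, fq)
    paths[paste0("sam_", cond)] <- sam
    paths[paste0("fastq_", cond)] <- fq
  }
  invisible(paths)
}
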