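#' Read and validate a run configuration
#'
#' The YAML layout has a `genes` list (each entry: `id`, `fasta`,
#' `sam_before`, `sam_after`, optional `sam_mock`), an optional
#' `thresholds` block (`min_mean_q`, `min_count_scoring`,
#' `min_count_variety`, `max_affected`, `w`, `k_sd`), an optional `seed`
#' and an `outdir`.
#'
#' @param path YAML file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

default_thresholds <- function() {
  list(min_mean_q = 30, min_count_scoring = 9L, min_count_variety = 5L,
       max_affected = 3L, w = 1, k_sd = 3)
}

validate_run_config <- function(cfg, dir = ".") {
  if (is.null(cfg$genes) || length(cfg$genes) == 0L) {
    stop("config field 'genes' is missing or empty")
  }
  th <- utils::modifyList(default_thresholds(),
                          if (is.null(cfg$thresholds)) list()
                          else cfg$thresholds)
  if (any(unlist(th[c("min_mean_q", "min_count_scoring",
                      "min_count_variety", "max_affected")]) <= 0)) {
    stop("thresholds must be positive")
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(dir, p)
  }
  for (i in seq_along(cfg$genes)) {
    g <- cfg$genes[[i]]
    for (field in c("fasta", "sam_before", "sam_after")) {
      if (is.null(g[[field]])) {
        stop("gene entry ", i, " is missing required field '", field, "'")
      }
      g[[field]] <- resolve(g[[field]])
      if (!file.exists(g[[field]])) {
        stop("gene entry ", i, ": file for '", field, "' not found: ",
             g[[field]])
      }
    }
    if (!is.null(g$sam_mock)) g$sam_mock <- resolve(g$sam_mock)
    if (is.null(g$id)) g$id <- NULL
    cfg$genes[[i]] <- g
  }
  cfg$thresholds <- th
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "."
  class(cfg) <- "run_config"
  cfg
}

#' Run the full scoring pipeline for every configured gene
#'
#' For each gene: load the CDS, read and quality-filter the before/after
#' (and optional mock) alignments, call per-read effects, quantify
#' deletion/combo/substitution frequencies, compute per-residue essential
#' scores, and write a score TSV plus a JSON manifest with thresholds and
#' stage accounting. A failure in one gene aborts that gene only; the
#' attribute `failed` lists failed gene ids.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return Named list of per-gene results (each the [score_screen()]
#'   bundle plus `ref` and `accounting`), invisibly also written under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  failed <- character()
  for (g in config$genes) {
    id <- if (!is.null(g$id)) g$id else NULL
    res <- tryCatch({
      ref <- load_cds(g$fasta, gene_id = id)
      process_gene(ref, g, th, config$outdir)
    }, error = function(e) {
      warning("gene '", if (is.null(id)) g$fasta else id, "' failed: ",
              conditionMessage(e))
      NULL
    })
    key <- if (!is.null(id)) id else basename(g$fasta)
    if (is.null(res)) failed <- c(failed, key) else results[[key]] <- res
  }
  attr(results, "failed") <- failed
  if (length(failed)) {
    warning("pipeline failed for: ", paste(failed, collapse = ", "))
  }
  results
}

process_gene <- function(ref, gene_cfg, th, outdir) {
  read_one <- function(path) {
    frags <- read_alignments(path, ref)
    call_effects(frags, ref, min_mean_q = th$min_mean_q)
  }
  eff_b <- read_one(gene_cfg$sam_before)
  eff_a <- read_one(gene_cfg$sam_after)
  bundle <- score_screen(eff_b, eff_a, ref,
                         min_count = th$min_count_scoring,
                         max_affected = th$max_affected,
                         w = th$w, k_sd = th$k_sd)
  bundle$ref <- ref
  bundle$accounting <- list(before = attr(eff_b, "accounting"),
                            after = attr(eff_a, "accounting"))
  if (!is.null(gene_cfg$sam_mock)) {
    eff_m <- read_one(gene_cfg$sam_mock)
    bundle$mock_table <- effect_frequencies(eff_m,
                                            min_count = th$min_count_scoring)
    bundle$accounting$mock <- attr(eff_m, "accounting")
  }
  score_path <- file.path(outdir, paste0(ref$gene_id, "_scores.tsv"))
  scores <- bundle$scores
  scores$gene <- ref$gene_id
  utils::write.table(
    scores[, c("gene", "residue", "ref_aa", "dfc_aa", "cmfc_aa",
               "freq_sub", "sf_score", "z", "p", "essential_score",
               "rank", "above_cutoff")],
    score_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(gene = ref$gene_id, thresholds = th,
                   cutoff = bundle$cutoff,
                   sub_cutoff = bundle$sub_cutoff,
                   accounting = lapply(bundle$accounting, as.list),
                   n_hits = sum(scores$above_cutoff))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0(ref$gene_id,
                                                "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle$score_path <- score_path
  bundle
}

#' Render a per-residue linear map from a score table
#'
#' Produces the tested track table (one row per residue with the score,
#' cutoff flag and the deletion/combo/substitution tracks) and optionally
#' a plot of essential scores with the cutoff as a dashed line.
#'
#' @param scores Per-residue score table (data.frame or TSV path) with an
#'   `essential_score` column.
#' @param cutoff Essential-score cutoff; recomputed with [score_cutoff()]
#'   when `NULL`.
#' @param plot_file Optional PNG/PDF path for the figure.
#' @return The track data.frame.
#' @export
render_map <- function(scores, cutoff = NULL, plot_file = NULL) {
  if (is.character(scores)) {
    scores <- utils::read.delim(scores, stringsAsFactors = FALSE)
  }
  if (nrow(scores) == 0L) stop("empty score table")
  if (is.null(cutoff)) cutoff <- score_cutoff(scores)$cutoff
  track <- data.frame(
    residue = scores$residue,
    essential_score = scores$essential_score,
    dfc_aa = scores$dfc_aa,
    cmfc_aa = scores$cmfc_aa,
    freq_sub = scores$freq_sub,
    above_cutoff = scores$essential_score > cutoff,
    stringsAsFactors = FALSE
  )
  if (!is.null(plot_file)) {
    if (grepl("\\.pdf$", plot_file)) grDevices::pdf(plot_file, 9, 4)
    else grDevices::png(plot_file, 1200, 500, res = 120)
    graphics::plot(track$residue, track$essential_score, type = "h",
                   xlab = "residue", ylab = "essential score",
                   col = ifelse(track$above_cutoff, "black", "grey60"))
    graphics::abline(h = cutoff, lty = 2)
    grDevices::dev.off()
  }
  attr(track, "cutoff") <- cutoff
  track
}
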