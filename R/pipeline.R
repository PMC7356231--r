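#' Pipeline configuration
#'
#' Bundles every stage threshold with its standard default: clustering
#' identity 0.95, expression identity 0.95 (novel-candidate divergence
#' 0.05), selection p-value threshold 0.1, promoter length 500 bp, sliding
#' window 15 residues, motif widths 6-30 bp, genome-scan accuracy 0.70.
#' The configuration is echoed verbatim into the run report.
#'
#' @param params a [family_params()] object for the simulation stage.
#' @param score_min,identity_min mining thresholds ([translated_search()]).
#' @param cluster_identity greedy clustering threshold.
#' @param expression_identity expression-evidence threshold.
#' @param selection_p selection-test significance threshold.
#' @param promoter_len promoter length (bp).
#' @param window sliding-window width (residues).
#' @param wmin,wmax motif width bounds (bp).
#' @param n_motifs motifs to discover.
#' @param scan_accuracy genome-scan relative-score threshold.
#' @param n_transcriptomes how many individuals get a simulated
#'   transcriptome for the expression stage.
#' @param out_dir output directory (NULL for no file output).
#' @param seed master seed for every stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(params = family_params(),
                       score_min = 60, identity_min = 0.40,
                       cluster_identity = 0.95,
                       expression_identity = 0.95,
                       selection_p = 0.1,
                       promoter_len = 500L,
                       window = 15L,
                       wmin = 6L, wmax = 30L, n_motifs = 2L,
                       scan_accuracy = 0.70,
                       n_transcriptomes = 3L,
                       out_dir = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline on a synthetic family
#'
#' Stages in dependency order: simulate -> mine -> catalog (dereplicate,
#' classify, align, cluster, consensus, PAV) -> biophysics, selection,
#' promoter motifs, expression/editing -> report.  All randomness derives
#' from the config seed; re-running with the same config gives identical
#' results.
#'
#' @param cfg a [run_config()] object.
#' @return List of class `run_report`: per-stage counts and results, plus
#'   the config echo.  With `out_dir` set, stage outputs (TSV/FASTA/BED/
#'   newick/JSON) are written there.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  log_line <- function(...) message(sprintf(...))
  t_stage <- function() Sys.time()
  elapsed <- function(t0) round(as.numeric(Sys.time() - t0, units = "secs"), 2)

  # --- simulate ---------------------------------------------------------
  t0 <- t_stage()
  fam <- simulate_family(cfg$params)
  truth <- fam$truth
  log_line("simulate: %d individuals, %d planted copies [%ss]",
           length(fam$genomes), nrow(truth), elapsed(t0))

  # --- mine -------------------------------------------------------------
  t0 <- t_stage()
  loci <- mine_genomes(fam$genomes, reference_mature_peptide(),
                       score_min = cfg$score_min,
                       identity_min = cfg$identity_min,
                       promoter_len = cfg$promoter_len)
  log_line("mine: %d loci from %d individuals [%ss]",
           nrow(loci), length(fam$genomes), elapsed(t0))

  # --- catalog ----------------------------------------------------------
  t0 <- t_stage()
  variants <- classify_variants(dereplicate(loci))
  cl <- cluster_greedy(variants, cfg$cluster_identity)
  aln <- align_family(stats::setNames(variants$cds, variants$variant_id))
  cons <- lapply(seq_len(nrow(cl$clusters)), function(k) {
    cluster_consensus(strsplit(cl$clusters$members[k], ",")[[1]], aln)
  })
  names(cons) <- cl$clusters$cluster_id
  pav <- build_pav(variants, names(fam$genomes), cl$assignment)
  stats_v <- pav_stats(pav$variant)
  log_line("catalog: %d variants, %d clusters [%ss]",
           nrow(variants), nrow(cl$clusters), elapsed(t0))

  # --- biophysics -------------------------------------------------------
  t0 <- t_stage()
  conv <- variants[variants$class == "conventional", , drop = FALSE]
  biophys <- data.frame(
    variant_id = conv$variant_id,
    pI = vapply(conv$peptide, function(p)
      suppressWarnings(isoelectric_point(p)), 0, USE.NAMES = FALSE),
    charge = vapply(conv$peptide, function(p)
      suppressWarnings(net_charge(p)), 0, USE.NAMES = FALSE),
    mw = vapply(conv$peptide, molecular_weight, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  sliding <- if (nrow(conv)) {
    sliding_pi(conv$peptide[1], cfg$window)
  } else numeric(0)
  log_line("biophys: %d conventional peptides [%ss]", nrow(conv), elapsed(t0))

  # --- selection --------------------------------------------------------
  t0 <- t_stage()
  selection <- NULL
  if (nrow(conv) >= 3L) {
    selection <- site_selection(aln[conv$variant_id, , drop = FALSE],
                                cfg$selection_p)
  }
  n_pos <- if (is.null(selection)) 0L else sum(selection$sites$call == "positive")
  n_neg <- if (is.null(selection)) 0L else sum(selection$sites$call == "negative")
  log_line("selection: %d positive, %d negative sites [%ss]",
           n_pos, n_neg, elapsed(t0))

  # --- promoter ---------------------------------------------------------
  t0 <- t_stage()
  proms <- loci$promoter[!loci$promoter_truncated & nzchar(loci$promoter)]
  names(proms) <- paste0("prom", seq_along(proms))
  motifs <- list()
  prom_report <- NULL
  if (length(proms) >= 2L) {
    motifs <- discover_motifs(proms, n_motifs = cfg$n_motifs,
                              wmin = cfg$wmin, wmax = cfg$wmax,
                              seed = cfg$seed)
    if (length(motifs)) {
      prom_report <- data.frame(
        promoter = names(proms),
        combined_p = vapply(proms, function(p)
          combined_match_pvalue(p, motifs), 0, USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  log_line("promoter: %d motifs from %d promoters [%ss]",
           length(motifs), length(proms), elapsed(t0))

  # --- expression / editing --------------------------------------------
  t0 <- t_stage()
  inds <- names(fam$genomes)[seq_len(min(cfg$n_transcriptomes,
                                         length(fam$genomes)))]
  txs <- list()
  for (ind in inds) {
    sim <- simulate_transcriptome(truth, ind, cfg$params$edit_rate,
                                  seed = derive_seed(cfg$seed, match(ind, inds)))
    truth <- sim$truth
    txs[[ind]] <- sim$transcripts
  }
  cons_nt <- vapply(cons, function(x) gsub("-", "", x$cds), "")
  expr <- expression_evidence(cons_nt, txs,
                              id_threshold = cfg$expression_identity)
  log_line("express: %d/%d cluster-transcriptome pairs expressed [%ss]",
           sum(expr$expressed), length(expr$expressed), elapsed(t0))

  report <- list(
    config = cfg,
    counts = list(
      individuals = length(fam$genomes),
      planted_copies = nrow(fam$truth),
      loci = nrow(loci),
      variants = nrow(variants),
      class_counts = as.list(table(variants$class)),
      clusters = nrow(cl$clusters),
      mean_variants_per_individual = stats_v$mean_per_individual,
      mean_private_per_individual = stats_v$mean_private_per_individual,
      universal_clusters = pav_stats(pav$cluster)$n_universal,
      positive_sites = n_pos,
      negative_sites = n_neg,
      motifs = length(motifs),
      expressed_pairs = sum(expr$expressed)),
    truth = fam$truth,
    loci = loci, variants = variants, clusters = cl, alignment = aln,
    consensus = cons, pav = pav, biophys = biophys, sliding = sliding,
    selection = selection, motifs = motifs, promoter_report = prom_report,
    expression = expr)
  class(report) <- "run_report"

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write pipeline outputs to disk
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$loci[, setdiff(names(report$loci), "promoter")],
            file.path(dir, "loci.tsv"))
  write_tsv(report$variants, file.path(dir, "variants.tsv"))
  write_tsv(report$clusters$clusters, file.path(dir, "clusters.tsv"))
  pav <- report$pav$variant
  write_tsv(data.frame(variant_id = rownames(pav),
                       frequency = rowMeans(pav), pav + 0),
            file.path(dir, "pav_variants.tsv"))
  cons <- Biostrings::DNAStringSet(
    vapply(report$consensus, function(x) gsub("-", "", x$cds), ""))
  Biostrings::writeXStringSet(cons, file.path(dir, "consensus_nt.fasta"))
  if (!is.null(report$selection)) {
    write_tsv(report$selection$sites, file.path(dir, "selection_sites.tsv"))
    ape::write.tree(report$selection$tree, file.path(dir, "tree.nwk"))
  }
  write_tsv(report$biophys, file.path(dir, "biophys.tsv"))
  if (length(report$motifs)) {
    write_motifs_meme(report$motifs, file.path(dir, "motifs.meme"))
  }
  if (!is.null(report$promoter_report)) {
    write_tsv(report$promoter_report, file.path(dir, "promoter_report.tsv"))
  }
  jsonlite::write_json(report$counts, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs motif list from [discover_motifs()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_motifs_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", NUCS, motifs[[1]]$bg),
                     collapse = " "), ""), con)
  for (k in seq_along(motifs)) {
    mo <- motifs[[k]]
    writeLines(sprintf("MOTIF m%d %s", k, mo$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      mo$width, mo$n_sites), con)
    for (j in seq_len(mo$width)) {
      writeLines(paste(sprintf("%.6f", mo$pwm[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
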