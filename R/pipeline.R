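#' Genome-scale reference tabulations (maize B73 RefGen_v2)
#'
#' Loads one of the plain-text reference tables shipped with the package:
#' genome-scale tabulations from the maize B73 (RefGen_v2, filtered gene set
#' 5b) codon-position GC and DSB hotspot motif analysis.  Desk-scale
#' verification recomputes summary statistics and chi-square p-values from
#' these printed counts; the genome-scale analysis itself requires the maize
#' reference and is not reproduced here.
#'
#' @param name one of `"gcx_class_counts"` (high/low gene counts per codon
#'   position), `"motifs_per_gene"` (motifs-per-gene histogram),
#'   `"motif_totals"` (key/value scalars: motif, gene and frame totals and
#'   the intron:CDS base ratio), `"motif_gcx_enrichment"` (high/low GCx
#'   observed among motif genes with reported p),
#'   `"gcx_class_overlap"` (class co-occurrence counts with reported p),
#'   `"expression_motif_bias"`, `"expression_gcx"` (expression-class
#'   cross-tabs with reported p)
#' @return a data.frame
#' @export
referenceTable <- function(name = c("gcx_class_counts", "motifs_per_gene",
                                    "motif_totals", "motif_gcx_enrichment",
                                    "gcx_class_overlap",
                                    "expression_motif_bias",
                                    "expression_gcx")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("maize_", name, ".tsv"),
                      package = "GCxMotif", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: read genome and annotation, compute
#' per-gene GC profiles and high/low GCx classes, scan for the DSB hotspot
#' motif, localize hits and assign codon frames, summarise motif GC
#' periodicity, and run the enrichment chi-squares.  Writes the table
#' analogues as TSV, the figure analogues as PDF, a machine-readable JSON
#' summary and a run log into `out_dir`.
#'
#' @param fasta path to the genome FASTA
#' @param gff path to the GFF3 annotation
#' @param out_dir output directory
#' @param expression_labels optional TSV of expression labels (gene_id,
#'   direction, comparison); when absent the expression tables are skipped
#'   with a notice
#' @param consensus motif consensus (IUPAC)
#' @param gc_cutoff inclusive high-GCx cutoff, default 0.80
#' @param stringency motif scan stringency, default 0.80
#' @param f_alpha variance-gate level for the periodicity t tests
#' @param both_strands scan both strands, default TRUE
#' @param plots write the figure analogues, default TRUE
#' @return invisibly, a list with all stage results (`gene_models`,
#'   `profile`, `hits`, `per_gene`, `group_tests`, `enrichment`,
#'   `class_overlap`, `expression`, `summary`)
#' @export
runPipeline <- function(fasta, gff, out_dir,
                        expression_labels = NULL,
                        consensus = DSB_MOTIF_CONSENSUS,
                        gc_cutoff = 0.80,
                        stringency = 0.80,
                        f_alpha = 0.10,
                        both_strands = TRUE,
                        plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logit <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                             "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logit("GCxMotif ", as.character(utils::packageVersion("GCxMotif")),
        "; R ", as.character(getRversion()))
  logit("parameters: cutoff=", gc_cutoff, " stringency=", stringency,
        " f_alpha=", f_alpha, " both_strands=", both_strands,
        " consensus=", consensus)

  stage <- function(name, expr) {
    logit("stage ", name, " ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genome <- stage("genome_io", readGenome(fasta))
  gm <- stage("genome_io", suppressWarnings(readAnnotation(gff)))
  profile <- stage("codon_gc", classifyGCx(gcProfile(gm, genome), gc_cutoff))
  utils::write.table(profile, file.path(out_dir, "gc_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- classCounts(profile)
  utils::write.table(counts, file.path(out_dir, "table_class_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  model <- consensusToPWM(consensus, stringency = stringency)
  hits <- stage("motif_scan", {
    h <- scanSeq(genome, model, both_strands = both_strands)
    localizeHits(h, gm)
  })
  writeHitsBed(hits, file.path(out_dir, "motif_hits.bed"))
  hits_df <- as.data.frame(hits)
  utils::write.table(hits_df, file.path(out_dir, "motif_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genic <- hits[!is.na(hits$gene_id)]
  pg <- perGeneCounts(genic)
  utils::write.table(pg$histogram,
                     file.path(out_dir, "table_motifs_per_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logit("motifs: ", length(hits), " total, ", length(genic), " genic in ",
        pg$n_genes, " genes; expectation precision: full double")

  # CDS preference among genic hits, expectation from base composition
  cds_b <- sum(gm@genes$cds_len, na.rm = TRUE)
  span_b <- sum(width(gm@genes))
  other_b <- span_b - cds_b
  n_cds <- sum(hits_df$region == "CDS", na.rm = TRUE)
  n_other <- sum(hits_df$region %in% c("INTRON", "UTR5", "UTR3"))
  cds_pref <- if (n_cds + n_other > 0)
    cdsPreferenceTest(n_cds, n_other, cds_b, other_b) else NULL

  group_tests <- stage("motif_stats", {
    if (length(genic) >= 2L) {
      ppg <- perPositionGC(genic)
      grp <- periodicityGroups(ppg)
      tab <- groupComparisonTable(grp$groups, f_alpha)
      utils::write.table(data.frame(position = seq_along(ppg), gc = ppg),
                         file.path(out_dir, "per_position_gc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(tab, file.path(out_dir, "table_group_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(per_position = ppg, groups = grp, table = tab)
    } else NULL
  })
  gcx_prof <- motifGCxProfile(genic)
  utils::write.table(gcx_prof, file.path(out_dir, "motif_gcx_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  motif_gene_ids <- unique(genic$gene_id[!is.na(genic$gene_id)])
  enr <- stage("enrichment", gcxEnrichmentTests(profile, motif_gene_ids))
  utils::write.table(enr, file.path(out_dir, "table_motif_gcx.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ovl <- stage("enrichment", classOverlapTests(profile))
  utils::write.table(ovl, file.path(out_dir, "table_class_overlap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  expr <- NULL
  if (!is.null(expression_labels) && file.exists(expression_labels)) {
    labels <- readExpressionLabels(expression_labels)
    expr <- stage("enrichment",
                  expressionBiasTests(motif_gene_ids, labels, profile))
    utils::write.table(expr$motif_bias,
                       file.path(out_dir, "table_expression_motif.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expr$gcx_by_class,
                       file.path(out_dir, "table_expression_gcx.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    logit("no expression labels supplied; expression tables skipped")
  }

  if (plots) {
    stage("reporting", plotReportFigures(profile, gcx_prof, group_tests,
                                         out_dir, gc_cutoff))
  }

  summary <- list(
    n_genes = length(gm),
    n_coding = sum(gm@genes$coding),
    class_counts = counts,
    n_hits = length(hits),
    n_genic_hits = length(genic),
    n_motif_genes = pg$n_genes,
    total_motifs = pg$total_motifs,
    frac_multi = pg$frac_multi,
    frame_counts = as.list(table(factor(genic$codon_frame, levels = 1:3))),
    cds_preference_p = if (!is.null(cds_pref)) pValue(cds_pref) else NA,
    parameters = list(gc_cutoff = gc_cutoff, stringency = stringency,
                      f_alpha = f_alpha, both_strands = both_strands,
                      consensus = consensus)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logit("done")
  invisible(list(gene_models = gm, profile = profile, hits = hits,
                 per_gene = pg, cds_preference = cds_pref,
                 group_tests = group_tests, motif_gcx = gcx_prof,
                 enrichment = enr, class_overlap = ovl, expression = expr,
                 summary = summary))
}

#' Write the figure analogues for a pipeline run
#'
#' Kernel density plots of genic/CDS GC and of GC1/GC2/GC3 (with the high
#' cutoff marked), pairwise GCx scatter plots, per-position motif GC, and
#' the per-motif GCx densities; vector PDF output.
#'
#' @param profile classified GC profile
#' @param gcx_prof per-motif codon-position GC profile
#' @param group_tests periodicity-group summary from [runPipeline()]
#' @param out_dir output directory
#' @param gc_cutoff cutoff to mark
#' @return invisibly NULL
#' @export
plotReportFigures <- function(profile, gcx_prof, group_tests, out_dir,
                              gc_cutoff = 0.80) {
  safeDens <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2L && stats::var(v) > 0) gcDensity(v) else NULL
  }
  pdf(file.path(out_dir, "fig_gc_density.pdf"), width = 9, height = 4)
  graphics::par(mfrow = c(1, 2))
  for (cl in c("gc_gene", "gc_cds")) {
    d <- safeDens(profile[[cl]])
    if (!is.null(d)) plot(d, main = cl, xlab = "GC fraction")
  }
  grDevices::dev.off()

  pdf(file.path(out_dir, "fig_gcx_density.pdf"), width = 12, height = 4)
  graphics::par(mfrow = c(1, 3))
  for (k in 1:3) {
    d <- safeDens(profile[[paste0("gc", k)]])
    if (!is.null(d)) {
      plot(d, main = paste0("GC", k), xlab = "GC fraction")
      graphics::abline(v = gc_cutoff, col = "blue")
    }
  }
  grDevices::dev.off()

  pdf(file.path(out_dir, "fig_gcx_pairs.pdf"), width = 12, height = 4)
  graphics::par(mfrow = c(1, 3))
  prs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in prs) {
    x <- profile[[paste0("gc", p[1])]]
    y <- profile[[paste0("gc", p[2])]]
    plot(x, y, pch = 16, cex = 0.4,
         xlab = paste0("GC", p[1]), ylab = paste0("GC", p[2]),
         main = paste0("GC", p[1], " vs GC", p[2]))
    graphics::abline(v = gc_cutoff, h = gc_cutoff, col = "blue")
  }
  grDevices::dev.off()

  if (!is.null(group_tests)) {
    pdf(file.path(out_dir, "fig_motif_periodicity.pdf"), width = 6,
        height = 4)
    plot(seq_along(group_tests$per_position), group_tests$per_position,
         type = "h", lwd = 3, ylim = c(0, 1),
         xlab = "motif position", ylab = "GC fraction",
         main = "per-position motif GC")
    grDevices::dev.off()
  }
  if (!is.null(gcx_prof) && nrow(gcx_prof) >= 2L) {
    pdf(file.path(out_dir, "fig_motif_gcx_density.pdf"), width = 12,
        height = 4)
    graphics::par(mfrow = c(1, 3))
    for (k in 1:3) {
      d <- safeDens(gcx_prof[[paste0("gc", k)]])
      if (!is.null(d)) plot(d, main = paste0("motif GC", k),
                            xlab = "GC fraction")
    }
    grDevices::dev.off()
  }
  invisible(NULL)
}
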