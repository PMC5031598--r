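#' Goodness-of-fit chi-square against genome-wide proportions
#'
#' Tests whether `observed_yes` of `observed_yes + observed_no` genes is
#' consistent with the genome-wide fraction `universe_yes / (universe_yes +
#' universe_no)`.  Expected counts are carried at full precision (never the
#' rounded values a report would print — rounding them visibly distorts
#' vanishing p-values).  Pearson chi-square with 1 df, two-sided, no
#' continuity correction, computed via [stats::chisq.test()].
#'
#' @param observed_yes,observed_no observed counts in the gene subset
#' @param universe_yes,universe_no genome-wide class counts defining the
#'   expected proportions
#' @return a [ContingencyResult]
#' @examples
#' # high-GC1 genes among 544 motif-containing genes, genome 3647/36009
#' gofChisq(130, 414, 3647, 36009)
#' @export
gofChisq <- function(observed_yes, observed_no, universe_yes, universe_no) {
  if (any(c(observed_yes, observed_no, universe_yes, universe_no) < 0))
    stop("counts must be non-negative")
  tot_u <- universe_yes + universe_no
  if (tot_u <= 0) stop("universe must be non-empty")
  p <- c(universe_yes, universe_no) / tot_u
  n <- observed_yes + observed_no
  if (any(p * n == 0))
    stop("zero expected cell: universe proportion ",
         paste(signif(p, 4), collapse = "/"), " with n = ", n)
  ct <- suppressWarnings(stats::chisq.test(c(observed_yes, observed_no),
                                           p = p))
  new("ContingencyResult",
      observed = c(yes = observed_yes, no = observed_no),
      expected = c(yes = unname(ct$expected[1]), no = unname(ct$expected[2])),
      statistic = unname(ct$statistic),
      df = 1,
      p.value = unname(ct$p.value))
}

#' Expected overlap of two gene classes under random sampling
#'
#' The count of genes expected in both classes if class-a membership were a
#' random sample of the genome: `n_class_a * n_class_b / n_genome`.
#'
#' @param n_class_a,n_class_b class sizes
#' @param n_genome genome-wide gene count
#' @return list with `expected` (full precision) and `rounded`
#' @examples
#' expectedOverlap(3647, 5719, 39656)  # 525.97 -> 526
#' @export
expectedOverlap <- function(n_class_a, n_class_b, n_genome) {
  stopifnot(n_class_a >= 0, n_class_b >= 0, n_genome > 0)
  e <- n_class_a * n_class_b / n_genome
  list(expected = e, rounded = round(e))
}

# one ContingencyResult flattened to a report row
.crRow <- function(condition, cr) {
  data.frame(condition = condition,
             observed_yes = cr@observed[["yes"]],
             expected_yes = cr@expected[["yes"]],
             observed_no = cr@observed[["no"]],
             expected_no = cr@expected[["no"]],
             chi2 = cr@statistic,
             p = cr@p.value,
             stringsAsFactors = FALSE)
}

#' High/low GCx enrichment within a gene subset
#'
#' For each codon position, tests whether high-GCx membership within a gene
#' subset (e.g. the motif-containing genes) departs from the genome-wide
#' high/low split.
#'
#' @param labels data.frame from [classifyGCx()] covering the genome (must
#'   contain `gene_id` and `high_gc1..3`)
#' @param subset_ids character vector of gene ids defining the subset
#' @return data.frame with one row per GCx: condition, observed/expected
#'   yes/no, chi2, p
#' @export
gcxEnrichmentTests <- function(labels, subset_ids) {
  sub <- labels[labels$gene_id %in% subset_ids, , drop = FALSE]
  rows <- lapply(1:3, function(k) {
    col <- paste0("high_gc", k)
    g <- labels[[col]]
    s <- sub[[col]]
    u_yes <- sum(g, na.rm = TRUE); u_no <- sum(!g, na.rm = TRUE)
    if (u_yes == 0L || u_no == 0L || sum(!is.na(s)) == 0L) {
      # degenerate universe: the proportion test is undefined
      return(data.frame(condition = paste0("GC", k),
                        observed_yes = sum(s, na.rm = TRUE),
                        expected_yes = NA_real_,
                        observed_no = sum(!s, na.rm = TRUE),
                        expected_no = NA_real_,
                        chi2 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    cr <- gofChisq(sum(s, na.rm = TRUE), sum(!s, na.rm = TRUE), u_yes, u_no)
    .crRow(paste0("GC", k), cr)
  })
  do.call(rbind, rows)
}

#' Co-occurrence tests between high-GCx classes
#'
#' Conditioning on each high-GCx class in turn, tests whether membership in
#' each other high class within the conditioning class matches the
#' genome-wide proportion of that other class.
#'
#' @param labels data.frame from [classifyGCx()]
#' @return data.frame: conditioning class, tested class, observed/expected
#'   yes/no, chi2, p; conditioning classes with no member are skipped with a
#'   warning
#' @export
classOverlapTests <- function(labels) {
  rows <- list()
  for (a in 1:3) {
    cond <- labels[[paste0("high_gc", a)]]
    cond[is.na(cond)] <- FALSE
    if (!any(cond)) {
      warning("empty conditioning class GC", a, "; skipped")
      next
    }
    for (b in setdiff(1:3, a)) {
      colb <- paste0("high_gc", b)
      g <- labels[[colb]]
      s <- labels[[colb]][cond]
      if (sum(g, na.rm = TRUE) == 0L || sum(!g, na.rm = TRUE) == 0L) {
        warning("class GC", b, " empty genome-wide; test within GC", a,
                " skipped")
        next
      }
      cr <- gofChisq(sum(s, na.rm = TRUE), sum(!s, na.rm = TRUE),
                     sum(g, na.rm = TRUE), sum(!g, na.rm = TRUE))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(within = paste0("high_GC", a)),
              .crRow(paste0("GC", b), cr))
    }
  }
  do.call(rbind, rows)
}

#' Read expression labels from TSV
#'
#' Expected columns: `gene_id`, `direction` (`up`/`down`), `comparison`
#' (e.g. `anther`, `seedling`).  A gene may not be both up and down in the
#' same comparison.
#'
#' @param path TSV file path
#' @return data.frame with those three columns
#' @export
readExpressionLabels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "direction", "comparison")
  if (!all(need %in% names(df)))
    stop("expression label file must have columns: ",
         paste(need, collapse = ", "))
  dup <- stats::aggregate(direction ~ gene_id + comparison, df,
                          function(d) length(unique(d)))
  if (any(dup$direction > 1L))
    stop("gene(s) labeled both up and down in one comparison")
  df[need]
}

#' Expression-class bias tests
#'
#' Two families of tests on differential-expression labels (consumed as
#' input, never recomputed here):
#'
#' * `motif_bias`: within the motif-containing genes, are up- (resp. down-)
#'   regulated genes present at the rate expected from their genome-wide
#'   fraction?
#' * `gcx_by_class`: within each expression class, do high/low GCx counts
#'   match the genome-wide GCx proportions?
#'
#' @param motif_gene_ids character vector: motif-containing genes
#' @param labels data.frame as from [readExpressionLabels()]
#' @param gcx_labels data.frame from [classifyGCx()] covering the genome
#' @param n_genome genome-wide number of genes (defaults to
#'   `nrow(gcx_labels)`)
#' @return list of two data.frames, `motif_bias` and `gcx_by_class`
#' @export
expressionBiasTests <- function(motif_gene_ids, labels, gcx_labels,
                                n_genome = nrow(gcx_labels)) {
  known <- labels$gene_id %in% gcx_labels$gene_id
  if (!all(known)) {
    message(sum(!known), " labeled gene(s) absent from the gene universe; ",
            "excluded")
    labels <- labels[known, , drop = FALSE]
  }
  classes <- unique(labels[c("direction", "comparison")])
  classes <- classes[order(classes$direction, classes$comparison), ,
                     drop = FALSE]

  motif_rows <- lapply(seq_len(nrow(classes)), function(i) {
    d <- classes$direction[i]; cmp <- classes$comparison[i]
    ids <- labels$gene_id[labels$direction == d & labels$comparison == cmp]
    n_lab <- length(unique(ids))
    obs_yes <- sum(motif_gene_ids %in% ids)
    obs_no <- length(motif_gene_ids) - obs_yes
    cr <- gofChisq(obs_yes, obs_no, n_lab, n_genome - n_lab)
    .crRow(paste(d, "vs", cmp), cr)
  })

  gcx_rows <- list()
  for (i in seq_len(nrow(classes))) {
    d <- classes$direction[i]; cmp <- classes$comparison[i]
    ids <- unique(labels$gene_id[labels$direction == d &
                                 labels$comparison == cmp])
    sub <- gcx_labels[gcx_labels$gene_id %in% ids, , drop = FALSE]
    for (k in 1:3) {
      col <- paste0("high_gc", k)
      g <- gcx_labels[[col]]
      s <- sub[[col]]
      if (sum(!is.na(s)) == 0L) next
      # an empty genome-wide class gives a zero expected cell; skip the row
      if (sum(g, na.rm = TRUE) == 0L || sum(!g, na.rm = TRUE) == 0L) next
      cr <- gofChisq(sum(!s, na.rm = TRUE), sum(s, na.rm = TRUE),
                     sum(!g, na.rm = TRUE), sum(g, na.rm = TRUE))
      # reported low-first to match the usual layout of these tables
      gcx_rows[[length(gcx_rows) + 1L]] <-
        cbind(data.frame(class = paste(d, "vs", cmp)),
              .crRow(paste0("GC", k, " (low/high)"), cr))
    }
  }
  list(motif_bias = do.call(rbind, motif_rows),
       gcx_by_class = if (length(gcx_rows)) do.call(rbind, gcx_rows)
                      else NULL)
}
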