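#' Per-position GC fraction across motif hits
#'
#' For each of the motif's positions, the GC fraction across all hit
#' sequences (N excluded from numerator and denominator).
#'
#' @param sequences character vector of matched motif sequences (hit-strand
#'   orientation), all the same width; or a `GRanges` of localized hits with
#'   a `sequence` column
#' @return numeric vector of per-position GC fractions (length = motif width)
#' @export
perPositionGC <- function(sequences) {
  if (is(sequences, "GRanges")) sequences <- sequences$sequence
  stopifnot(length(sequences) >= 1L)
  W <- unique(nchar(sequences))
  if (length(W) != 1L) stop("hit sequences must share one width")
  m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  vapply(seq_len(W), function(k) {
    b <- m[, k]
    gc <- sum(b == "G" | b == "C")
    at <- sum(b == "A" | b == "T")
    if (gc + at == 0L) NA_real_ else gc / (gc + at)
  }, numeric(1))
}

#' 3-nt periodicity groups of per-position GC values
#'
#' Partitions the 19 motif positions into the fixed periodicity groups:
#' group 1 = positions 1, 4, 7, 10, 13, 16, 19; group 2 = 2, 5, 8, 11, 14,
#' 17; group 3 = 3, 6, 9, 12, 15, 18.  These groups are framed on the motif
#' start, not on the containing gene's codons.
#'
#' @param per_position numeric vector of 19 per-position GC fractions
#' @return list with `groups` (list of three numeric samples of sizes 7, 6,
#'   6) and `summary` (data.frame: group, n, mean, var)
#' @export
periodicityGroups <- function(per_position) {
  stopifnot(length(per_position) == 19L)
  idx <- split(1:19, ((1:19 - 1L) %% 3L) + 1L)
  groups <- lapply(idx, function(i) per_position[i])
  names(groups) <- paste0("nt", 1:3)
  list(groups = groups,
       summary = data.frame(
         group = names(groups),
         n = lengths(groups),
         mean = vapply(groups, mean, numeric(1)),
         var = vapply(groups, stats::var, numeric(1)),
         row.names = NULL))
}

#' Codon-position GC of one motif instance
#'
#' Places each motif base into a codon-position bin according to the hit's
#' codon frame (base i of the motif occupies codon position
#' `((frame - 1 + i - 1) mod 3) + 1`), trims the end overhangs — bases of a
#' first codon whose position 1 the motif does not cover, and of a last
#' codon whose position 3 it does not cover — so only complete codon columns
#' remain, then computes GC per codon position.
#'
#' @param sequence the matched motif sequence (character)
#' @param codon_frame 1, 2 or 3: codon position of the motif's first base
#' @return list gc1, gc2, gc3, n1, n2, n3 (bases counted per position),
#'   trimmed_length
#' @export
motifCodonGCx <- function(sequence, codon_frame) {
  stopifnot(codon_frame %in% 1:3)
  v <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  lead <- (3L - (codon_frame - 1L)) %% 3L   # bases of the incomplete first codon
  if (lead >= length(v)) v <- character(0) else if (lead) v <- v[-seq_len(lead)]
  keep <- 3L * (length(v) %/% 3L)
  v <- v[seq_len(keep)]
  gc_at <- function(k) {
    b <- v[seq_along(v) %% 3L == (k %% 3L)]
    gc <- sum(b == "G" | b == "C")
    at <- sum(b == "A" | b == "T")
    c(if (gc + at == 0L) NA_real_ else gc / (gc + at), gc + at)
  }
  g1 <- gc_at(1L); g2 <- gc_at(2L); g3 <- gc_at(3L)
  list(gc1 = g1[1], gc2 = g2[1], gc3 = g3[1],
       n1 = as.integer(g1[2]), n2 = as.integer(g2[2]), n3 = as.integer(g3[2]),
       trimmed_length = keep)
}

#' Codon-position GC profile of all frame-defined hits
#'
#' @param hits localized hits (`GRanges` with `sequence` and `codon_frame`);
#'   hits without a frame are excluded
#' @return data.frame: gene_id, codon_frame, gc1, gc2, gc3, n1, n2, n3
#' @export
motifGCxProfile <- function(hits) {
  keep <- which(!is.na(hits$codon_frame))
  rows <- lapply(keep, function(i) {
    p <- motifCodonGCx(hits$sequence[i], hits$codon_frame[i])
    data.frame(gene_id = hits$gene_id[i], codon_frame = hits$codon_frame[i],
               gc1 = p$gc1, gc2 = p$gc2, gc3 = p$gc3,
               n1 = p$n1, n2 = p$n2, n3 = p$n3,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene_id = character(0), codon_frame = integer(0),
                      gc1 = numeric(0), gc2 = numeric(0), gc3 = numeric(0),
                      n1 = integer(0), n2 = integer(0), n3 = integer(0)))
  do.call(rbind, rows)
}

#' Variance-gated two-sample t test
#'
#' The spreadsheet-style two-stage procedure: a two-sided F test for equal
#' variances decides which two-tailed t test follows — pooled-variance
#' (homoscedastic) when the F test does not reject at `f_alpha`, Welch
#' (heteroscedastic) when it does.  `f_alpha` defaults to 0.10.
#'
#' @param a,b numeric samples, each of length >= 2
#' @param f_alpha significance level of the variance gate
#' @return list: f_test_p, variance_equal, t_test_kind ("pooled"/"welch"),
#'   t_statistic, t_p_two_sided
#' @export
varianceGatedTTest <- function(a, b, f_alpha = 0.10) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(f_test_p = NA_real_, variance_equal = TRUE,
                t_test_kind = "pooled", t_statistic = if (same) 0 else Inf,
                t_p_two_sided = if (same) 1 else 0))
  }
  fp <- stats::var.test(a, b)$p.value
  equal <- fp >= f_alpha
  tt <- stats::t.test(a, b, var.equal = equal)
  list(f_test_p = fp,
       variance_equal = equal,
       t_test_kind = if (equal) "pooled" else "welch",
       t_statistic = unname(tt$statistic),
       t_p_two_sided = tt$p.value)
}

#' Pairwise periodicity-group comparisons
#'
#' Runs the variance-gated t test between every pair of the three
#' periodicity groups (or any named list of samples).
#'
#' @param groups named list of numeric samples
#' @param f_alpha variance-gate level, default 0.10
#' @return data.frame: comparison, f_test_p, t_test_kind, t_p_two_sided
#' @export
groupComparisonTable <- function(groups, f_alpha = 0.10) {
  nm <- names(groups)
  cmb <- utils::combn(length(groups), 2)
  rows <- apply(cmb, 2, function(ij) {
    r <- varianceGatedTTest(groups[[ij[1]]], groups[[ij[2]]], f_alpha)
    data.frame(comparison = paste(nm[ij[1]], "vs.", nm[ij[2]]),
               f_test_p = r$f_test_p, t_test_kind = r$t_test_kind,
               t_p_two_sided = r$t_p_two_sided, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-motif codon-position GC densities and 100%-GC fractions
#'
#' @param profiles data.frame from [motifGCxProfile()]
#' @return list: `density` (list of three [stats::density] objects, or NULL
#'   for degenerate zero-spread samples) and `frac_at_one` (named fractions
#'   of hits at exactly 1.0 per codon position)
#' @export
perMotifGCxDensity <- function(profiles) {
  stopifnot(nrow(profiles) >= 2L)
  cols <- c("gc1", "gc2", "gc3")
  dens <- lapply(cols, function(cl) {
    v <- profiles[[cl]]
    v <- v[!is.na(v)]
    if (length(v) < 2L || stats::var(v) == 0) NULL else gcDensity(v)
  })
  names(dens) <- cols
  frac1 <- vapply(cols, function(cl) {
    v <- profiles[[cl]]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v == 1)
  }, numeric(1))
  list(density = dens, frac_at_one = frac1)
}
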