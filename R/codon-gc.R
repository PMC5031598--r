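#' GC fraction of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #T).  N and every other ambiguity code are
#' excluded from numerator and denominator; a sequence with no unambiguous
#' base yields `NA`, never 0, so undefined values cannot silently enter
#' downstream summaries.
#'
#' @param seq a character string, [Biostrings::DNAString] or `DNAStringSet`
#' @return numeric fraction in \[0, 1\], or `NA` when undefined;
#'   vectorised over a `DNAStringSet` or character vector
#' @examples
#' gcFraction("GGCC")   # 1
#' gcFraction("ATGN")   # 1/3
#' @export
gcFraction <- function(seq) {
  if (is(seq, "DNAString")) seq <- as.character(seq)
  if (is(seq, "DNAStringSet")) seq <- as.character(seq)
  vapply(seq, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    gc <- sum(v == "G" | v == "C")
    at <- sum(v == "A" | v == "T")
    if (gc + at == 0L) NA_real_ else gc / (gc + at)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Codon-position GC content of a coding sequence
#'
#' Drops the first `phase_offset` bases (they complete a codon begun in an
#' unretained upstream segment), partitions the remainder into consecutive
#' triplets, and computes the GC fraction over each triplet column.  By
#' default a trailing partial triplet contributes its present positions;
#' set `drop_partial = TRUE` to discard incomplete trailing codons.
#'
#' @param seq coding sequence (character or `DNAString`)
#' @param phase_offset integer in 0..2, the phase of the first base
#' @param drop_partial drop a trailing incomplete codon instead of using its
#'   present positions
#' @return list with `gc1`, `gc2`, `gc3` (NA when no countable base at that
#'   position), `n_codons` (complete codons) and `counted_bases` (non-N bases
#'   entering any of the three fractions)
#' @examples
#' codonPositionGC("ATGGCCGTA", 0)  # gc1 = 2/3, gc2 = 1/3, gc3 = 2/3
#' codonPositionGC("GATGGC", 1)     # framed over ATG | GC.
#' @export
codonPositionGC <- function(seq, phase_offset = 0L, drop_partial = FALSE) {
  stopifnot(phase_offset %in% 0:2)
  if (is(seq, "DNAString")) seq <- as.character(seq)
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(v) <= phase_offset) v <- character(0)
  else if (phase_offset > 0L) v <- v[-seq_len(phase_offset)]
  if (drop_partial) v <- v[seq_len(3L * (length(v) %/% 3L))]
  if (length(v) == 0L)
    return(list(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
                n_codons = 0L, counted_bases = 0L))
  posk <- ((seq_along(v) - 1L) %% 3L) + 1L
  one <- function(k) {
    b <- v[posk == k]
    gc <- sum(b == "G" | b == "C")
    at <- sum(b == "A" | b == "T")
    if (gc + at == 0L) NA_real_ else gc / (gc + at)
  }
  list(gc1 = one(1L), gc2 = one(2L), gc3 = one(3L),
       n_codons = length(v) %/% 3L,
       counted_bases = sum(v %in% c("A", "C", "G", "T")))
}

#' Per-gene GC profile: genic, CDS and codon-position GC
#'
#' For every coding gene computes: `gc_gene`, GC over the transcription
#' start-to-stop span (exons + introns + UTRs of the representative
#' transcript); `gc_cds`, GC over the spliced coding sequence; and the
#' phase-aware codon-position fractions `gc1`/`gc2`/`gc3`.  Non-coding genes
#' appear with only `gc_gene` defined.
#'
#' @param gm a [GeneModels] object
#' @param genome a named [Biostrings::DNAStringSet]
#' @param drop_partial passed to [codonPositionGC()]
#' @return a data.frame: gene_id, gc_gene, gc_cds, gc1, gc2, gc3, n_codons,
#'   counted_bases
#' @export
gcProfile <- function(gm, genome, drop_partial = FALSE) {
  cseq <- assembleCodingSequences(gm, genome)
  n <- length(gm)
  out <- data.frame(
    gene_id = gm@genes$gene_id,
    gc_gene = NA_real_, gc_cds = NA_real_,
    gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
    n_codons = NA_integer_, counted_bases = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    span <- gm@genes[i]
    contig <- as.character(seqnames(span))
    if (contig %in% names(genome)) {
      s <- as.character(Biostrings::subseq(genome[[contig]],
                                           start(span), end(span)))
      out$gc_gene[i] <- gcFraction(s)
    }
    gid <- gm@genes$gene_id[i]
    if (gm@genes$coding[i] && gid %in% names(cseq)) {
      cs <- as.character(cseq[[gid]])
      out$gc_cds[i] <- gcFraction(cs)
      cp <- codonPositionGC(cs, gm@genes$phase_offset[i], drop_partial)
      out$gc1[i] <- cp$gc1; out$gc2[i] <- cp$gc2; out$gc3[i] <- cp$gc3
      out$n_codons[i] <- cp$n_codons
      out$counted_bases[i] <- cp$counted_bases
    }
  }
  out
}

#' Classify genes into high/low GCx classes
#'
#' A gene is high-GCx when its codon-position GC fraction meets the cutoff
#' (inclusive: `gc_x >= cutoff`, default 0.80).  Undefined fractions yield
#' `NA` labels, excluding the gene from that class tally.
#'
#' @param profile data.frame from [gcProfile()] (needs gc1, gc2, gc3)
#' @param cutoff inclusive high-class threshold, default 0.80
#' @return `profile` with logical columns high_gc1, high_gc2, high_gc3 and
#'   the cutoff stored in `attr(, "cutoff")`
#' @export
classifyGCx <- function(profile, cutoff = 0.80) {
  stopifnot(is.numeric(cutoff), cutoff > 0, cutoff <= 1)
  profile$high_gc1 <- profile$gc1 >= cutoff
  profile$high_gc2 <- profile$gc2 >= cutoff
  profile$high_gc3 <- profile$gc3 >= cutoff
  attr(profile, "cutoff") <- cutoff
  profile
}

#' Count high and low GCx genes
#'
#' @param labels data.frame with high_gc1..high_gc3 from [classifyGCx()]
#' @return data.frame with one row per codon position: gcx, n_high, n_low,
#'   n_labeled
#' @export
classCounts <- function(labels) {
  one <- function(col) {
    v <- labels[[col]]
    c(n_high = sum(v, na.rm = TRUE),
      n_low = sum(!v, na.rm = TRUE),
      n_labeled = sum(!is.na(v)))
  }
  m <- t(vapply(c("high_gc1", "high_gc2", "high_gc3"), one, numeric(3)))
  data.frame(gcx = c("GC1", "GC2", "GC3"), m, row.names = NULL)
}

#' Pairwise overlap of high-GCx classes
#'
#' Counts genes simultaneously high in each pair of codon-position classes,
#' and returns the raw fraction pairs for scatter plotting.
#'
#' @param labels data.frame from [classifyGCx()]
#' @return list with `overlap` (data.frame: pair, n_both) and `pairs`
#'   (list of two-column matrices of the raw gc fractions)
#' @export
pairwiseClassOverlap <- function(labels) {
  pr <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  both <- vapply(pr, function(p) {
    a <- labels[[paste0("high_gc", p[1])]]
    b <- labels[[paste0("high_gc", p[2])]]
    sum(a & b, na.rm = TRUE)
  }, numeric(1))
  scat <- lapply(pr, function(p) {
    cbind(labels[[paste0("gc", p[1])]], labels[[paste0("gc", p[2])]])
  })
  names(scat) <- vapply(pr, function(p) paste0("GC", p[1], "_GC", p[2]),
                        character(1))
  list(overlap = data.frame(pair = names(scat), n_both = both),
       pairs = scat)
}

#' Kernel density estimate of GC fractions
#'
#' Gaussian KDE (Scott's bandwidth rule by default, [stats::bw.nrd()]),
#' renormalised so the curve integrates to 1 over its support.
#'
#' @param values numeric GC fractions; NAs dropped
#' @param bandwidth optional numeric bandwidth (overrides Scott's rule)
#' @return the [stats::density] object (renormalised `y`)
#' @export
gcDensity <- function(values, bandwidth = NULL) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) stop("need at least 2 defined values for a density")
  bw <- if (is.null(bandwidth)) {
    b <- tryCatch(stats::bw.nrd(v), error = function(e) NA_real_)
    if (!is.finite(b) || b <= 0) "nrd0" else b
  } else bandwidth
  d <- stats::density(v, bw = bw)
  area <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  d$y <- d$y / area
  d
}

#' Degeneracy of the standard genetic code by codon position
#'
#' For each codon position k, counts the codons (of 64) for which at least
#' one substitution at position k is synonymous.  Stop codons are treated as
#' their own "amino acid" class, so a stop-to-stop change counts as
#' synonymous.  The third (wobble) position carries far more degeneracy than
#' the first or second.
#'
#' @param code named character vector mapping codons to amino-acid letters;
#'   defaults to [Biostrings::GENETIC_CODE]
#' @return named integer vector `c(pos1 =, pos2 =, pos3 =)`
#' @examples
#' degeneracyProfile()  # pos3 much larger than pos1 or pos2
#' @export
degeneracyProfile <- function(code = Biostrings::GENETIC_CODE) {
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  out <- integer(3)
  for (k in 1:3) {
    deg <- vapply(codons, function(cd) {
      v <- strsplit(cd, "")[[1]]
      any(vapply(setdiff(bases, v[k]), function(b) {
        w <- v; w[k] <- b
        code[[paste(w, collapse = "")]] == code[[cd]]
      }, logical(1)))
    }, logical(1))
    out[k] <- sum(deg)
  }
  names(out) <- paste0("pos", 1:3)
  out
}
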