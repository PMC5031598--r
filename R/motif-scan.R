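#' The default DSB hotspot motif consensus
#'
#' The degenerate 19-nt GC-rich consensus underlying maize genic meiotic
#' double-strand-break hotspots, with a near-invariant G every third base.
#' @export
DSB_MOTIF_CONSENSUS <- "GVSGRSGNSGRSGVSGRSG"

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Build a position weight matrix from a degenerate IUPAC consensus
#'
#' Each consensus position's probability mass is divided uniformly over the
#' bases its IUPAC code allows; bases the code disallows receive a small
#' pseudo-probability `epsilon` (so one mismatch is penalised but never
#' scores minus infinity), and the column is renormalised to sum to 1.
#' Scores are log2 odds against the background composition; a window's score
#' is compared to `stringency * maxScore` by [scanSeq()].
#'
#' @param consensus IUPAC string; default the 19-nt DSB hotspot consensus
#' @param background base composition (A, C, G, T); default uniform
#' @param stringency fraction of the maximum score a hit must reach,
#'   default 0.80
#' @param epsilon pseudo-probability for disallowed bases, default 1e-3
#' @return a [MotifModel]
#' @examples
#' m <- consensusToPWM("GVSGRSGNSGRSGVSGRSG")
#' width(m)     # 19
#' maxScore(m)  # attained by the all-G 19-mer
#' @export
consensusToPWM <- function(consensus = DSB_MOTIF_CONSENSUS,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           stringency = 0.80,
                           epsilon = 1e-3) {
  stopifnot(length(consensus) == 1L, nchar(consensus) >= 1L,
            length(background) == 4L, all(background > 0),
            stringency > 0, stringency <= 1, epsilon > 0, epsilon < 0.25)
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- which(!letters %in% names(.IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code '", letters[bad[1]], "' at consensus position ",
         bad[1])
  W <- length(letters)
  pwm <- matrix(0, nrow = 4, ncol = W,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(W)) {
    allowed <- .IUPAC_SETS[[letters[j]]]
    col <- rep(epsilon, 4)
    names(col) <- rownames(pwm)
    col[allowed] <- 1 / length(allowed)
    pwm[, j] <- col / sum(col)
  }
  lo <- log2(pwm / background)
  new("MotifModel",
      consensus = toupper(consensus), pwm = pwm, logOdds = lo,
      background = background,
      maxScore = sum(apply(lo, 2, max)),
      minScore = sum(apply(lo, 2, min)),
      stringency = stringency, epsilon = epsilon)
}

# integer-coded score lookup: rows A,C,G,T plus a 5th row for N/ambiguity,
# scored as the background-weighted mean of the column (the expected score
# of a background-distributed base)
.scoreMatrix <- function(model) {
  rbind(model@logOdds, colSums(model@logOdds * model@background))
}

.encode <- function(seq) {
  v <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  idx <- match(v, c("A", "C", "G", "T"))
  idx[is.na(idx)] <- 5L
  idx
}

# raw window scores for one orientation; NULL when seq shorter than motif
.windowScores <- function(idx, S) {
  W <- ncol(S)
  n <- length(idx)
  if (n < W) return(NULL)
  tot <- numeric(n - W + 1L)
  for (k in seq_len(W)) tot <- tot + S[idx[k:(n - W + k)], k]
  unname(tot)
}

#' Scan a sequence for motif hits
#'
#' Slides the motif over every window of the sequence and reports each
#' offset whose score reaches the threshold; overlapping hits are all
#' retained.  With `both_strands = TRUE` (the default) the reverse
#' complement is scanned too and minus-strand hits are reported in
#' plus-strand coordinates.  The default threshold is
#' `stringency * maxScore`; `scoring = "minmax"` instead anchors the
#' fraction to the score range, `minScore + stringency * (maxScore -
#' minScore)`.
#'
#' @param seq a character string, `DNAString`, or named list/`DNAStringSet`
#'   of contigs
#' @param model a [MotifModel] from [consensusToPWM()]
#' @param both_strands scan the reverse complement as well (default TRUE)
#' @param contig name used for `seqnames` when `seq` is a single sequence
#' @param scoring `"max"` (default) or `"minmax"` threshold anchoring
#' @return a `GRanges` of hits (1-based closed) with metadata columns
#'   `score`, `score_fraction` and `sequence` (the matched 19-mer on the hit
#'   strand); empty when the sequence is shorter than the motif
#' @export
scanSeq <- function(seq, model, both_strands = TRUE, contig = "seq",
                    scoring = c("max", "minmax")) {
  scoring <- match.arg(scoring)
  if (is(seq, "DNAStringSet") || (is.list(seq) && !is.null(names(seq)))) {
    hits <- lapply(names(seq), function(nm)
      scanSeq(seq[[nm]], model, both_strands, contig = nm, scoring = scoring))
    return(suppressWarnings(do.call(c, hits)))
  }
  s <- as.character(seq)
  W <- ncol(model@pwm)
  thr <- if (scoring == "max") model@stringency * model@maxScore
         else model@minScore + model@stringency *
              (model@maxScore - model@minScore)
  S <- .scoreMatrix(model)
  empty <- GRanges(score = numeric(0), score_fraction = numeric(0),
                   sequence = character(0))

  collect <- function(chars, strand_lab) {
    idx <- .encode(chars)
    sc <- .windowScores(idx, S)
    if (is.null(sc)) return(NULL)
    at <- which(sc >= thr)
    if (!length(at)) return(NULL)
    n <- length(idx)
    starts <- if (strand_lab == "+") at else n - at - W + 2L
    GRanges(contig, IRanges(starts, width = W), strand = strand_lab,
            score = sc[at],
            score_fraction = sc[at] / model@maxScore,
            sequence = substring(chars, at, at + W - 1L))
  }

  fwd <- collect(s, "+")
  rev <- if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    collect(rc, "-")
  } else NULL
  parts <- Filter(Negate(is.null), list(fwd, rev))
  if (!length(parts)) return(empty)
  out <- if (length(parts) == 1L) parts[[1]]
         else suppressWarnings(c(parts[[1]], parts[[2]]))
  sort(out, ignore.strand = TRUE)
}

#' Locate motif hits within gene models
#'
#' Assigns each hit the region class of its leftmost genomic base (CDS,
#' UTR5, UTR3, INTRON or INTERGENIC), and — when the full hit lies within a
#' single CDS segment so its bases are consecutive in the spliced coding
#' sequence — the hit's coding-sequence offset and codon frame.  A hit that
#' starts in CDS but runs past the segment keeps region CDS with no frame
#' and `split = TRUE`.  A hit overlapping several genes yields one row per
#' gene with `multi_gene = TRUE`.
#'
#' @param hits `GRanges` from [scanSeq()]
#' @param gm a [GeneModels] object
#' @return `hits` with added metadata columns `gene_id`, `region`,
#'   `cds_offset` (0-based position of the motif's first base in the spliced
#'   coding sequence), `codon_frame` (1..3 or NA), `split`, `multi_gene`
#' @export
localizeHits <- function(hits, gm) {
  genes <- gm@genes
  ov <- GenomicRanges::findOverlaps(
    GRanges(seqnames(hits), IRanges(start(hits), width = 1L)),
    granges(genes), ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keepNoGene <- setdiff(seq_along(hits), qh)

  rows <- c(qh, keepNoGene)
  out <- hits[rows]
  out$gene_id <- c(genes$gene_id[sh], rep(NA_character_, length(keepNoGene)))
  out$region <- factor(rep("INTERGENIC", length(out)),
                       levels = c("CDS", "UTR5", "UTR3", "INTRON",
                                  "INTERGENIC"))
  out$cds_offset <- rep(NA_integer_, length(out))
  out$codon_frame <- rep(NA_integer_, length(out))
  out$split <- rep(FALSE, length(out))
  multi <- table(qh)
  out$multi_gene <- c(as.integer(multi[as.character(qh)]) > 1L,
                      rep(FALSE, length(keepNoGene)))

  for (r in seq_along(qh)) {
    h <- hits[qh[r]]
    gi <- sh[r]
    reg <- as.character(classifyPosition(gm, genes$gene_id[gi], start(h)))
    out$region[r] <- reg
    if (reg != "CDS" || !genes$coding[gi]) next
    segs <- gm@cds[[gi]]
    within <- which(start(h) >= start(segs) & end(h) <= end(segs))
    if (!length(within)) {
      out$split[r] <- TRUE
      next
    }
    k <- within[1]
    prior <- if (k > 1L) sum(width(segs)[seq_len(k - 1L)]) else 0L
    minus_gene <- as.character(strand(segs)[1]) == "-"
    # genomic position of the motif's first base on its own strand
    first <- if (as.character(strand(h)) == "-") end(h) else start(h)
    off <- if (minus_gene) prior + (end(segs)[k] - first)
           else prior + (first - start(segs)[k])
    out$cds_offset[r] <- as.integer(off)
    out$codon_frame[r] <- assignCodonFrame(off, genes$phase_offset[gi])
  }
  out
}

#' Codon frame of a motif's first base
#'
#' Frame 1 means the motif's first base occupies a codon's first position.
#'
#' @param cds_offset 0-based offset of the motif's first base in the spliced
#'   coding sequence
#' @param phase_offset the gene's coding phase offset (0..2)
#' @return integer in 1..3, or NA for NA input
#' @examples
#' assignCodonFrame(0, 0)  # 1
#' assignCodonFrame(4, 0)  # 2
#' @export
assignCodonFrame <- function(cds_offset, phase_offset = 0L) {
  ifelse(is.na(cds_offset) | is.na(phase_offset), NA_integer_,
         ((cds_offset - phase_offset) %% 3L) + 1L)
}

#' Motif counts per gene
#'
#' Tabulates hit counts per motif-containing gene, the
#' frequency-of-frequencies histogram, the weighted total of motifs and the
#' fraction of genes carrying more than one instance.
#'
#' @param hits localized hits (`GRanges` with `gene_id`), or a data.frame
#'   with a `gene_id` column; rows with NA gene_id are ignored
#' @return list: `per_gene` (data.frame gene_id, n_motifs), `histogram`
#'   (data.frame motifs_per_gene, n_genes), `total_motifs`,
#'   `frac_multi` (fraction of motif genes with >= 2 hits)
#' @export
perGeneCounts <- function(hits) {
  gid <- if (is(hits, "GRanges")) hits$gene_id else hits$gene_id
  gid <- gid[!is.na(gid)]
  tb <- table(gid)
  per_gene <- data.frame(gene_id = names(tb), n_motifs = as.integer(tb),
                         stringsAsFactors = FALSE)
  hh <- table(factor(as.integer(tb)))
  histogram <- data.frame(motifs_per_gene = as.integer(names(hh)),
                          n_genes = as.integer(hh))
  summariseMotifHistogram(histogram)
}

#' Summary statistics of a motifs-per-gene histogram
#'
#' @param histogram data.frame with columns `motifs_per_gene`, `n_genes`
#' @return list: `histogram`, `per_gene` (NULL if not derivable),
#'   `total_motifs` = sum(count x genes), `n_genes` and `frac_multi`
#' @export
summariseMotifHistogram <- function(histogram) {
  stopifnot(all(c("motifs_per_gene", "n_genes") %in% names(histogram)))
  tot <- sum(histogram$motifs_per_gene * histogram$n_genes)
  ng <- sum(histogram$n_genes)
  multi <- sum(histogram$n_genes[histogram$motifs_per_gene >= 2])
  list(histogram = histogram,
       total_motifs = tot,
       n_genes = ng,
       frac_multi = if (ng > 0) multi / ng else NA_real_)
}

#' Chi-square test for CDS preference of genic motif hits
#'
#' Tests whether genic hits split between CDS and non-CDS (intron/UTR)
#' sequence in proportion to the base composition of genes: the expected
#' split of the `n_cds_hits + n_other_hits` genic hits is proportional to
#' `cds_bases : other_bases`.  1-df goodness of fit, two-sided, no
#' continuity correction.
#'
#' @param n_cds_hits,n_other_hits observed hit counts
#' @param cds_bases,other_bases total genomic bases of each region class
#'   (any common unit)
#' @return a [ContingencyResult]
#' @export
cdsPreferenceTest <- function(n_cds_hits, n_other_hits,
                              cds_bases, other_bases) {
  stopifnot(cds_bases > 0, other_bases > 0)
  gofChisq(n_cds_hits, n_other_hits, cds_bases, other_bases)
}
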