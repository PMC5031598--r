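#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' GeneModels: phase-aware gene models for codon-position GC analysis
#'
#' One representative transcript per locus, with CDS segments held in
#' transcription order so that spliced coding sequence and codon frames are
#' well defined.  Constructed by [readAnnotation()].
#'
#' @slot genes a [GenomicRanges::GRanges] with one range per gene (the
#'   transcription-start to transcription-stop span) and metadata columns
#'   `gene_id`, `tx_id`, `coding` (logical), `phase_offset` (phase of the
#'   first retained CDS base, 0/1/2), `n_cds` and `cds_len`.
#' @slot cds a [GenomicRanges::GRangesList] parallel to `genes`: the retained
#'   CDS segments of the representative transcript in transcription order
#'   (reversed for minus-strand genes), overlaps merged.
#' @slot exons,utr5,utr3 `GRangesList`s parallel to `genes` with the exon and
#'   UTR segments (possibly empty per gene).
#'
#' @seealso [readAnnotation()], [assembleCodingSequences()],
#'   [classifyPosition()]
#' @export
setClass("GeneModels",
  representation(
    genes = "GRanges",
    cds   = "GRangesList",
    exons = "GRangesList",
    utr5  = "GRangesList",
    utr3  = "GRangesList"
  )
)

setValidity("GeneModels", function(object) {
  n <- length(object@genes)
  msg <- character(0)
  for (sl in c("cds", "exons", "utr5", "utr3"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, sprintf("slot '%s' not parallel to 'genes'", sl))
  need <- c("gene_id", "coding", "phase_offset")
  if (!all(need %in% names(mcols(object@genes))))
    msg <- c(msg, "genes must carry gene_id, coding, phase_offset")
  po <- object@genes$phase_offset
  if (any(!is.na(po) & !(po %in% 0:2)))
    msg <- c(msg, "phase_offset must be in {0,1,2}")
  # a genomic base may enter the coding sequence at most once
  ovl <- vapply(seq_len(n), function(i) {
    cd <- object@cds[[i]]
    length(cd) > 1L &&
      any(IRanges::overlapsAny(cd, drop.self = TRUE, drop.redundant = TRUE))
  }, logical(1))
  if (any(ovl))
    msg <- c(msg, "overlapping CDS segments within a gene after merging")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModels number of gene models
#' @param x,object a `GeneModels` object
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels gene identifiers
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels
#' @export
setMethod("geneIds", "GeneModels", function(x) x@genes$gene_id)

#' @describeIn GeneModels gene spans as a `GRanges`
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModels
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)

#' @describeIn GeneModels CDS segments per gene, transcription order
#' @export
setGeneric("cdsByGene", function(x) standardGeneric("cdsByGene"))

#' @rdname GeneModels
#' @export
setMethod("cdsByGene", "GeneModels", function(x) {
  y <- x@cds
  names(y) <- x@genes$gene_id
  y
})

#' @describeIn GeneModels phase of the first retained CDS base per gene
#' @export
setGeneric("phaseOffset", function(x) standardGeneric("phaseOffset"))

#' @rdname GeneModels
#' @export
setMethod("phaseOffset", "GeneModels", function(x) {
  stats::setNames(x@genes$phase_offset, x@genes$gene_id)
})

#' @rdname GeneModels
#' @param i index or gene-id character vector
#' @export
setMethod("[", "GeneModels", function(x, i) {
  if (is.character(i)) i <- match(i, x@genes$gene_id)
  initialize(x,
    genes = x@genes[i], cds = x@cds[i], exons = x@exons[i],
    utr5 = x@utr5[i], utr3 = x@utr3[i])
})

setMethod("show", "GeneModels", function(object) {
  n <- length(object)
  nc <- sum(object@genes$coding)
  cat(sprintf("GeneModels with %d gene(s) (%d coding) on %d contig(s)\n",
              n, nc, length(unique(as.character(seqnames(object@genes))))))
  if (n) {
    cat(sprintf("  total CDS length: %d nt; phase offsets: %s\n",
                sum(object@genes$cds_len, na.rm = TRUE),
                paste(names(table(object@genes$phase_offset)),
                      table(object@genes$phase_offset),
                      sep = ":", collapse = " ")))
  }
  invisible(NULL)
})

#' MotifModel: a degenerate consensus turned into a scoring matrix
#'
#' Holds the IUPAC consensus, the per-position probability matrix (uniform
#' mass over the bases each code allows, with a small pseudo-probability on
#' disallowed bases), the log2 odds against a background composition, and the
#' attainable score range used to express the scan stringency as a fraction
#' of the maximum score.  Constructed by [consensusToPWM()].
#'
#' @slot consensus single IUPAC string (default motif is the 19-nt DSB
#'   hotspot consensus `GVSGRSGNSGRSGVSGRSG`)
#' @slot pwm 4 x W probability matrix, rows A,C,G,T; columns sum to 1
#' @slot logOdds 4 x W log2-odds score matrix
#' @slot background length-4 base composition the odds are taken against
#' @slot maxScore,minScore attainable per-window score range
#' @slot stringency fraction of `maxScore` a window must reach, in (0, 1]
#' @slot epsilon pseudo-probability given to bases the consensus disallows
#' @export
setClass("MotifModel",
  representation(
    consensus  = "character",
    pwm        = "matrix",
    logOdds    = "matrix",
    background = "numeric",
    maxScore   = "numeric",
    minScore   = "numeric",
    stringency = "numeric",
    epsilon    = "numeric"
  )
)

setValidity("MotifModel", function(object) {
  msg <- character(0)
  if (length(object@consensus) != 1L || !nzchar(object@consensus))
    msg <- c(msg, "consensus must be a single non-empty string")
  if (nrow(object@pwm) != 4L || ncol(object@pwm) != nchar(object@consensus))
    msg <- c(msg, "pwm must be 4 x nchar(consensus)")
  if (any(abs(colSums(object@pwm) - 1) > 1e-9))
    msg <- c(msg, "pwm columns must each sum to 1")
  if (object@stringency <= 0 || object@stringency > 1)
    msg <- c(msg, "stringency must lie in (0, 1]")
  if (abs(object@maxScore - sum(apply(object@logOdds, 2, max))) > 1e-9)
    msg <- c(msg, "maxScore must equal the sum of per-position maxima")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifModel motif width in nucleotides
#' @param x,object a `MotifModel`
#' @export
setMethod("width", "MotifModel", function(x) ncol(x@pwm))

#' @describeIn MotifModel the IUPAC consensus string
#' @export
setGeneric("consensus", function(x, ...) standardGeneric("consensus"))

#' @rdname MotifModel
#' @param ... ignored
#' @export
setMethod("consensus", "MotifModel", function(x, ...) x@consensus)

#' @describeIn MotifModel the probability matrix
#' @export
setGeneric("pwm", function(x) standardGeneric("pwm"))

#' @rdname MotifModel
#' @export
setMethod("pwm", "MotifModel", function(x) x@pwm)

#' @describeIn MotifModel maximum attainable window score
#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))

#' @rdname MotifModel
#' @export
setMethod("maxScore", "MotifModel", function(x) x@maxScore)

#' @describeIn MotifModel the fractional score threshold
#' @export
setGeneric("stringency", function(x) standardGeneric("stringency"))

#' @rdname MotifModel
#' @export
setMethod("stringency", "MotifModel", function(x) x@stringency)

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel %s (width %d)\n", object@consensus,
              ncol(object@pwm)))
  cat(sprintf("  score range [%.3f, %.3f]; stringency %.2f (threshold %.3f)\n",
              object@minScore, object@maxScore, object@stringency,
              object@stringency * object@maxScore))
  invisible(NULL)
})

#' ContingencyResult: one goodness-of-fit chi-square outcome
#'
#' A two-cell observed/expected comparison against genome-wide proportions:
#' expected counts carried at full precision (never the rounded values a
#' report would print), Pearson chi-square on 1 df, two-sided upper-tail p.
#'
#' @slot observed named numeric of length 2 (`yes`, `no`)
#' @slot expected named numeric of length 2, full precision
#' @slot statistic Pearson chi-square statistic
#' @slot df degrees of freedom (1)
#' @slot p.value upper-tail probability
#' @export
setClass("ContingencyResult",
  representation(
    observed  = "numeric",
    expected  = "numeric",
    statistic = "numeric",
    df        = "numeric",
    p.value   = "numeric"
  )
)

setValidity("ContingencyResult", function(object) {
  msg <- character(0)
  if (length(object@observed) != 2L || length(object@expected) != 2L)
    msg <- c(msg, "observed and expected must have length 2")
  if (abs(sum(object@expected) - sum(object@observed)) > 1e-9)
    msg <- c(msg, "expected must sum to the observed total")
  if (object@statistic < 0) msg <- c(msg, "chi-square must be >= 0")
  if (object@p.value < 0 || object@p.value > 1)
    msg <- c(msg, "p must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Format a p-value, flooring display at 1e-300
#'
#' Probabilities below the double-precision floor are shown as `< 1e-300`,
#' mirroring how vanishing chi-square tails are reported.
#'
#' @param p numeric vector of probabilities
#' @return character vector
#' @export
formatPValue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-300, "< 1e-300", format(p, digits = 6)))
}

setMethod("show", "ContingencyResult", function(object) {
  cat("Goodness-of-fit chi-square (two-sided, df = 1)\n")
  cat(sprintf("  observed: %s = %g, %s = %g\n",
              names(object@observed)[1], object@observed[1],
              names(object@observed)[2], object@observed[2]))
  cat(sprintf("  expected: %.4f, %.4f\n",
              object@expected[1], object@expected[2]))
  cat(sprintf("  X-squared = %.4f, p = %s\n", object@statistic,
              formatPValue(object@p.value)))
  invisible(NULL)
})

#' @describeIn ContingencyResult the p-value
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname ContingencyResult
#' @param x a `ContingencyResult`
#' @export
setMethod("pValue", "ContingencyResult", function(x) x@p.value)

#' @describeIn ContingencyResult observed counts
#' @export
setGeneric("observedCounts", function(x) standardGeneric("observedCounts"))

#' @rdname ContingencyResult
#' @export
setMethod("observedCounts", "ContingencyResult", function(x) x@observed)

#' @describeIn ContingencyResult expected counts at full precision
#' @export
setGeneric("expectedCounts", function(x) standardGeneric("expectedCounts"))

#' @rdname ContingencyResult
#' @export
setMethod("expectedCounts", "ContingencyResult", function(x) x@expected)
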