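#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]: record names are
#' truncated at the first whitespace, sequences are held uppercase
#' (soft-masked lowercase becomes its uppercase nucleotide), and duplicate
#' contig ids are an error.
#'
#' @param path path to a (multi-record) FASTA file
#' @return a named [Biostrings::DNAStringSet], one entry per record in file
#'   order
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig id(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

# CDS phases implied by segment lengths, assuming the first retained base
# starts a codon (phase 0); used only when the GFF3 phase column is missing.
.inferPhases <- function(widths) {
  (3L - (cumsum(c(0L, widths[-length(widths)])) %% 3L)) %% 3L
}

# transcription-order sort: ascending start on +, descending on -
.txOrder <- function(gr) {
  if (length(gr) == 0L) return(gr)
  neg <- as.character(strand(gr)[1]) == "-"
  gr[order(start(gr), decreasing = neg)]
}

#' Read a GFF3 annotation into gene models
#'
#' Parses a GFF3 file (via [rtracklayer::import()]) into one [GeneModels]
#' object with one representative transcript per gene: the transcript with
#' the longest total CDS, ties broken by the lexicographically smallest
#' transcript ID.  Within the chosen transcript, overlapping CDS intervals
#' are merged so no genomic base can enter the coding sequence twice; the
#' coding phase offset is the phase of the first CDS base in transcription
#' order.  Genes without CDS are retained but flagged non-coding (and are
#' excluded from codon-position GC analyses downstream).
#'
#' UTRs are taken from `five_prime_UTR`/`three_prime_UTR` features when
#' annotated; otherwise exonic sequence outside the CDS span is classed as
#' 5' or 3' UTR by its position relative to the CDS on the coding strand.
#'
#' @param path path to a GFF3 file with gene/mRNA/CDS (optionally exon, UTR)
#'   features; CDS phase read from column 8, inferred from segment lengths
#'   (first segment phase 0) when absent
#' @return a [GeneModels] object
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  type <- as.character(g$type)
  feat_id <- as.character(g$ID)
  parent1 <- function(gr) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  }

  genes <- g[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gene_ids <- as.character(genes$ID)
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in ", path)

  tx <- g[type %in% c("mRNA", "transcript")]
  tx_ids <- as.character(tx$ID)
  tx_gene <- parent1(tx)

  cds <- g[type == "CDS"]
  exon <- g[type == "exon"]
  u5 <- g[type == "five_prime_UTR"]
  u3 <- g[type == "three_prime_UTR"]

  # CDS may name several parent transcripts; expand to one row per parent
  # and index rows by parent id so per-gene lookups stay cheap
  expandByParent <- function(gr) {
    if (length(gr) == 0L)
      return(list(gr = gr, parent = character(0), by = list()))
    np <- lengths(gr$Parent)
    idx <- rep(seq_along(gr), np)
    parent <- unlist(gr$Parent)
    list(gr = gr[idx], parent = parent,
         by = split(seq_along(parent), parent))
  }
  rowsOf <- function(x, ids) unlist(x$by[ids], use.names = FALSE)
  cdsx <- expandByParent(cds)
  exonx <- expandByParent(exon)
  u5x <- expandByParent(u5)
  u3x <- expandByParent(u3)
  cds_w <- width(cdsx$gr)
  tx_cds_len <- vapply(cdsx$by, function(i) sum(cds_w[i]), numeric(1))

  cds_list <- vector("list", length(genes))
  exon_list <- vector("list", length(genes))
  u5_list <- vector("list", length(genes))
  u3_list <- vector("list", length(genes))
  phase_off <- integer(length(genes))
  tx_sel <- character(length(genes))
  coding <- logical(length(genes))
  empty <- GRanges()

  for (i in seq_along(genes)) {
    gid <- gene_ids[i]
    cand <- tx_ids[tx_gene == gid]
    pick_cds <- empty
    if (length(cand)) {
      lens <- tx_cds_len[cand]
      lens[is.na(lens)] <- 0
      cand <- cand[order(-lens, cand)]
      tx_sel[i] <- cand[1]
      pick_cds <- cdsx$gr[rowsOf(cdsx, cand[1])]
    } else if (gid %in% names(cdsx$by)) {
      # tolerate CDS attached directly to the gene feature
      tx_sel[i] <- gid
      pick_cds <- cdsx$gr[rowsOf(cdsx, gid)]
    } else {
      tx_sel[i] <- NA_character_
    }

    if (length(pick_cds) == 0L) {
      coding[i] <- FALSE
      phase_off[i] <- NA_integer_
      cds_list[[i]] <- empty
    } else {
      coding[i] <- TRUE
      pick_cds <- .txOrder(pick_cds)
      ph <- pick_cds$phase
      if (all(is.na(ph))) {
        ph <- .inferPhases(width(pick_cds))
        warning("gene ", gid, ": CDS phase missing, inferred from segment ",
                "lengths (first segment phase 0)", call. = FALSE)
      } else if (anyNA(ph)) {
        stop("gene ", gid, ": some CDS segments lack phase")
      }
      phase_off[i] <- as.integer(ph[1])
      # merge overlaps (tolerated, should not occur in valid GFF3);
      # reduce() preserves nothing, so re-sort to transcription order
      merged <- .txOrder(GenomicRanges::reduce(pick_cds))
      if (length(merged) != length(pick_cds))
        warning("gene ", gid, ": overlapping CDS segments merged",
                call. = FALSE)
      mcols(merged) <- NULL
      cds_list[[i]] <- merged
    }

    gx <- exonx$gr[rowsOf(exonx, c(tx_sel[i], gid))]
    mcols(gx) <- NULL
    exon_list[[i]] <- .txOrder(gx)
    g5 <- u5x$gr[rowsOf(u5x, c(tx_sel[i], gid))]
    g3 <- u3x$gr[rowsOf(u3x, c(tx_sel[i], gid))]
    mcols(g5) <- NULL
    mcols(g3) <- NULL

    if (length(g5) == 0L && length(g3) == 0L && coding[i] &&
        length(exon_list[[i]])) {
      # derive UTRs as exonic sequence outside the CDS span, sided by strand
      cspan <- range(cds_list[[i]])
      ex_nc <- GenomicRanges::setdiff(exon_list[[i]], cspan,
                                      ignore.strand = TRUE)
      if (length(ex_nc)) {
        strand(ex_nc) <- strand(genes[i])
        upstream <- end(ex_nc) < start(cspan)
        if (as.character(strand(genes[i])) == "-") upstream <- !upstream
        g5 <- ex_nc[upstream]
        g3 <- ex_nc[!upstream]
      }
    }
    u5_list[[i]] <- g5
    u3_list[[i]] <- g3
  }

  gr <- granges(genes)
  mcols(gr) <- DataFrame(
    gene_id = gene_ids,
    tx_id = tx_sel,
    coding = coding,
    phase_offset = phase_off,
    n_cds = lengths(cds_list),
    cds_len = vapply(cds_list, function(x) sum(width(x)), numeric(1))
  )
  new("GeneModels",
      genes = gr,
      cds = GRangesList(cds_list, compress = TRUE),
      exons = GRangesList(exon_list, compress = TRUE),
      utr5 = GRangesList(u5_list, compress = TRUE),
      utr3 = GRangesList(u3_list, compress = TRUE))
}

#' Assemble spliced coding sequences
#'
#' Splices each gene's retained CDS segments in transcription order
#' (reverse-complementing minus-strand genes) into the sequence that
#' contributes to the protein.  The first `phase_offset` bases of the result
#' belong to no complete codon and are dropped by codon framing downstream.
#'
#' @param gm a [GeneModels] object
#' @param genome a named [Biostrings::DNAStringSet] as from [readGenome()]
#' @return a named `DNAStringSet` over the coding genes of `gm`
#' @export
assembleCodingSequences <- function(gm, genome) {
  stopifnot(is(gm, "GeneModels"), is(genome, "DNAStringSet"))
  keep <- which(gm@genes$coding)
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    segs <- gm@cds[[i]]
    contig <- as.character(seqnames(segs)[1])
    if (!contig %in% names(genome))
      stop("contig '", contig, "' not in genome")
    clen <- length(genome[[contig]])
    if (any(end(segs) > clen) || any(start(segs) < 1L))
      stop("gene ", gm@genes$gene_id[i], ": CDS segment exceeds contig '",
           contig, "' bounds")
    pieces <- Biostrings::DNAStringSet(genome[[contig]],
                                       start = start(segs), end = end(segs))
    if (as.character(strand(segs)[1]) == "-")
      pieces <- Biostrings::reverseComplement(pieces)
    out[[j]] <- Biostrings::DNAString(paste(as.character(pieces),
                                            collapse = ""))
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- gm@genes$gene_id[keep]
  res
}

#' Classify a genomic position relative to a gene model
#'
#' @param gm a [GeneModels] object
#' @param gene_id a gene identifier present in `gm`
#' @param pos 1-based genomic position(s) on the gene's contig
#' @return factor with levels CDS, UTR5, UTR3, INTRON, INTERGENIC
#' @export
classifyPosition <- function(gm, gene_id, pos) {
  i <- match(gene_id, gm@genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  span <- gm@genes[i]
  lv <- c("CDS", "UTR5", "UTR3", "INTRON", "INTERGENIC")
  inAny <- function(gr, p) {
    length(gr) > 0L && any(p >= start(gr) & p <= end(gr))
  }
  res <- vapply(pos, function(p) {
    if (p < start(span) || p > end(span)) return("INTERGENIC")
    if (inAny(gm@cds[[i]], p)) return("CDS")
    if (inAny(gm@utr5[[i]], p)) return("UTR5")
    if (inAny(gm@utr3[[i]], p)) return("UTR3")
    "INTRON"
  }, character(1))
  factor(res, levels = lv)
}

#' Summarise gene models as a table
#'
#' @param gm a [GeneModels] object
#' @return a data.frame with one row per gene: gene_id, contig, strand,
#'   coding flag, number of CDS segments, total CDS length, phase offset
#' @export
geneModelTable <- function(gm) {
  data.frame(
    gene_id = gm@genes$gene_id,
    contig = as.character(seqnames(gm@genes)),
    strand = as.character(strand(gm@genes)),
    coding = gm@genes$coding,
    n_cds = gm@genes$n_cds,
    cds_len = gm@genes$cds_len,
    phase_offset = gm@genes$phase_offset,
    stringsAsFactors = FALSE
  )
}

#' Write motif hits as BED6
#'
#' Converts 1-based closed hit ranges to BED's 0-based half-open convention;
#' the score column is `1000 * score_fraction` rounded to integer.
#'
#' @param hits a `GRanges` of motif hits as from [scanSeq()]
#' @param path output path
#' @return the path, invisibly
#' @export
writeHitsBed <- function(hits, path) {
  df <- data.frame(
    chrom = as.character(seqnames(hits)),
    chromStart = start(hits) - 1L,
    chromEnd = end(hits),
    name = if (!is.null(hits$gene_id)) hits$gene_id
           else paste0("hit", seq_along(hits)),
    score = as.integer(round(1000 * hits$score_fraction)),
    strand = as.character(strand(hits))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
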