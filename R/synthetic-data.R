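#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic genome
#' generator.  Defaults mirror the structure of the maize study system:
#' gene-class proportions from the genome-wide high/low GCx tabulation
#' (high-GC1 0.0920, high-GC2 0.0159, high-GC3 0.1442, rest low), a high
#' peak at 0.90 GC probability at the designated codon position, low-class
#' peaks at 0.50 (positions 1 and 3) and 0.45 (position 2), 0.45 at
#' non-designated positions of high genes, introns and UTRs at 0.40,
#' intergenic spacers at 0.35.  Motif plantings default to a geometric
#' per-gene count truncated at 16, enrichment odds of 5 toward high-GCx
#' genes, and the observed genic frame split (0.369/0.165/0.466).
#' Expression-label fractions default to the genome-wide differential
#' expression class sizes, with odds 0.3 of up-regulation for
#' motif-containing genes (down-regulation unbiased by motifs, high-GCx
#' genes biased toward down, odds 2.5, and away from up, odds 0.4).
#'
#' @param seed integer random seed (mandatory; every simulation call is a
#'   deterministic function of the config)
#' @param n_genes number of genes to simulate
#' @param class_props named proportions (high1, high2, high3, low), must sum
#'   to 1
#' @param gc_high,gc_other,gc_low_pos GC probabilities: designated position
#'   of a high gene; other positions of a high gene; the three positions of
#'   a low gene
#' @param intron_gc,utr_gc,intergenic_gc GC probability of non-coding
#'   sequence
#' @param codons_range,n_exons_range,intron_len_range,utr_len_range,intergenic_len_range
#'   integer ranges sampled uniformly
#' @param genes_per_contig genes laid out per contig
#' @param motif_consensus,motif_stringency passed to [consensusToPWM()]
#' @param motif_gene_prob_low probability a low-GCx gene carries motifs
#' @param motif_enrichment_odds odds ratio of motif carriage for high-GCx vs
#'   low genes
#' @param motif_count_p,motif_count_max truncated-geometric per-gene count
#'   distribution (support 1..max)
#' @param frame_probs planting probabilities of codon frames 1..3
#' @param consensus_max plant the maximal-scoring sequence instead of PWM
#'   samples
#' @param expressed_frac,up_frac,down_frac expression-label fractions;
#'   `up_frac`/`down_frac` are named per comparison tissue
#' @param motif_up_odds,motif_down_odds,high_up_odds,high_down_odds odds
#'   multipliers linking labels to motif carriage and high-GCx class
#' @return a validated list of class `SimulationConfig`
#' @export
simulationConfig <- function(seed,
    n_genes = 500L,
    class_props = c(high1 = 3647, high2 = 629, high3 = 5719,
                    low = 39656 - 3647 - 629 - 5719) / 39656,
    gc_high = 0.90,
    gc_other = 0.45,
    gc_low_pos = c(0.50, 0.45, 0.50),
    intron_gc = 0.40,
    utr_gc = 0.40,
    intergenic_gc = 0.35,
    codons_range = c(100L, 400L),
    n_exons_range = c(1L, 4L),
    intron_len_range = c(60L, 180L),
    utr_len_range = c(30L, 120L),
    intergenic_len_range = c(100L, 300L),
    genes_per_contig = 25L,
    motif_consensus = DSB_MOTIF_CONSENSUS,
    motif_stringency = 0.80,
    motif_gene_prob_low = 0.05,
    motif_enrichment_odds = 5,
    motif_count_p = 0.25,
    motif_count_max = 16L,
    frame_probs = c(868, 389, 1094) / (868 + 389 + 1094),
    consensus_max = FALSE,
    expressed_frac = 0.61,
    up_frac = c(anther = 189, seedling = 3236) / 39656,
    down_frac = c(anther = 232, seedling = 4140) / 39656,
    motif_up_odds = 0.3,
    motif_down_odds = 1,
    high_up_odds = 0.4,
    high_down_odds = 2.5) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  stopifnot(abs(sum(cfg$class_props) - 1) < 1e-9,
            all(cfg$class_props >= 0),
            all(c(gc_high, gc_other, gc_low_pos, intron_gc, utr_gc,
                  intergenic_gc) >= 0),
            all(c(gc_high, gc_other, gc_low_pos, intron_gc, utr_gc,
                  intergenic_gc) <= 1),
            length(gc_low_pos) == 3L,
            abs(sum(frame_probs) - 1) < 1e-9,
            motif_count_p > 0, motif_count_p < 1,
            motif_count_max >= 1L,
            n_genes >= 1L)
  if (3L * codons_range[1] < nchar(motif_consensus) + 3L)
    stop("shortest CDS cannot hold the motif")
  class(cfg) <- "SimulationConfig"
  cfg
}

# sample one base with given GC probability (G/C then A/T split evenly)
.sampleBases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

.STOPS <- c("TAA", "TAG", "TGA")

# sample body codons with per-position GC probabilities, rejecting stops
.sampleCodons <- function(n, gc3probs) {
  draw <- function(m) paste0(.sampleBases(m, gc3probs[1]),
                             .sampleBases(m, gc3probs[2]),
                             .sampleBases(m, gc3probs[3]))
  out <- draw(n)
  bad <- out %in% .STOPS
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out %in% .STOPS
  }
  out
}

# split total length into k segments, each >= minlen
.splitLen <- function(total, k, minlen = 30L) {
  if (k == 1L) return(total)
  while (k > 1L && total < k * minlen) k <- k - 1L
  if (k == 1L) return(total)
  cuts <- sort(sample(seq_len(total - k * minlen + k - 1L), k - 1L))
  w <- diff(c(0L, cuts, total - k * minlen + k - 1L + 1L)) - 1L + minlen
  w[length(w)] <- total - sum(w[-length(w)])
  w
}

#' Simulate a synthetic genome with known GCx classes
#'
#' Draws each gene's class from `class_props`, samples its codons
#' independently with the class's per-position GC probabilities (stop
#' codons rejected in the body, one appended at the end), splits the CDS
#' across exons at arbitrary base boundaries (so downstream CDS phases are
#' exercised), adds UTRs, introns and intergenic spacers of their own GC
#' composition, and lays genes out on contigs on both strands.  Everything
#' is a deterministic function of the config (including its seed).
#'
#' @param config a `SimulationConfig` from [simulationConfig()]
#' @return list of class `GCxSimulation`: `genome` (DNAStringSet),
#'   `annotation` (GFF3-shaped `GRanges` with type/ID/Parent/phase),
#'   `truth` (per-gene data.frame: gene_id, class, strand, n_codons,
#'   n_exons, cds_len), `motifs` (NULL until [plantMotifs()]), `config`
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ng <- config$n_genes
  cls <- sample(names(config$class_props), ng, replace = TRUE,
                prob = config$class_props)
  strands <- sample(c("+", "-"), ng, replace = TRUE)
  contig_of <- ceiling(seq_len(ng) / config$genes_per_contig)
  contig_ids <- paste0("ctg", sprintf("%03d", unique(contig_of)))

  runi <- function(rg) sample(seq(rg[1], rg[2]), 1L)

  contig_seq <- stats::setNames(vector("list", length(unique(contig_of))),
                                contig_ids)
  for (nm in contig_ids) contig_seq[[nm]] <- character(0)
  contig_len <- stats::setNames(integer(length(contig_ids)), contig_ids)

  gff <- list()
  truth <- data.frame(gene_id = sprintf("gene%04d", seq_len(ng)),
                      class = cls, strand = strands,
                      contig = contig_ids[contig_of],
                      n_codons = NA_integer_, n_exons = NA_integer_,
                      cds_len = NA_integer_, stringsAsFactors = FALSE)

  for (i in seq_len(ng)) {
    gid <- truth$gene_id[i]
    ctg <- truth$contig[i]
    gc3 <- if (cls[i] == "low") config$gc_low_pos else {
      v <- rep(config$gc_other, 3)
      v[as.integer(substring(cls[i], 5))] <- config$gc_high
      v
    }
    n_codons <- runi(config$codons_range)
    body <- paste(.sampleCodons(n_codons, gc3), collapse = "")
    cds_seq <- paste0(body, sample(.STOPS, 1L))
    cds_len <- nchar(cds_seq)
    n_ex <- runi(config$n_exons_range)
    seg_w <- .splitLen(cds_len, n_ex)
    n_ex <- length(seg_w)
    u5 <- paste(.sampleBases(runi(config$utr_len_range), config$utr_gc),
                collapse = "")
    u3 <- paste(.sampleBases(runi(config$utr_len_range), config$utr_gc),
                collapse = "")
    introns <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(j)
        paste(.sampleBases(runi(config$intron_len_range), config$intron_gc),
              collapse = ""), character(1))
    else character(0)

    # sense-orientation layout, then local 1-based sense coordinates
    seg_seqs <- substring(cds_seq, cumsum(c(1L, seg_w[-n_ex])),
                          cumsum(seg_w))
    parts <- character(0)
    sense_cds <- matrix(0L, nrow = n_ex, ncol = 2)
    pos <- 1L
    parts <- c(parts, u5); pos <- pos + nchar(u5)
    for (j in seq_len(n_ex)) {
      sense_cds[j, ] <- c(pos, pos + seg_w[j] - 1L)
      parts <- c(parts, seg_seqs[j]); pos <- pos + seg_w[j]
      if (j < n_ex) { parts <- c(parts, introns[j]); pos <- pos + nchar(introns[j]) }
    }
    parts <- c(parts, u3)
    sense_seq <- paste(parts, collapse = "")
    glen <- nchar(sense_seq)
    u5_iv <- c(1L, nchar(u5))
    u3_iv <- c(glen - nchar(u3) + 1L, glen)

    spacer <- paste(.sampleBases(runi(config$intergenic_len_range),
                                 config$intergenic_gc), collapse = "")
    gstart <- contig_len[ctg] + nchar(spacer) + 1L
    if (strands[i] == "-") {
      sense_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sense_seq)))
      flip <- function(iv) c(gstart + glen - iv[2], gstart + glen - iv[1])
      cds_g <- t(apply(sense_cds, 1, function(iv)
        c(gstart + glen - iv[2], gstart + glen - iv[1])))
      u5_g <- flip(u5_iv); u3_g <- flip(u3_iv)
    } else {
      shift <- function(iv) c(gstart + iv[1] - 1L, gstart + iv[2] - 1L)
      cds_g <- t(apply(sense_cds, 1, function(iv)
        c(gstart + iv[1] - 1L, gstart + iv[2] - 1L)))
      u5_g <- shift(u5_iv); u3_g <- shift(u3_iv)
    }
    contig_seq[[ctg]] <- c(contig_seq[[ctg]], spacer, sense_seq)
    contig_len[ctg] <- contig_len[ctg] + nchar(spacer) + glen

    phases <- .inferPhases(seg_w)
    tid <- paste0(gid, "_t1")
    gff[[length(gff) + 1L]] <- data.frame(
      contig = ctg,
      start = c(gstart, gstart, cds_g[, 1], u5_g[1], u3_g[1]),
      end = c(gstart + glen - 1L, gstart + glen - 1L,
              cds_g[, 2], u5_g[2], u3_g[2]),
      strand = strands[i],
      type = c("gene", "mRNA", rep("CDS", n_ex),
               "five_prime_UTR", "three_prime_UTR"),
      ID = c(gid, tid, rep(NA, n_ex + 2L)),
      Parent = c(NA, gid, rep(tid, n_ex + 2L)),
      phase = c(NA, NA,
                if (strands[i] == "-") phases else phases,
                NA, NA)[seq_len(n_ex + 4L)],
      stringsAsFactors = FALSE)
    # CDS rows were emitted in sense order; phases already match that order
    truth$n_codons[i] <- n_codons
    truth$n_exons[i] <- n_ex
    truth$cds_len[i] <- cds_len
  }

  genome <- Biostrings::DNAStringSet(vapply(contig_seq, paste,
                                            character(1), collapse = ""))
  names(genome) <- contig_ids

  gff_df <- do.call(rbind, gff)
  gr <- GRanges(gff_df$contig, IRanges(gff_df$start, gff_df$end),
                strand = gff_df$strand)
  mcols(gr) <- DataFrame(
    type = gff_df$type,
    ID = gff_df$ID,
    Parent = IRanges::CharacterList(
      lapply(gff_df$Parent, function(p) if (is.na(p)) character(0) else p)),
    phase = as.integer(gff_df$phase))

  structure(list(genome = genome, annotation = gr, truth = truth,
                 motifs = NULL, labels = NULL, config = config),
            class = "GCxSimulation")
}

# truncated geometric on 1..max
.rtgeom <- function(n, p, max) {
  x <- stats::rgeom(n, p) + 1L
  while (any(x > max)) x[x > max] <- stats::rgeom(sum(x > max), p) + 1L
  x
}

#' Plant motif instances into a simulated genome
#'
#' Selects motif-carrying genes with configured enrichment odds toward
#' high-GCx genes, draws per-gene instance counts from the truncated
#' geometric, samples instance sequences from the motif PWM (resampling
#' until the score reaches the stringency, or the maximal sequence when
#' `consensus_max`), and writes each instance into a CDS segment at a
#' codon-frame-controlled offset, avoiding overlaps.  Plantings with no
#' feasible site are skipped and logged in the returned truth.
#'
#' @param sim a `GCxSimulation` from [simulateGenome()]
#' @param model optional [MotifModel]; defaults to the config's consensus
#'   and stringency
#' @return `sim` with modified `genome`, a `motifs` data.frame (gene_id,
#'   contig, start, end, strand, frame, cds_offset, sequence) and a
#'   `motif_count` column added to `truth`
#' @export
plantMotifs <- function(sim, model = NULL) {
  stopifnot(inherits(sim, "GCxSimulation"))
  config <- sim$config
  if (is.null(model))
    model <- consensusToPWM(config$motif_consensus,
                            stringency = config$motif_stringency)
  W <- ncol(model@pwm)
  gm <- .simGeneModels(sim)
  genome_chr <- as.character(sim$genome)

  p_low <- config$motif_gene_prob_low
  odds_low <- p_low / (1 - p_low)
  odds_high <- odds_low * config$motif_enrichment_odds
  p_high <- odds_high / (1 + odds_high)

  is_high <- sim$truth$class != "low"
  carrier <- stats::runif(nrow(sim$truth)) < ifelse(is_high, p_high, p_low)

  thr <- model@stringency * model@maxScore
  S <- .scoreMatrix(model)
  drawInstance <- function() {
    if (config$consensus_max)
      return(paste(rownames(model@pwm)[apply(model@pwm, 2, which.max)],
                   collapse = ""))
    repeat {
      b <- vapply(seq_len(W), function(j)
        sample(rownames(model@pwm), 1L, prob = model@pwm[, j]), character(1))
      sc <- sum(S[cbind(match(b, c("A", "C", "G", "T")), seq_len(W))])
      if (sc >= thr) return(paste(b, collapse = ""))
    }
  }

  motifs <- list()
  counts <- integer(nrow(sim$truth))
  skipped <- 0L
  for (i in which(carrier)) {
    gid <- sim$truth$gene_id[i]
    gi <- match(gid, gm@genes$gene_id)
    segs <- gm@cds[[gi]]
    segw <- width(segs)
    prior <- cumsum(c(0L, segw[-length(segw)]))
    m <- .rtgeom(1L, config$motif_count_p, config$motif_count_max)
    used <- matrix(0L, nrow = 0, ncol = 2)  # cds-coordinate intervals
    for (k in seq_len(m)) {
      frame <- sample(1:3, 1L, prob = config$frame_probs)
      # candidate cds offsets: within one segment, matching the frame
      placed <- FALSE
      for (try in seq_len(25L)) {
        j <- sample(seq_along(segs), 1L, prob = segw)
        max_local <- segw[j] - W
        if (max_local < 0L) next
        # cds offset prior[j] + off_local must be = frame - 1 (mod 3)
        first_ok <- (frame - 1L - prior[j]) %% 3L
        if (first_ok > max_local) next
        cand <- seq(first_ok, max_local, by = 3L)
        off_local <- sample(rep(cand, 2L), 1L)  # rep() guards length-1 sample
        off <- prior[j] + off_local
        if (nrow(used) &&
            any(off <= used[, 2] & off + W - 1L >= used[, 1])) next
        inst <- drawInstance()
        strand_g <- as.character(strand(segs)[1])
        ctg <- as.character(seqnames(segs)[1])
        if (strand_g == "+") {
          gs <- start(segs)[j] + off_local
          ge <- gs + W - 1L
          write_seq <- inst
        } else {
          ge <- end(segs)[j] - off_local
          gs <- ge - W + 1L
          write_seq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(inst)))
        }
        substr(genome_chr[ctg], gs, ge) <- write_seq
        used <- rbind(used, c(off, off + W - 1L))
        motifs[[length(motifs) + 1L]] <- data.frame(
          gene_id = gid, contig = ctg, start = gs, end = ge,
          strand = strand_g, frame = frame, cds_offset = off,
          sequence = inst, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) skipped <- skipped + 1L
    }
    counts[i] <- sum(vapply(motifs, function(x) x$gene_id == gid, logical(1)))
  }
  if (skipped)
    message(skipped, " motif planting(s) had no feasible site; skipped")

  sim$genome <- Biostrings::DNAStringSet(genome_chr)
  sim$motifs <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(gene_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               frame = integer(0), cds_offset = integer(0),
               sequence = character(0))
  sim$truth$motif_count <- counts
  sim
}

# GeneModels straight from the simulation's annotation GRanges
.simGeneModels <- function(sim) {
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  rtracklayer::export(sim$annotation, tf, format = "gff3")
  suppressWarnings(readAnnotation(tf))
}

#' Simulate expression labels linked to motif carriage and GCx class
#'
#' Draws up/down differential-expression labels per comparison tissue with
#' the configured base fractions, odds-multiplied for motif-carrying genes
#' and high-GCx genes.  Up is drawn first; down only among non-up genes, so
#' no gene is both in one comparison.  An `expressed` indicator defines the
#' expressed-gene universe.
#'
#' @param sim a `GCxSimulation` (after [plantMotifs()]; genes with no
#'   `motif_count` column count as motif-free)
#' @return `sim` with `labels` (data.frame gene_id, direction, comparison)
#'   and `expressed`/per-comparison columns added to `truth`
#' @export
simulateExpressionLabels <- function(sim) {
  stopifnot(inherits(sim, "GCxSimulation"))
  config <- sim$config
  tr <- sim$truth
  has_motif <- if (is.null(tr$motif_count)) rep(FALSE, nrow(tr))
               else tr$motif_count > 0
  is_high <- tr$class != "low"
  tr$expressed <- stats::runif(nrow(tr)) < config$expressed_frac

  oddsAdj <- function(p, mult) {
    o <- p / (1 - p) * mult
    o / (1 + o)
  }
  labels <- list()
  for (cmp in names(config$up_frac)) {
    p_up <- rep(config$up_frac[[cmp]], nrow(tr))
    p_up[has_motif] <- oddsAdj(p_up[has_motif], config$motif_up_odds)
    p_up[is_high] <- oddsAdj(p_up[is_high], config$high_up_odds)
    up <- stats::runif(nrow(tr)) < p_up
    p_dn <- rep(config$down_frac[[cmp]], nrow(tr))
    p_dn[has_motif] <- oddsAdj(p_dn[has_motif], config$motif_down_odds)
    p_dn[is_high] <- oddsAdj(p_dn[is_high], config$high_down_odds)
    dn <- !up & stats::runif(nrow(tr)) < p_dn
    if (any(up))
      labels[[length(labels) + 1L]] <- data.frame(
        gene_id = tr$gene_id[up], direction = "up", comparison = cmp,
        stringsAsFactors = FALSE)
    if (any(dn))
      labels[[length(labels) + 1L]] <- data.frame(
        gene_id = tr$gene_id[dn], direction = "down", comparison = cmp,
        stringsAsFactors = FALSE)
    tr[[paste0("up_", cmp)]] <- up
    tr[[paste0("down_", cmp)]] <- dn
  }
  sim$truth <- tr
  sim$labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(gene_id = character(0), direction = character(0),
               comparison = character(0))
  sim
}

#' Run the full simulation: genome, motif plantings, expression labels
#'
#' One call, one seed, fully deterministic.
#'
#' @param config a `SimulationConfig`
#' @return a `GCxSimulation` with genome, annotation, motifs, labels, truth
#' @export
simulateStudy <- function(config) {
  sim <- simulateGenome(config)
  sim <- plantMotifs(sim)
  simulateExpressionLabels(sim)
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `annotation.gff3` (1-based closed, phase in column
#' 8), `truth.tsv`, `motifs.tsv`, `labels.tsv` and `config.yaml`.
#'
#' @param sim a `GCxSimulation`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(sim$annotation, file.path(dir, "annotation.gff3"),
                      format = "gff3")
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$motifs))
    utils::write.table(sim$motifs, file.path(dir, "motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(sim$labels))
    utils::write.table(sim$labels, file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$class_props <- as.list(cfg$class_props)
  cfg$up_frac <- as.list(cfg$up_frac)
  cfg$down_frac <- as.list(cfg$down_frac)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
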