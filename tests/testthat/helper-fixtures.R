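# programmatic fixtures and independent oracles shared across tests

writeFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

# minimal GFF3 writer for hand-built toy annotations: `rows` is a data.frame
# with contig, type, start, end, strand, phase, ID, Parent (NA allowed)
writeGff3 <- function(rows, path = tempfile(fileext = ".gff3")) {
  attr_of <- function(i) {
    a <- character(0)
    if (!is.na(rows$ID[i])) a <- c(a, paste0("ID=", rows$ID[i]))
    if (!is.na(rows$Parent[i])) a <- c(a, paste0("Parent=", rows$Parent[i]))
    if (!length(a)) "." else paste(a, collapse = ";")
  }
  lines <- c("##gff-version 3", vapply(seq_len(nrow(rows)), function(i) {
    paste(rows$contig[i], "test", rows$type[i], rows$start[i], rows$end[i],
          ".", rows$strand[i],
          ifelse(is.na(rows$phase[i]), ".", rows$phase[i]),
          attr_of(i), sep = "\t")
  }, character(1)))
  writeLines(lines, path)
  path
}

gffRow <- function(contig, type, start, end, strand, phase = NA,
                   ID = NA, Parent = NA) {
  data.frame(contig = contig, type = type, start = start, end = end,
             strand = strand, phase = phase, ID = ID, Parent = Parent,
             stringsAsFactors = FALSE)
}

# a two-gene toy: gene g1 (+, two CDS segments with intron), gene g2 (-)
toyGenome <- function() {
  # 120-nt contig, layout engineered by hand
  set.seed(99)
  bases <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  list(seq = paste(bases, collapse = ""), bases = bases)
}

randomDNA <- function(n, letters = c("A", "C", "G", "T"),
                      prob = NULL) {
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

# independent oracle: codon-position GC via an explicit per-codon loop
bruteCodonGC <- function(seq, phase_offset) {
  v <- strsplit(seq, "")[[1]]
  if (phase_offset > 0 && length(v) >= phase_offset)
    v <- v[-(1:phase_offset)]
  else if (length(v) < phase_offset) v <- character(0)
  gc <- c(0, 0, 0); tot <- c(0, 0, 0)
  i <- 1
  while (i <= length(v)) {
    codon <- v[i:min(i + 2, length(v))]
    for (k in seq_along(codon)) {
      b <- codon[k]
      if (b %in% c("G", "C")) { gc[k] <- gc[k] + 1; tot[k] <- tot[k] + 1 }
      else if (b %in% c("A", "T")) tot[k] <- tot[k] + 1
    }
    i <- i + 3
  }
  ifelse(tot == 0, NA_real_, gc / tot)
}

# independent oracle: score every window of seq against the model naively
naiveWindowScores <- function(seq, model) {
  v <- strsplit(toupper(seq), "")[[1]]
  W <- ncol(GCxMotif::pwm(model))
  lo <- model@logOdds
  bg <- model@background
  n <- length(v)
  if (n < W) return(numeric(0))
  vapply(1:(n - W + 1), function(s) {
    tot <- 0
    for (k in 1:W) {
      b <- v[s + k - 1]
      tot <- tot + if (b %in% rownames(lo)) lo[b, k]
                   else sum(bg * lo[, k])
    }
    tot
  }, numeric(1))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

smallSim <- function(seed = 7, n_genes = 60, ...) {
  simulateStudy(simulationConfig(seed = seed, n_genes = n_genes, ...))
}
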