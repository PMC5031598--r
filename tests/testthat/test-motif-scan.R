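test_that("consensus positions spread probability over allowed bases", {
  m <- consensusToPWM("S")
  p <- pwm(m)[, 1]
  expect_equal(unname(p["C"]), unname(p["G"]))
  expect_true(p["C"] > 0.49 && p["C"] < 0.5)
  expect_true(p["A"] < 0.002 && p["T"] < 0.002)
  expect_equal(sum(p), 1)
  expect_equal(width(consensusToPWM()), 19L)
  expect_error(consensusToPWM("GXS"), "position 2")
})

test_that("the all-G word scores the maximum for the hotspot consensus", {
  m <- consensusToPWM()
  sc <- naiveWindowScores(strrep("G", 19), m)
  expect_equal(sc, maxScore(m))
  h <- scanSeq(strrep("G", 19), m, both_strands = FALSE)
  expect_equal(h$score_fraction, 1)
})

test_that("sequences shorter than the motif yield no hits, no error", {
  m <- consensusToPWM()
  expect_equal(length(scanSeq(strrep("G", 18), m)), 0L)
})

test_that("AT-only backgrounds produce no hits at stringency 0.8", {
  set.seed(12)
  m <- consensusToPWM()
  seq <- randomDNA(2000, c("A", "T"))
  expect_equal(length(scanSeq(seq, m)), 0L)
  expect_true(max(naiveWindowScores(seq, m)) < 0.8 * maxScore(m))
})

test_that("a planted consensus-max word is found exactly where planted", {
  set.seed(13)
  bg <- randomDNA(200, c("A", "T"))
  seq <- paste0(substr(bg, 1, 37), strrep("G", 19),
                substr(bg, 57, 200))
  m <- consensusToPWM()
  h <- scanSeq(seq, m, both_strands = FALSE)
  expect_equal(length(h), 1L)
  expect_equal(GenomicRanges::start(h), 38L)  # planted after 37 background nt
  expect_equal(h$score_fraction, 1)
})

test_that("scan matches naive per-window rescoring on random sequences", {
  set.seed(14)
  m <- consensusToPWM(stringency = 0.5)  # lower threshold exercises hits
  thr <- 0.5 * maxScore(m)
  for (i in 1:500) {
    seq <- randomDNA(sample(10:120, 1), c("A", "C", "G", "T", "N"),
                     prob = c(0.15, 0.3, 0.35, 0.15, 0.05))
    want <- which(naiveWindowScores(seq, m) >= thr)
    h <- scanSeq(seq, m, both_strands = FALSE)
    expect_equal(GenomicRanges::start(h), want)
    if (length(h))
      expect_equal(h$score, naiveWindowScores(seq, m)[want],
                   tolerance = 1e-9)
  }
})

test_that("both-strand hit sets mirror under reverse complement", {
  set.seed(15)
  m <- consensusToPWM(stringency = 0.6)
  n <- 150
  for (i in 1:20) {
    seq <- randomDNA(n, prob = c(0.2, 0.3, 0.3, 0.2))
    a <- scanSeq(seq, m, both_strands = TRUE)
    b <- scanSeq(revcomp(seq), m, both_strands = TRUE)
    flip <- c("+" = "-", "-" = "+")
    key_a <- sort(paste(GenomicRanges::start(a),
                        as.character(GenomicRanges::strand(a))))
    key_b <- sort(paste(n - GenomicRanges::end(b) + 1,
                        flip[as.character(GenomicRanges::strand(b))]))
    expect_equal(key_a, key_b)
    # minus-strand hits are the forward hits of the reverse complement,
    # reported in plus-strand coordinates
    minus <- a[as.character(GenomicRanges::strand(a)) == "-"]
    fwd_rc <- scanSeq(revcomp(seq), m, both_strands = FALSE)
    expect_setequal(GenomicRanges::start(minus),
                    n - GenomicRanges::start(fwd_rc) - 19 + 2)
  }
})

test_that("windows with N score the background-average contribution", {
  m <- consensusToPWM(stringency = 0.5)
  seq <- paste0(strrep("G", 9), "N", strrep("G", 9))
  sc <- naiveWindowScores(seq, m)
  h <- scanSeq(seq, m, both_strands = FALSE)
  expect_equal(h$score, sc)
  expect_true(h$score < maxScore(m))
})

test_that("min-max anchored scoring is available behind the switch", {
  m <- consensusToPWM(stringency = 0.8)
  seq <- strrep("G", 19)
  h1 <- scanSeq(seq, m, both_strands = FALSE, scoring = "max")
  h2 <- scanSeq(seq, m, both_strands = FALSE, scoring = "minmax")
  expect_equal(length(h1), 1L)
  expect_equal(length(h2), 1L)  # the max word passes either anchoring
})

test_that("codon frame assignment follows the modular rule", {
  expect_equal(assignCodonFrame(0, 0), 1L)
  expect_equal(assignCodonFrame(4, 0), 2L)
  expect_equal(assignCodonFrame(3, 1), 3L)
  expect_true(is.na(assignCodonFrame(NA, 0)))
  # exhaustive: frame cycles with offset
  off <- 0:11
  expect_equal(assignCodonFrame(off, 0), rep(1:3, 4))
})

test_that("hits are localized to region, offset and frame in gene models", {
  # gene on +: UTR5 1..10, CDS 11..40 and 61..90, UTR3 91..100
  left <- randomDNA(10, c("A", "T"))
  intron <- randomDNA(20, c("A", "T"))
  right <- randomDNA(10, c("A", "T"))
  cds1 <- paste0(randomDNA(6, c("A", "T")), strrep("G", 19),
                 randomDNA(5, c("A", "T")))
  cds2 <- randomDNA(30, c("A", "T"))
  contig <- paste0(left, cds1, intron, cds2, right)
  fa <- writeFasta(list(c1 = contig))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 100, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 100, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "exon", 1, 40, "+", Parent = "t1"),
    gffRow("c1", "exon", 61, 100, "+", Parent = "t1"),
    gffRow("c1", "CDS", 11, 40, "+", phase = 0, Parent = "t1"),
    gffRow("c1", "CDS", 61, 90, "+", phase = 0, Parent = "t1")))
  gm <- readAnnotation(gff)
  m <- consensusToPWM()
  h <- localizeHits(scanSeq(readGenome(fa), m), gm)
  genic <- h[!is.na(h$gene_id)]
  expect_true(length(genic) >= 1L)
  top <- genic[which.max(genic$score_fraction)]
  expect_equal(as.character(top$region), "CDS")
  # planted at CDS-local offset 6 -> frame (6 mod 3) + 1 = 1
  expect_equal(top$cds_offset, 6L)
  expect_equal(top$codon_frame, 1L)
})

test_that("hits crossing a splice junction keep region CDS but no frame", {
  # CDS 11..20 then 31..60: plant the max word straddling 15..33
  pre <- randomDNA(10, c("A", "T"))
  g19 <- strrep("G", 19)
  contig <- paste0(pre, randomDNA(4, c("A", "T")), g19,
                   randomDNA(40, c("A", "T")))
  fa <- writeFasta(list(c1 = contig))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 11, 60, "+", ID = "g1"),
    gffRow("c1", "mRNA", 11, 60, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", 11, 20, "+", phase = 0, Parent = "t1"),
    gffRow("c1", "CDS", 31, 60, "+", phase = 2, Parent = "t1")))
  gm <- readAnnotation(gff)
  h <- localizeHits(scanSeq(readGenome(fa), consensusToPWM()), gm)
  hit <- h[which(GenomicRanges::start(h) == 15 &
                 as.character(GenomicRanges::strand(h)) == "+")]
  expect_equal(as.character(hit$region), "CDS")
  expect_true(hit$split)
  expect_true(is.na(hit$codon_frame))
})

test_that("per-gene counts summarise the motif histogram", {
  hits <- data.frame(gene_id = c(rep("a", 3), "b", NA))
  pg <- perGeneCounts(hits)
  expect_equal(pg$total_motifs, 4)
  expect_equal(pg$histogram$n_genes[pg$histogram$motifs_per_gene == 3], 1)
  expect_equal(pg$frac_multi, 0.5)
})

test_that("the reference motif histogram reproduces its printed summaries", {
  tab <- referenceTable("motifs_per_gene")
  s <- summariseMotifHistogram(tab)
  expect_equal(s$total_motifs, 2143)
  expect_equal(s$frac_multi, 1 - 85 / sum(tab$n_genes))
  expect_gt(s$frac_multi, 0.84 - 0.01)
  # rows sum to 545 although the overall text total is 544; surfaced as-is
  expect_equal(s$n_genes, 545)
})

test_that("CDS preference chi-square responds to base composition", {
  # proportional split: p = 1
  cr <- cdsPreferenceTest(100, 50, 1000, 500)
  expect_equal(pValue(cr), 1)
  # strong CDS preference with more intron than CDS sequence
  cr <- cdsPreferenceTest(1909, 234, 1000, 1153.7)
  expect_lt(pValue(cr), 1e-300)
  # reversal flips direction but stays significant
  cr2 <- cdsPreferenceTest(0, 200, 1000, 1000)
  expect_lt(pValue(cr2), 0.05)
  expect_lt(observedCounts(cr2)[1], expectedCounts(cr2)[1])
})
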