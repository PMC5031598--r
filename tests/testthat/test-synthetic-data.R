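test_that("the config validates and the seed is mandatory", {
  expect_error(simulationConfig(), "seed")
  expect_error(simulationConfig(seed = 1, class_props = c(1, 1, 1, 1)),
               "class_props|sum")
  expect_error(simulationConfig(seed = 1, codons_range = c(5L, 10L)),
               "motif")
  cfg <- simulationConfig(seed = 1)
  expect_s3_class(cfg, "SimulationConfig")
  expect_equal(sum(cfg$class_props), 1)
})

test_that("the same seed reproduces byte-identical outputs", {
  s1 <- simulateStudy(simulationConfig(seed = 5, n_genes = 20))
  s2 <- simulateStudy(simulationConfig(seed = 5, n_genes = 20))
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$motifs, s2$motifs)
  expect_identical(s1$labels, s2$labels)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(s1, d1); writeSimulation(s2, d2)
  for (f in c("genome.fa", "truth.tsv", "motifs.tsv", "labels.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("a degenerate all-high-GC3 config yields gc3 of 1 everywhere", {
  cfg <- simulationConfig(seed = 2, n_genes = 8,
                          class_props = c(high1 = 0, high2 = 0, high3 = 1,
                                          low = 0),
                          gc_high = 1.0)
  sim <- simulateGenome(cfg)
  d <- tempfile(); writeSimulation(sim, d)
  prof <- gcProfile(readAnnotation(file.path(d, "annotation.gff3")),
                    readGenome(file.path(d, "genome.fa")))
  # the appended stop codon contributes one A/T at positions 1 and 3 at
  # most; gc3 over the body is 1, the stop's third base can be A/G
  expect_true(all(prof$gc3 > 0.99))
})

test_that("emitted FASTA/GFF3 reproduce the planted classes on re-reading", {
  sim <- smallSim(seed = 17, n_genes = 120)
  d <- tempfile(); writeSimulation(sim, d)
  prof <- classifyGCx(gcProfile(readAnnotation(file.path(d, "annotation.gff3")),
                                readGenome(file.path(d, "genome.fa"))))
  m <- merge(prof, sim$truth, by = "gene_id")
  agree <- vapply(seq_len(nrow(m)), function(i) {
    cls <- m$class[i]
    if (cls == "low") !any(c(m$high_gc1[i], m$high_gc2[i], m$high_gc3[i]))
    else m[[paste0("high_gc", substring(cls, 5))]][i]
  }, logical(1))
  expect_gte(mean(agree), 0.99)
})

test_that("planted class proportions are recovered within binomial 99% CI", {
  sim <- smallSim(seed = 23, n_genes = 500)
  d <- tempfile(); writeSimulation(sim, d)
  prof <- classifyGCx(gcProfile(readAnnotation(file.path(d, "annotation.gff3")),
                                readGenome(file.path(d, "genome.fa"))))
  n <- nrow(prof)
  for (k in c(1, 3)) {  # GC2's class is tiny at n=500; checked via truth
    obs <- sum(prof[[paste0("high_gc", k)]], na.rm = TRUE)
    p0 <- sim$config$class_props[[paste0("high", k)]]
    ci <- stats::binom.test(obs, n, p0, conf.level = 0.99)$p.value
    expect_gt(ci, 0.01)
  }
  # and the classes recovered match the planted truth genes exactly enough
  tcounts <- table(sim$truth$class)
  expect_equal(sum(prof$high_gc3, na.rm = TRUE),
               unname(tcounts["high3"]), tolerance = 0.05)
})

test_that("every planted motif is found at its recorded position and frame", {
  sim <- smallSim(seed = 29, n_genes = 80)
  d <- tempfile(); writeSimulation(sim, d)
  genome <- readGenome(file.path(d, "genome.fa"))
  gm <- readAnnotation(file.path(d, "annotation.gff3"))
  model <- consensusToPWM(sim$config$motif_consensus,
                          stringency = sim$config$motif_stringency)
  hits <- localizeHits(scanSeq(genome, model), gm)
  key_hits <- paste(as.character(GenomicRanges::seqnames(hits)),
                    GenomicRanges::start(hits))
  key_plant <- paste(sim$motifs$contig, sim$motifs$start)
  expect_true(all(key_plant %in% key_hits))
  idx <- match(key_plant, key_hits)
  expect_equal(hits$codon_frame[idx], sim$motifs$frame)
  expect_equal(hits$cds_offset[idx], sim$motifs$cds_offset)
  # no hits on a motif-free AT-rich background at stringency 0.8
  set.seed(1)
  expect_equal(length(scanSeq(randomDNA(5000, c("A", "T", "G", "C"),
                                        prob = c(0.4, 0.4, 0.1, 0.1)),
                              model)), 0L)
})

test_that("planted enrichment odds and frame distribution are recovered", {
  sim <- smallSim(seed = 37, n_genes = 600,
                  motif_gene_prob_low = 0.10, motif_enrichment_odds = 5)
  tr <- sim$truth
  has <- tr$motif_count > 0
  high <- tr$class != "low"
  # enrichment direction: motif genes overrepresent high-GCx classes
  cr <- gofChisq(sum(has & high), sum(has & !high), sum(high), sum(!high))
  expect_gt(observedCounts(cr)["yes"], expectedCounts(cr)["yes"])
  expect_lt(pValue(cr), 0.05)
  # frame distribution against planted probabilities (chi-square GOF)
  fr <- table(factor(sim$motifs$frame, levels = 1:3))
  p <- stats::chisq.test(fr, p = sim$config$frame_probs)$p.value
  expect_gt(p, 0.001)
})

test_that("expression labels respect the configured odds links", {
  sim <- smallSim(seed = 41, n_genes = 800,
                  motif_gene_prob_low = 0.2, motif_enrichment_odds = 1,
                  up_frac = c(seedling = 0.3), down_frac = c(seedling = 0.2),
                  motif_up_odds = 0.1, high_up_odds = 1, high_down_odds = 1)
  tr <- sim$truth
  has <- tr$motif_count > 0
  # up-regulation strongly biased against motif genes
  up_motif <- mean(tr$up_seedling[has])
  up_free <- mean(tr$up_seedling[!has])
  expect_lt(up_motif, up_free)
  # no gene both up and down in one comparison
  expect_false(any(tr$up_seedling & tr$down_seedling))
  # zero up-fraction degenerates gracefully
  s0 <- smallSim(seed = 43, n_genes = 30,
                 up_frac = c(seedling = 0), down_frac = c(seedling = 0.2))
  expect_false(any(s0$truth$up_seedling))
})

test_that("independent labels yield null-calibrated bias tests", {
  set.seed(47)
  ps <- replicate(60, {
    n <- 800
    ids <- paste0("g", 1:n)
    motif_ids <- sample(ids, 120)
    lab_ids <- ids[runif(n) < 0.15]
    gcx <- classifyGCx(data.frame(gene_id = ids, gc1 = 0.5, gc2 = 0.5,
                                  gc3 = 0.5))
    labels <- data.frame(gene_id = lab_ids, direction = "up",
                         comparison = "seedling")
    expressionBiasTests(motif_ids, labels, gcx)$motif_bias$p
  })
  expect_gt(mean(ps > 0.05), 0.85)
  expect_lt(min(ps), 0.9)  # not degenerate at 1
})
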