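test_that("readGenome returns uppercased records in file order", {
  fa <- writeFasta(list(c1 = "acgt", c2 = "NNGC"))
  g <- readGenome(fa)
  expect_identical(names(g), c("c1", "c2"))
  expect_identical(as.character(g[["c1"]]), "ACGT")
  expect_identical(as.character(g[["c2"]]), "NNGC")
})

test_that("readGenome rejects duplicate contig ids and missing files", {
  fa <- writeFasta(list(c1 = "ACGT"))
  txt <- readLines(fa)
  writeLines(c(txt, txt[1], "GGGG"), fa)
  expect_error(readGenome(fa), "duplicate contig")
  expect_error(readGenome(tempfile()), "not found")
})

test_that("GFF3 coordinates convert 1-based closed to internal ranges", {
  fa <- writeFasta(list(c1 = strrep("ACGT", 10)))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 12, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 12, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", 1, 9, "+", phase = 0, Parent = "t1")))
  gm <- readAnnotation(gff)
  cds <- cdsByGene(gm)[["g1"]]
  expect_equal(GenomicRanges::start(cds), 1)
  expect_equal(GenomicRanges::end(cds), 9)
  # BED emission is 0-based half-open
  hits <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 9), strand = "+",
                                 score_fraction = 1)
  bed <- tempfile(fileext = ".bed")
  writeHitsBed(hits, bed)
  f <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(as.integer(f[2:3]), c(0L, 9L))
})

test_that("minus-strand genes splice to the hand-derived coding sequence", {
  # 25-nt contig; CDS segments [11,19] and [1,6] in 1-based closed coords,
  # transcription order on - strand is [11,19] then [1,6]
  contig <- "ATGCCGTAGATTTGCACGGCATGCA"
  fa <- writeFasta(list(c1 = contig))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 25, "-", ID = "g1"),
    gffRow("c1", "mRNA", 1, 25, "-", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", 11, 19, "-", phase = 0, Parent = "t1"),
    gffRow("c1", "CDS", 1, 6, "-", phase = 0, Parent = "t1")))
  gm <- readAnnotation(gff)
  cs <- assembleCodingSequences(gm, readGenome(fa))
  expected <- paste0(revcomp(substr(contig, 11, 19)),
                     revcomp(substr(contig, 1, 6)))
  expect_identical(as.character(cs[["g1"]]), expected)
})

test_that("representative transcript is the longest CDS, ties by id", {
  fa <- writeFasta(list(c1 = strrep("ACGTGGCCAT", 10)))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 100, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 100, "+", ID = "tB", Parent = "g1"),
    gffRow("c1", "mRNA", 1, 100, "+", ID = "tA", Parent = "g1"),
    gffRow("c1", "CDS", 1, 30, "+", phase = 0, Parent = "tB"),
    gffRow("c1", "CDS", 1, 30, "+", phase = 0, Parent = "tA"),
    gffRow("c1", "CDS", 41, 60, "+", phase = 0, Parent = "tB")))
  gm <- readAnnotation(gff)
  expect_identical(gm@genes$tx_id, "tB")   # longest total CDS
  expect_equal(gm@genes$cds_len, 50)

  # equal lengths: lexicographically smallest transcript id
  gff2 <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 100, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 100, "+", ID = "tB", Parent = "g1"),
    gffRow("c1", "mRNA", 1, 100, "+", ID = "tA", Parent = "g1"),
    gffRow("c1", "CDS", 1, 30, "+", phase = 0, Parent = "tB"),
    gffRow("c1", "CDS", 1, 30, "+", phase = 0, Parent = "tA")))
  expect_identical(readAnnotation(gff2)@genes$tx_id, "tA")
})

test_that("overlapping CDS segments are merged so no base counts twice", {
  fa <- writeFasta(list(c1 = strrep("ACGTGGCCAT", 10)))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 100, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 100, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", 1, 30, "+", phase = 0, Parent = "t1"),
    gffRow("c1", "CDS", 21, 45, "+", phase = 0, Parent = "t1")))
  expect_warning(gm <- readAnnotation(gff), "merged")
  cds <- cdsByGene(gm)[["g1"]]
  expect_equal(length(cds), 1L)
  expect_equal(sum(GenomicRanges::width(cds)), 45)
  cs <- assembleCodingSequences(gm, readGenome(fa))
  expect_equal(nchar(as.character(cs[["g1"]])), 45)
})

test_that("coding sequence length always equals the segment-length sum", {
  sim <- smallSim(seed = 11, n_genes = 30)
  d <- tempfile(); writeSimulation(sim, d)
  gm <- readAnnotation(file.path(d, "annotation.gff3"))
  cs <- assembleCodingSequences(gm, readGenome(file.path(d, "genome.fa")))
  lens <- vapply(cdsByGene(gm), function(x)
    sum(GenomicRanges::width(x)), numeric(1))
  expect_equal(unname(Biostrings::width(cs)), unname(lens[names(cs)]))
})

test_that("strand property: mirrored contig yields the same coding seq", {
  contig <- paste0("AAAA", "ATGGCCGGTTAA", "TTTT")  # gene at 5..16 on +
  n <- nchar(contig)
  fa1 <- writeFasta(list(c1 = contig))
  gff1 <- writeGff3(rbind(
    gffRow("c1", "gene", 5, 16, "+", ID = "g1"),
    gffRow("c1", "mRNA", 5, 16, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", 5, 16, "+", phase = 0, Parent = "t1")))
  fa2 <- writeFasta(list(c1 = revcomp(contig)))
  gff2 <- writeGff3(rbind(
    gffRow("c1", "gene", n - 16 + 1, n - 5 + 1, "-", ID = "g1"),
    gffRow("c1", "mRNA", n - 16 + 1, n - 5 + 1, "-", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", n - 16 + 1, n - 5 + 1, "-", phase = 0,
           Parent = "t1")))
  cs1 <- assembleCodingSequences(readAnnotation(gff1), readGenome(fa1))
  cs2 <- assembleCodingSequences(readAnnotation(gff2), readGenome(fa2))
  expect_identical(as.character(cs1[["g1"]]), as.character(cs2[["g1"]]))
})

test_that("positions classify as CDS, intron, UTR or intergenic", {
  fa <- writeFasta(list(c1 = strrep("ACGT", 30)))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 11, 90, "+", ID = "g1"),
    gffRow("c1", "mRNA", 11, 90, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "exon", 11, 50, "+", Parent = "t1"),
    gffRow("c1", "exon", 71, 90, "+", Parent = "t1"),
    gffRow("c1", "CDS", 21, 50, "+", phase = 0, Parent = "t1"),
    gffRow("c1", "CDS", 71, 85, "+", phase = 0, Parent = "t1")))
  gm <- readAnnotation(gff)
  expect_equal(as.character(classifyPosition(gm, "g1", 30)), "CDS")
  expect_equal(as.character(classifyPosition(gm, "g1", 60)), "INTRON")
  expect_equal(as.character(classifyPosition(gm, "g1", 5)), "INTERGENIC")
  # exonic non-CDS ahead of the CDS span derives as 5' UTR
  expect_equal(as.character(classifyPosition(gm, "g1", 15)), "UTR5")
  expect_equal(as.character(classifyPosition(gm, "g1", 88)), "UTR3")
})

test_that("genes without CDS are retained but flagged non-coding", {
  fa <- writeFasta(list(c1 = strrep("ACGT", 10)))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 40, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 40, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "exon", 1, 40, "+", Parent = "t1")))
  gm <- readAnnotation(gff)
  expect_equal(length(gm), 1L)
  expect_false(gm@genes$coding)
  prof <- gcProfile(gm, readGenome(fa))
  expect_true(is.na(prof$gc1))
  expect_false(is.na(prof$gc_gene))
})

test_that("CDS segments beyond contig bounds are an error", {
  fa <- writeFasta(list(c1 = "ACGTACGT"))
  gff <- writeGff3(rbind(
    gffRow("c1", "gene", 1, 8, "+", ID = "g1"),
    gffRow("c1", "mRNA", 1, 8, "+", ID = "t1", Parent = "g1"),
    gffRow("c1", "CDS", 3, 20, "+", phase = 0, Parent = "t1")))
  gm <- readAnnotation(gff)
  expect_error(assembleCodingSequences(gm, readGenome(fa)), "bounds")
})
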