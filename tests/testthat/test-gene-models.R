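test_that("GTF parsing assigns exon ranks by strand and ignores other genes", {
  gtf <- write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 301, 400, "+", "g1", "t1"),
    gtf_exon("chr2", 50, 90, "+", "g2", "t9")))
  gm <- parseGeneModels(gtf, "g1", "t1")
  ex <- exonsBy(gm, "t1")
  expect_equal(GenomicRanges::start(ex), c(101, 301))
  expect_equal(ex$transcript_rank, c(1L, 2L))
  expect_equal(transcriptIds(gm), "t1")

  # exon count for the requested gene matches a line-by-line scan
  expect_equal(sum(lengths(exonsBy(gm))), oracle_gtf_exon_count(gtf, "g1"))

  # strand symmetry: on the minus strand rank 1 is the rightmost exon
  gtf_m <- write_gtf(c(
    gtf_exon("chr1", 101, 200, "-", "g1", "t1"),
    gtf_exon("chr1", 301, 400, "-", "g1", "t1")))
  gm_m <- parseGeneModels(gtf_m, "g1", "t1")
  ex_m <- exonsBy(gm_m, "t1")
  expect_equal(ex_m$transcript_rank[GenomicRanges::start(ex_m) == 301], 1L)
})

test_that("GFF3 Parent/ID chains are accepted", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t101\t400\t.\t+\t.\tID=gene:g1",
    "chr1\tt\tmRNA\t101\t400\t.\t+\t.\tID=transcript:t1;Parent=gene:g1;Name=var1",
    "chr1\tt\texon\t101\t200\t.\t+\t.\tParent=transcript:t1",
    "chr1\tt\texon\t301\t400\t.\t+\t.\tParent=transcript:t1"), gff)
  gm <- parseGeneModels(gff, "g1", "t1")
  expect_equal(unname(variantNames(gm)), "var1")
  expect_equal(lengths(exonsBy(gm))[["t1"]], 2L)
})

test_that("annotation errors are explicit", {
  gtf <- write_gtf(gtf_exon("chr1", 101, 200, "+", "g1", "t1"))
  expect_error(parseGeneModels(gtf, "nope", "t1"), "gene not found")
  expect_error(parseGeneModels(gtf, "g1", "nope"),
               "canonical transcript not found")
  bad <- write_gtf(gtf_exon("chr1", 300, 200, "+", "g1", "t1"))
  expect_error(parseGeneModels(bad, "g1", "t1"), "malformed annotation")
})

test_that("junction derivation: one junction per adjacent exon pair", {
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301), c(200, 400)))
  j <- deriveJunctions(ex)
  expect_equal(j$donor_end, 200)
  expect_equal(j$acceptor_start, 301)

  single <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  expect_equal(nrow(deriveJunctions(single)), 0L)

  overlapping <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 150), c(200, 400)))
  expect_error(deriveJunctions(overlapping), "invalid transcript structure")

  # exon-3 skip joins exon 2's end to exon 4's start; confirmed by
  # enumerating the skipping transcript's adjacent pairs by hand:
  # (101-200, 301-400) -> (200, 301); (301-400, 701-800) -> (400, 701)
  gm <- skip_gene()
  js <- deriveJunctions(gm, "skip")
  expect_equal(js$donor_end, c(200, 400))
  expect_equal(js$acceptor_start, c(301, 701))
})

test_that("junction count per transcript equals exon count minus one", {
  gm <- many_variant_gene()
  for (tid in transcriptIds(gm)) {
    expect_equal(nrow(deriveJunctions(exonsBy(gm, tid))),
                 length(exonsBy(gm, tid)) - 1L)
  }
})

test_that("discriminating junctions match brute-force set difference", {
  gm <- skip_gene()
  cat_ <- discriminatingJunctions(gm)
  skip_set <- variantJunctions(cat_, "skip")
  expect_equal(nrow(skip_set), 1L)
  expect_equal(skip_set$donor_end, 400)
  expect_equal(skip_set$acceptor_start, 701)
  can_set <- variantJunctions(cat_, "can")
  expect_setequal(junctionKey(can_set$chrom, can_set$donor_end,
                              can_set$acceptor_start),
                  c("chr1:400-501", "chr1:600-701"))
  # agrees with the independent set-difference oracle
  oracle <- oracle_discriminating(gm)
  expect_setequal(junctionKey(skip_set$chrom, skip_set$donor_end,
                              skip_set$acceptor_start), oracle$skip)
})

test_that("identical transcripts are both unquantifiable", {
  gm <- geneModel("g", "chr1", "+", "a", list(
    a = rbind(c(101, 200), c(301, 400)),
    b = rbind(c(101, 200), c(301, 400))))
  cat_ <- discriminatingJunctions(gm)
  expect_setequal(unquantifiableVariants(cat_), c("a", "b"))
  expect_equal(sum(junctionCounts(cat_)$discriminating), 0L)
})

test_that("discriminating sets are pairwise disjoint on a 10-variant gene", {
  gm <- many_variant_gene()
  cat_ <- discriminatingJunctions(gm)
  j <- junctionCounts(cat_)
  disc <- j[j$discriminating, ]
  keys_by_var <- split(junctionKey(disc$chrom, disc$donor_end,
                                   disc$acceptor_start), disc$variant_name)
  vars <- names(keys_by_var)
  for (a in seq_along(vars)) for (b in seq_along(vars)) if (a < b)
    expect_length(intersect(keys_by_var[[a]], keys_by_var[[b]]), 0)
  # each discriminating junction occurs in exactly one transcript
  oracle <- oracle_discriminating(gm)
  for (v in vars)
    expect_setequal(keys_by_var[[v]], oracle[[v]])
})

test_that("spliced sequence concatenates exons and honors strand", {
  genome <- Biostrings::DNAStringSet(c(c1 = "ACGTTTGCA"))
  gm_p <- geneModel("g", "c1", "+", "t", list(t = rbind(c(1, 3), c(7, 9))))
  expect_equal(as.character(splicedSequence(gm_p, "t", genome)), "ACGGCA")
  gm_m <- geneModel("g", "c1", "-", "t", list(t = rbind(c(1, 3), c(7, 9))))
  expect_equal(as.character(splicedSequence(gm_m, "t", genome)), "TGCCGT")
  gm_all <- geneModel("g", "c1", "+", "t", list(t = rbind(c(1, 9))))
  expect_equal(as.character(splicedSequence(gm_all, "t", genome)),
               "ACGTTTGCA")
  gm_oob <- geneModel("g", "c1", "+", "t", list(t = rbind(c(5, 12))))
  expect_error(splicedSequence(gm_oob, "t", genome), "sequence out of range")
})

test_that("spliced sequence length is the exon length sum; strands mirror", {
  set.seed(11)
  for (i in 1:5) {
    cfg <- simulationConfig(nExons = sample(2:6, 1), seed = i,
                            variants = list(), junctionProb = numeric())
    toy <- makeToyGene(cfg)
    ex <- exonsBy(toy$gene, "canonical")
    s_p <- splicedSequence(toy$gene, "canonical", toy$contig)
    expect_equal(length(s_p), sum(GenomicRanges::width(ex)))
    # coordinate-mirrored minus-strand copy gives the reverse complement
    gm_m <- geneModel("g", names(toy$contig), "-", "canonical",
      list(canonical = cbind(GenomicRanges::start(ex),
                             GenomicRanges::end(ex))))
    s_m <- splicedSequence(gm_m, "canonical", toy$contig)
    expect_equal(as.character(s_m),
                 as.character(Biostrings::reverseComplement(s_p)))
  }
})

test_that("junction catalogue TSV round-trips", {
  cat_ <- discriminatingJunctions(skip_gene())
  path <- tempfile(fileext = ".tsv")
  writeJunctionCatalogue(cat_, path)
  back <- readJunctionCatalogue(path, "g")
  expect_equal(junctionCounts(back)$donor_end,
               junctionCounts(cat_)$donor_end)
  expect_equal(junctionCounts(back)$discriminating,
               junctionCounts(cat_)$discriminating)
})

test_that("GTF writer round-trips through the parser", {
  gm <- skip_gene("-")
  path <- tempfile(fileext = ".gtf")
  writeGeneGTF(gm, path)
  back <- parseGeneModels(path, "g", "can")
  expect_setequal(transcriptIds(back), transcriptIds(gm))
  for (tid in transcriptIds(gm))
    expect_equal(GenomicRanges::start(exonsBy(back, tid)),
                 GenomicRanges::start(exonsBy(gm, tid)))
  expect_equal(back@strand, "-")
})
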