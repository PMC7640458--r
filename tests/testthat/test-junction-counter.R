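test_that("junctions are read off the CIGAR skip operations", {
  j <- extractReadJunctions("50M200N50M", 100)
  expect_equal(j$donor_end, 149)
  expect_equal(j$acceptor_start, 350)

  expect_equal(nrow(extractReadJunctions("100M", 100)), 0L)

  j2 <- extractReadJunctions("30M100N40M50N30M", 10)
  expect_equal(j2$donor_end, c(39, 179))
  expect_equal(j2$acceptor_start, c(140, 230))

  # unmapped and soft-clip handling: clips consume no reference
  expect_equal(nrow(extractReadJunctions("*", 0)), 0L)
  j3 <- extractReadJunctions("5S45M200N50M10S", 100)
  expect_equal(j3$donor_end, 144)
  expect_equal(j3$left_anchor, 45)
  expect_error(extractReadJunctions("50Q50M", 100), "unparseable alignment")
})

test_that("anchors are the flanking reference-consuming blocks", {
  expect_equal(unname(anchorLengths("50M200N50M", 100, 149, 350)), c(50, 50))
  expect_equal(unname(anchorLengths("5M200N95M", 100, 104, 305)), c(5, 95))
  expect_equal(unname(anchorLengths("30M100N40M50N30M", 10, 179, 230)),
               c(40, 30))
  # a deletion adjacent to the junction extends the anchor (ref-consuming)
  expect_equal(unname(anchorLengths("40M2D8M200N50M", 100, 149, 350))[1], 50)
  expect_error(anchorLengths("100M", 100, 149, 350),
               "junction not spanned")
})

test_that("filter boundaries are inclusive and flags are honored", {
  cfg <- filterConfig(minAnchor = 8)
  expect_true(passesFilters(0L, 60L, 50L, 50L, cfg))
  expect_false(passesFilters(0L, 60L, 5L, 95L, cfg))
  expect_true(passesFilters(0L, 60L, 8L, 8L, cfg))   # "at least" = inclusive
  expect_false(passesFilters(0L, 60L, 7L, 8L, cfg))
  expect_false(passesFilters(4L, 60L, 50L, 50L, cfg))     # unmapped
  expect_false(passesFilters(1024L, 60L, 50L, 50L, cfg))  # duplicate
  expect_false(passesFilters(256L, 60L, 50L, 50L, cfg))   # secondary
  expect_false(passesFilters(0L, 5L, 50L, 50L,
                             filterConfig(minMapq = 10)))
  expect_true(passesFilters(1024L, 60L, 50L, 50L,
                            filterConfig(excludeDuplicates = FALSE)))
})

test_that("counts match a hand-tallied SAM exactly", {
  gm <- skip_gene()
  cat_ <- discriminatingJunctions(gm)
  # 7 reads spanning the skip junction (400, 701), 93 unspliced: 100 records
  body <- c(
    vapply(1:7, function(i)
      sam_line(sprintf("s%d", i), 0, "chr1", 351, 60, "50M300N50M"),
      character(1)),
    vapply(1:93, function(i)
      sam_line(sprintf("u%d", i), 0, "chr1", 101, 60, "100M"), character(1)))
  path <- write_sam(body)
  tb <- countJunctions(path, cat_, gm, filterConfig(), "s")
  cts <- junctionCounts(tb)
  expect_equal(cts$count[cts$donor_end == 400 & cts$acceptor_start == 701], 7L)
  expect_equal(totalReads(tb), 100)
  expect_equal(geneReads(tb), 100)
  # independent text-scan recount agrees
  keys <- junctionKey(cts$chrom, cts$donor_end, cts$acceptor_start)
  o <- oracle_sam_count(path, keys)
  expect_equal(stats::setNames(cts$count, keys), o$counts)
})

test_that("a read spanning two catalogue junctions counts once per junction", {
  gm <- skip_gene()
  cat_ <- discriminatingJunctions(gm)
  # canonical junctions (400,501) and (600,701): one read spans both
  body <- vapply(1:3, function(i)
    sam_line(sprintf("d%d", i), 0, "chr1", 361, 60, "40M100N100M100N40M"),
    character(1))
  tb <- countJunctions(write_sam(body), cat_, gm, filterConfig(), "s")
  cts <- junctionCounts(tb)
  expect_equal(cts$count[cts$donor_end == 400 & cts$acceptor_start == 501], 3L)
  expect_equal(cts$count[cts$donor_end == 600 & cts$acceptor_start == 701], 3L)
  expect_equal(totalReads(tb), 3)  # each read counted once in the total
})

test_that("unspliced-only input gives all-zero junction counts", {
  gm <- skip_gene()
  cat_ <- discriminatingJunctions(gm)
  body <- sam_line("u1", 0, "chr1", 101, 60, "100M")
  tb <- countJunctions(write_sam(body), cat_, gm)
  expect_true(all(junctionCounts(tb)$count == 0L))
  # empty stream: all-zero table, not an error
  tb0 <- countJunctions(write_sam(character()), cat_, gm)
  expect_true(all(junctionCounts(tb0)$count == 0L))
  expect_equal(totalReads(tb0), 0)
  expect_error(countJunctions("/no/such/file.sam", cat_, gm),
               "alignment input error")
})

test_that("counting equals the brute-force SAM recount on simulated data", {
  cfg <- simulationConfig(nReads = 5000, seed = 31,
                          junctionProb = c(skip3 = 0.01))
  s <- simulateSample(cfg, sam_path = tempfile(fileext = ".sam"))
  path <- tempfile(fileext = ".sam")
  writeSAM(s$records, stats::setNames(Biostrings::width(s$contig),
                                      names(s$contig)), path)
  for (ma in c(1, 8, 20)) {
    tb <- countJunctions(path, s$catalogue, s$gene,
                         filterConfig(minAnchor = ma))
    cts <- junctionCounts(tb)
    keys <- junctionKey(cts$chrom, cts$donor_end, cts$acceptor_start)
    span <- geneSpan(s$gene)
    o <- oracle_sam_count(path, keys, min_anchor = ma,
                          gene_span = list(chrom = as.character(
                            GenomicRanges::seqnames(span)),
                            start = GenomicRanges::start(span),
                            end = GenomicRanges::end(span)))
    expect_equal(stats::setNames(cts$count, keys), o$counts)
    expect_equal(totalReads(tb), o$total)
    expect_equal(geneReads(tb), o$gene_reads)
  }
})

test_that("raising minAnchor or minMapq never increases any count", {
  cfg <- simulationConfig(nReads = 20000, seed = 5,
                          junctionProb = c(skip3 = 0.02))
  s <- simulateSample(cfg)
  prev <- NULL
  for (ma in c(1, 4, 8, 16, 40)) {
    cts <- junctionCounts(countJunctions(s$records, s$catalogue, s$gene,
                                         filterConfig(minAnchor = ma)))
    if (!is.null(prev)) expect_true(all(cts$count <= prev))
    prev <- cts$count
  }
  prev <- NULL
  for (mq in c(0, 30, 60, 61)) {
    cts <- junctionCounts(countJunctions(s$records, s$catalogue, s$gene,
                                         filterConfig(minAnchor = 1,
                                                      minMapq = mq)))
    if (!is.null(prev)) expect_true(all(cts$count <= prev))
    prev <- cts$count
  }
})

test_that("counts are additive over concatenated inputs", {
  cfg1 <- simulationConfig(nReads = 3000, seed = 1,
                           junctionProb = c(skip3 = 0.02))
  cfg2 <- simulationConfig(nReads = 4000, seed = 2,
                           junctionProb = c(skip3 = 0.02))
  toy <- makeToyGene(cfg1)
  a <- simulateReads(toy$gene, toy$contig, cfg1)
  b <- simulateReads(toy$gene, toy$contig, cfg2)
  cat_ <- discriminatingJunctions(toy$gene)
  ta <- countJunctions(a$records, cat_, toy$gene)
  tb <- countJunctions(b$records, cat_, toy$gene)
  tab <- countJunctions(rbind(a$records, b$records), cat_, toy$gene)
  expect_equal(junctionCounts(tab)$count,
               junctionCounts(ta)$count + junctionCounts(tb)$count)
  expect_equal(totalReads(tab), totalReads(ta) + totalReads(tb))
})
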