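# build a small SJTPMExperiment directly from a hand-written counts frame
make_se <- function(counts_by_sample, totals, genereads = totals,
                    samples = NULL) {
  sids <- names(counts_by_sample)
  vars <- names(counts_by_sample[[1L]])
  counts <- do.call(rbind, lapply(sids, function(s)
    data.frame(sample_id = s, variant_name = vars,
               chrom = "chr1", donor_end = 400L, acceptor_start = 701L,
               spliced_reads = unname(counts_by_sample[[s]]),
               total_reads = totals[[s]], gene_reads = genereads[[s]],
               stringsAsFactors = FALSE)))
  buildSJTPMExperiment(counts, samples)
}

test_that("SJ TPM is spliced reads over total reads times one million", {
  expect_identical(sjTPM(5, 1e6), 5)
  expect_identical(sjTPM(0, 123), 0)
  expect_identical(sjTPM(7, 2e8), 0.035)
  expect_error(sjTPM(1, 0), "empty library")
  # scale invariance: multiplying both counts leaves SJ TPM unchanged
  expect_equal(sjTPM(7 * 13, 2e8 * 13), sjTPM(7, 2e8))
})

test_that("gene-relative fraction and its error cases", {
  expect_equal(variantFraction(3, 1000), 0.003)
  expect_equal(variantFraction(0, 1000), 0)
  expect_error(variantFraction(1, 0), "gene not expressed")
})

test_that("a simulated 0.7% variant is recovered within binomial error", {
  p <- 0.007
  n <- 1e5
  cfg <- simulationConfig(nReads = n, seed = 99,
                          junctionProb = c(skip3 = p),
                          anchorRange = c(8, 92))
  s <- simulateSample(cfg)
  tb <- countJunctions(s$records, s$catalogue, s$gene, filterConfig(), "x")
  cts <- junctionCounts(tb)
  tj <- s$truth$junctions
  frac <- variantFraction(cts$count[cts$donor_end == tj$donor_end &
                                      cts$acceptor_start ==
                                        tj$acceptor_start],
                          geneReads(tb))
  se3 <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), se3)
})

test_that("replicate averaging collapses donors to arithmetic means", {
  se <- make_se(list(a1 = c(v = 3), a2 = c(v = 6), a3 = c(v = 9),
                     b = c(v = 10)),
                totals = list(a1 = 1e6, a2 = 1e6, a3 = 1e6, b = 1e6),
                samples = data.frame(
                  sample_id = c("a1", "a2", "a3", "b"),
                  group = "g",
                  replicate_of = c("dA", "dA", "dA", NA)))
  avg <- averageReplicates(se)
  expect_equal(ncol(avg), 2L)
  expect_equal(SummarizedExperiment::assay(avg, "sjtpm")["v", "dA"], 6)
  # singleton group: row unchanged
  expect_equal(SummarizedExperiment::assay(avg, "sjtpm")["v", "b"], 10)
  # identical metadata propagated
  expect_equal(unique(SummarizedExperiment::colData(avg)$group), "g")
  expect_error(averageReplicates(se, c(zz = "d1")),
               "unknown replicate member")
})

test_that("70 samples with 6 triplicated donors average to 58 columns", {
  sids <- sprintf("s%02d", 1:70)
  rep_of <- rep(NA_character_, 70)
  # 6 donors x 3 replicates occupy the first 18 samples
  for (d in 1:6) rep_of[(3 * d - 2):(3 * d)] <- sprintf("donor%d", d)
  cts <- stats::setNames(lapply(seq_along(sids), function(i) c(v = i)), sids)
  se <- make_se(cts, totals = as.list(stats::setNames(rep(1e6, 70), sids)),
                samples = data.frame(sample_id = sids, group = "g",
                                     replicate_of = rep_of))
  avg <- averageReplicates(se)
  expect_equal(ncol(avg), 70 - 6 * (3 - 1))   # 58, by direct counting
})

test_that("group aggregation reports mean and sample SD", {
  se <- make_se(list(s1 = c(v = 2), s2 = c(v = 4), s3 = c(v = 5),
                     s4 = c(v = 0), s5 = c(v = 0)),
                totals = list(s1 = 1e6, s2 = 1e6, s3 = 1e6, s4 = 1e6,
                              s5 = 1e6),
                samples = data.frame(
                  sample_id = paste0("s", 1:5),
                  group = c("g1", "g1", "solo", "zero", "zero")))
  gs <- aggregateGroups(se, "group")
  g1 <- gs[gs$group == "g1", ]
  expect_equal(g1$mean, 3)
  expect_equal(g1$sd, sqrt(2))
  solo <- gs[gs$group == "solo", ]
  expect_equal(solo$mean, 5)
  expect_equal(solo$sd, 0)      # singleton: SD reported as 0
  zero <- gs[gs$group == "zero", ]
  expect_equal(c(zero$mean, zero$sd), c(0, 0))
  expect_error(aggregateGroups(se, "nope"), "missing metadata column")
})

test_that("presence counts samples at or above the detection threshold", {
  sids <- sprintf("s%02d", 1:70)
  cts <- stats::setNames(lapply(seq_along(sids), function(i)
    c(hit = if (i <= 28) 5 else 0, none = 0)), sids)
  se <- make_se(cts, totals = as.list(stats::setNames(rep(1e6, 70), sids)))
  pres <- presenceSummary(se)
  expect_equal(pres[["hit"]], 28L)   # built to be present in 28 of 70
  expect_equal(pres[["none"]], 0L)
  expect_true(all(presenceSummary(se, detection_threshold = 100) == 0L))
  # non-increasing in the threshold
  th <- c(1, 2, 5, 6, 100)
  ps <- vapply(th, function(t) presenceSummary(se, t)[["hit"]], integer(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("SJ TPM is invariant to a common scaling of all counts", {
  se1 <- make_se(list(s = c(v1 = 7, v2 = 3)), totals = list(s = 2e5))
  se9 <- make_se(list(s = c(v1 = 63, v2 = 27)), totals = list(s = 18e5))
  expect_equal(SummarizedExperiment::assay(se1, "sjtpm"),
               SummarizedExperiment::assay(se9, "sjtpm"))
})

test_that("replicate averaging commutes with balanced group aggregation", {
  sids <- paste0("s", 1:6)
  cts <- stats::setNames(lapply(c(1, 3, 8, 10, 4, 6), function(i)
    c(v = i)), sids)
  # each donor's replicates sit entirely inside one balanced group
  samples <- data.frame(sample_id = sids,
                        group = rep(c("gA", "gB"), each = 3),
                        replicate_of = c("d1", "d1", "d1",
                                         "d2", "d2", "d2"))
  se <- make_se(cts, totals = as.list(stats::setNames(rep(1e6, 6), sids)),
                samples = samples)
  direct <- aggregateGroups(se, "group")
  avg <- averageReplicates(se)
  via <- aggregateGroups(avg, "group")
  expect_equal(via$mean[order(via$group)], direct$mean[order(direct$group)])
})

test_that("fraction of total isoform expression sums to 100 percent", {
  se <- make_se(list(s1 = c(v1 = 30, v2 = 70), s2 = c(v1 = 10, v2 = 10)),
                totals = list(s1 = 1e6, s2 = 1e6))
  for (m in c("pooled", "per_sample")) {
    pct <- fractionOfExpression(se, m)
    expect_equal(sum(pct), 100)
  }
  expect_equal(fractionOfExpression(se, "pooled")[["v1"]],
               100 * (30 + 10) / (30 + 70 + 10 + 10))
})

test_that("experiment assembly validates denominators", {
  counts <- data.frame(sample_id = "s", variant_name = "v",
                       spliced_reads = 1, total_reads = 0, gene_reads = 10)
  expect_error(buildSJTPMExperiment(counts), "empty library")
  counts$total_reads <- 100; counts$gene_reads <- 0
  expect_error(buildSJTPMExperiment(counts), "gene not expressed")
})
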