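#' Splice Junction Tags Per Million
#'
#' The per-variant expression unit: junction-spanning reads for the variant
#' divided by the total number of reads in the library, times one million.
#' At a depth of 2e8 reads, 7 spanning reads give 0.035 SJ TPM. Vectorized;
#' recycling applies.
#'
#' @param spliced_reads junction-spanning read count(s).
#' @param total_reads library denominator(s); must be positive.
#' @return numeric SJ TPM value(s).
#' @examples
#' sjTPM(5, 1e6)    # 5.0
#' sjTPM(7, 2e8)    # 0.035
#' @export
sjTPM <- function(spliced_reads, total_reads) {
  if (any(total_reads == 0)) .stopf("empty library: total_reads is 0")
  spliced_reads / total_reads * 1e6
}

#' Gene-relative isoform fraction
#'
#' Variant junction-spanning reads divided by the filtered reads overlapping
#' the gene span: the fraction of the gene's expression attributable to the
#' variant's discriminating junction. Multiply by 100 for percent.
#'
#' @param variant_spliced_reads variant junction-spanning read count(s).
#' @param gene_reads filtered reads overlapping the gene span; must be > 0.
#' @return numeric proportion(s).
#' @examples
#' variantFraction(3, 1000)  # 0.003, i.e. 0.3%
#' @export
variantFraction <- function(variant_spliced_reads, gene_reads) {
  if (any(gene_reads == 0)) .stopf("gene not expressed in sample")
  variant_spliced_reads / gene_reads
}

#' Long-format counts frame from per-sample count tables
#'
#' One row per (sample, discriminating junction), the same layout written by
#' [writeCountsTSV()] and consumed by [buildSJTPMExperiment()].
#'
#' @param tables list of [JunctionCountTable-class].
#' @param catalogue the [JunctionCatalogue-class] used for counting.
#' @return data.frame with columns sample_id, variant_name, chrom,
#'   donor_end, acceptor_start, spliced_reads, total_reads, gene_reads.
#' @export
countsFrame <- function(tables, catalogue) {
  jn <- catalogue@junctions
  disc <- jn[jn$discriminating, , drop = FALSE]
  if (nrow(disc) == 0L) .stopf("catalogue has no discriminating junctions")
  do.call(rbind, lapply(tables, function(tb) {
    cts <- tb@counts
    m <- match(junctionKey(disc$chrom, disc$donor_end, disc$acceptor_start),
               junctionKey(cts$chrom, cts$donor_end, cts$acceptor_start))
    data.frame(sample_id = tb@sampleId, variant_name = disc$variant_name,
               chrom = disc$chrom, donor_end = disc$donor_end,
               acceptor_start = disc$acceptor_start,
               spliced_reads = cts$count[m],
               total_reads = tb@totalReads, gene_reads = tb@geneReads,
               stringsAsFactors = FALSE)
  }))
}

#' Assemble the variants x samples expression container
#'
#' Builds an [SJTPMExperiment-class] from a long counts frame (from
#' [countsFrame()] or a counts TSV read back with [readCountsTSV()]).
#' A variant with several discriminating junctions is quantified as the sum
#' of their counts (one number per variant); the per-junction breakdown is
#' kept in \code{metadata()$junction_counts}.
#'
#' @param counts long counts data.frame (sample_id, variant_name,
#'   spliced_reads, total_reads, gene_reads, and junction columns).
#' @param samples optional sample sheet data.frame with \code{sample_id} and
#'   metadata columns (e.g. \code{group}, \code{replicate_of}).
#' @return an [SJTPMExperiment-class] with assays \code{counts},
#'   \code{sjtpm}, \code{fraction}.
#' @export
buildSJTPMExperiment <- function(counts, samples = NULL) {
  need <- c("sample_id", "variant_name", "spliced_reads", "total_reads",
            "gene_reads")
  if (!all(need %in% names(counts)))
    .stopf("counts frame needs columns %s", paste(need, collapse = ", "))
  sids <- unique(counts$sample_id)
  vars <- unique(counts$variant_name)
  agg <- stats::aggregate(spliced_reads ~ variant_name + sample_id,
                          data = counts, FUN = sum)
  cmat <- matrix(0, nrow = length(vars), ncol = length(sids),
                 dimnames = list(vars, sids))
  cmat[cbind(agg$variant_name, agg$sample_id)] <- agg$spliced_reads

  denom <- unique(counts[, c("sample_id", "total_reads", "gene_reads")])
  if (anyDuplicated(denom$sample_id))
    .stopf("inconsistent denominators within a sample")
  denom <- denom[match(sids, denom$sample_id), ]
  if (any(denom$total_reads == 0))
    .stopf("empty library: total_reads is 0 for sample %s",
           denom$sample_id[denom$total_reads == 0][1L])
  if (any(denom$gene_reads == 0))
    .stopf("gene not expressed in sample %s",
           denom$sample_id[denom$gene_reads == 0][1L])

  tpm <- sweep(cmat, 2L, denom$total_reads, "/") * 1e6
  frac <- sweep(cmat, 2L, denom$gene_reads, "/")

  cd <- S4Vectors::DataFrame(sample_id = sids,
                             total_reads = denom$total_reads,
                             gene_reads = denom$gene_reads,
                             row.names = sids)
  if (!is.null(samples)) {
    missing <- setdiff(sids, samples$sample_id)
    if (length(missing))
      .stopf("sample sheet is missing sample(s): %s",
             paste(missing, collapse = ", "))
    extra <- samples[match(sids, samples$sample_id),
                     setdiff(names(samples), "sample_id"), drop = FALSE]
    for (nm in names(extra)) cd[[nm]] <- extra[[nm]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cmat, sjtpm = tpm, fraction = frac),
    rowData = S4Vectors::DataFrame(variant_name = vars, row.names = vars),
    colData = cd)
  out <- new("SJTPMExperiment", se)
  S4Vectors::metadata(out)$junction_counts <- counts
  out
}

#' Average technical/biological replicates to one row per donor
#'
#' Collapses replicate samples (same donor) to their arithmetic mean, per
#' variant and per assay. The mapping comes from the \code{replicate_of}
#' column of \code{colData} unless given explicitly; samples without an
#' entry (NA or empty) are their own singleton group. Sample metadata is
#' propagated when identical across the replicates of a donor, otherwise
#' set to NA.
#'
#' @param se an [SJTPMExperiment-class].
#' @param replicate_map optional named character vector sample_id -> donor.
#' @return an [SJTPMExperiment-class] with one column per donor.
#' @export
averageReplicates <- function(se, replicate_map = NULL) {
  cd <- SummarizedExperiment::colData(se)
  if (is.null(replicate_map)) {
    rep_of <- if ("replicate_of" %in% names(cd))
      as.character(cd$replicate_of) else rep(NA_character_, ncol(se))
    rep_of[is.na(rep_of) | rep_of == ""] <-
      rownames(cd)[is.na(rep_of) | rep_of == ""]
    replicate_map <- stats::setNames(rep_of, rownames(cd))
  } else {
    unknown <- setdiff(names(replicate_map), colnames(se))
    if (length(unknown))
      .stopf("unknown replicate member: %s", paste(unknown, collapse = ", "))
    full <- stats::setNames(colnames(se), colnames(se))
    full[names(replicate_map)] <- replicate_map
    replicate_map <- full
  }
  donor <- replicate_map[colnames(se)]
  donors <- unique(donor)
  avg <- function(mat) {
    out <- vapply(donors, function(d)
      rowMeans(mat[, donor == d, drop = FALSE]), numeric(nrow(mat)))
    out <- matrix(out, nrow = nrow(mat),
                  dimnames = list(rownames(mat), donors))
    out
  }
  assays <- lapply(SummarizedExperiment::assays(se), avg)
  newcd <- S4Vectors::DataFrame(row.names = donors)
  for (nm in names(cd)) {
    vals <- lapply(donors, function(d) unique(cd[[nm]][donor == d]))
    one <- vapply(vals, length, integer(1)) == 1L
    col <- rep(NA, length(donors))
    col[one] <- unlist(vals[one])
    newcd[[nm]] <- col
  }
  newcd$sample_id <- donors
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = SummarizedExperiment::rowData(se), colData = newcd)
  out <- new("SJTPMExperiment", se2)
  S4Vectors::metadata(out) <- S4Vectors::metadata(se)
  out
}

#' Per-group mean and standard deviation per variant
#'
#' Summarizes an assay (SJ TPM by default) over a sample grouping, the way
#' per-tissue distributions are usually displayed: group mean and sample
#' standard deviation (n - 1 denominator; 0 for singleton groups).
#'
#' @param se an [SJTPMExperiment-class].
#' @param group_key name of a \code{colData} column.
#' @param assay which assay to summarize.
#' @return data.frame with columns group, variant, mean, sd, n.
#' @export
aggregateGroups <- function(se, group_key = "group", assay = "sjtpm") {
  cd <- SummarizedExperiment::colData(se)
  if (!group_key %in% names(cd))
    .stopf("missing metadata column: %s", group_key)
  g <- as.character(cd[[group_key]])
  mat <- SummarizedExperiment::assay(se, assay)
  out <- do.call(rbind, lapply(unique(g), function(grp) {
    sub <- mat[, g == grp, drop = FALSE]
    data.frame(group = grp, variant = rownames(mat),
               mean = rowMeans(sub),
               sd = if (ncol(sub) > 1L) apply(sub, 1L, stats::sd) else 0,
               n = ncol(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Number of samples in which each variant is detected
#'
#' A variant is "present" in a sample when its raw junction-spanning read
#' count reaches the detection threshold (default: a single filtered read).
#' Non-increasing in the threshold.
#'
#' @param se an [SJTPMExperiment-class].
#' @param detection_threshold minimum raw count to call presence.
#' @return named integer vector, one entry per variant, in [0, n samples].
#' @export
presenceSummary <- function(se, detection_threshold = 1) {
  cmat <- SummarizedExperiment::assay(se, "counts")
  apply(cmat >= detection_threshold, 1L, sum)
}

#' Fraction of total isoform expression per variant
#'
#' Percent of the summed isoform SJ TPM attributable to each variant.
#' \code{"pooled"} sums SJ TPM over all samples before taking percentages;
#' \code{"per_sample"} computes per-sample percentages and averages them
#' (samples with no isoform signal are skipped). Both views are offered
#' because either is a reasonable reading of a whole-cohort isoform pie.
#'
#' @param se an [SJTPMExperiment-class].
#' @param method \code{"pooled"} or \code{"per_sample"}.
#' @return named numeric vector of percentages summing to 100.
#' @export
fractionOfExpression <- function(se, method = c("pooled", "per_sample")) {
  method <- match.arg(method)
  tpm <- SummarizedExperiment::assay(se, "sjtpm")
  if (method == "pooled") {
    tot <- rowSums(tpm)
    return(100 * tot / sum(tot))
  }
  cs <- colSums(tpm)
  keep <- cs > 0
  pct <- sweep(tpm[, keep, drop = FALSE], 2L, cs[keep], "/") * 100
  rowMeans(pct)
}

#' Read a sample sheet TSV (sample_id, group, replicate_of, ...)
#' @param path TSV path.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  ss <- .readTSV(path)
  if (!"sample_id" %in% names(ss))
    .stopf("sample sheet needs a sample_id column")
  ss
}

#' Read a counts TSV written by [writeCountsTSV()]
#' @param path TSV path.
#' @return long counts data.frame.
#' @export
readCountsTSV <- function(path) .readTSV(path)
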