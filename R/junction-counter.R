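## Junction-spanning read counting.
##
## Junctions are extracted from the skipped-region (N) operations of the
## CIGAR, in genomic coordinates, and matched against the catalogue exactly
## (no coordinate tolerance). Anchors are the contiguous reference-consuming
## blocks immediately flanking the junction within the read's alignment;
## soft clips and insertions never contribute.

# SAM flag bits
.FLAG_UNMAPPED <- 0x4L
.FLAG_SECONDARY <- 0x100L
.FLAG_DUP <- 0x400L
.FLAG_SUPPLEMENTARY <- 0x800L

# reference-consuming blocks between N gaps, as an IRangesList per record
.refBlocks <- function(cigar, pos) {
  bad <- !grepl("^(\\d+[MIDNSHP=X])+$", cigar)
  if (any(bad))
    .stopf("unparseable alignment: bad CIGAR '%s'", cigar[bad][1L])
  tryCatch(
    GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, pos = pos, ops = c("M", "D", "=", "X"), reduce.ranges = TRUE),
    error = function(e) .stopf("unparseable alignment: %s",
                               conditionMessage(e)))
}

#' Extract splice junctions spanned by alignment records
#'
#' One junction per skipped-region (N) CIGAR operation: \code{donor_end} is
#' the last reference base consumed before the skip, \code{acceptor_start}
#' the first reference base after it. Anchor lengths are the widths of the
#' reference-consuming blocks flanking the junction, bounded by the adjacent
#' skip or the read end. Vectorized over records; reads without skips
#' contribute no rows.
#'
#' @param cigar CIGAR string(s); records with CIGAR \code{"*"} (unmapped)
#'   yield no junctions.
#' @param pos 1-based leftmost mapping position(s).
#' @param chrom optional chromosome name(s), recycled; carried into the
#'   result when given.
#' @return \code{data.frame} with columns \code{record} (index into the
#'   input), \code{chrom} (if given), \code{donor_end},
#'   \code{acceptor_start}, \code{left_anchor}, \code{right_anchor}.
#' @examples
#' extractReadJunctions("50M200N50M", 100)   # junction (149, 350)
#' extractReadJunctions("100M", 100)         # no junctions
#' @export
extractReadJunctions <- function(cigar, pos, chrom = NULL) {
  stopifnot(length(cigar) == length(pos))
  mapped <- cigar != "*" & !is.na(cigar)
  empty <- data.frame(record = integer(), donor_end = integer(),
                      acceptor_start = integer(), left_anchor = integer(),
                      right_anchor = integer())
  if (!is.null(chrom))
    empty <- cbind(empty[, 1L, drop = FALSE], chrom = character(),
                   empty[, -1L])
  if (!any(mapped)) return(empty)
  idx <- which(mapped)
  irl <- .refBlocks(cigar[idx], pos[idx])
  nb <- S4Vectors::elementNROWS(irl)
  if (all(nb <= 1L)) return(empty)
  ir <- unlist(irl, use.names = FALSE)
  rec <- rep(idx, nb)
  i <- which(rec[-1L] == rec[-length(rec)])
  out <- data.frame(
    record = rec[i],
    donor_end = IRanges::end(ir)[i],
    acceptor_start = IRanges::start(ir)[i + 1L],
    left_anchor = IRanges::width(ir)[i],
    right_anchor = IRanges::width(ir)[i + 1L])
  if (!is.null(chrom)) {
    chrom <- rep(chrom, length.out = length(cigar))
    out <- cbind(out[, 1L, drop = FALSE], chrom = chrom[out$record],
                 out[, -1L])
  }
  out
}

#' Anchor lengths of a read around one junction
#'
#' @param cigar,pos one alignment record.
#' @param donor_end,acceptor_start the junction, 1-based genomic.
#' @return named integer vector \code{c(left, right)}.
#' @examples
#' anchorLengths("5M200N95M", 100, 104, 305)  # c(left = 5, right = 95)
#' @export
anchorLengths <- function(cigar, pos, donor_end, acceptor_start) {
  j <- extractReadJunctions(cigar, pos)
  hit <- j$donor_end == donor_end & j$acceptor_start == acceptor_start
  if (!any(hit)) .stopf("junction not spanned by read")
  c(left = j$left_anchor[hit][1L], right = j$right_anchor[hit][1L])
}

# record-level filter (mapping state, flags, mapq); vectorized
.recordPass <- function(flag, mapq, cfg) {
  pass <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  if (cfg@primaryOnly)
    pass <- pass & bitwAnd(flag, .FLAG_SECONDARY) == 0L
  if (cfg@excludeSecondarySupplementary)
    pass <- pass & bitwAnd(flag, .FLAG_SECONDARY) == 0L &
      bitwAnd(flag, .FLAG_SUPPLEMENTARY) == 0L
  if (cfg@excludeDuplicates)
    pass <- pass & bitwAnd(flag, .FLAG_DUP) == 0L
  pass & !is.na(mapq) & mapq >= cfg@minMapq
}

#' Does a junction-spanning record pass the stringent filters?
#'
#' Record-level: mapped, primary/duplicate/secondary-supplementary flags per
#' the config, mapping quality at least \code{minMapq}. Junction-level: both
#' anchors at least \code{minAnchor} aligned bases ("at least" is inclusive:
#' an 8 nt anchor passes at \code{minAnchor = 8}). Vectorized.
#'
#' @param flag SAM flag(s).
#' @param mapq mapping quality(ies).
#' @param left_anchor,right_anchor anchor lengths around the junction.
#' @param cfg a [FilterConfig-class].
#' @return logical vector.
#' @export
passesFilters <- function(flag, mapq, left_anchor, right_anchor,
                          cfg = filterConfig()) {
  .recordPass(flag, mapq, cfg) &
    left_anchor >= cfg@minAnchor & right_anchor >= cfg@minAnchor
}

# parse SAM text / BAM into a uniform record frame
.readRecords <- function(x) {
  if (is.data.frame(x)) {
    need <- c("flag", "rname", "pos", "mapq", "cigar")
    if (!all(need %in% names(x)))
      .stopf("alignment input error: records need columns %s",
             paste(need, collapse = ", "))
    return(x)
  }
  if (!file.exists(x)) .stopf("alignment input error: no such file: %s", x)
  if (grepl("\\.bam$", x, ignore.case = TRUE)) {
    res <- tryCatch(
      Rsamtools::scanBam(x, param = Rsamtools::ScanBamParam(
        what = c("flag", "rname", "pos", "mapq", "cigar")))[[1L]],
      error = function(e) .stopf("alignment input error: %s",
                                 conditionMessage(e)))
    return(data.frame(flag = res$flag, rname = as.character(res$rname),
                      pos = res$pos, mapq = res$mapq, cigar = res$cigar,
                      stringsAsFactors = FALSE))
  }
  lines <- tryCatch(readLines(x), error = function(e)
    .stopf("alignment input error: %s", conditionMessage(e)))
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(f, length, integer(1)) < 11L))
    .stopf("alignment input error: SAM record with fewer than 11 fields")
  data.frame(
    flag = as.integer(vapply(f, `[[`, character(1), 2L)),
    rname = vapply(f, `[[`, character(1), 3L),
    pos = as.integer(vapply(f, `[[`, character(1), 4L)),
    mapq = as.integer(vapply(f, `[[`, character(1), 5L)),
    cigar = vapply(f, `[[`, character(1), 6L),
    stringsAsFactors = FALSE)
}

#' Count junction-spanning reads in an alignment file
#'
#' Counts, for every junction in the catalogue, the distinct filtered reads
#' whose alignment spans that exact junction (coordinate match, no
#' tolerance) with both anchors at least \code{minAnchor}. A read spanning k
#' catalogue junctions contributes 1 to each of the k counts but only once
#' to \code{totalReads}. \code{totalReads} is the number of records passing
#' the record-level filters regardless of splicing (the SJ TPM denominator);
#' \code{geneReads} is the subset of those overlapping the gene's genomic
#' span (the gene-relative fraction denominator). Reads with additional,
#' unannotated junctions still count for the catalogue junctions they span.
#'
#' @param x path to a SAM or BAM file, or an in-memory record
#'   \code{data.frame} with columns \code{flag}, \code{rname}, \code{pos},
#'   \code{mapq}, \code{cigar} (as produced by [simulateReads()]).
#' @param catalogue a [JunctionCatalogue-class].
#' @param gene the [GeneModel-class] (for the gene-span denominator).
#' @param cfg a [FilterConfig-class]; the object returned embeds it.
#' @param sample_id sample identifier recorded in the result.
#' @return a [JunctionCountTable-class].
#' @export
countJunctions <- function(x, catalogue, gene, cfg = filterConfig(),
                           sample_id = "sample") {
  stopifnot(is(catalogue, "JunctionCatalogue"), is(gene, "GeneModel"))
  jn <- catalogue@junctions
  if (nrow(jn) == 0L) .stopf("empty junction catalogue")
  uj <- unique(jn[, c("chrom", "donor_end", "acceptor_start")])
  rec <- .readRecords(x)

  pass <- .recordPass(rec$flag, rec$mapq, cfg)
  total <- sum(pass)

  span <- geneSpan(gene)
  gene_reads <- 0L
  if (total > 0L) {
    pidx <- which(pass)
    on_chrom <- rec$rname[pidx] == as.character(
      GenomicRanges::seqnames(span))
    if (any(on_chrom)) {
      ci <- pidx[on_chrom]
      w <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar[ci])
      gene_reads <- sum(rec$pos[ci] <= GenomicRanges::end(span) &
                        rec$pos[ci] + w - 1L >= GenomicRanges::start(span))
    }
  }

  counts <- integer(nrow(uj))
  pidx <- which(pass & grepl("N", rec$cigar, fixed = TRUE))
  if (length(pidx)) {
    j <- extractReadJunctions(rec$cigar[pidx], rec$pos[pidx],
                              chrom = rec$rname[pidx])
    ok <- j$left_anchor >= cfg@minAnchor & j$right_anchor >= cfg@minAnchor
    j <- j[ok, , drop = FALSE]
    if (nrow(j)) {
      keys <- junctionKey(j$chrom, j$donor_end, j$acceptor_start)
      ukeys <- junctionKey(uj$chrom, uj$donor_end, uj$acceptor_start)
      tab <- table(factor(keys, levels = ukeys))
      counts <- as.integer(tab)
    }
  }
  uj$count <- counts
  rownames(uj) <- NULL
  new("JunctionCountTable", sampleId = sample_id, counts = uj,
      totalReads = as.numeric(total), geneReads = as.numeric(gene_reads),
      filter = cfg)
}

## accessors and IO -----------------------------------------------------

#' @rdname JunctionCountTable-class
#' @export
setMethod("totalReads", "JunctionCountTable", function(x) x@totalReads)

#' @rdname JunctionCountTable-class
#' @export
setMethod("geneReads", "JunctionCountTable", function(x) x@geneReads)

#' @rdname JunctionCountTable-class
#' @export
setMethod("junctionCounts", "JunctionCountTable", function(x) x@counts)

setMethod("show", "JunctionCountTable", function(object) {
  cat("JunctionCountTable:", object@sampleId, "\n")
  cat(sprintf("  %d junctions; totalReads %g; geneReads %g\n",
              nrow(object@counts), object@totalReads, object@geneReads))
  cat(sprintf("  filters: minAnchor %d, minMapq %d\n",
              object@filter@minAnchor, object@filter@minMapq))
})

#' Write per-sample junction counts as TSV
#'
#' One row per (sample, discriminating junction): sample_id, variant_name,
#' chrom, donor_end, acceptor_start, spliced_reads, total_reads, gene_reads.
#'
#' @param tables list of [JunctionCountTable-class] (one per sample).
#' @param catalogue the [JunctionCatalogue-class] used for counting.
#' @param path output TSV.
#' @param comments optional '#' header comment lines.
#' @return the combined data.frame, invisibly.
#' @export
writeCountsTSV <- function(tables, catalogue, path, comments = character()) {
  jn <- catalogue@junctions
  disc <- jn[jn$discriminating, , drop = FALSE]
  rows <- lapply(tables, function(tb) {
    cts <- tb@counts
    m <- match(junctionKey(disc$chrom, disc$donor_end, disc$acceptor_start),
               junctionKey(cts$chrom, cts$donor_end, cts$acceptor_start))
    data.frame(sample_id = tb@sampleId,
               variant_name = disc$variant_name,
               chrom = disc$chrom, donor_end = disc$donor_end,
               acceptor_start = disc$acceptor_start,
               spliced_reads = cts$count[m],
               total_reads = tb@totalReads, gene_reads = tb@geneReads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  .writeTSV(out, path, comments)
  invisible(out)
}
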