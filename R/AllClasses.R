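#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList start end strand seqnames
#' @importFrom IRanges IRanges
NULL

#' GeneModel: one gene and its transcript structures
#'
#' Container for a single gene of interest: its genomic location, strand,
#' canonical transcript, and the exon structure of every transcript
#' (splice variant) attributed to it. All coordinates are 1-based and
#' inclusive, as in GTF. Exons within each transcript carry a
#' \code{transcript_rank} column numbering exons in transcript orientation
#' (rank 1 is the 5' exon, i.e. the genomically rightmost exon for a
#' minus-strand gene such as P4HB).
#'
#' @slot geneId gene identifier from the annotation.
#' @slot chrom chromosome name shared by all transcripts.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot canonicalId transcript_id of the canonical isoform.
#' @slot exons \code{GRangesList} named by transcript_id; each element holds
#'   that transcript's exons with a \code{transcript_rank} metadata column.
#' @slot txData \code{DataFrame} with one row per transcript: columns
#'   \code{transcript_id}, \code{variant_name}, \code{biotype},
#'   \code{cds_start}, \code{cds_end} (CDS bounds may be \code{NA}).
#'
#' @seealso [parseGeneModels()], [deriveJunctions()],
#'   [discriminatingJunctions()]
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    chrom = "character",
    strand = "character",
    canonicalId = "character",
    exons = "GRangesList",
    txData = "DataFrame"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (length(object@exons) < 1L)
    msg <- c(msg, "a GeneModel needs at least one transcript")
  if (!identical(names(object@exons), object@txData$transcript_id))
    msg <- c(msg, "exons names and txData$transcript_id must agree")
  if (!object@canonicalId %in% object@txData$transcript_id)
    msg <- c(msg, "canonical transcript not found")
  if (anyDuplicated(object@txData$variant_name))
    msg <- c(msg, "variant_name must be unique within a gene")
  for (i in seq_along(object@exons)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) {
      msg <- c(msg, "transcript with no exons")
      next
    }
    if (length(ex) > 1L) {
      o <- order(GenomicRanges::start(ex))
      if (any(GenomicRanges::start(ex)[o][-1L] <=
              GenomicRanges::end(ex)[o][-length(ex)]))
        msg <- c(msg, sprintf("invalid transcript structure: overlapping exons in %s",
                              names(object@exons)[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' FilterConfig: stringent read filters for junction counting
#'
#' Bundle of the record- and junction-level filters applied when counting
#' junction-spanning reads. The anchor filter requires a minimum number of
#' aligned (reference-consuming) bases on each side of the splice junction
#' within the read; short anchors are unreliable evidence for a junction.
#' The default of 8 nt mirrors the junction-overlap rule used for
#' junction-spanning qPCR primers (at least 8 bases on each side).
#'
#' @slot minAnchor minimum aligned bases flanking the junction on each side
#'   (nt, default 8).
#' @slot minMapq minimum mapping quality (default 0).
#' @slot primaryOnly drop non-primary alignments (default \code{TRUE}).
#' @slot excludeDuplicates drop PCR/optical duplicates (default \code{TRUE}).
#' @slot excludeSecondarySupplementary drop secondary and supplementary
#'   records (default \code{TRUE}).
#' @export
setClass("FilterConfig",
  representation(
    minAnchor = "integer",
    minMapq = "integer",
    primaryOnly = "logical",
    excludeDuplicates = "logical",
    excludeSecondarySupplementary = "logical"
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@minAnchor < 1L) msg <- c(msg, "minAnchor must be >= 1")
  if (object@minMapq < 0L) msg <- c(msg, "minMapq must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname FilterConfig-class
#' @param minAnchor,minMapq,primaryOnly,excludeDuplicates,excludeSecondarySupplementary
#'   see slot documentation.
#' @return a \code{FilterConfig} object.
#' @examples
#' filterConfig()               # stringent defaults
#' filterConfig(minAnchor = 1)  # permissive anchors
#' @export
filterConfig <- function(minAnchor = 8, minMapq = 0, primaryOnly = TRUE,
                         excludeDuplicates = TRUE,
                         excludeSecondarySupplementary = TRUE) {
  new("FilterConfig",
      minAnchor = as.integer(minAnchor),
      minMapq = as.integer(minMapq),
      primaryOnly = primaryOnly,
      excludeDuplicates = excludeDuplicates,
      excludeSecondarySupplementary = excludeSecondarySupplementary)
}

#' JunctionCatalogue: the junctions that identify each splice variant
#'
#' One row per (transcript, junction). A junction is keyed on
#' (chrom, donor_end, acceptor_start): the last base of the genomically-left
#' flanking exon and the first base of the genomically-right flanking exon,
#' both 1-based. Junction identity is strand-agnostic; counting operates in
#' genomic space. The \code{discriminating} flag marks junctions present in
#' exactly one transcript of the gene, which makes their spanning reads
#' attributable to that variant. Variants none of whose junctions are unique
#' are listed in \code{unquantifiable}: the method cannot see them, and users
#' must know that.
#'
#' @slot geneId the gene the catalogue was built for.
#' @slot junctions \code{data.frame} with columns \code{variant_name},
#'   \code{transcript_id}, \code{chrom}, \code{donor_end},
#'   \code{acceptor_start}, \code{discriminating}.
#' @slot unquantifiable character vector of variant_names with no
#'   discriminating junction.
#' @seealso [discriminatingJunctions()], [countJunctions()]
#' @export
setClass("JunctionCatalogue",
  representation(
    geneId = "character",
    junctions = "data.frame",
    unquantifiable = "character"
  )
)

setValidity("JunctionCatalogue", function(object) {
  need <- c("variant_name", "transcript_id", "chrom", "donor_end",
            "acceptor_start", "discriminating")
  if (!all(need %in% names(object@junctions)))
    return("junctions must have variant_name, transcript_id, chrom, donor_end, acceptor_start, discriminating")
  j <- object@junctions
  if (nrow(j) && any(j$acceptor_start < j$donor_end + 2L))
    return("acceptor_start must be >= donor_end + 2 (intron length >= 1)")
  TRUE
})

#' JunctionCountTable: per-sample junction-spanning read counts
#'
#' Junction-spanning read counts for one sample, together with the
#' denominators needed for normalization: \code{totalReads} (records passing
#' the record-level filters, whether spliced or not — the SJ TPM denominator)
#' and \code{geneReads} (the subset overlapping the gene's genomic span — the
#' gene-relative fraction denominator). The \code{FilterConfig} actually
#' applied is carried along so reports are self-describing.
#'
#' @slot sampleId sample identifier.
#' @slot counts \code{data.frame} with columns \code{chrom},
#'   \code{donor_end}, \code{acceptor_start}, \code{count}.
#' @slot totalReads number of records passing record-level filters.
#' @slot geneReads filtered records overlapping the gene span.
#' @slot filter the \code{FilterConfig} applied.
#' @export
setClass("JunctionCountTable",
  representation(
    sampleId = "character",
    counts = "data.frame",
    totalReads = "numeric",
    geneReads = "numeric",
    filter = "FilterConfig"
  )
)

setValidity("JunctionCountTable", function(object) {
  msg <- character()
  if (object@geneReads > object@totalReads)
    msg <- c(msg, "geneReads cannot exceed totalReads")
  if (nrow(object@counts) && any(object@counts$count > object@totalReads))
    msg <- c(msg, "a junction count cannot exceed totalReads")
  if (nrow(object@counts) && any(object@counts$count < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SJTPMExperiment: variants x samples expression container
#'
#' A \code{SummarizedExperiment} with splice variants as rows and samples as
#' columns, holding three assays: \code{counts} (raw junction-spanning reads
#' summed over each variant's discriminating junctions), \code{sjtpm}
#' (Splice Junction Tags Per Million) and \code{fraction} (gene-relative
#' isoform fraction, counts / gene reads). Sample metadata (group,
#' replicate_of, the denominators) live in \code{colData}; the per-junction
#' count breakdown is kept in \code{metadata(x)$junction_counts}.
#'
#' Note that discriminating-junction counts are not a partition of the gene's
#' reads, so fractions are comparable across variants but need not sum to 1.
#'
#' @seealso [buildSJTPMExperiment()], [sjTPM()], [variantFraction()]
#' @export
setClass("SJTPMExperiment", contains = "SummarizedExperiment")
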