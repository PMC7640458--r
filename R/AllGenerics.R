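#' @rdname GeneModel-class
#' @param x,object a \code{GeneModel} (or other object with the accessor).
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname GeneModel-class
#' @export
setGeneric("canonicalId", function(x) standardGeneric("canonicalId"))

#' @rdname GeneModel-class
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname GeneModel-class
#' @export
setGeneric("variantNames", function(x) standardGeneric("variantNames"))

#' @rdname GeneModel-class
#' @export
setGeneric("exonsBy", function(x, ...) standardGeneric("exonsBy"))

#' Derive splice junctions from exon structures
#'
#' One junction per adjacent genomic exon pair: \code{donor_end} is the last
#' base of the genomically-left exon, \code{acceptor_start} the first base of
#' the genomically-right exon (1-based, inclusive). A transcript with n exons
#' yields n - 1 junctions; single-exon transcripts yield none. Junctions are
#' strand-agnostic.
#'
#' @param x a \code{GeneModel} or a \code{GRanges} of one transcript's exons.
#' @param ... for the \code{GeneModel} method, \code{transcript_id} restricts
#'   to one transcript.
#' @return \code{data.frame} with columns \code{transcript_id} (GeneModel
#'   method), \code{chrom}, \code{donor_end}, \code{acceptor_start}.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 301), c(200, 400)))
#' deriveJunctions(ex)  # one junction: 200 -> 301
#' @export
setGeneric("deriveJunctions", function(x, ...) standardGeneric("deriveJunctions"))

#' @rdname JunctionCatalogue-class
#' @param x a \code{JunctionCatalogue}.
#' @export
setGeneric("unquantifiableVariants",
           function(x) standardGeneric("unquantifiableVariants"))

#' @rdname JunctionCountTable-class
#' @param x a \code{JunctionCountTable}.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname JunctionCountTable-class
#' @export
setGeneric("geneReads", function(x) standardGeneric("geneReads"))

#' @rdname JunctionCountTable-class
#' @export
setGeneric("junctionCounts", function(x) standardGeneric("junctionCounts"))
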