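#' Parse a gene's transcript models from GTF/GFF3
#'
#' Reads an annotation file (GTF or GFF3, plain or gzipped), keeps the exon
#' features attributable to one gene, and assembles a [GeneModel-class].
#' Exons are sorted genomically within each transcript and numbered in
#' transcript orientation (\code{transcript_rank} 1 is the 5' exon; for a
#' minus-strand gene that is the genomically rightmost exon). Features of
#' other genes are ignored.
#'
#' GTF attribution uses \code{gene_id}/\code{transcript_id}; GFF3 uses
#' \code{ID}/\code{Parent} chains (common \code{"gene:"} /
#' \code{"transcript:"} identifier prefixes are tolerated). Display names
#' come from \code{transcript_name} (GTF) or \code{Name} (GFF3), falling
#' back to the transcript identifier.
#'
#' @param annotation path to a GTF or GFF3 file.
#' @param gene_id identifier of the gene of interest.
#' @param canonical_id transcript_id of the canonical isoform.
#' @return a [GeneModel-class].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'  'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'  'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
#'  gtf)
#' parseGeneModels(gtf, "g1", "t1")
#' @export
parseGeneModels <- function(annotation, gene_id, canonical_id) {
  gr <- tryCatch(rtracklayer::import(annotation),
                 error = function(e) .stopf("malformed annotation: %s",
                                            conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  strip <- function(x) sub("^(gene|transcript|gene_id|tx):", "", x)

  if ("transcript_id" %in% names(mc)) {            # GTF-style attributes
    keep <- !is.na(mc$gene_id) & mc$gene_id == gene_id
    if (!any(keep)) .stopf("gene not found: %s", gene_id)
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    tx_of <- as.character(mc$transcript_id)
    vname_of <- if ("transcript_name" %in% names(mc))
      as.character(mc$transcript_name) else tx_of
    bio_of <- if ("transcript_biotype" %in% names(mc))
      as.character(mc$transcript_biotype) else NA_character_
  } else if ("Parent" %in% names(mc)) {            # GFF3 Parent/ID chains
    id <- strip(as.character(mc$ID))
    parent <- strip(vapply(mc$Parent, function(p)
      if (length(p)) as.character(p)[1L] else NA_character_, character(1)))
    tx_rows <- !is.na(parent) & parent == gene_id & !is.na(id)
    tx_ids <- id[tx_rows]
    if (!length(tx_ids)) .stopf("gene not found: %s", gene_id)
    names(tx_ids) <- tx_ids
    vnames <- if ("Name" %in% names(mc))
      ifelse(is.na(mc$Name[tx_rows]), tx_ids, as.character(mc$Name[tx_rows]))
      else tx_ids
    bios <- if ("biotype" %in% names(mc))
      as.character(mc$biotype[tx_rows]) else NA_character_
    keep <- !is.na(parent) & parent %in% tx_ids
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    tx_of <- strip(vapply(mc$Parent, function(p) as.character(p)[1L],
                          character(1)))
    vname_of <- stats::setNames(vnames, tx_ids)[tx_of]
    bio_of <- stats::setNames(rep(bios, length.out = length(tx_ids)),
                              tx_ids)[tx_of]
  } else {
    .stopf("malformed annotation: no transcript_id or Parent attributes")
  }

  type <- as.character(gr$type)
  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  if (!any(is_exon)) .stopf("gene not found: %s (no exon features)", gene_id)

  if (any(GenomicRanges::end(gr)[is_exon] < GenomicRanges::start(gr)[is_exon]))
    .stopf("malformed annotation: exon with end < start")

  tx_ids <- unique(tx_of[is_exon])
  if (!canonical_id %in% tx_ids)
    .stopf("canonical transcript not found: %s", canonical_id)

  strand <- as.character(GenomicRanges::strand(gr)[is_exon][1L])
  if (!strand %in% c("+", "-")) strand <- "+"
  chrom <- as.character(GenomicRanges::seqnames(gr)[is_exon][1L])

  exon_list <- lapply(tx_ids, function(tid) {
    ex <- gr[is_exon & tx_of == tid]
    ex <- ex[order(GenomicRanges::start(ex))]
    out <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)),
      strand = strand)
    rk <- seq_along(out)
    if (strand == "-") rk <- rev(rk)
    out$transcript_rank <- rk
    out
  })
  names(exon_list) <- tx_ids

  cds_start <- cds_end <- rep(NA_integer_, length(tx_ids))
  if (any(is_cds)) {
    for (i in seq_along(tx_ids)) {
      cc <- gr[is_cds & tx_of == tx_ids[i]]
      if (length(cc)) {
        cds_start[i] <- min(GenomicRanges::start(cc))
        cds_end[i] <- max(GenomicRanges::end(cc))
      }
    }
  }

  vn <- vapply(tx_ids, function(tid) {
    v <- vname_of[tx_of == tid & is_exon][1L]
    if (is.na(v) || !nzchar(v)) tid else v
  }, character(1))
  bio <- vapply(tx_ids, function(tid) {
    b <- bio_of[tx_of == tid & is_exon][1L]
    as.character(b)
  }, character(1))

  new("GeneModel",
      geneId = gene_id, chrom = chrom, strand = strand,
      canonicalId = canonical_id,
      exons = GenomicRanges::GRangesList(exon_list),
      txData = S4Vectors::DataFrame(
        transcript_id = tx_ids, variant_name = unname(vn),
        biotype = unname(bio),
        cds_start = cds_start, cds_end = cds_end))
}

#' Construct a GeneModel from exon coordinate lists
#'
#' Programmatic constructor used by the simulator and by tests: supply exon
#' (start, end) pairs per transcript and get a validated [GeneModel-class].
#'
#' @param gene_id,chrom,strand,canonical_id gene-level fields.
#' @param transcripts named list; each element a 2-column matrix or
#'   data.frame of exon (start, end) rows, names are transcript_ids.
#' @param variant_names optional display names (defaults to transcript_ids).
#' @param biotype optional biotype strings.
#' @param cds optional named list of c(start, end) CDS genomic bounds.
#' @return a [GeneModel-class].
#' @export
geneModel <- function(gene_id, chrom, strand, canonical_id, transcripts,
                      variant_names = names(transcripts),
                      biotype = NA_character_, cds = NULL) {
  stopifnot(is.list(transcripts), !is.null(names(transcripts)))
  exon_list <- lapply(names(transcripts), function(tid) {
    m <- as.matrix(transcripts[[tid]])
    o <- order(m[, 1L])
    m <- m[o, , drop = FALSE]
    gr <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(as.integer(m[, 1L]), as.integer(m[, 2L])),
      strand = strand)
    rk <- seq_along(gr)
    if (strand == "-") rk <- rev(rk)
    gr$transcript_rank <- rk
    gr
  })
  names(exon_list) <- names(transcripts)
  cs <- ce <- rep(NA_integer_, length(transcripts))
  if (!is.null(cds)) {
    for (i in seq_along(transcripts)) {
      b <- cds[[names(transcripts)[i]]]
      if (!is.null(b)) { cs[i] <- as.integer(b[1L]); ce[i] <- as.integer(b[2L]) }
    }
  }
  new("GeneModel",
      geneId = gene_id, chrom = chrom, strand = strand,
      canonicalId = canonical_id,
      exons = GenomicRanges::GRangesList(exon_list),
      txData = S4Vectors::DataFrame(
        transcript_id = names(transcripts),
        variant_name = variant_names,
        biotype = rep(biotype, length.out = length(transcripts)),
        cds_start = cs, cds_end = ce))
}

## accessors ------------------------------------------------------------

#' @rdname GeneModel-class
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname GeneModel-class
#' @export
setMethod("canonicalId", "GeneModel", function(x) x@canonicalId)

#' @rdname GeneModel-class
#' @export
setMethod("transcriptIds", "GeneModel", function(x) x@txData$transcript_id)

#' @rdname GeneModel-class
#' @export
setMethod("variantNames", "GeneModel", function(x)
  stats::setNames(x@txData$variant_name, x@txData$transcript_id))

#' @rdname GeneModel-class
#' @param transcript_id optional transcript to restrict to.
#' @export
setMethod("exonsBy", "GeneModel", function(x, transcript_id = NULL) {
  if (is.null(transcript_id)) return(x@exons)
  if (!transcript_id %in% names(x@exons))
    .stopf("unknown transcript: %s", transcript_id)
  x@exons[[transcript_id]]
})

#' Genomic span of the gene (min exon start to max exon end)
#' @param x a \code{GeneModel}.
#' @return \code{GRanges} of length 1.
#' @export
geneSpan <- function(x) {
  ex <- unlist(x@exons)
  GenomicRanges::GRanges(x@chrom,
    IRanges::IRanges(min(GenomicRanges::start(ex)),
                     max(GenomicRanges::end(ex))),
    strand = x@strand)
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", object@geneId, sprintf("(%s, %s strand)\n",
      object@chrom, object@strand))
  cat(" ", length(object@exons), "transcripts; canonical:",
      object@canonicalId, "\n")
  n_ex <- vapply(object@exons, length, integer(1))
  for (i in seq_along(object@exons))
    cat(sprintf("   %s [%s]: %d exon(s)\n", object@txData$variant_name[i],
                names(object@exons)[i], n_ex[i]))
})

## junction derivation --------------------------------------------------

#' @rdname deriveJunctions
#' @export
setMethod("deriveJunctions", "GRanges", function(x, ...) {
  if (length(x) > 1L) {
    o <- order(GenomicRanges::start(x))
    x <- x[o]
    if (any(GenomicRanges::start(x)[-1L] <=
            GenomicRanges::end(x)[-length(x)]))
      .stopf("invalid transcript structure: overlapping exons")
  }
  if (length(x) < 2L)
    return(data.frame(chrom = character(), donor_end = integer(),
                      acceptor_start = integer()))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(x))[-length(x)],
    donor_end = GenomicRanges::end(x)[-length(x)],
    acceptor_start = GenomicRanges::start(x)[-1L])
})

#' @rdname deriveJunctions
#' @export
setMethod("deriveJunctions", "GeneModel", function(x, transcript_id = NULL) {
  ids <- if (is.null(transcript_id)) transcriptIds(x) else transcript_id
  out <- lapply(ids, function(tid) {
    j <- deriveJunctions(exonsBy(x, tid))
    if (nrow(j)) cbind(transcript_id = tid, j)
    else data.frame(transcript_id = character(), chrom = character(),
                    donor_end = integer(), acceptor_start = integer())
  })
  do.call(rbind, out)
})

#' Identify the junctions that uniquely discriminate each splice variant
#'
#' For every transcript of the gene (the canonical included, treated the same
#' way), the discriminating set is its junctions absent from every other
#' transcript of the supplied set. Uniqueness scope is the supplied transcript
#' set only. Variants with no unique junction are reported as unquantifiable
#' rather than dropped: the junction-counting method is blind to them.
#'
#' @param gene a [GeneModel-class].
#' @return a [JunctionCatalogue-class].
#' @examples
#' gm <- geneModel("g", "chr1", "+", "can", list(
#'   can  = rbind(c(1, 100), c(201, 300), c(401, 500), c(601, 700)),
#'   skip = rbind(c(1, 100), c(201, 300), c(601, 700))))
#' discriminatingJunctions(gm)
#' @export
discriminatingJunctions <- function(gene) {
  stopifnot(is(gene, "GeneModel"))
  jn <- deriveJunctions(gene)
  vn <- variantNames(gene)
  if (nrow(jn) == 0L) {
    return(new("JunctionCatalogue", geneId = geneId(gene),
               junctions = data.frame(
                 variant_name = character(), transcript_id = character(),
                 chrom = character(), donor_end = integer(),
                 acceptor_start = integer(), discriminating = logical()),
               unquantifiable = unname(vn)))
  }
  key <- junctionKey(jn$chrom, jn$donor_end, jn$acceptor_start)
  n_tx_with <- tapply(jn$transcript_id, key,
                      function(t) length(unique(t)))
  jn$discriminating <- unname(as.vector(n_tx_with[key]) == 1L)
  jn <- data.frame(variant_name = unname(vn[jn$transcript_id]),
                   jn, stringsAsFactors = FALSE)
  has_disc <- tapply(jn$discriminating, jn$transcript_id, any)
  unq <- unname(vn[setdiff(transcriptIds(gene),
                           names(has_disc)[unlist(has_disc)])])
  new("JunctionCatalogue", geneId = geneId(gene),
      junctions = jn[, c("variant_name", "transcript_id", "chrom",
                         "donor_end", "acceptor_start", "discriminating")],
      unquantifiable = unq)
}

#' @rdname JunctionCatalogue-class
#' @export
setMethod("unquantifiableVariants", "JunctionCatalogue",
          function(x) x@unquantifiable)

#' @rdname JunctionCatalogue-class
#' @param object a \code{JunctionCatalogue}.
#' @export
setMethod("junctionCounts", "JunctionCatalogue", function(x) x@junctions)

setMethod("show", "JunctionCatalogue", function(object) {
  j <- object@junctions
  cat("JunctionCatalogue for", object@geneId, "\n")
  cat(" ", nrow(j), "junction records,",
      sum(j$discriminating), "discriminating\n")
  if (length(object@unquantifiable))
    cat("  unquantifiable variants:",
        paste(object@unquantifiable, collapse = ", "), "\n")
})

#' Discriminating junctions of one variant
#' @param catalogue a [JunctionCatalogue-class].
#' @param variant_name the variant.
#' @return data.frame of that variant's discriminating junctions.
#' @export
variantJunctions <- function(catalogue, variant_name) {
  j <- catalogue@junctions
  j[j$variant_name == variant_name & j$discriminating, , drop = FALSE]
}

#' Write the junction catalogue as TSV
#' @param catalogue a [JunctionCatalogue-class].
#' @param path output file.
#' @param comments optional '#' header comment lines.
#' @return the path, invisibly.
#' @export
writeJunctionCatalogue <- function(catalogue, path, comments = character()) {
  j <- catalogue@junctions
  j$discriminating <- ifelse(j$discriminating, "true", "false")
  .writeTSV(j, path, comments)
}

#' Read a junction catalogue TSV back
#' @param path TSV written by [writeJunctionCatalogue()].
#' @param gene_id gene identifier to record.
#' @return a [JunctionCatalogue-class].
#' @export
readJunctionCatalogue <- function(path, gene_id = NA_character_) {
  j <- .readTSV(path)
  j$discriminating <- j$discriminating %in% c("true", "TRUE", "True")
  all_v <- unique(j$variant_name)
  unq <- setdiff(all_v, unique(j$variant_name[j$discriminating]))
  new("JunctionCatalogue", geneId = gene_id, junctions = j,
      unquantifiable = unq)
}

## spliced sequence -----------------------------------------------------

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon sequences in transcript (5' to 3') order; for a
#' minus-strand gene the result is the reverse complement of the genomic
#' concatenation. Length equals the sum of exon lengths.
#'
#' @param gene a [GeneModel-class].
#' @param transcript_id which transcript.
#' @param genome a named \code{DNAStringSet} (or path to a FASTA file)
#'   covering all exon intervals.
#' @return a \code{DNAString}.
#' @export
splicedSequence <- function(gene, transcript_id, genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  ex <- exonsBy(gene, transcript_id)
  chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
  if (!chrom %in% names(genome))
    .stopf("sequence out of range: contig %s not in genome", chrom)
  contig <- genome[[chrom]]
  if (max(GenomicRanges::end(ex)) > length(contig) ||
      min(GenomicRanges::start(ex)) < 1L)
    .stopf("sequence out of range: exon outside contig bounds")
  parts <- Biostrings::extractAt(contig,
    IRanges::IRanges(GenomicRanges::start(ex), GenomicRanges::end(ex)))
  seq <- Biostrings::DNAString(paste(vapply(parts, as.character,
                                            character(1)), collapse = ""))
  if (gene@strand == "-") seq <- Biostrings::reverseComplement(seq)
  seq
}

#' Write a GeneModel as a GTF file
#'
#' Emits gene, transcript and exon lines with gene_id/transcript_id/
#' transcript_name attributes, round-trippable through [parseGeneModels()].
#'
#' @param gene a [GeneModel-class].
#' @param path output GTF path.
#' @return the path, invisibly.
#' @export
writeGeneGTF <- function(gene, path) {
  vn <- variantNames(gene)
  span <- geneSpan(gene)
  lines <- sprintf('%s\tsjquant\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   gene@chrom, GenomicRanges::start(span),
                   GenomicRanges::end(span), gene@strand, gene@geneId)
  for (tid in transcriptIds(gene)) {
    ex <- exonsBy(gene, tid)
    lines <- c(lines, sprintf(
      '%s\tsjquant\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s";',
      gene@chrom, min(GenomicRanges::start(ex)),
      max(GenomicRanges::end(ex)), gene@strand, gene@geneId, tid,
      unname(vn[tid])))
    lines <- c(lines, sprintf(
      '%s\tsjquant\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s"; exon_number "%d";',
      gene@chrom, GenomicRanges::start(ex), GenomicRanges::end(ex),
      gene@strand, gene@geneId, tid, unname(vn[tid]), ex$transcript_rank))
  }
  writeLines(lines, path)
  invisible(path)
}
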