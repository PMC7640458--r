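## Seeded spliced-read simulator.
##
## Emits already-aligned records (POS/CIGAR/FLAG), not FASTQ: the counting
## pipeline consumes alignments, so simulating alignments directly keeps
## ground truth exact and the whole chain deterministic under one seed.

#' Simulation configuration
#'
#' Defines a toy multi-isoform gene and a read regime with known
#' per-junction read proportions. Defaults emulate a scaled-down deep
#' short-read library: 100 nt single-end reads, 1e5 reads per sample, and a
#' per-junction probability of 0.007 (a variant junction carried by ~0.7%
#' of the library's reads, the order of magnitude at which minor splice
#' variants of a highly expressed gene sit). Real study depths of ~2e8
#' reads per library are emulated in ratio, not volume.
#'
#' @param nExons exons in the canonical transcript.
#' @param exonLength,intronLength c(min, max) length ranges (nt).
#' @param variants named list; each element the genomic exon indices of the
#'   canonical structure that the variant skips (e.g. \code{list(skip3 = 3)}
#'   joins exon 2 to exon 4, the classic exon-skipping topology).
#' @param nReads reads per simulated sample.
#' @param readLength read length in nt, within 75-200.
#' @param junctionProb named numeric: probability that a read spans the
#'   discriminating junction of that variant (names are variant names) or a
#'   junction key (\code{"chrom:donor-acceptor"}). Must sum to at most 1;
#'   the remainder of the library is unspliced.
#' @param unsplicedFraction optional; when given it must equal
#'   1 - sum(junctionProb) (it is implied, the argument only documents it).
#' @param anchorRange optional c(min, max) range for the left anchor length
#'   of simulated junction reads (default: the full feasible range). Setting
#'   it below the counting filter's minAnchor makes every simulated junction
#'   read fail the anchor filter.
#' @param strand gene strand; minus-strand genes are emitted as
#'   reverse-complemented sequences (FLAG 16) with identical coordinates.
#' @param chrom contig name.
#' @param mapq mapping quality written on every record.
#' @param pairedEnd emit alternating first/second-mate flags (mates are
#'   independent records; there is no fragment-length model).
#' @param seed integer seed; every simulator draw derives from it.
#' @return object of class \code{SimulationConfig} (a validated list).
#' @export
simulationConfig <- function(nExons = 4, exonLength = c(150, 300),
                             intronLength = c(200, 800),
                             variants = list(skip3 = 3),
                             nReads = 1e5, readLength = 100,
                             junctionProb = c(skip3 = 0.007),
                             unsplicedFraction = NULL,
                             anchorRange = NULL,
                             strand = "+", chrom = "chrT",
                             mapq = 60, pairedEnd = FALSE, seed = 1) {
  if (readLength < 75 || readLength > 200)
    .stopf("readLength must be within 75-200 nt")
  if (sum(junctionProb) > 1)
    .stopf("junction probabilities must sum to at most 1")
  if (!is.null(unsplicedFraction) &&
      abs(unsplicedFraction + sum(junctionProb) - 1) > 1e-9)
    .stopf("unsplicedFraction must equal 1 - sum(junctionProb)")
  if (!strand %in% c("+", "-")) .stopf("strand must be '+' or '-'")
  for (v in variants)
    if (any(v < 1 | v > nExons)) .stopf("invalid variant spec: exon index out of range")
  structure(list(
    nExons = as.integer(nExons), exonLength = as.integer(exonLength),
    intronLength = as.integer(intronLength), variants = variants,
    nReads = as.integer(nReads), readLength = as.integer(readLength),
    junctionProb = junctionProb,
    unsplicedFraction = 1 - sum(junctionProb),
    anchorRange = if (is.null(anchorRange)) NULL else as.integer(anchorRange),
    strand = strand, chrom = chrom, mapq = as.integer(mapq),
    pairedEnd = isTRUE(pairedEnd), seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Build a toy multi-isoform gene and its contig
#'
#' Canonical transcript with \code{nExons} exons (lengths and intron lengths
#' drawn from the configured ranges under the seed) plus one transcript per
#' requested variant, formed by skipping the listed exons of the canonical
#' structure. The contig is random sequence covering all exons with 100 nt
#' flanks. Deterministic under the config seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list with \code{gene} (a [GeneModel-class]) and \code{contig}
#'   (a named \code{DNAStringSet}).
#' @export
makeToyGene <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  elen <- sample(seq(cfg$exonLength[1L], cfg$exonLength[2L]), cfg$nExons,
                 replace = TRUE)
  ilen <- sample(seq(cfg$intronLength[1L], cfg$intronLength[2L]),
                 max(cfg$nExons - 1L, 1L), replace = TRUE)
  starts <- integer(cfg$nExons)
  starts[1L] <- 101L
  if (cfg$nExons > 1L)
    for (i in 2L:cfg$nExons)
      starts[i] <- starts[i - 1L] + elen[i - 1L] + ilen[i - 1L]
  ends <- starts + elen - 1L
  canon <- cbind(starts, ends)

  txs <- list(canonical = canon)
  for (v in names(cfg$variants)) {
    skip <- cfg$variants[[v]]
    if (length(skip) >= cfg$nExons) .stopf("invalid variant spec: no exons left")
    txs[[v]] <- canon[-skip, , drop = FALSE]
  }
  gene <- geneModel("toyGene", cfg$chrom, cfg$strand, "canonical", txs)

  contig_len <- max(ends) + 100L
  seq <- paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
               collapse = "")
  contig <- Biostrings::DNAStringSet(stats::setNames(seq, cfg$chrom))
  list(gene = gene, contig = contig)
}

# resolve junctionProb names to concrete junctions of the gene
.resolveJunctions <- function(gene, cfg) {
  if (!length(cfg$junctionProb))
    return(data.frame(name = character(), chrom = character(),
                      donor_end = integer(), acceptor_start = integer(),
                      p = numeric()))
  cat_ <- discriminatingJunctions(gene)
  out <- lapply(names(cfg$junctionProb), function(nm) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- regmatches(nm, regexec("^(.+):(\\d+)-(\\d+)$", nm))[[1L]]
      if (length(parts) != 4L) .stopf("bad junction key: %s", nm)
      data.frame(name = nm, chrom = parts[2L],
                 donor_end = as.integer(parts[3L]),
                 acceptor_start = as.integer(parts[4L]))
    } else {
      vj <- variantJunctions(cat_, nm)
      if (nrow(vj) == 0L)
        .stopf("junctionProb names a variant with no discriminating junction: %s", nm)
      if (nrow(vj) > 1L)
        .stopf("variant %s has %d discriminating junctions; use junction keys",
               nm, nrow(vj))
      data.frame(name = nm, chrom = vj$chrom, donor_end = vj$donor_end,
                 acceptor_start = vj$acceptor_start)
    }
  })
  jt <- do.call(rbind, out)
  jt$p <- unname(cfg$junctionProb)
  jt
}

#' Simulate spliced alignment records with known ground truth
#'
#' Each read is assigned to one configured junction with its probability
#' (spanning it with a left anchor drawn uniformly over the feasible range,
#' or over \code{anchorRange} when set) or emitted as an unspliced read
#' placed uniformly on the canonical exons. Records carry correct POS, CIGAR
#' (M/N operations), FLAG, MAPQ and SEQ (reverse-complemented for a
#' minus-strand gene). The truth set records every assignment; counting the
#' realized tallies is exact, the intended count is \code{nReads * p}.
#'
#' @param gene a [GeneModel-class] from [makeToyGene()].
#' @param contig the matching \code{DNAStringSet}.
#' @param cfg the [simulationConfig()].
#' @return list with \code{records} (data.frame: qname, flag, rname, pos,
#'   mapq, cigar, seq, qual) and \code{truth} (list: \code{assignments}
#'   per-read, \code{junctions} per-junction intended/realized counts,
#'   \code{seed}).
#' @export
simulateReads <- function(gene, contig, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed + 1L)
  n <- cfg$nReads
  L <- cfg$readLength
  jt <- .resolveJunctions(gene, cfg)
  contig_seq <- contig[[as.character(GenomicRanges::seqnames(geneSpan(gene)))]]

  # exon bounds flanking each junction (for anchor feasibility), taken from
  # the canonical structure in genomic space
  ex <- exonsBy(gene, canonicalId(gene))
  exs <- GenomicRanges::start(ex); exe <- GenomicRanges::end(ex)
  all_ex <- unlist(exonsBy(gene))
  left_len <- right_len <- integer(nrow(jt))
  for (i in seq_len(nrow(jt))) {
    le <- all_ex[GenomicRanges::end(all_ex) == jt$donor_end[i]]
    re <- all_ex[GenomicRanges::start(all_ex) == jt$acceptor_start[i]]
    if (!length(le) || !length(re))
      .stopf("junction %s does not flank annotated exons", jt$name[i])
    left_len[i] <- max(GenomicRanges::width(le))
    right_len[i] <- max(GenomicRanges::width(re))
  }
  a_min <- pmax(1L, L - right_len)
  a_max <- pmin(L - 1L, left_len)
  if (!is.null(cfg$anchorRange)) {
    a_min <- pmax(a_min, cfg$anchorRange[1L])
    a_max <- pmin(a_max, cfg$anchorRange[2L])
  }
  if (any(a_min > a_max))
    .stopf("read length too short: no feasible anchor for a junction")

  cats <- c(jt$name, ".unspliced")
  pick <- sample(cats, n, replace = TRUE,
                 prob = c(jt$p, 1 - sum(jt$p)))

  pos <- integer(n); cigar <- character(n)
  # junction-spanning reads
  for (i in seq_len(nrow(jt))) {
    idx <- which(pick == jt$name[i])
    if (!length(idx)) next
    a <- if (a_min[i] == a_max[i]) rep(a_min[i], length(idx))
         else sample(seq(a_min[i], a_max[i]), length(idx), replace = TRUE)
    gap <- jt$acceptor_start[i] - jt$donor_end[i] - 1L
    pos[idx] <- jt$donor_end[i] - a + 1L
    cigar[idx] <- sprintf("%dM%dN%dM", a, gap, L - a)
  }
  # unspliced reads, uniform over canonical exon positions that fit
  uidx <- which(pick == ".unspliced")
  if (length(uidx)) {
    fits <- which(exe - exs + 1L >= L)
    if (!length(fits)) .stopf("read length too short: no exon fits an unspliced read")
    w <- (exe - exs + 1L - L + 1L)[fits]
    exi <- fits[sample.int(length(fits), length(uidx), replace = TRUE,
                           prob = w)]
    off <- floor(stats::runif(length(uidx)) * (exe[exi] - exs[exi] - L + 2L))
    pos[uidx] <- exs[exi] + as.integer(off)
    cigar[uidx] <- sprintf("%dM", L)
  }

  flag <- rep(if (gene@strand == "-") 16L else 0L, n)
  if (cfg$pairedEnd) {
    mate1 <- seq_len(n) %% 2L == 1L
    flag <- flag + 1L + ifelse(mate1, 64L, 128L)
  }

  # sequences from the reference (spliced reads concatenate the two arms)
  seqs <- character(n)
  spl <- which(pick != ".unspliced")
  if (length(spl)) {
    jrow <- match(pick[spl], jt$name)
    a <- jt$donor_end[jrow] - pos[spl] + 1L
    left <- substring(as.character(contig_seq), pos[spl], jt$donor_end[jrow])
    right <- substring(as.character(contig_seq), jt$acceptor_start[jrow],
                       jt$acceptor_start[jrow] + (L - a) - 1L)
    seqs[spl] <- paste0(left, right)
  }
  if (length(uidx))
    seqs[uidx] <- substring(as.character(contig_seq), pos[uidx],
                            pos[uidx] + L - 1L)
  if (gene@strand == "-")
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))

  records <- data.frame(
    qname = sprintf("read%07d", seq_len(n)), flag = flag,
    rname = as.character(GenomicRanges::seqnames(geneSpan(gene))),
    pos = pos, mapq = cfg$mapq, cigar = cigar, seq = seqs,
    qual = strrep("I", L), stringsAsFactors = FALSE)

  realized <- vapply(jt$name, function(nm) sum(pick == nm), integer(1))
  truth <- list(
    assignments = data.frame(qname = records$qname,
                             junction = ifelse(pick == ".unspliced",
                                               NA_character_,
                                               junctionKey(jt$chrom,
                                                 jt$donor_end,
                                                 jt$acceptor_start)[
                                                   match(pick, jt$name)]),
                             stringsAsFactors = FALSE),
    junctions = data.frame(name = jt$name, chrom = jt$chrom,
                           donor_end = jt$donor_end,
                           acceptor_start = jt$acceptor_start,
                           p = jt$p, intended = n * jt$p,
                           realized = unname(realized),
                           stringsAsFactors = FALSE),
    seed = cfg$seed)
  list(records = records, truth = truth)
}

#' Write alignment records as a coordinate-sorted SAM file
#'
#' Emits a spec-conformant @HD/@SQ header and the records sorted by
#' (contig, position). Text SAM is used so fixtures stay human-readable;
#' convert with samtools when a BAM is wanted.
#'
#' @param records record data.frame (qname, flag, rname, pos, mapq, cigar,
#'   and optionally seq, qual).
#' @param contigs named integer vector of contig lengths.
#' @param path output SAM path.
#' @return the path, invisibly.
#' @export
writeSAM <- function(records, contigs, path) {
  if (nrow(records)) {
    if (!all(records$rname %in% names(contigs)))
      .stopf("record on undeclared contig")
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(records$cigar)
    if (any(records$pos < 1L) ||
        any(records$pos + w - 1L > contigs[records$rname]))
      .stopf("record out of bounds")
    records <- records[order(match(records$rname, names(contigs)),
                             records$pos), ]
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   as.integer(contigs)))
  seq <- if ("seq" %in% names(records)) records$seq else rep("*", nrow(records))
  qual <- if ("qual" %in% names(records)) records$qual else rep("*", nrow(records))
  body <- if (nrow(records))
    paste(records$qname, records$flag, records$rname, records$pos,
          records$mapq, records$cigar, "*", 0L, 0L, seq, qual, sep = "\t")
    else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate one sample end to end
#'
#' Convenience wrapper: build (or reuse) the toy gene, simulate reads and
#' optionally write the SAM file; returns everything needed to run the
#' counting and quantification stages against known truth.
#'
#' @param cfg a [simulationConfig()].
#' @param toy optional precomputed [makeToyGene()] result, so several
#'   samples share one gene.
#' @param sam_path optional path; when given the records are written there.
#' @return list: gene, contig, records, truth, catalogue.
#' @export
simulateSample <- function(cfg, toy = NULL, sam_path = NULL) {
  if (is.null(toy)) toy <- makeToyGene(cfg)
  sim <- simulateReads(toy$gene, toy$contig, cfg)
  if (!is.null(sam_path))
    writeSAM(sim$records,
             stats::setNames(Biostrings::width(toy$contig),
                             names(toy$contig)), sam_path)
  list(gene = toy$gene, contig = toy$contig, records = sim$records,
       truth = sim$truth, catalogue = discriminatingJunctions(toy$gene))
}

#' Synthetic amplicon templates for the bundled P4HB junction primers
#'
#' The bundled primer table (\code{inst/extdata/p4hb_primers.tsv}) holds the
#' published junction-spanning primer pairs for the P4HB splice variants
#' P4HB-02, P4HB-021 and P4HB-027 together with their expected amplicon
#' sizes (89, 211 and 148 bp). The real spliced transcript sequences are not
#' redistributable here, so this function builds synthetic stand-in
#' templates: random sequence carrying each primer pair at exactly the
#' expected amplicon geometry (forward site, spacer, reverse-complement
#' site), deterministically and with a uniqueness check so each primer
#' anneals exactly once. They validate the in-silico PCR arithmetic, not the
#' real transcript sequences; template names carry a "_synthetic" suffix to
#' make that impossible to miss.
#'
#' @param primers primer table with columns name, fwd, rvs, expected_bp
#'   (default: the bundled table).
#' @param flank flanking sequence length on each side (nt).
#' @return named \code{DNAStringSet} of templates.
#' @export
syntheticAmpliconTemplates <- function(
    primers = readPrimerTable(system.file("extdata", "p4hb_primers.tsv",
                                          package = "sjquant")),
    flank = 30L) {
  stopifnot(all(c("name", "fwd", "rvs", "expected_bp") %in% names(primers)))
  set.seed(104729L)  # fixed: templates are reference fixtures
  rnt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  out <- character(nrow(primers))
  for (i in seq_len(nrow(primers))) {
    fwd <- toupper(primers$fwd[i]); rvs <- toupper(primers$rvs[i])
    rcr <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rvs)))
    spacer_len <- primers$expected_bp[i] - nchar(fwd) - nchar(rvs)
    if (spacer_len < 0L) .stopf("expected_bp shorter than the two primers")
    repeat {
      tpl <- paste0(rnt(flank), fwd, rnt(spacer_len), rcr, rnt(flank))
      nf <- length(Biostrings::matchPattern(fwd, Biostrings::DNAString(tpl)))
      nr <- length(Biostrings::matchPattern(rcr, Biostrings::DNAString(tpl)))
      if (nf == 1L && nr == 1L) break
    }
    out[i] <- tpl
  }
  Biostrings::DNAStringSet(
    stats::setNames(out, paste0(primers$name, "_synthetic")))
}
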