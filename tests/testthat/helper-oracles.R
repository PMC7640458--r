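# Independent oracles. The SAM scan below re-derives junction counts from
# the SAM text with its own CIGAR walker; it deliberately shares no code
# with the package's counting path (no GenomicAlignments).

# walk one CIGAR: returns list(blocks, donors, acceptors, ref_end) where
# blocks are the reference-consuming run lengths between N gaps
walk_cigar <- function(cigar, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  n <- as.integer(sub(".$", "", ops))
  op <- substring(ops, nchar(ops))
  ref <- pos; runlen <- 0L
  blocks <- integer(); donors <- integer(); acceptors <- integer()
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "D", "=", "X")) {
      runlen <- runlen + n[k]; ref <- ref + n[k]
    } else if (op[k] == "N") {
      blocks <- c(blocks, runlen)
      donors <- c(donors, ref - 1L)
      ref <- ref + n[k]
      acceptors <- c(acceptors, ref)
      runlen <- 0L
    } # I/S/H/P consume no reference
  }
  list(blocks = c(blocks, runlen), donors = donors, acceptors = acceptors,
       ref_end = ref - 1L)
}

# brute-force recount of a SAM file against a set of junction keys
oracle_sam_count <- function(path, keys, min_anchor = 8, min_mapq = 0,
                             gene_span = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  total <- 0L; gene_reads <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    flag <- as.integer(f[2L]); rname <- f[3L]
    pos <- as.integer(f[4L]); mapq <- as.integer(f[5L]); cig <- f[6L]
    if (bitwAnd(flag, 4L) != 0L) next
    if (bitwAnd(flag, 256L) != 0L || bitwAnd(flag, 1024L) != 0L ||
        bitwAnd(flag, 2048L) != 0L) next
    if (mapq < min_mapq) next
    total <- total + 1L
    w <- walk_cigar(cig, pos)
    if (!is.null(gene_span) && rname == gene_span$chrom &&
        pos <= gene_span$end && w$ref_end >= gene_span$start)
      gene_reads <- gene_reads + 1L
    if (length(w$donors)) for (j in seq_along(w$donors)) {
      if (w$blocks[j] >= min_anchor && w$blocks[j + 1L] >= min_anchor) {
        key <- sprintf("%s:%d-%d", rname, w$donors[j], w$acceptors[j])
        if (key %in% keys) counts[key] <- counts[key] + 1L
      }
    }
  }
  list(counts = counts, total = total, gene_reads = gene_reads)
}

# plain text scan of a GTF: exon line count for one gene
oracle_gtf_exon_count <- function(path, gene_id) {
  lines <- readLines(path)
  sum(grepl("\texon\t", lines, fixed = TRUE) &
        grepl(sprintf('gene_id "%s"', gene_id), lines, fixed = TRUE))
}

# brute-force discriminating sets: per transcript, junction keys present in
# no other transcript (plain set difference over all pairs)
oracle_discriminating <- function(gene) {
  ids <- transcriptIds(gene)
  keysets <- lapply(ids, function(tid) {
    j <- deriveJunctions(exonsBy(gene, tid))
    if (nrow(j)) junctionKey(j$chrom, j$donor_end, j$acceptor_start)
    else character()
  })
  names(keysets) <- ids
  lapply(ids, function(tid) {
    others <- unlist(keysets[setdiff(ids, tid)])
    setdiff(keysets[[tid]], others)
  }) |> stats::setNames(ids)
}

# vectorized variant of the text-scan recount for larger files; same
# contract as oracle_sam_count, still pure text + regex (no package code)
oracle_sam_count_fast <- function(path, keys, min_anchor = 8, min_mapq = 0,
                                  gene_span = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  if (!length(lines))
    return(list(counts = counts, total = 0L, gene_reads = 0L))
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 2:6)
  flag <- as.integer(fields[[1L]]); rname <- fields[[2L]]
  pos <- as.integer(fields[[3L]]); mapq <- as.integer(fields[[4L]])
  cig <- fields[[5L]]
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 1024L) == 0L & bitwAnd(flag, 2048L) == 0L &
    mapq >= min_mapq
  total <- sum(keep)
  gene_reads <- 0L
  if (!is.null(gene_span)) {
    ki <- which(keep & rname == gene_span$chrom)
    refw <- vapply(regmatches(cig[ki],
                              gregexpr("\\d+[MDN=X]", cig[ki])),
                   function(o) sum(as.integer(sub(".$", "", o))),
                   numeric(1))
    gene_reads <- sum(pos[ki] <= gene_span$end &
                        pos[ki] + refw - 1L >= gene_span$start)
  }
  si <- which(keep & grepl("N", cig, fixed = TRUE))
  for (i in si) {
    w <- walk_cigar(cig[i], pos[i])
    for (j in seq_along(w$donors)) {
      if (w$blocks[j] >= min_anchor && w$blocks[j + 1L] >= min_anchor) {
        key <- sprintf("%s:%d-%d", rname[i], w$donors[j], w$acceptors[j])
        if (key %in% keys) counts[key] <- counts[key] + 1L
      }
    }
  }
  list(counts = counts, total = total, gene_reads = gene_reads)
}
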