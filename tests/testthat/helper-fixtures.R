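# shared in-code fixtures; nothing is stored on disk

# write GTF text lines to a temp file
write_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon <- function(chrom, start, end, strand, gene, tx, name = tx) {
  sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_name "%s";',
          chrom, start, end, strand, gene, tx, name)
}

# canonical 4-exon gene (exons 1-4) plus an exon-3-skipping variant:
# the classic topology where the skip joins exon 2's end to exon 4's start
skip_gene <- function(strand = "+") {
  geneModel("g", "chr1", strand, "can", list(
    can  = rbind(c(101, 200), c(301, 400), c(501, 600), c(701, 800)),
    skip = rbind(c(101, 200), c(301, 400), c(701, 800))))
}

# a 10-variant toy gene: 11-exon canonical plus 9 single-exon-skip variants
many_variant_gene <- function() {
  n <- 11L
  starts <- 101L + (0:(n - 1L)) * 300L
  canon <- cbind(starts, starts + 199L)
  txs <- list(can = canon)
  for (k in 2:10) txs[[paste0("skip", k)]] <- canon[-k, , drop = FALSE]
  geneModel("g", "chr1", "-", "can", txs)
}

# one SAM record line
sam_line <- function(qname, flag, rname, pos, mapq, cigar, seq = "*",
                     qual = "*") {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, qual,
        sep = "\t")
}

write_sam <- function(body, contigs = c(chr1 = 100000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                       as.integer(contigs)),
               body), path)
  path
}

# record frame shortcut for in-memory counting
rec <- function(flag, pos, cigar, mapq = 60, rname = "chr1") {
  data.frame(flag = flag, rname = rname, pos = pos, mapq = mapq,
             cigar = cigar, stringsAsFactors = FALSE)
}

# synthetic canonical protein for domain tests: random residues with two
# CGHC motifs and a terminal KDEL, all at known positions. Boundary
# residues around the excision points used in tests are forced to differ
# so each constructed deletion has a unique (unambiguous) placement.
toy_protein <- function() {
  set.seed(42)
  aa <- c("A", "R", "N", "D", "E", "Q", "I", "L", "K", "M", "F", "P",
          "S", "T", "W", "Y", "V")   # no C/G/H: CGHC only where planted
  v <- sample(aa, 200, replace = TRUE)
  cuts <- list(c(41, 84), c(10, 45), c(30, 60), c(101, 140), c(150, 190),
               c(65, 70), c(65, 90), c(65, 110), c(65, 140))
  for (ct in cuts) {
    f <- ct[1]; t <- ct[2]
    if (v[f - 1] == v[t])
      v[t] <- setdiff(aa, c(v[t - 1], v[t + 1], v[f - 1]))[1]
    if (v[f] == v[t + 1])
      v[t + 1] <- setdiff(aa, c(v[t], v[t + 2], v[f]))[1]
  }
  p <- paste(v, collapse = "")
  substr(p, 21, 24) <- "CGHC"
  substr(p, 171, 174) <- "CGHC"
  substr(p, 197, 200) <- "KDEL"
  p
}

toy_domains <- function() {
  data.frame(domain = c("a", "b", "bp", "x", "ap", "c"),
             start_aa = c(1, 61, 101, 141, 160, 197),
             end_aa = c(60, 100, 140, 159, 196, 200),
             stringsAsFactors = FALSE)
}

# excise canonical residues pos_from..pos_to (a pure internal deletion)
delete_block <- function(protein, from, to) {
  paste0(substring(protein, 1, from - 1), substring(protein, to + 1))
}
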