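#' Junction key string
#'
#' Canonical strand-agnostic identity of a splice junction:
#' \code{"chrom:donor_end-acceptor_start"} with 1-based inclusive flanking
#' exon coordinates.
#'
#' @param chrom chromosome name(s).
#' @param donor_end last base of the genomically-left flanking exon.
#' @param acceptor_start first base of the genomically-right flanking exon.
#' @return character vector of keys.
#' @export
junctionKey <- function(chrom, donor_end, acceptor_start) {
  sprintf("%s:%d-%d", chrom, as.integer(donor_end), as.integer(acceptor_start))
}

# write a data.frame as TSV with optional '#'-prefixed header comment lines
.writeTSV <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
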