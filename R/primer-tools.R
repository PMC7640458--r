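## Junction-spanning qPCR primer validation and in-silico PCR.
##
## Annealing is exact-match only (no mismatch tolerance, no melting
## temperature model), case-insensitive, plain ACGT alphabet. The amplicon
## is inclusive of both primer sites, matching gel-observed product sizes.

#' Validate the junction-overlap rule for a junction-spanning primer
#'
#' An isoform-specific qPCR primer must straddle the splice junction with at
#' least 8 bases on each side (both the 5' and the 3' arm), so that it
#' cannot co-amplify transcripts lacking the junction. "At least" is
#' inclusive: an 8/8 split passes. The rule is symmetric in the two arms.
#'
#' @param primer_length primer length (nt).
#' @param junction_position_in_primer bases on the 5' side of the junction,
#'   i.e. the junction sits after this base; must be strictly inside the
#'   primer.
#' @param min_overlap minimum bases required on each side (default 8).
#' @return logical.
#' @examples
#' validateJunctionPrimer(20, 10)  # TRUE  (10/10)
#' validateJunctionPrimer(20, 15)  # FALSE (5 on the 3' arm)
#' validateJunctionPrimer(16, 8)   # TRUE  (exactly 8/8)
#' @export
validateJunctionPrimer <- function(primer_length, junction_position_in_primer,
                                   min_overlap = 8L) {
  if (junction_position_in_primer <= 0 ||
      junction_position_in_primer >= primer_length)
    .stopf("primer does not span junction")
  junction_position_in_primer >= min_overlap &&
    (primer_length - junction_position_in_primer) >= min_overlap
}

.checkPrimer <- function(p, what) {
  p <- toupper(as.character(p))
  if (grepl("[^ACGT]", p))
    .stopf("%s primer contains non-ACGT characters (ambiguity codes are not supported)", what)
  p
}

#' In-silico PCR of one primer pair on one template
#'
#' The forward primer must match the template exactly; the reverse primer
#' must match as its reverse complement, downstream of the forward site.
#' Both matches must be unique. The amplicon spans from the first base of
#' the forward site to the last base of the reverse site, inclusive.
#'
#' @param fwd forward primer, 5'->3'.
#' @param rvs reverse primer, 5'->3' (anneals to the given strand as its
#'   reverse complement).
#' @param template template sequence (string or \code{DNAString}).
#' @param name optional primer-pair name carried into the result.
#' @return one-row data.frame: name, fwd_start, fwd_end, rvs_start,
#'   rvs_end, amplicon_length.
#' @examples
#' inSilicoPCR("ACGTACGT", "GGGCCC", "AAAACGTACGTTTTTGGGCCC")
#' @export
inSilicoPCR <- function(fwd, rvs, template, name = NA_character_) {
  fwd <- .checkPrimer(fwd, "forward")
  rvs <- .checkPrimer(rvs, "reverse")
  tpl <- Biostrings::DNAString(toupper(as.character(template)))
  if (length(tpl) == 0L) .stopf("empty template")

  fhit <- Biostrings::matchPattern(Biostrings::DNAString(fwd), tpl)
  rhit <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(rvs)), tpl)
  if (length(fhit) == 0L || length(rhit) == 0L)
    .stopf("primer does not anneal")
  if (length(fhit) > 1L || length(rhit) > 1L)
    .stopf("ambiguous priming: multiple exact matches")
  fs <- Biostrings::start(fhit)[1L]; fe <- Biostrings::end(fhit)[1L]
  rs <- Biostrings::start(rhit)[1L]; re <- Biostrings::end(rhit)[1L]
  if (rs <= fe) .stopf("primer does not anneal: sites are not convergent")
  data.frame(name = name, fwd_start = fs, fwd_end = fe,
             rvs_start = rs, rvs_end = re,
             amplicon_length = re - fs + 1L, stringsAsFactors = FALSE)
}

#' Amplicon report over primer pairs and templates
#'
#' Runs [inSilicoPCR()] for each primer pair against each template and
#' collects results; pairs that do not anneal (or anneal ambiguously) on a
#' template get an NA amplicon with the failure reason.
#'
#' @param primers data.frame with columns name, fwd, rvs (and optionally
#'   target_variant), as read by [readPrimerTable()].
#' @param templates named character vector or \code{DNAStringSet} of
#'   template sequences.
#' @return data.frame: name, template, fwd_start, rvs_end, amplicon_length,
#'   status.
#' @export
ampliconReport <- function(primers, templates) {
  tnames <- names(templates)
  do.call(rbind, lapply(seq_len(nrow(primers)), function(i) {
    do.call(rbind, lapply(tnames, function(tn) {
      res <- tryCatch(
        inSilicoPCR(primers$fwd[i], primers$rvs[i],
                    as.character(templates[[tn]]), name = primers$name[i]),
        error = function(e) NULL)
      if (is.null(res))
        data.frame(name = primers$name[i], template = tn,
                   fwd_start = NA_integer_, rvs_end = NA_integer_,
                   amplicon_length = NA_integer_, status = "no amplicon",
                   stringsAsFactors = FALSE)
      else
        data.frame(name = res$name, template = tn,
                   fwd_start = res$fwd_start, rvs_end = res$rvs_end,
                   amplicon_length = res$amplicon_length, status = "ok",
                   stringsAsFactors = FALSE)
    }))
  }))
}

#' Read a primers TSV (name, fwd, rvs, target_variant)
#' @param path TSV path.
#' @return data.frame.
#' @export
readPrimerTable <- function(path) {
  pr <- .readTSV(path)
  need <- c("name", "fwd", "rvs")
  if (!all(need %in% names(pr)))
    .stopf("primer table needs columns %s", paste(need, collapse = ", "))
  pr
}
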