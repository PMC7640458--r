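## Domain-architecture projection for splice-variant protein products.
##
## Splice variants differ from the canonical protein by whole exonic blocks,
## so the variant-to-canonical mapping is a chain of exact shared blocks
## (no substitution scoring). Canonical positions not covered by any chained
## block are the deletions; from those we classify each canonical domain as
## intact, truncated or absent in the variant.

# maximal exact shared blocks (>= min_block aa) between two sequences,
# seeded on k-mers and extended; returns start pairs and lengths
.sharedBlocks <- function(a, b, min_block = 5L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < min_block || nb < min_block) return(NULL)
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  k <- min_block
  akm <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  bkm <- substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  bpos <- split(seq_along(bkm), bkm)
  hits <- list()
  for (i in seq_along(akm)) {
    js <- bpos[[akm[i]]]
    if (!is.null(js))
      hits[[length(hits) + 1L]] <- cbind(i = i, j = js)
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  # keep only seeds that start a maximal block (previous chars differ)
  first <- hits[, "i"] == 1L | hits[, "j"] == 1L |
    av[pmax(hits[, "i"] - 1L, 1L)] != bv[pmax(hits[, "j"] - 1L, 1L)]
  hits <- hits[first, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  len <- integer(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    i <- hits[r, "i"]; j <- hits[r, "j"]; l <- k
    while (i + l <= na && j + l <= nb && av[i + l] == bv[j + l]) l <- l + 1L
    len[r] <- l
  }
  data.frame(a_start = hits[, "i"], b_start = hits[, "j"], len = len)
}

#' Map variant protein residues onto canonical coordinates
#'
#' Chains exact shared blocks (at least \code{min_block} residues) between a
#' variant protein and the canonical protein, colinearly and without
#' overlap, maximizing the total matched length; ties are broken toward the
#' leftmost placement. Returns, for each variant residue, the canonical
#' position it corresponds to (NA for residues outside any shared block).
#' Canonical positions absent from the map are the variant's deletions.
#'
#' @param canonical_protein canonical amino-acid sequence (string or
#'   \code{AAString}).
#' @param variant_protein variant amino-acid sequence.
#' @param min_block minimum exact shared block length (default 5 aa).
#' @return integer vector of length \code{nchar(variant_protein)}: matched
#'   canonical positions, NA where unmatched.
#' @examples
#' proteinAlignmentMap("MABCDEFGHIJ", "MABCDEFGHIJ")  # identity
#' @export
proteinAlignmentMap <- function(canonical_protein, variant_protein,
                                min_block = 5L) {
  can <- toupper(as.character(canonical_protein))
  var <- toupper(as.character(variant_protein))
  if (!nchar(can) || !nchar(var)) .stopf("empty sequence")
  bl <- .sharedBlocks(can, var, min_block)
  if (is.null(bl) || !nrow(bl))
    .stopf("unrelated sequences: no shared block >= %d aa", min_block)
  # chain blocks by DP: order by (variant start, canonical start), maximize
  # total matched length over colinear chains. Blocks may overlap when the
  # sequence repeats around an excision point; the overlap is trimmed off
  # the later block, keeping the earlier (leftmost) placement intact.
  bl <- bl[order(bl$b_start, bl$a_start), , drop = FALSE]
  n <- nrow(bl)
  overlap <- function(q, r)
    max(0L, bl$b_start[q] + bl$len[q] - bl$b_start[r],
        bl$a_start[q] + bl$len[q] - bl$a_start[r])
  best <- bl$len
  prev <- rep(0L, n)
  for (r in seq_len(n)) {
    for (q in seq_len(r - 1L)) {
      if (bl$b_start[q] >= bl$b_start[r] || bl$a_start[q] >= bl$a_start[r])
        next
      gain <- bl$len[r] - overlap(q, r)
      if (gain > 0L && best[q] + gain > best[r]) {
        best[r] <- best[q] + gain
        prev[r] <- q
      }
    }
  }
  r <- which.max(best)   # ties: first (leftmost) maximum
  chain <- integer()
  while (r != 0L) { chain <- c(r, chain); r <- prev[r] }
  map <- rep(NA_integer_, nchar(var))
  for (k in seq_along(chain)) {
    r <- chain[k]
    o <- if (k == 1L) 0L else overlap(chain[k - 1L], r)
    idx <- (o + 1L):bl$len[r]
    map[bl$b_start[r] + idx - 1L] <- bl$a_start[r] + idx - 1L
  }
  map
}

#' Read a domain map TSV (domain, start_aa, end_aa)
#'
#' Domain coordinates on the canonical protein are user-supplied input, not
#' computed: supply the architecture (e.g. the a, b, b', x-linker, a', c
#' domains of PDIA1) as a three-column TSV.
#'
#' @param path TSV with columns domain, start_aa, end_aa.
#' @return data.frame, intervals checked ascending and non-overlapping.
#' @export
readDomainMap <- function(path) {
  dm <- .readTSV(path)
  need <- c("domain", "start_aa", "end_aa")
  if (!all(need %in% names(dm)))
    .stopf("domain map needs columns %s", paste(need, collapse = ", "))
  dm <- dm[order(dm$start_aa), ]
  if (any(dm$end_aa < dm$start_aa) ||
      (nrow(dm) > 1L && any(dm$start_aa[-1L] <= dm$end_aa[-nrow(dm)])))
    .stopf("inconsistent domain map: intervals must be ascending and non-overlapping")
  rownames(dm) <- NULL
  dm
}

#' Locate CGHC redox motifs on the canonical protein
#' @param canonical_protein amino-acid sequence.
#' @return integer vector of motif start positions (1-based).
#' @export
findCGHC <- function(canonical_protein) {
  m <- gregexpr("CGHC", toupper(as.character(canonical_protein)),
                fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Project the canonical domain architecture through a variant
#'
#' Tallies, for every canonical domain, how many of its residues the variant
#' retains (per the block alignment map) and classifies the domain as
#' intact (nothing missing), truncated, or absent (nothing retained).
#' A CGHC motif counts as retained only when all 4 of its positions are.
#'
#' @param map integer vector from [proteinAlignmentMap()] (variant residue ->
#'   canonical position).
#' @param domains data.frame with domain, start_aa, end_aa on the canonical
#'   protein (see [readDomainMap()]).
#' @param cghc_positions canonical start positions of CGHC motifs (from
#'   [findCGHC()]); may be empty.
#' @param canonical_length length of the canonical protein, to validate the
#'   domain map (defaults to the largest domain end).
#' @return list with \code{domains} (data.frame: domain, start_aa, end_aa,
#'   retained_aa, missing_aa, status) and \code{cghc_count}.
#' @export
projectDomains <- function(map, domains, cghc_positions = integer(),
                           canonical_length = max(domains$end_aa)) {
  if (any(domains$end_aa > canonical_length | domains$start_aa < 1L))
    .stopf("inconsistent domain map: interval outside canonical length")
  retained <- sort(unique(map[!is.na(map)]))
  dm <- domains
  dm$retained_aa <- vapply(seq_len(nrow(dm)), function(i)
    sum(retained >= dm$start_aa[i] & retained <= dm$end_aa[i]), integer(1))
  dm$missing_aa <- (dm$end_aa - dm$start_aa + 1L) - dm$retained_aa
  dm$status <- ifelse(dm$missing_aa == 0L, "intact",
                      ifelse(dm$retained_aa == 0L, "absent", "truncated"))
  cghc <- sum(vapply(cghc_positions, function(p)
    all((p:(p + 3L)) %in% retained), logical(1)))
  list(domains = dm, cghc_count = as.integer(cghc))
}

#' Sequence motif flags for a variant
#'
#' \code{has_KDEL}: the protein ends with the exact ER-retrieval tetrapeptide
#' KDEL. \code{has_start_codon}: the CDS begins with ATG.
#' \code{has_stop_codon}: the CDS ends with a stop triplet (TAA/TAG/TGA).
#' CDS-based flags are NA when no CDS is supplied.
#'
#' @param variant_protein amino-acid sequence (or NULL).
#' @param variant_cds coding nucleotide sequence (or NULL).
#' @return named logical vector (has_KDEL, has_start_codon, has_stop_codon).
#' @examples
#' motifFlags("MAVKDEL", "ATGGCTGTTAAAGATGAACTGTAA")
#' @export
motifFlags <- function(variant_protein = NULL, variant_cds = NULL) {
  has_kdel <- NA
  if (!is.null(variant_protein)) {
    p <- toupper(as.character(variant_protein))
    has_kdel <- nchar(p) >= 4L && substring(p, nchar(p) - 3L) == "KDEL"
  }
  has_start <- has_stop <- NA
  if (!is.null(variant_cds)) {
    cds <- toupper(as.character(variant_cds))
    has_start <- substring(cds, 1L, 3L) == "ATG"
    last <- substring(cds, nchar(cds) - 2L)
    has_stop <- nchar(cds) >= 3L && last %in% c("TAA", "TAG", "TGA")
  }
  c(has_KDEL = has_kdel, has_start_codon = has_start,
    has_stop_codon = has_stop)
}

#' Architecture report over a set of variant proteins
#'
#' Runs the block alignment, domain projection and motif flags for each
#' variant against the canonical protein and returns one row per
#' (variant, domain) plus per-variant flags, the layout written by
#' [writeArchitectureTSV()].
#'
#' @param canonical_protein canonical amino-acid sequence.
#' @param variants named list/character vector of variant protein sequences.
#' @param domains domain map data.frame (see [readDomainMap()]).
#' @param cds optional named list of CDS nucleotide sequences.
#' @return data.frame: variant, domain, status, retained_aa, missing_aa,
#'   cghc_count, has_KDEL, has_start_codon, has_stop_codon.
#' @export
architectureReport <- function(canonical_protein, variants, domains,
                               cds = NULL) {
  cghc <- findCGHC(canonical_protein)
  do.call(rbind, lapply(names(variants), function(v) {
    map <- proteinAlignmentMap(canonical_protein, variants[[v]])
    pr <- projectDomains(map, domains, cghc,
                         canonical_length = nchar(as.character(canonical_protein)))
    fl <- motifFlags(variants[[v]],
                     if (!is.null(cds)) cds[[v]] else NULL)
    data.frame(variant = v, domain = pr$domains$domain,
               status = pr$domains$status,
               retained_aa = pr$domains$retained_aa,
               missing_aa = pr$domains$missing_aa,
               cghc_count = pr$cghc_count,
               has_KDEL = fl[["has_KDEL"]],
               has_start_codon = fl[["has_start_codon"]],
               has_stop_codon = fl[["has_stop_codon"]],
               stringsAsFactors = FALSE)
  }))
}

#' Write the architecture report TSV
#' @param report data.frame from [architectureReport()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeArchitectureTSV <- function(report, path) .writeTSV(report, path)
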