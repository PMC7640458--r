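#' Pipeline run configuration
#'
#' Bundles everything one quantification run needs: the annotation, the gene
#' and canonical transcript, the sample sheet (sample_id, group,
#' replicate_of, and a \code{path} column pointing at each sample's SAM/BAM
#' file), the read filters and the output directory. The configuration is
#' echoed verbatim into the output directory, and its hash is stamped into
#' every table header, so a report is always traceable to its inputs.
#'
#' @param annotation path to GTF/GFF3.
#' @param gene_id,canonical_id gene and canonical transcript identifiers.
#' @param sample_sheet path to the sample sheet TSV (needs \code{sample_id}
#'   and \code{path} columns).
#' @param filter a [FilterConfig-class].
#' @param out_dir output directory (created if needed).
#' @param detection_threshold raw-count threshold for presence calls.
#' @param keep_going continue past per-sample failures instead of aborting
#'   (failed samples are dropped with a logged warning; default is
#'   fail-fast, since silently dropping samples would bias group summaries).
#' @return object of class \code{RunConfig}.
#' @export
runConfig <- function(annotation, gene_id, canonical_id, sample_sheet,
                      filter = filterConfig(), out_dir,
                      detection_threshold = 1, keep_going = FALSE) {
  for (p in c(annotation, sample_sheet))
    if (!file.exists(p)) .stopf("path not resolvable: %s", p)
  structure(list(annotation = annotation, gene_id = gene_id,
                 canonical_id = canonical_id, sample_sheet = sample_sheet,
                 filter = filter, out_dir = out_dir,
                 detection_threshold = detection_threshold,
                 keep_going = isTRUE(keep_going)),
            class = "RunConfig")
}

.configText <- function(cfg) {
  f <- cfg$filter
  c(sprintf("annotation=%s", cfg$annotation),
    sprintf("gene_id=%s", cfg$gene_id),
    sprintf("canonical_id=%s", cfg$canonical_id),
    sprintf("sample_sheet=%s", cfg$sample_sheet),
    sprintf("min_anchor=%d", f@minAnchor),
    sprintf("min_mapq=%d", f@minMapq),
    sprintf("primary_only=%s", f@primaryOnly),
    sprintf("exclude_duplicates=%s", f@excludeDuplicates),
    sprintf("exclude_secondary_supplementary=%s",
            f@excludeSecondarySupplementary),
    sprintf("detection_threshold=%g", cfg$detection_threshold))
}

#' Run the full annotation -> counting -> quantification pipeline
#'
#' Produces, under \code{out_dir}: \code{junction_catalogue.tsv},
#' \code{counts.tsv}, \code{sjtpm_matrix.tsv}, \code{fractions.tsv},
#' \code{group_summary.tsv} (when the sample sheet has a \code{group}
#' column), \code{presence.tsv}, the echoed \code{run_config.txt} and a
#' \code{run_log.txt} with tool version, config hash and filter settings.
#' Reruns on identical inputs reproduce identical tables. Per-sample
#' failures abort the run unless \code{keep_going} was set.
#'
#' Every table carries a '#' header comment with the package version and
#' the config hash. Fractions are comparable across variants but are not
#' forced to sum to 1: discriminating-junction counts are not a partition
#' of the gene's reads.
#'
#' @param cfg a [runConfig()].
#' @return the [SJTPMExperiment-class], invisibly.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, "run_config.txt")
  writeLines(.configText(cfg), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  version <- as.character(utils::packageVersion("sjquant"))
  stamp <- sprintf("sjquant %s | config %s", version, cfg_hash)

  log <- c(sprintf("sjquant %s", version),
           sprintf("config hash: %s", cfg_hash), .configText(cfg))

  gene <- parseGeneModels(cfg$annotation, cfg$gene_id, cfg$canonical_id)
  catalogue <- discriminatingJunctions(gene)
  writeJunctionCatalogue(catalogue,
                         file.path(cfg$out_dir, "junction_catalogue.tsv"),
                         comments = stamp)
  if (length(unquantifiableVariants(catalogue)))
    log <- c(log, sprintf("unquantifiable variants: %s",
                          paste(unquantifiableVariants(catalogue),
                                collapse = ", ")))

  samples <- readSampleSheet(cfg$sample_sheet)
  if (nrow(samples) == 0L) .stopf("no samples in sample sheet")
  if (!"path" %in% names(samples))
    .stopf("sample sheet needs a path column")

  tables <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    tb <- tryCatch(
      countJunctions(samples$path[i], catalogue, gene, cfg$filter,
                     sample_id = sid),
      error = function(e) {
        msg <- sprintf("sample %s failed: %s", sid, conditionMessage(e))
        if (!cfg$keep_going) .stopf("%s", msg)
        warning(msg, call. = FALSE)
        NULL
      })
    if (!is.null(tb)) tables[[sid]] <- tb
    else log <- c(log, sprintf("INCOMPLETE: sample %s dropped", sid))
  }
  if (!length(tables)) .stopf("no samples counted")

  counts <- countsFrame(tables, catalogue)
  .writeTSV(counts, file.path(cfg$out_dir, "counts.tsv"), stamp)

  se <- buildSJTPMExperiment(counts,
                             samples[samples$sample_id %in% names(tables), ])
  tpm <- SummarizedExperiment::assay(se, "sjtpm")
  .writeTSV(data.frame(variant = rownames(tpm), tpm, check.names = FALSE),
            file.path(cfg$out_dir, "sjtpm_matrix.tsv"), stamp)
  frac <- SummarizedExperiment::assay(se, "fraction")
  .writeTSV(data.frame(variant = rownames(frac), frac, check.names = FALSE),
            file.path(cfg$out_dir, "fractions.tsv"),
            c(stamp, "fractions are per-variant vs gene reads; not a partition, may not sum to 1"))

  if ("group" %in% names(samples)) {
    gs <- aggregateGroups(se, "group")
    .writeTSV(gs, file.path(cfg$out_dir, "group_summary.tsv"), stamp)
  }
  pres <- presenceSummary(se, cfg$detection_threshold)
  .writeTSV(data.frame(variant = names(pres), n_samples_present = pres),
            file.path(cfg$out_dir, "presence.tsv"), stamp)

  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  invisible(se)
}
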