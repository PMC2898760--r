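#' Pipeline configuration
#'
#' Assembles and validates every parameter of an end-to-end run. Unknown
#' keys are rejected so config typos fail before any stage runs. May be
#' loaded from a YAML or JSON file; arguments override file values.
#'
#' @param reference path to the transcriptome FASTA, or a
#'   `DNAStringSet` / [TagReference-class] object.
#' @param libraries named list/vector: per sample, a path to a tag file
#'   (TSV or FASTQ) or a [RawTagLibrary-class] / [TagLibrary-class].
#' @param outdir output directory for report artifacts (`NULL` = return
#'   results only, write nothing).
#' @param adaptor adaptor sequence stripped during filtering.
#' @param anchorExact mismatch policy, see [mapTag()].
#' @param bothStrands index reverse-complement tags, see
#'   [buildTagReference()].
#' @param bins lower bin edges for [abundanceDistribution()].
#' @param alpha,minAbsLog2 DE thresholds, see [callDE()].
#' @param saturationStep subsample increment for [saturationCurve()]
#'   (`NULL` skips saturation).
#' @param seed integer seed for the stochastic stages.
#' @param file optional YAML (`.yml`/`.yaml`) or JSON config file whose
#'   values are used as defaults.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(reference = NULL, libraries = NULL,
                           outdir = NULL, adaptor = "",
                           anchorExact = TRUE, bothStrands = FALSE,
                           bins = c(1, 2, 6, 11, 21, 51, 101, 501, 1001),
                           alpha = 0.001, minAbsLog2 = 1,
                           saturationStep = NULL, seed = 1L,
                           file = NULL) {
  cfg <- list(reference = reference, libraries = libraries,
              outdir = outdir, adaptor = adaptor,
              anchorExact = anchorExact, bothStrands = bothStrands,
              bins = bins, alpha = alpha, minAbsLog2 = minAbsLog2,
              saturationStep = saturationStep, seed = as.integer(seed))
  if (!is.null(file)) {
    vals <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
      yaml::read_yaml(file) else jsonlite::read_json(file, simplifyVector = TRUE)
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    supplied <- names(as.list(match.call()))
    for (k in setdiff(names(vals), supplied)) cfg[[k]] <- vals[[k]]
  }
  if (is.null(cfg$reference)) stop("config requires a reference")
  if (is.null(cfg$libraries) || length(cfg$libraries) < 1L)
    stop("config requires at least one library")
  if (is.null(names(cfg$libraries)) || any(names(cfg$libraries) == ""))
    stop("libraries must be named by sample")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  class(cfg) <- "PipelineConfig"
  cfg
}

# Stable hash of the configuration for provenance stamping.
.configHash <- function(cfg) {
  norm <- cfg
  norm$reference <- if (is.character(norm$reference)) norm$reference else class(norm$reference)[1L]
  norm$libraries <- lapply(norm$libraries, function(x)
    if (is.character(x)) x else class(x)[1L])
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(norm), auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("tagdge_stage_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

#' Run the DGE pipeline end-to-end
#'
#' Sequences the analysis stages in order: build (or accept) the virtual
#' tag reference, filter each raw library, map and count unambiguous
#' tags, normalize to TPM, compute tag-abundance distributions,
#' saturation curves and pairwise library correlations, and call
#' differential expression for every ordered pair of consecutive
#' libraries plus all unordered pairs. If `outdir` is set, writes the
#' report bundle: reference census, per-library clean counts and filter
#' audits, a library statistics table (raw/clean/mapped counts and
#' percentages), expression TSV, distributions, correlations, DE tables
#' with up/down tallies, and a run manifest stamped with the config hash
#' and seed. Identical config + seed reproduces identical outputs.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with `reference`, `libs` (clean
#'   [TagLibrary-class] objects), `se` (the expression
#'   `SummarizedExperiment`), `libraryStats` (Table-style summary data
#'   frame), `distributions`, `saturation`, `correlations`, `de`
#'   (per-pair result tables) and `manifest`.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  set.seed(cfg$seed)

  ref <- .stage("build-ref", {
    r <- cfg$reference
    if (is(r, "TagReference")) r
    else if (is.character(r)) buildTagReference(readTranscriptome(r),
                                                bothStrands = cfg$bothStrands)
    else buildTagReference(r, bothStrands = cfg$bothStrands)
  })

  libs <- .stage("filter", {
    lapply(cfg$libraries, function(x) {
      if (is(x, "TagLibrary")) return(x)
      raw <- if (is(x, "RawTagLibrary")) x else readTagLibrary(x)
      filterTags(raw, adaptor = cfg$adaptor)
    })
  })
  for (nm in names(libs)) libs[[nm]]@sampleId <- nm

  se <- .stage("express", expressionTable(libs, ref,
                                          anchorExact = cfg$anchorExact))

  dists <- .stage("distributions",
    lapply(libs, abundanceDistribution, breaks = cfg$bins))

  sat <- if (!is.null(cfg$saturationStep)) .stage("saturate", {
    lapply(libs, saturationCurve, ref = ref, step = cfg$saturationStep,
           anchorExact = cfg$anchorExact)
  }) else NULL

  cors <- .stage("correlate", {
    nm <- names(libs)
    if (length(nm) < 2L) NULL else {
      prs <- utils::combn(nm, 2L, simplify = FALSE)
      out <- lapply(prs, function(p)
        libraryCorrelation(libs[[p[1L]]], libs[[p[2L]]]))
      names(out) <- vapply(prs, paste, character(1), collapse = "_vs_")
      out
    }
  })

  de <- .stage("de", {
    nm <- names(libs)
    if (length(nm) < 2L) NULL else {
      prs <- utils::combn(nm, 2L, simplify = FALSE)
      out <- lapply(prs, function(p)
        callDE(se, p[1L], p[2L], alpha = cfg$alpha,
               minAbsLog2 = cfg$minAbsLog2))
      names(out) <- vapply(prs, paste, character(1), collapse = "_vs_")
      out
    }
  })

  stats <- .libraryStats(libs, se)
  manifest <- list(
    tool = "tagDGE", version = as.character(utils::packageVersion("tagDGE")),
    config_hash = .configHash(cfg), seed = cfg$seed,
    samples = names(libs),
    reference_census = tagCensus(ref),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  res <- list(reference = ref, libs = libs, se = se,
              libraryStats = stats, distributions = dists,
              saturation = sat, correlations = cors, de = de,
              manifest = manifest)
  if (!is.null(cfg$outdir)) .stage("report", .writeReport(res, cfg))
  invisible(res)
}

# Library statistics table in the layout of a DGE sequencing summary:
# one column per sample, rows for raw/clean totals and distinct counts,
# mapped tags (with % of clean) and tag-mapped genes (with % of
# reference genes).
.libraryStats <- function(libs, se) {
  maps <- S4Vectors::metadata(se)$mapping
  one <- function(nm) {
    l <- libs[[nm]]; m <- maps[[nm]]
    c(raw_tag_total = rawTotal(l),
      raw_tag_distinct = rawDistinct(l),
      clean_tag_total = cleanTotal(l),
      clean_tag_distinct = cleanDistinct(l),
      mapped_total = m$n_total_tags_mapped,
      mapped_total_pct = m$pct_total_tags_mapped,
      mapped_distinct = m$n_distinct_tags_mapped,
      mapped_distinct_pct = m$pct_distinct_tags_mapped,
      unambiguous_total = m$n_unambiguous_total,
      tag_mapped_genes = m$n_tag_mapped_genes,
      tag_mapped_genes_pct = m$pct_tag_mapped_genes,
      canonical_fraction = m$canonical_fraction)
  }
  cols <- lapply(names(libs), one)
  df <- as.data.frame(cols, col.names = names(libs), check.names = FALSE)
  cbind(statistic = rownames(df), df, row.names = NULL)
}

.writeReport <- function(res, cfg) {
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  writeTagReference(res$reference, file.path(out, "reference"))
  for (nm in names(res$libs)) {
    writeTagCounts(res$libs[[nm]], file.path(out, paste0(nm, ".tags.tsv")))
    jsonlite::write_json(
      lapply(filterLog(res$libs[[nm]]), as.list),
      file.path(out, paste0(nm, ".filter_audit.json")),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.table(res$libraryStats, file.path(out, "library_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(
    gene_id = rownames(res$se),
    SummarizedExperiment::assay(res$se, "counts"),
    check.names = FALSE)
  tpm <- SummarizedExperiment::assay(res$se, "tpm")
  colnames(tpm) <- paste0(colnames(tpm), "_tpm")
  utils::write.table(cbind(expr, tpm), file.path(out, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(res$distributions))
    utils::write.table(res$distributions[[nm]],
                       file.path(out, paste0(nm, ".abundance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$saturation))
    for (nm in names(res$saturation))
      utils::write.table(res$saturation[[nm]],
                         file.path(out, paste0(nm, ".saturation.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$correlations))
    jsonlite::write_json(res$correlations,
                         file.path(out, "correlations.json"),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$de)) {
    summaries <- list()
    for (nm in names(res$de)) {
      utils::write.table(as.data.frame(res$de[[nm]]),
                         file.path(out, paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summaries[[nm]] <- S4Vectors::metadata(res$de[[nm]])$summary
    }
    jsonlite::write_json(summaries, file.path(out, "de_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Per-gene TPM profiles across libraries
#'
#' Extracts stage profiles (TPM per gene per library) for a set of
#' genes, the form used to follow marker genes across developmental
#' stages. Genes present in the reference but undetected in a library
#' report TPM 0, not missing. Unknown gene identifiers are collected in
#' a `warnings` attribute and reported with a warning, not an error.
#'
#' @param se a `SummarizedExperiment` from [expressionTable()].
#' @param geneIds character vector of gene identifiers.
#' @return a `data.frame` of TPM values, genes x libraries, with
#'   attribute `warnings` listing unknown identifiers.
#' @export
profileGenes <- function(se, geneIds) {
  stopifnot(is(se, "SummarizedExperiment"))
  known <- geneIds %in% rownames(se)
  if (any(!known))
    warning("unknown gene_id: ", paste(geneIds[!known], collapse = ", "))
  tpm <- SummarizedExperiment::assay(se, "tpm")
  out <- as.data.frame(tpm[geneIds[known], , drop = FALSE])
  attr(out, "warnings") <- geneIds[!known]
  out
}
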