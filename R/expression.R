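#' Normalize tag counts to transcripts per million tags (TPM)
#'
#' TPM is the raw unambiguous tag count divided by the library's clean
#' tag total, times 1e6. Genes absent from `counts` keep TPM 0; the
#' pseudo-value 0.001 TPM for zeros is applied only when log ratios are
#' formed (see [callDE()]), never here.
#'
#' @param counts named numeric vector of per-gene raw counts.
#' @param libraryTotal clean tag total of the library (> 0).
#' @return named numeric vector of TPM values.
#' @examples
#' toTPM(c(g1 = 5), 20)   # 250000
#' @export
toTPM <- function(counts, libraryTotal) {
  if (length(libraryTotal) != 1L || is.na(libraryTotal) || libraryTotal <= 0)
    stop("libraryTotal must be a single positive count")
  counts / libraryTotal * 1e6
}

#' Build a per-gene expression table across libraries
#'
#' Maps each clean library against the reference, assembles the gene x
#' sample matrix of unambiguous tag counts, and returns a
#' `SummarizedExperiment` with assays `counts` and `tpm` (normalized by
#' each library's clean total), the clean totals in `colData`, and the
#' per-library mapping summaries in `metadata`.
#'
#' @param libs a named list of [TagLibrary-class] objects (names become
#'   column names; defaults to each library's `sampleId`).
#' @param ref the [TagReference-class] all libraries are mapped against.
#' @param anchorExact see [mapTag()].
#' @return a [SummarizedExperiment::SummarizedExperiment].
#' @export
expressionTable <- function(libs, ref, anchorExact = TRUE) {
  stopifnot(is.list(libs), length(libs) > 0L, is(ref, "TagReference"))
  if (is.null(names(libs)))
    names(libs) <- vapply(libs, sampleId, character(1))
  genes <- names(ref@transcripts)
  maps <- lapply(libs, countUnambiguous, ref = ref, anchorExact = anchorExact)
  counts <- do.call(cbind, lapply(maps, `[[`, "counts"))
  colnames(counts) <- names(libs)
  totals <- vapply(libs, cleanTotal, numeric(1))
  tpm <- sweep(counts, 2L, totals, "/") * 1e6
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm),
    colData = S4Vectors::DataFrame(
      sample = names(libs),
      clean_total = totals,
      clean_distinct = vapply(libs, cleanDistinct, numeric(1)),
      row.names = names(libs)),
    metadata = list(mapping = lapply(maps, `[[`, "summary")))
  se
}

#' Bin a tag-abundance or gene-expression distribution
#'
#' Partitions entities (distinct tags by copy number, or genes by TPM)
#' into ordered bins covering `[1, Inf)` and reports per bin the number
#' of entities and the total they carry, conserving both totals.
#'
#' @param x a [TagLibrary-class] (entities are distinct tags, values are
#'   copy numbers) or a numeric vector (e.g. per-gene TPM; values below
#'   the first bin edge, such as undetected genes, are dropped with a
#'   message).
#' @param breaks increasing numeric vector of lower bin edges, first
#'   edge 1, implicitly closing with `Inf`; bin i is
#'   `[breaks[i], breaks[i+1])`. The default reproduces copy-number
#'   categories of the form `[1], [2,5], [6,10], ...` for integer counts.
#' @return a `data.frame` with columns `bin`, `n_distinct`, `n_total`.
#' @examples
#' lib <- tagLibrary("s", setNames(c(2, 3, 5, 7, 150),
#'   paste0("CATG", c("AAAAAAAAAAAAAAAGA", "AAAAAAAAAAAAAAGAC",
#'                    "AAAAAAAAAAAAAGACA", "AAAAAAAAAAAAGACAA",
#'                    "AAAAAAAAAAAGAAACA"))))
#' abundanceDistribution(lib, breaks = c(2, 6, 11, 101))
#' @export
abundanceDistribution <- function(x,
    breaks = c(1, 2, 6, 11, 21, 51, 101, 501, 1001)) {
  if (is(x, "TagLibrary")) v <- as.numeric(tagCounts(x)) else v <- as.numeric(x)
  if (any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing (disjoint, ordered bins)")
  low <- v < breaks[1L]
  if (any(low)) {
    message(sum(low), " entities below the first bin edge dropped")
    v <- v[!low]
  }
  bin <- findInterval(v, breaks)
  edges_hi <- c(breaks[-1L], Inf)
  lab <- ifelse(is.finite(edges_hi),
                ifelse(edges_hi - 1 == breaks, sprintf("[%g]", breaks),
                       sprintf("[%g,%g]", breaks, edges_hi - 1)),
                sprintf(">=%g", breaks))
  data.frame(
    bin = lab,
    n_distinct = vapply(seq_along(breaks), function(i) sum(bin == i), numeric(1)),
    n_total = vapply(seq_along(breaks), function(i) sum(v[bin == i]), numeric(1))
  )
}

#' Sequencing saturation curve
#'
#' Subsamples the library's tag occurrences without replacement at
#' cumulative depths `step, 2*step, ...` (one random permutation of the
#' occurrence multiset; nested prefixes, not independent re-draws) and
#' reports the number of genes detected by at least one unambiguously
#' mapped tag at each depth. A plateau indicates the library depth
#' suffices to see the expressed gene catalogue.
#'
#' @param lib a [TagLibrary-class].
#' @param ref a [TagReference-class].
#' @param step subsample increment in tag occurrences (> 0). If `step`
#'   exceeds the library size a single full-depth point is returned.
#' @param seed optional integer seed for the permutation.
#' @param anchorExact see [mapTag()].
#' @return a `data.frame` with columns `n_subsampled_tags`,
#'   `n_detected_genes` (non-decreasing; the last row is the full
#'   library).
#' @export
saturationCurve <- function(lib, ref, step, seed = NULL, anchorExact = TRUE) {
  stopifnot(is(lib, "TagLibrary"), is(ref, "TagReference"))
  if (length(step) != 1L || is.na(step) || step <= 0)
    stop("step must be a single positive count")
  if (!is.null(seed)) set.seed(seed)
  occ_counts <- tagCounts(lib)
  N <- sum(occ_counts)
  map <- .mapTags(names(occ_counts), ref, anchorExact = anchorExact)
  gene_of_tag <- ifelse(map$status == "unique", map$gene_id, NA_character_)
  gene_idx <- match(gene_of_tag, names(ref@transcripts))
  occ_gene <- rep(gene_idx, occ_counts)        # gene per occurrence (NA = unusable)
  occ_gene <- occ_gene[sample.int(N, N)]       # one permutation
  depths <- unique(c(seq(min(step, N), N, by = step), N))
  first_seen <- !duplicated(occ_gene, incomparables = NA) & !is.na(occ_gene)
  cum_genes <- cumsum(first_seen)
  data.frame(n_subsampled_tags = depths, n_detected_genes = cum_genes[depths])
}

#' Pearson correlation between two tag libraries
#'
#' Correlates the two libraries over the union of their distinct tag
#' entities (a tag absent from one library contributes 0), by default on
#' the `log10(count + 1)` scale; `logScale = FALSE` correlates raw
#' counts.
#'
#' @param a,b [TagLibrary-class] objects.
#' @param logScale correlate `log10(count+1)` (default) or raw counts.
#' @return the Pearson correlation coefficient.
#' @export
libraryCorrelation <- function(a, b, logScale = TRUE) {
  stopifnot(is(a, "TagLibrary"), is(b, "TagLibrary"))
  ca <- tagCounts(a); cb <- tagCounts(b)
  if (length(ca) == 0L || length(cb) == 0L) stop("both libraries must be nonempty")
  tags <- union(names(ca), names(cb))
  va <- as.numeric(ca[tags]); va[is.na(va)] <- 0
  vb <- as.numeric(cb[tags]); vb[is.na(vb)] <- 0
  if (logScale) { va <- log10(va + 1); vb <- log10(vb + 1) }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("a library has zero variance over the tag union")
  stats::cor(va, vb)
}
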