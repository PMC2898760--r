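#' Audic-Claverie exact p-value for two tag counts
#'
#' Given a feature observed `x` times among `n1` tags in library 1 and
#' `y` times among `n2` tags in library 2, the Audic-Claverie model
#' gives the conditional distribution of the second count,
#' \deqn{P(y \mid x) = \left(\frac{n_2}{n_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+n_2/n_1)^{x+y+1}},}
#' equivalently `y | x ~ NegBinomial(size = x+1, prob = n1/(n1+n2))`.
#' The two-sided p-value doubles the smaller of the two tail sums
#' (each tail including the observed point) and caps at 1:
#' `p = min(1, 2 * min(sum_{y' <= y} P(y'|x), sum_{y' >= y} P(y'|x)))`.
#' Tails are accumulated in the log domain with long double arithmetic
#' and truncated once the running term falls below 1e-18 of the
#' accumulated mass past the mode.
#'
#' Because the observed point is counted in both tails, swapping the two
#' libraries changes the p-value by at most twice the probability of the
#' observed point; the underlying tail sums obey the exact symmetry
#' `P(Y <= y | x, r) = 1 - P(X <= x-1 | y, 1/r)`.
#'
#' @param x,y observed counts (non-negative integers; recycled).
#' @param n1,n2 clean tag totals of the two libraries (>= 1).
#' @param alternative `"two.sided"` (default), `"less"` (library-2 count
#'   depleted) or `"greater"` (elevated), the one-sided tails.
#' @return numeric vector of p-values in `[0, 1]`.
#' @examples
#' acPvalue(0, 0, 1e5, 1e5)        # 1
#' acPvalue(20, 0, 1e5, 1e5)       # 2^-20
#' @export
acPvalue <- function(x, y, n1, n2,
                     alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  n1 <- rep_len(as.numeric(n1), n); n2 <- rep_len(as.numeric(n2), n)
  if (anyNA(c(x, y, n1, n2))) stop("inputs must be non-missing")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 < 1) || any(n2 < 1)) stop("library totals must be >= 1")
  if (any(x > n1) || any(y > n2)) stop("a count exceeds its library total")
  alt <- match(alternative, c("two.sided", "less", "greater")) - 1L
  .ac_pvalue_cpp(x, y, n1, n2, alt)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH q-values `q_(i) = min_{j >= i} m * p_(j) / j`, returned
#' in the input order. A thin validated front end to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))   # all 0.03
#' @export
bhFdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differential expression between two libraries
#'
#' Pairwise gene-level test between two columns of an expression table:
#' per-gene Audic-Claverie exact p-value from the raw unambiguous counts
#' and clean library totals, BH-FDR across genes, log2 TPM ratio with
#' the 0.001 TPM pseudo-value substituted for zeros, and significance
#' calls. A gene is called up-regulated if `fdr < alpha` and
#' `log2_ratio >= minAbsLog2` (library 2 over library 1), down-regulated
#' symmetrically. Genes with zero counts in both libraries are excluded
#' from testing.
#'
#' @param se a `SummarizedExperiment` from [expressionTable()].
#' @param sample1,sample2 column names (or indices) of the two libraries.
#' @param alpha FDR threshold for significance (default 0.001).
#' @param minAbsLog2 minimum absolute log2 ratio (default 1).
#' @param alternative sidedness passed to [acPvalue()].
#' @return a [S4Vectors::DataFrame] with one row per tested gene:
#'   `gene_id`, `count1`, `count2`, `tpm1`, `tpm2`, `log2_ratio`,
#'   `p_value`, `fdr`, `call` (`"up"`, `"down"` or `"ns"`) and
#'   `one_sample_only` (count zero in exactly one library). The up/down
#'   tallies are in `metadata(x)$summary`.
#' @export
callDE <- function(se, sample1, sample2, alpha = 0.001, minAbsLog2 = 1,
                   alternative = "two.sided") {
  stopifnot(is(se, "SummarizedExperiment"))
  cn <- colnames(se)
  s1 <- if (is.numeric(sample1)) cn[sample1] else sample1
  s2 <- if (is.numeric(sample2)) cn[sample2] else sample2
  if (!all(c(s1, s2) %in% cn))
    stop("samples not found in expression table: ",
         paste(setdiff(c(s1, s2), cn), collapse = ", "))
  counts <- SummarizedExperiment::assay(se, "counts")
  tpm <- SummarizedExperiment::assay(se, "tpm")
  tot <- SummarizedExperiment::colData(se)$clean_total
  names(tot) <- cn
  x <- counts[, s1]; y <- counts[, s2]
  keep <- x + y > 0
  x <- x[keep]; y <- y[keep]
  t1 <- tpm[keep, s1]; t2 <- tpm[keep, s2]
  lr <- log2(pmax(t2, 0.001) / pmax(t1, 0.001))
  p <- acPvalue(x, y, tot[s1], tot[s2], alternative = alternative)
  q <- bhFdr(p)
  call <- rep("ns", length(p))
  call[q < alpha & lr >= minAbsLog2] <- "up"
  call[q < alpha & lr <= -minAbsLog2] <- "down"
  res <- S4Vectors::DataFrame(
    gene_id = rownames(counts)[keep],
    count1 = unname(x), count2 = unname(y),
    tpm1 = unname(t1), tpm2 = unname(t2),
    log2_ratio = unname(lr),
    p_value = p, fdr = q, call = call,
    one_sample_only = unname(xor(x == 0, y == 0)))
  S4Vectors::metadata(res) <- list(summary = list(
    sample1 = s1, sample2 = s2,
    n_tested = nrow(res),
    n_up = sum(call == "up"),
    n_down = sum(call == "down"),
    alpha = alpha, min_abs_log2 = minAbsLog2))
  res
}

#' Tag-level differential expression collapsed to genes
#'
#' Tests every unambiguously mapped distinct tag entity (over the union
#' of the two libraries) with the Audic-Claverie statistic, then calls a
#' gene differentially expressed if at least one of its tags is
#' significant and all its significant tags agree in direction; genes
#' whose significant tags conflict are reported as `"conflict"` and not
#' counted in the up/down tallies.
#'
#' @param lib1,lib2 clean [TagLibrary-class] objects.
#' @param ref the common [TagReference-class].
#' @param alpha FDR threshold (default 0.001).
#' @param minAbsLog2 minimum absolute log2 ratio of tag TPM (default 1).
#' @param anchorExact see [mapTag()].
#' @return a list with `tags` (per-tag test table) and `genes`
#'   (per-gene collapsed calls with `n_sig_tags`), plus a `summary`
#'   element with the tallies.
#' @export
callDETags <- function(lib1, lib2, ref, alpha = 0.001, minAbsLog2 = 1,
                       anchorExact = TRUE) {
  stopifnot(is(lib1, "TagLibrary"), is(lib2, "TagLibrary"))
  c1 <- tagCounts(lib1); c2 <- tagCounts(lib2)
  tags <- union(names(c1), names(c2))
  map <- .mapTags(tags, ref, anchorExact = anchorExact)
  uniq <- map$status == "unique"
  tags <- tags[uniq]; gene <- map$gene_id[uniq]
  x <- as.numeric(c1[tags]); x[is.na(x)] <- 0
  y <- as.numeric(c2[tags]); y[is.na(y)] <- 0
  N1 <- cleanTotal(lib1); N2 <- cleanTotal(lib2)
  t1 <- toTPM(x, N1); t2 <- toTPM(y, N2)
  lr <- log2(pmax(t2, 0.001) / pmax(t1, 0.001))
  p <- acPvalue(x, y, N1, N2)
  q <- bhFdr(p)
  sig <- q < alpha & abs(lr) >= minAbsLog2
  tagtab <- S4Vectors::DataFrame(
    tag_seq = tags, gene_id = gene, count1 = x, count2 = y,
    log2_ratio = lr, p_value = p, fdr = q, significant = sig)
  dir <- sign(lr)
  gcall <- vapply(split(seq_along(tags), gene), function(i) {
    s <- i[sig[i]]
    if (!length(s)) return("ns")
    d <- unique(dir[s])
    if (length(d) > 1L) "conflict" else if (d > 0) "up" else "down"
  }, character(1))
  nsig <- vapply(split(sig, gene), sum, numeric(1))
  genes <- S4Vectors::DataFrame(
    gene_id = names(gcall), call = unname(gcall),
    n_sig_tags = as.integer(unname(nsig[names(gcall)])))
  list(tags = tagtab, genes = genes,
       summary = list(
         n_sig_tag_entities = sum(sig),
         n_de_genes = sum(gcall != "ns" & gcall != "conflict"),
         n_up = sum(gcall == "up"), n_down = sum(gcall == "down"),
         n_conflict = sum(gcall == "conflict")))
}
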