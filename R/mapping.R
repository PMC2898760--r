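# One-mismatch tag mapping. Exact hits are looked up directly in the
# reference index; misses are expanded into their substitution
# neighborhood and looked up in one vectorised pass. Exact hits shadow
# 1-mismatch hits: gene sets are never mixed across mismatch levels.

# Enumerate the 1-substitution neighborhood of each query. With
# anchorExact the mismatch is confined to the 17 variable positions
# (3 alternatives x 17 positions = 51 variants); otherwise all 21
# positions are mutable. Variants equal to the original sequence are
# harmless: the original already failed exact lookup.
.variantTable <- function(tags, anchorExact = TRUE) {
  pos <- if (anchorExact) (ANCHOR_WIDTH + 1L):TAG_WIDTH else 1L:TAG_WIDTH
  nt <- length(tags)
  np <- length(pos)
  qi <- rep(seq_len(nt), each = np * 4L)
  pp <- rep(rep(pos, each = 4L), times = nt)
  bb <- rep(DNA_BASES, times = np * nt)
  v <- tags[qi]
  orig <- substr(v, pp, pp)
  keep <- orig != bb
  v <- v[keep]; pp <- pp[keep]; bb <- bb[keep]; qi <- qi[keep]
  substr(v, pp, pp) <- bb
  list(query = qi, variant = v)
}

# Vectorised mapping of distinct clean tags against a TagReference.
# Returns one row per query tag: status in {unique, ambiguous, unmapped},
# gene_id / site_pos / is_canonical for unique hits, n_mismatches.
.mapTags <- function(tags, ref, anchorExact = TRUE) {
  idx <- ref@index
  n <- length(tags)
  status <- rep("unmapped", n)
  gene <- rep(NA_character_, n)
  site <- rep(NA_integer_, n)
  canon <- rep(NA, n)
  mm <- rep(NA_integer_, n)

  j <- match(tags, idx$tag_seq)
  hit0 <- !is.na(j)
  if (any(hit0)) {
    jj <- j[hit0]
    amb <- idx$n_genes[jj] > 1L
    status[hit0] <- ifelse(amb, "ambiguous", "unique")
    gene[hit0] <- idx$gene_id[jj]
    site[hit0] <- idx$site_pos[jj]
    canon[hit0] <- idx$is_canonical[jj]
    mm[hit0] <- 0L
  }
  miss <- which(!hit0)
  if (length(miss)) {
    vt <- .variantTable(tags[miss], anchorExact = anchorExact)
    vj <- match(vt$variant, idx$tag_seq)
    vh <- !is.na(vj)
    if (any(vh)) {
      q <- vt$query[vh]          # index into miss
      jj <- vj[vh]
      hg <- idx$n_genes[jj]
      hgene <- idx$gene_id[jj]
      hsite <- idx$site_pos[jj]
      hcan <- idx$is_canonical[jj]
      # resolve all queries at once: a query is ambiguous if any hit is a
      # multi-gene tag or its single-gene hits span > 1 gene; otherwise
      # unique, attributed to the 3'-most hit site of its gene
      qs <- sort(unique(q))
      nq <- length(qs)
      qf <- match(q, qs)
      multi <- tabulate(qf[hg > 1L], nbins = nq) > 0L
      firstpair <- !duplicated(paste0(q, "\r", hgene))
      ngenes <- tabulate(qf[firstpair], nbins = nq)
      ambQ <- multi | ngenes > 1L
      o <- order(qf, hsite)
      ends <- cumsum(rle(qf[o])$lengths)
      best <- o[ends]                     # max-site hit row per query
      i <- miss[qs]
      mm[i] <- 1L
      status[i] <- ifelse(ambQ, "ambiguous", "unique")
      iu <- i[!ambQ]; bu <- best[!ambQ]
      gene[iu] <- hgene[bu]
      site[iu] <- hsite[bu]
      canon[iu] <- hcan[bu]
    }
  }
  S4Vectors::DataFrame(tag_seq = tags, status = status, gene_id = gene,
                       site_pos = site, is_canonical = canon,
                       n_mismatches = mm)
}

#' Map a single tag to the reference with at most one mismatch
#'
#' Exact matches are preferred; if none exists, the one-substitution
#' neighborhood is searched and the gene set is the union of genes hit
#' at the minimal mismatch level. Tags hitting multiple genes are
#' reported ambiguous (and are excluded from quantification downstream);
#' a tag hitting several sites of the same gene is unambiguous at the
#' gene level, with the 3'-most site used for the canonical flag.
#'
#' @param tagSeq a clean 21 nt tag (CATG prefix, no N).
#' @param ref a [TagReference-class].
#' @param anchorExact if `TRUE` (default) the mismatch budget applies to
#'   the 17 variable positions only and the CATG anchor must match
#'   exactly; if `FALSE` all 21 positions are mutable.
#' @return a list with `tag_seq`, `status` (`"unique"`, `"ambiguous"` or
#'   `"unmapped"`), `gene_ids` (character vector; empty if unmapped),
#'   `n_mismatches` (NA if unmapped) and `site_is_canonical` (meaningful
#'   for unique hits only).
#' @export
mapTag <- function(tagSeq, ref, anchorExact = TRUE) {
  stopifnot(is(ref, "TagReference"))
  tagSeq <- as.character(tagSeq)
  if (length(tagSeq) != 1L || nchar(tagSeq) != TAG_WIDTH ||
      !startsWith(tagSeq, ANCHOR) || grepl("[^ACGT]", tagSeq))
    stop("malformed tag: need 21 nt over ACGT starting with CATG")
  row <- .mapTags(tagSeq, ref, anchorExact = anchorExact)
  gene_ids <- character()
  if (row$status == "unique") {
    gene_ids <- row$gene_id
  } else if (row$status == "ambiguous") {
    # reconstruct the full gene set at the minimal mismatch level
    idx <- ref@index
    tab <- ref@tags
    if (row$n_mismatches == 0L) {
      gene_ids <- sort(unique(tab$gene_id[tab$tag_seq == tagSeq]))
    } else {
      vt <- .variantTable(tagSeq, anchorExact = anchorExact)
      hits <- vt$variant[vt$variant %in% idx$tag_seq]
      gene_ids <- sort(unique(tab$gene_id[tab$tag_seq %in% hits]))
    }
  }
  list(tag_seq = tagSeq, status = row$status, gene_ids = gene_ids,
       n_mismatches = if (is.na(row$n_mismatches)) NA_integer_ else row$n_mismatches,
       site_is_canonical = row$is_canonical)
}

#' Count unambiguous tags per gene and summarise mapping
#'
#' Maps every distinct tag of a clean library against the reference and
#' accumulates per-gene counts from tags whose hits fall within a single
#' gene (the unambiguous subset, the only tags that explicitly identify
#' a transcript). The summary mirrors the structure of a DGE library
#' statistics table: total and distinct tags mapped (with percentages of
#' the clean totals), tag-mapped genes (with percentage of reference
#' genes), and the fraction of unambiguously mapped tag occurrences
#' whose hit site is the canonical (3'-most) NlaIII site.
#'
#' @param lib a [TagLibrary-class] (clean).
#' @param ref a [TagReference-class].
#' @param anchorExact see [mapTag()].
#' @return a list with elements `counts` (named integer vector over all
#'   reference genes; zero for undetected genes), `summary` (list of
#'   mapping statistics) and `tags` (per-distinct-tag mapping table).
#' @export
countUnambiguous <- function(lib, ref, anchorExact = TRUE) {
  stopifnot(is(lib, "TagLibrary"), is(ref, "TagReference"))
  genes <- names(ref@transcripts)
  occ <- tagCounts(lib)
  if (length(occ) == 0L) {
    return(list(
      counts = setNames(integer(length(genes)), genes),
      summary = .mappingSummary(numeric(), numeric(), character(),
                                logical(), 0, 0, length(genes)),
      tags = .mapTags(character(), ref)))
  }
  map <- .mapTags(names(occ), ref, anchorExact = anchorExact)
  uniq <- map$status == "unique"
  amb <- map$status == "ambiguous"
  counts <- setNames(integer(length(genes)), genes)
  if (any(uniq)) {
    agg <- rowsum(as.numeric(occ[uniq]), map$gene_id[uniq])
    counts[rownames(agg)] <- as.integer(agg[, 1L])
  }
  summary <- .mappingSummary(
    occ_uniq = as.numeric(occ[uniq]),
    occ_amb = as.numeric(occ[amb]),
    genes_hit = map$gene_id[uniq],
    canon = map$is_canonical[uniq],
    clean_total = cleanTotal(lib),
    clean_distinct = cleanDistinct(lib),
    n_ref_genes = length(genes))
  list(counts = counts, summary = summary, tags = map)
}

.mappingSummary <- function(occ_uniq, occ_amb, genes_hit, canon,
                            clean_total, clean_distinct, n_ref_genes) {
  n_total_mapped <- sum(occ_uniq) + sum(occ_amb)
  n_distinct_mapped <- length(occ_uniq) + length(occ_amb)
  n_genes_detected <- length(unique(genes_hit))
  pct <- function(a, b) if (b > 0) 100 * a / b else 0
  list(
    n_total_tags_mapped = n_total_mapped,
    pct_total_tags_mapped = pct(n_total_mapped, clean_total),
    n_distinct_tags_mapped = n_distinct_mapped,
    pct_distinct_tags_mapped = pct(n_distinct_mapped, clean_distinct),
    n_unambiguous_total = sum(occ_uniq),
    n_unambiguous_distinct = length(occ_uniq),
    n_ambiguous_total = sum(occ_amb),
    n_unmapped_total = clean_total - n_total_mapped,
    n_tag_mapped_genes = n_genes_detected,
    pct_tag_mapped_genes = pct(n_genes_detected, n_ref_genes),
    canonical_fraction = if (sum(occ_uniq) > 0)
      sum(occ_uniq[canon]) / sum(occ_uniq) else NA_real_
  )
}
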