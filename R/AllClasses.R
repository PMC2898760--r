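#' TagReference: virtual NlaIII tag database for a transcriptome
#'
#' Holds the transcript sequences, the per-site virtual tag table
#' (every CATG with at least 17 nt downstream on the sense strand yields one
#' CATG+17 tag), and a collapsed tag-sequence index used for mapping. The
#' 3'-most usable site of each transcript is flagged canonical; under
#' complete NlaIII digestion all sequenced tags originate there.
#'
#' @slot transcripts a named [Biostrings::DNAStringSet] of transcript
#'   sequences; names are gene identifiers, unique.
#' @slot tags a [S4Vectors::DataFrame] with one row per virtual tag:
#'   `tag_seq`, `gene_id`, `site_pos` (0-based offset of the C of CATG),
#'   `is_canonical`, `strand`.
#' @slot index a [S4Vectors::DataFrame] with one row per distinct
#'   `tag_seq`: `n_genes`, and for single-gene tags the owning `gene_id`,
#'   the 3'-most `site_pos` carrying that sequence and its `is_canonical`
#'   flag (`NA` for multi-gene tags).
#' @slot census list of reference-level counts (total virtual tags, distinct
#'   tag sequences, unambiguous tag sequences, genes with >= 1 tag,
#'   untaggable genes).
#' @aliases TagReference-class
#' @exportClass TagReference
setClass("TagReference",
  slots = c(
    transcripts = "DNAStringSet",
    tags = "DataFrame",
    index = "DataFrame",
    census = "list"
  )
)

setValidity("TagReference", function(object) {
  msg <- character()
  ids <- names(object@transcripts)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "transcripts must be named by non-empty gene_id")
  if (anyDuplicated(ids))
    msg <- c(msg, "gene_id values must be unique")
  needed <- c("tag_seq", "gene_id", "site_pos", "is_canonical")
  if (!all(needed %in% colnames(object@tags)))
    msg <- c(msg, "tags table lacks required columns")
  if (nrow(object@tags)) {
    if (!all(object@tags$tag_seq %in% object@index$tag_seq))
      msg <- c(msg, "every virtual tag_seq must be a key of the index")
    if (any(nchar(object@tags$tag_seq) != TAG_WIDTH))
      msg <- c(msg, "tag_seq must be 21 nt")
  }
  nun <- sum(object@index$n_genes == 1L)
  if (!identical(as.integer(object@census$n_unambiguous_ref_tags), as.integer(nun)))
    msg <- c(msg, "census n_unambiguous_ref_tags inconsistent with index")
  if (length(msg)) msg else TRUE
})

#' RawTagLibrary: an unfiltered tag library
#'
#' A sample's raw tag multiset before any cleaning, stored as distinct
#' read sequences with multiplicities. Reads may be bare 21 nt tags or
#' longer reads still carrying adaptor sequence.
#'
#' @slot sampleId single character sample identifier.
#' @slot counts named integer vector: names are distinct read sequences,
#'   values their occurrence counts (all >= 1).
#' @aliases RawTagLibrary-class
#' @exportClass RawTagLibrary
setClass("RawTagLibrary",
  slots = c(sampleId = "character", counts = "integer")
)

setValidity("RawTagLibrary", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  if (length(object@counts)) {
    if (is.null(names(object@counts)) || anyNA(names(object@counts)))
      msg <- c(msg, "counts must be named by read sequence")
    if (any(object@counts < 1L))
      msg <- c(msg, "counts must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' TagLibrary: a cleaned tag library with filtering provenance
#'
#' Distinct 21 nt CATG-anchored tag sequences with counts after the fixed
#' filtering cascade (adaptor/empty, 'N', low-complexity, copy-number-1),
#' plus an audit trail of occurrences removed by each rule.
#'
#' @slot sampleId single character sample identifier.
#' @slot counts named integer vector over distinct clean tags.
#' @slot nRawTotal raw occurrence total before filtering.
#' @slot nRawDistinct distinct raw sequences before filtering.
#' @slot filterLog list with per-rule removed occurrence and distinct
#'   counts (`adaptor_or_empty`, `contains_N`, `low_complexity`,
#'   `copy_number_1`).
#' @aliases TagLibrary-class
#' @exportClass TagLibrary
setClass("TagLibrary",
  slots = c(
    sampleId = "character",
    counts = "integer",
    nRawTotal = "integer",
    nRawDistinct = "integer",
    filterLog = "list"
  )
)

setValidity("TagLibrary", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-NA string")
  tg <- names(object@counts)
  if (length(object@counts)) {
    if (is.null(tg))
      msg <- c(msg, "counts must be named by tag sequence")
    else {
      if (any(nchar(tg) != TAG_WIDTH))
        msg <- c(msg, "all tags must be 21 nt")
      if (any(substr(tg, 1L, ANCHOR_WIDTH) != ANCHOR))
        msg <- c(msg, "all tags must start with CATG")
      if (any(grepl("N", tg, fixed = TRUE)))
        msg <- c(msg, "clean tags must not contain N")
    }
    if (any(object@counts < 1L))
      msg <- c(msg, "counts must be positive")
  }
  fl <- object@filterLog
  if (length(fl)) {
    kept <- sum(object@counts)
    removed <- sum(vapply(fl, function(x) as.numeric(x["occurrences"]), numeric(1)))
    if (!isTRUE(all.equal(kept + removed, as.numeric(object@nRawTotal))))
      msg <- c(msg, "occurrence conservation violated: kept + removed != raw total")
  }
  if (length(msg)) msg else TRUE
})
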