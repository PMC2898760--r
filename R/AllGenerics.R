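#' @rdname TagLibrary-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("tagCounts", function(x) standardGeneric("tagCounts"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("rawTotal", function(x) standardGeneric("rawTotal"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("rawDistinct", function(x) standardGeneric("rawDistinct"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("cleanTotal", function(x) standardGeneric("cleanTotal"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("cleanDistinct", function(x) standardGeneric("cleanDistinct"))

#' @rdname TagLibrary-accessors
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname TagReference-accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname TagReference-accessors
#' @export
setGeneric("virtualTags", function(x) standardGeneric("virtualTags"))

#' @rdname TagReference-accessors
#' @export
setGeneric("tagIndex", function(x) standardGeneric("tagIndex"))

#' @rdname TagReference-accessors
#' @export
setGeneric("tagCensus", function(x) standardGeneric("tagCensus"))

#' Accessors for TagLibrary and RawTagLibrary objects
#'
#' `sampleId()` returns the sample identifier; `tagCounts()` the named
#' integer count vector over distinct tag sequences; `rawTotal()` /
#' `rawDistinct()` the pre-filtering occurrence and distinct-sequence
#' totals; `cleanTotal()` / `cleanDistinct()` the post-filtering totals;
#' `filterLog()` the per-rule removal audit.
#'
#' @param x a `TagLibrary` or `RawTagLibrary`.
#' @return the corresponding component.
#' @name TagLibrary-accessors
NULL

#' Accessors for TagReference objects
#'
#' `transcripts()` returns the transcript `DNAStringSet`; `virtualTags()`
#' the per-site virtual tag table; `tagIndex()` the collapsed distinct
#' tag-sequence index used for mapping; `tagCensus()` the reference-level
#' counts.
#'
#' @param x a `TagReference`.
#' @return the corresponding component.
#' @name TagReference-accessors
NULL

#' @rdname TagLibrary-accessors
setMethod("sampleId", "TagLibrary", function(x) x@sampleId)
#' @rdname TagLibrary-accessors
setMethod("sampleId", "RawTagLibrary", function(x) x@sampleId)
#' @rdname TagLibrary-accessors
setMethod("tagCounts", "TagLibrary", function(x) x@counts)
#' @rdname TagLibrary-accessors
setMethod("tagCounts", "RawTagLibrary", function(x) x@counts)
#' @rdname TagLibrary-accessors
setMethod("rawTotal", "RawTagLibrary", function(x) sum(x@counts))
#' @rdname TagLibrary-accessors
setMethod("rawTotal", "TagLibrary", function(x) x@nRawTotal)
#' @rdname TagLibrary-accessors
setMethod("rawDistinct", "RawTagLibrary", function(x) length(x@counts))
#' @rdname TagLibrary-accessors
setMethod("rawDistinct", "TagLibrary", function(x) x@nRawDistinct)
#' @rdname TagLibrary-accessors
setMethod("cleanTotal", "TagLibrary", function(x) sum(x@counts))
#' @rdname TagLibrary-accessors
setMethod("cleanDistinct", "TagLibrary", function(x) length(x@counts))
#' @rdname TagLibrary-accessors
setMethod("filterLog", "TagLibrary", function(x) x@filterLog)

#' @rdname TagReference-accessors
setMethod("transcripts", "TagReference", function(x) x@transcripts)
#' @rdname TagReference-accessors
setMethod("virtualTags", "TagReference", function(x) x@tags)
#' @rdname TagReference-accessors
setMethod("tagIndex", "TagReference", function(x) x@index)
#' @rdname TagReference-accessors
setMethod("tagCensus", "TagReference", function(x) x@census)

setMethod("show", "TagReference", function(object) {
  cs <- object@census
  cat("TagReference with", length(object@transcripts), "transcripts\n")
  cat("  virtual tags:        ", cs$n_virtual_tags, "\n")
  cat("  distinct tag seqs:   ", cs$n_distinct_tags, "\n")
  cat("  unambiguous tag seqs:", cs$n_unambiguous_ref_tags, "\n")
  cat("  genes with >=1 tag:  ", cs$n_genes_with_tag,
      "(", cs$n_untaggable, "untaggable )\n")
  invisible(NULL)
})

setMethod("show", "RawTagLibrary", function(object) {
  cat("RawTagLibrary", object@sampleId, "-", sum(object@counts),
      "occurrences,", length(object@counts), "distinct reads\n")
  invisible(NULL)
})

setMethod("show", "TagLibrary", function(object) {
  cat("TagLibrary", object@sampleId, "\n")
  cat("  raw:  ", object@nRawTotal, "occurrences,",
      object@nRawDistinct, "distinct\n")
  cat("  clean:", sum(object@counts), "occurrences,",
      length(object@counts), "distinct\n")
  if (length(object@filterLog)) {
    rm_ <- vapply(object@filterLog, function(x) as.integer(x["occurrences"]),
                  integer(1))
    cat("  removed occurrences:",
        paste(names(rm_), rm_, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})
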