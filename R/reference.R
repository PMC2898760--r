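#' Extract virtual CATG+17 tags from one transcript
#'
#' Scans the sense strand for every occurrence of the NlaIII recognition
#' site CATG and returns one 21 nt virtual tag (CATG plus the 17 nt
#' released by MmeI) per site with at least 17 nt downstream. The 3'-most
#' usable site is flagged canonical. Tags containing `N` are excluded:
#' they can never match a clean sequenced tag exactly and would only
#' inflate ambiguity. Sites closer than 17 nt to the 3' end yield no
#' (truncated) tag.
#'
#' @param sequence a single uppercase DNA string (or `DNAString`).
#' @param geneId gene identifier recorded in the result.
#' @return a `data.frame` with columns `tag_seq`, `gene_id`, `site_pos`
#'   (0-based offset of the C of CATG), `is_canonical`; zero rows if the
#'   transcript has no usable site.
#' @examples
#' extractVirtualTags(paste0("GGGCATG", strrep("A", 17), "TTT"), "g1")
#' @export
extractVirtualTags <- function(sequence, geneId = "gene") {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  tab <- .virtualTagTable(setNames(sequence, geneId))
  as.data.frame(tab)
}

# Vectorised workhorse: virtual tag table over a named character vector
# of transcript sequences. One row per usable CATG site.
.virtualTagTable <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  hits <- gregexpr(ANCHOR, seqs, fixed = TRUE)
  n_per <- vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h),
                  integer(1))
  starts <- unlist(lapply(hits, function(h) if (h[1L] == -1L) integer() else as.integer(h)),
                   use.names = FALSE)
  gene <- rep(names(seqs), n_per)
  seqv <- rep(unname(seqs), n_per)
  lens <- rep(nchar(seqs), n_per)
  usable <- starts + TAG_WIDTH - 1L <= lens
  gene <- gene[usable]; seqv <- seqv[usable]; starts <- starts[usable]
  tag <- substr(seqv, starts, starts + TAG_WIDTH - 1L)
  keep <- !grepl("N", tag, fixed = TRUE)
  gene <- gene[keep]; starts <- starts[keep]; tag <- tag[keep]
  # canonical = maximal site_pos within each gene
  is_canon <- logical(length(tag))
  if (length(tag)) {
    ord <- order(gene, starts)
    g <- gene[ord]
    last_of_gene <- c(g[-1L] != g[-length(g)], TRUE)
    is_canon[ord] <- last_of_gene
  }
  S4Vectors::DataFrame(
    tag_seq = tag,
    gene_id = gene,
    site_pos = starts - 1L,   # 0-based offset of the C of CATG
    is_canonical = is_canon
  )
}

#' Build a virtual tag reference from a transcriptome
#'
#' Creates the preprocessed database of all possible CATG+17 nt tag
#' sequences for a transcript set, together with an inverted index
#' mapping each distinct tag sequence to the set of genes carrying it.
#' Tags present in more than one gene are ambiguous and never used for
#' quantification; the census reports how many distinct tag sequences
#' are unambiguous. With `bothStrands = TRUE` tags are additionally
#' extracted from the reverse complement of each transcript (for de novo
#' contigs of unknown orientation); the default indexes the sense strand
#' only.
#'
#' @param transcripts a named `DNAStringSet` or named character vector of
#'   uppercase transcript sequences; names are unique gene identifiers.
#' @param bothStrands also index reverse-complement tags (default `FALSE`).
#' @return a [TagReference-class] object.
#' @examples
#' tx <- c(g1 = paste0("AAACATG", strrep("G", 17)),
#'         g2 = paste0("CATG", strrep("T", 17), "CC"))
#' buildTagReference(tx)
#' @export
buildTagReference <- function(transcripts, bothStrands = FALSE) {
  if (is.character(transcripts)) {
    if (is.null(names(transcripts)))
      stop("transcripts must be named by gene_id")
    transcripts <- Biostrings::DNAStringSet(transcripts)
  }
  ids <- names(transcripts)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    stop("transcripts must be named by non-empty gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in transcriptome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- setNames(as.character(transcripts), ids)
  tab <- .virtualTagTable(seqs)
  tab$strand <- rep("+", nrow(tab))
  if (bothStrands) {
    rc <- setNames(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs))), ids)
    rtab <- .virtualTagTable(rc)
    if (nrow(rtab)) {
      rtab$strand <- rep("-", nrow(rtab))
      rtab$is_canonical <- rep(FALSE, nrow(rtab))  # canonical is a sense-strand notion
      tab <- rbind(tab, rtab)
    }
  }
  # deterministic order regardless of input order at the index level:
  # index keyed by tag_seq, per-tag gene sets sorted
  tab <- tab[order(tab$gene_id, tab$strand, tab$site_pos), , drop = FALSE]
  index <- .buildIndex(tab)
  census <- list(
    n_transcripts = length(seqs),
    n_virtual_tags = nrow(tab),
    n_distinct_tags = nrow(index),
    n_unambiguous_ref_tags = sum(index$n_genes == 1L),
    n_genes_with_tag = length(unique(tab$gene_id)),
    n_untaggable = length(seqs) - length(unique(tab$gene_id))
  )
  new("TagReference",
      transcripts = Biostrings::DNAStringSet(seqs),
      tags = tab, index = index, census = census)
}

# Collapse the per-site tag table to one row per distinct tag sequence.
# For tags confined to one gene, record the 3'-most sense-strand site
# carrying the sequence and whether that site is canonical (a tag hitting
# two sites of the same gene is still unambiguous at gene level; its
# 3'-most site is the one used for the canonical-fraction statistic).
.buildIndex <- function(tab) {
  if (!nrow(tab)) {
    return(S4Vectors::DataFrame(
      tag_seq = character(), n_genes = integer(),
      gene_id = character(), site_pos = integer(),
      is_canonical = logical()))
  }
  key <- factor(tab$tag_seq, levels = sort(unique(tab$tag_seq)))
  ng <- vapply(split(tab$gene_id, key), function(g) length(unique(g)),
               integer(1))
  # 3'-most sense-strand row per tag (fall back to any row for "-" only tags)
  ord <- order(key, tab$strand == "+", tab$site_pos)
  lastof <- ord[cumsum(tabulate(key))]   # last row (max site_pos) per level
  uniq <- ng == 1L
  S4Vectors::DataFrame(
    tag_seq = levels(key),
    n_genes = as.integer(ng),
    gene_id = ifelse(uniq, tab$gene_id[lastof], NA_character_),
    site_pos = ifelse(uniq, tab$site_pos[lastof], NA_integer_),
    is_canonical = ifelse(uniq, tab$is_canonical[lastof], NA)
  )
}

#' Read a transcriptome reference from FASTA
#'
#' Standard multi-FASTA (wrapped or single-line); the first
#' whitespace-delimited token of each header is the gene identifier.
#' Sequences are uppercased.
#'
#' @param path FASTA file path.
#' @return a named `DNAStringSet`.
#' @export
readTranscriptome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  dna <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(dna) <- names(x)
  dna
}

#' Export a tag reference to TSV and JSON
#'
#' Writes the per-site virtual tag table (with the number of genes
#' sharing each tag sequence) as TSV and the reference census as JSON.
#'
#' @param ref a [TagReference-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeTagReference <- function(ref, dir) {
  stopifnot(is(ref, "TagReference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(ref@tags)
  idx <- ref@index
  tab$n_genes_sharing <- idx$n_genes[match(tab$tag_seq, idx$tag_seq)]
  tsv <- file.path(dir, "virtual_tags.tsv")
  json <- file.path(dir, "reference_census.json")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ref@census, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tags = tsv, census = json))
}
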