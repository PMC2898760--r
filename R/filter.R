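#' Construct a raw tag library
#'
#' @param sampleId sample identifier.
#' @param reads either a character vector of read sequences (a multiset;
#'   duplicates allowed) or a named integer vector of counts over
#'   distinct read sequences.
#' @return a [RawTagLibrary-class].
#' @export
rawTagLibrary <- function(sampleId, reads) {
  if (is.numeric(reads)) {
    if (is.null(names(reads))) stop("count vector must be named by sequence")
    counts <- as.integer(reads)
    names(counts) <- names(reads)
    if (anyDuplicated(names(counts))) {
      counts <- vapply(split(counts, names(counts)), sum, integer(1))
    }
  } else {
    reads <- as.character(reads)
    r <- rle(sort(reads))
    counts <- setNames(r$lengths, r$values)
  }
  new("RawTagLibrary", sampleId = as.character(sampleId), counts = counts)
}

#' Read a tag library from a two-column TSV or a FASTQ file
#'
#' TSV input has columns tag sequence and count (header optional,
#' detected by a non-numeric second field in row 1). FASTQ input is
#' parsed as 4-line records; sequences are taken verbatim and counted.
#'
#' @param path input file.
#' @param sampleId sample identifier; defaults to the file base name.
#' @param format `"auto"` (by extension), `"tsv"` or `"fastq"`.
#' @return a [RawTagLibrary-class].
#' @export
readTagLibrary <- function(path, sampleId = NULL,
                           format = c("auto", "tsv", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE))
      "fastq" else "tsv"
  }
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "fastq") {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    return(rawTagLibrary(sampleId, as.character(x)))
  }
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  skip <- if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L])))) 1L else 0L
  df <- utils::read.table(path, sep = "\t", skip = skip,
                          colClasses = c("character", "integer"),
                          col.names = c("tag_seq", "count"))
  rawTagLibrary(sampleId, setNames(df$count, df$tag_seq))
}

#' Write a tag count table as TSV
#'
#' @param lib a `TagLibrary` or `RawTagLibrary`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeTagCounts <- function(lib, path) {
  cnt <- tagCounts(lib)
  utils::write.table(
    data.frame(tag_seq = names(cnt), count = unname(cnt)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Low-complexity rule on the 17 nt variable region: a single nucleotide
# occupying >= maxMono of the 17 positions, or a pure period-2 repeat
# (which subsumes homopolymers). Catches primer/homopolymer artifacts
# without touching genuine tags.
.isLowComplexity <- function(var17, maxMono = 15L) {
  stopifnot(all(nchar(var17) == VAR_WIDTH))
  mono <- rep(FALSE, length(var17))
  for (b in DNA_BASES) {
    nb <- VAR_WIDTH - nchar(gsub(b, "", var17, fixed = TRUE))
    mono <- mono | nb >= maxMono
  }
  dinuc <- substr(var17, 3L, VAR_WIDTH) == substr(var17, 1L, VAR_WIDTH - 2L)
  mono | dinuc
}

#' Filter a raw tag library
#'
#' Applies the fixed cleaning cascade, in this order (the order is part
#' of the contract so audit numbers are reproducible):
#' \enumerate{
#'   \item adaptor/structure: strip a leading adaptor if present; reject
#'     reads that are adaptor-only/empty or do not then start with CATG
#'     with at least 17 nt following (reads longer than 21 nt are
#'     truncated to CATG+17);
#'   \item reject tags containing `N` (low-quality base calls);
#'   \item reject low-complexity tags (see `maxMono`);
#'   \item after aggregation over the whole library, delete distinct tags
#'     with total copy number 1 (probable sequencing errors).
#' }
#'
#' @param raw a [RawTagLibrary-class].
#' @param adaptor adaptor sequence to strip from the read 5' end
#'   (uppercase ACGT; `""` for none).
#' @param maxMono low-complexity threshold: maximum tolerated count of
#'   any single base within the 17 variable positions is `maxMono - 1`.
#' @param dropSingletons apply the copy-number-1 rule (default `TRUE`).
#' @return a [TagLibrary-class] with a per-rule `filterLog` audit; the
#'   occurrences kept plus the occurrences removed by the four rules
#'   equal the raw total exactly.
#' @examples
#' raw <- rawTagLibrary("s1", c(rep(paste0("CATG", strrep("A", 8), strrep("C", 9)), 5),
#'                              paste0("CATG", strrep("ACGTA", 4), "C")))
#' filterTags(raw)
#' @export
filterTags <- function(raw, adaptor = "", maxMono = 15L,
                       dropSingletons = TRUE) {
  stopifnot(is(raw, "RawTagLibrary"))
  if (length(raw@counts) == 0L) stop("raw library is empty")
  if (nchar(adaptor) > 0L && grepl("[^ACGT]", adaptor))
    stop("adaptor sequence must contain only A, C, G, T")
  s <- names(raw@counts)
  m <- raw@counts
  n_raw_total <- sum(m)
  n_raw_distinct <- length(m)

  # rule 1: adaptor stripping + structural validity
  if (nchar(adaptor) > 0L) {
    has_ad <- startsWith(s, adaptor)
    s <- ifelse(has_ad, substring(s, nchar(adaptor) + 1L), s)
  }
  ok1 <- nchar(s) >= TAG_WIDTH & startsWith(s, ANCHOR)
  rm1 <- c(occurrences = sum(m[!ok1]), distinct = sum(!ok1))
  s <- substr(s[ok1], 1L, TAG_WIDTH)
  m <- m[ok1]

  # rule 2: unknown bases
  hasN <- grepl("N", s, fixed = TRUE)
  rm2 <- c(occurrences = sum(m[hasN]), distinct = sum(hasN))
  s <- s[!hasN]; m <- m[!hasN]

  # rule 3: low complexity
  lc <- if (length(s)) .isLowComplexity(substr(s, ANCHOR_WIDTH + 1L, TAG_WIDTH),
                                        maxMono = maxMono) else logical()
  rm3 <- c(occurrences = sum(m[lc]), distinct = sum(lc))
  s <- s[!lc]; m <- m[!lc]

  # aggregate (different raw reads may trim to the same tag)
  if (length(s)) {
    agg <- rowsum(as.numeric(m), s)
    counts <- setNames(as.integer(agg[, 1L]), rownames(agg))
  } else counts <- setNames(integer(), character())

  # rule 4: copy-number-1 tags, judged on whole-library aggregated counts
  if (dropSingletons) {
    single <- counts == 1L
    rm4 <- c(occurrences = sum(counts[single]), distinct = sum(single))
    counts <- counts[!single]
  } else rm4 <- c(occurrences = 0, distinct = 0L)

  counts <- counts[order(names(counts))]
  new("TagLibrary",
      sampleId = raw@sampleId,
      counts = counts,
      nRawTotal = as.integer(n_raw_total),
      nRawDistinct = as.integer(n_raw_distinct),
      filterLog = list(
        adaptor_or_empty = rm1,
        contains_N = rm2,
        low_complexity = rm3,
        copy_number_1 = rm4
      ))
}

#' Coerce a clean count table to a TagLibrary without filtering
#'
#' For inputs that are already clean distinct-tag count tables. Validity
#' checks (21 nt, CATG anchor, no N) still apply.
#'
#' @param sampleId sample identifier.
#' @param counts named integer vector over distinct tag sequences.
#' @return a [TagLibrary-class] with an empty filter log.
#' @export
tagLibrary <- function(sampleId, counts) {
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  new("TagLibrary", sampleId = as.character(sampleId), counts = counts,
      nRawTotal = sum(counts), nRawDistinct = length(counts),
      filterLog = list())
}
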