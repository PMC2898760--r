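# Independent oracles and small fixture builders used across the suite.

# Naive virtual-tag scan: test every length-4 window for CATG, slice 21 nt.
naiveExtractTags <- function(seq, geneId = "g") {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- list()
  if (L >= 4) {
    for (i in 1:(L - 3)) {
      if (paste(chars[i:(i + 3)], collapse = "") == "CATG" && i + 20 <= L) {
        tag <- paste(chars[i:(i + 20)], collapse = "")
        if (!grepl("N", tag, fixed = TRUE))
          out[[length(out) + 1]] <- data.frame(
            tag_seq = tag, gene_id = geneId, site_pos = i - 1L,
            is_canonical = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(tag_seq = character(), gene_id = character(),
                      site_pos = integer(), is_canonical = logical()))
  df <- do.call(rbind, out)
  df$is_canonical[which.max(df$site_pos)] <- TRUE
  df
}

# Brute-force Hamming mapper over every reference tag row.
naiveMapTag <- function(tag, ref, anchorExact = TRUE) {
  tab <- as.data.frame(virtualTags(ref))
  qa <- strsplit(tag, "")[[1]]
  d <- vapply(tab$tag_seq, function(r) {
    rb <- strsplit(r, "")[[1]]
    mism <- which(qa != rb)
    if (anchorExact && any(mism <= 4)) return(99L)
    length(mism)
  }, integer(1))
  if (any(d == 0)) hits <- which(d == 0)
  else if (any(d == 1)) hits <- which(d == 1)
  else return(list(status = "unmapped", gene_ids = character(),
                  n_mismatches = NA_integer_))
  genes <- sort(unique(tab$gene_id[hits]))
  list(status = if (length(genes) == 1) "unique" else "ambiguous",
       gene_ids = genes, n_mismatches = min(d))
}

# Audic-Claverie tail oracle via the negative-binomial identity
# sum_{y' <= y} P(y'|x) = pnbinom(y, size = x+1, prob = n1/(n1+n2)).
acOracle <- function(x, y, n1, n2) {
  p0 <- n1 / (n1 + n2)
  lo <- pnbinom(y, size = x + 1, prob = p0)
  hi <- pnbinom(y - 1, size = x + 1, prob = p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

# Literal term-by-term summation of the conditional pmf (small counts).
acOracleSum <- function(x, y, n1, n2, ymax = 5000) {
  r <- n2 / n1
  logp <- function(yy) yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) -
    lgamma(yy + 1) - (x + yy + 1) * log1p(r)
  lo <- sum(exp(logp(0:y)))
  hi <- sum(exp(logp(y:ymax)))
  min(1, 2 * min(lo, hi))
}

# Matrix-based brute-force Hamming mapper (same contract as naiveMapTag,
# precomputes the reference once for large query batches).
naiveMapperFor <- function(ref, anchorExact = TRUE) {
  tab <- as.data.frame(virtualTags(ref))
  refM <- do.call(rbind, strsplit(tab$tag_seq, ""))
  function(tag) {
    qa <- strsplit(tag, "")[[1]]
    neq <- refM != matrix(qa, nrow(refM), 21, byrow = TRUE)
    d <- rowSums(neq)
    if (anchorExact) d[rowSums(neq[, 1:4, drop = FALSE]) > 0] <- 99L
    dmin <- if (length(d)) min(d) else 99L
    if (dmin > 1) return(list(status = "unmapped", gene_ids = character(),
                              n_mismatches = NA_integer_))
    genes <- sort(unique(tab$gene_id[d == dmin]))
    list(status = if (length(genes) == 1) "unique" else "ambiguous",
         gene_ids = genes, n_mismatches = as.integer(dmin))
  }
}

randomDNA <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = ""),
    character(1))
}

randomCleanTag <- function(n) {
  paste0("CATG", vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = ""),
    character(1)))
}

# A tiny deterministic reference used by several files.
toyReference <- function() {
  tx <- c(
    gA = paste0("AAA", "CATG", strrep("A", 17)),
    gB = paste0("CATG", paste(rep(c("G", "T"), length.out = 17), collapse = ""),
                "CCCC", "CATG", strrep("C", 17)),
    gC = paste0("TTTT", "CATG", strrep("A", 17))  # shares its tag with gA
  )
  buildTagReference(tx)
}
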