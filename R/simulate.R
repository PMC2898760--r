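#' Simulation configuration for synthetic DGE experiments
#'
#' Bundles and validates every parameter of the generator: transcriptome
#' shape, expression state, planted differential expression, and the
#' tag-sampling model (incomplete NlaIII digestion, per-base sequencing
#' error, contamination). Defaults describe a desk-scale analogue of a
#' bulk insect DGE study: ~log-normal transcript lengths around 250 nt,
#' log-normal expression with sdlog 1.5, two-million-tag libraries,
#' digestion completeness 0.6 and 1% per-base error.
#'
#' @param nGenes number of transcripts (>= 1).
#' @param lengthMeanLog,lengthSdLog log-normal parameters of transcript
#'   length (nt).
#' @param minLength,maxLength clamp on transcript length; `minLength`
#'   must be >= 60 when `guaranteeCatg` so both a canonical and an
#'   upstream CATG site fit.
#' @param guaranteeCatg plant a usable CATG 21 nt from the 3' end of
#'   every transcript, plus one upstream usable site so the digestion
#'   model always has an alternative site to draw (default `TRUE`).
#' @param exprMeanLog,exprSdLog log-normal parameters of per-gene
#'   abundance.
#' @param deFraction fraction of genes with planted differential
#'   expression between conditions (in `[0, 1]`).
#' @param deLog2fc magnitude of the planted log2 fold change (sign
#'   random per gene).
#' @param librarySize number of raw tags per library (>= 1).
#' @param digestion probability `d` that a tag originates from the
#'   canonical (3'-most) site; otherwise a uniformly chosen upstream
#'   usable site (in `[0, 1]`).
#' @param errorRate per-base substitution error probability `e`
#'   (uniform over the 3 alternative bases).
#' @param fracNTags fraction of reads carrying an undetermined base `N`.
#' @param fracAdaptorOnly fraction of adaptor-only reads.
#' @param adaptor adaptor sequence used for adaptor-only reads.
#' @param seed integer seed recorded in the config (used by
#'   [simulateExperiment()]).
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             lengthMeanLog = 5.5, lengthSdLog = 0.7,
                             minLength = 60L, maxLength = 5000L,
                             guaranteeCatg = TRUE,
                             exprMeanLog = 0, exprSdLog = 1.5,
                             deFraction = 0.1, deLog2fc = 2,
                             librarySize = 2e6,
                             digestion = 0.6, errorRate = 0.01,
                             fracNTags = 0.05, fracAdaptorOnly = 0.02,
                             adaptor = "TCGTATGCCGTCTTCTGCTTG",
                             seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
              minLength = as.integer(minLength),
              maxLength = as.integer(maxLength),
              guaranteeCatg = isTRUE(guaranteeCatg),
              exprMeanLog = exprMeanLog, exprSdLog = exprSdLog,
              deFraction = deFraction, deLog2fc = deLog2fc,
              librarySize = as.numeric(librarySize),
              digestion = digestion, errorRate = errorRate,
              fracNTags = fracNTags, fracAdaptorOnly = fracAdaptorOnly,
              adaptor = adaptor, seed = as.integer(seed))
  probs <- c(deFraction = cfg$deFraction, digestion = cfg$digestion,
             errorRate = cfg$errorRate, fracNTags = cfg$fracNTags,
             fracAdaptorOnly = cfg$fracAdaptorOnly)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (cfg$nGenes < 1L) stop("nGenes must be >= 1")
  if (cfg$librarySize < 1) stop("librarySize must be >= 1")
  if (cfg$guaranteeCatg && cfg$minLength < 60L)
    stop("guaranteeCatg requires minLength >= 60 ",
         "(room for a canonical and an upstream CATG site)")
  if (cfg$minLength < TAG_WIDTH)
    stop("minLength must be >= 21")
  if (cfg$fracNTags + cfg$fracAdaptorOnly >= 1)
    stop("contaminant fractions must sum to < 1")
  if (grepl("[^ACGT]", cfg$adaptor)) stop("adaptor must be over ACGT")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a transcriptome
#'
#' Generates i.i.d. uniform-base DNA transcripts with log-normal
#' lengths. With `guaranteeCatg` every transcript gets a planted CATG
#' exactly 21 nt from its 3' end (the canonical site) and one uniformly
#' placed upstream usable CATG, so every gene is taggable and the
#' incomplete-digestion model always has an alternative site available.
#' Additional CATG sites arise by chance.
#'
#' @param cfg a [simulationConfig()].
#' @return a named `DNAStringSet` of `cfg$nGenes` transcripts with gene
#'   identifiers `g0001, g0002, ...`.
#' @export
simulateTranscriptome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  n <- cfg$nGenes
  len <- pmin(pmax(round(rlnorm(n, cfg$lengthMeanLog, cfg$lengthSdLog)),
                   cfg$minLength), cfg$maxLength)
  seqs <- vapply(len, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
  if (cfg$guaranteeCatg) {
    for (i in seq_len(n)) {
      L <- len[i]
      s <- seqs[i]
      substr(s, L - 20L, L - 17L) <- ANCHOR            # canonical site
      u <- sample.int(L - 24L, 1L)                     # upstream usable site
      substr(s, u, u + 3L) <- ANCHOR
      seqs[i] <- s
    }
  }
  names(seqs) <- sprintf("g%04d", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Simulate per-condition expression states with planted DE
#'
#' Draws a log-normal base abundance per gene; a random subset of
#' `round(deFraction * nGenes)` genes receives a log2 fold change of
#' magnitude `deLog2fc` (sign random) in condition 2.
#'
#' @param cfg a [simulationConfig()].
#' @param geneIds gene identifiers (names of the transcriptome).
#' @return a `data.frame` (the expression truth table) with columns
#'   `gene_id`, `abundance1`, `abundance2`, `is_de`, `log2fc`.
#' @export
simulateExpressionTruth <- function(cfg, geneIds) {
  n <- length(geneIds)
  base <- rlnorm(n, cfg$exprMeanLog, cfg$exprSdLog)
  n_de <- round(cfg$deFraction * n)
  de <- sample.int(n, n_de)
  lfc <- numeric(n)
  lfc[de] <- sample(c(-1, 1), n_de, replace = TRUE) * cfg$deLog2fc
  data.frame(gene_id = geneIds,
             abundance1 = base,
             abundance2 = base * 2^lfc,
             is_de = seq_len(n) %in% de,
             log2fc = lfc)
}

# Substitute the base at position p of each string s by a uniformly
# chosen alternative base. Vectorised over (s, p).
.substituteBase <- function(s, p) {
  orig <- substr(s, p, p)
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 3L,
                dimnames = list(NULL, DNA_BASES))
  pick <- alt[cbind(sample.int(3L, length(s), replace = TRUE),
                    match(orig, DNA_BASES))]
  substr(s, p, p) <- pick
  s
}

# Per-base substitution errors: each of the 21 bases flips independently
# with probability e to one of the 3 alternatives. Returns mutated reads
# plus per-read error count and whether the CATG anchor was hit.
.mutateReads <- function(reads, e) {
  n <- length(reads)
  k <- rbinom(n, TAG_WIDTH, e)
  anchor_hit <- logical(n)
  i1 <- which(k == 1L)
  if (length(i1)) {
    p <- sample.int(TAG_WIDTH, length(i1), replace = TRUE)
    reads[i1] <- .substituteBase(reads[i1], p)
    anchor_hit[i1] <- p <= ANCHOR_WIDTH
  }
  i2 <- which(k >= 2L)
  for (i in i2) {
    p <- sample.int(TAG_WIDTH, k[i])
    s <- reads[i]
    for (pp in p) s <- .substituteBase(s, pp)
    reads[i] <- s
    anchor_hit[i] <- any(p <= ANCHOR_WIDTH)
  }
  list(reads = reads, n_errors = k, anchor_hit = anchor_hit)
}

#' Simulate one raw tag library
#'
#' Draws `librarySize` reads. Signal reads pick a gene proportional to
#' its abundance, then a site: the canonical (3'-most) site with
#' probability `digestion`, otherwise a uniformly chosen upstream usable
#' site. Each of the 21 bases is then substituted independently with
#' probability `errorRate`. Contaminant reads are injected at the
#' configured fractions: reads with a planted `N`, and adaptor-only
#' reads. Per-read provenance (gene, site, canonical origin, error
#' count, anchor integrity, contaminant class) is recorded as ground
#' truth.
#'
#' @param transcriptome a named `DNAStringSet` (see
#'   [simulateTranscriptome()]).
#' @param abundance named non-negative abundance vector over the
#'   transcriptome's genes (relative scale).
#' @param cfg a [simulationConfig()].
#' @param sampleId sample identifier for the returned library.
#' @return a list with `raw` (a [RawTagLibrary-class]) and `truth`
#'   (per-read provenance `data.frame` with columns `gene_id`,
#'   `site_pos`, `canonical`, `n_errors`, `anchor_intact`, `class`).
#' @export
simulateTagLibrary <- function(transcriptome, abundance, cfg, sampleId) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  genes <- names(transcriptome)
  stopifnot(!is.null(names(abundance)), all(genes %in% names(abundance)))
  abundance <- abundance[genes]
  vt <- .virtualTagTable(setNames(as.character(transcriptome), genes))
  usable <- genes %in% vt$gene_id
  if (!any(usable & abundance > 0))
    stop("all expressed genes are invisible (no usable CATG site)")

  N <- cfg$librarySize
  nN <- round(cfg$fracNTags * N)
  nAd <- round(cfg$fracAdaptorOnly * N)
  nSig <- N - nN - nAd

  canon_tab <- vt[vt$is_canonical, , drop = FALSE]
  canon_tag <- setNames(canon_tab$tag_seq, canon_tab$gene_id)
  canon_pos <- setNames(canon_tab$site_pos, canon_tab$gene_id)
  up_tab <- vt[!vt$is_canonical, , drop = FALSE]
  up_tab <- up_tab[order(up_tab$gene_id, up_tab$site_pos), , drop = FALSE]
  up_n <- table(factor(up_tab$gene_id, levels = genes))
  up_off <- cumsum(c(0, as.numeric(up_n)))[seq_along(genes)]
  names(up_off) <- genes

  drawReads <- function(m) {
    prob <- ifelse(usable, abundance, 0)
    gi <- sample.int(length(genes), m, replace = TRUE, prob = prob)
    g <- genes[gi]
    want_canon <- runif(m) < cfg$digestion
    has_up <- as.numeric(up_n)[gi] > 0L
    use_canon <- want_canon | !has_up
    row <- integer(m)       # row in up_tab for non-canonical reads
    nc <- which(!use_canon)
    if (length(nc)) {
      kk <- as.numeric(up_n)[gi[nc]]
      row[nc] <- up_off[gi[nc]] + 1L + floor(runif(length(nc)) * kk)
    }
    tag <- character(m)
    pos <- integer(m)
    cc <- which(use_canon)
    tag[cc] <- canon_tag[g[cc]]
    pos[cc] <- canon_pos[g[cc]]
    if (length(nc)) {
      tag[nc] <- up_tab$tag_seq[row[nc]]
      pos[nc] <- up_tab$site_pos[row[nc]]
    }
    list(gene = g, tag = tag, pos = pos, canonical = use_canon)
  }

  sig <- drawReads(nSig)
  mut <- .mutateReads(sig$tag, cfg$errorRate)

  # N-contaminants: signal-like reads with one undetermined base
  if (nN > 0) {
    nn <- drawReads(nN)
    p <- sample.int(TAG_WIDTH, nN, replace = TRUE)
    r <- nn$tag
    substr(r, p, p) <- "N"
    n_reads <- r
  } else { nn <- NULL; n_reads <- character() }

  ad_reads <- rep(cfg$adaptor, nAd)

  reads <- c(mut$reads, n_reads, ad_reads)
  truth <- data.frame(
    gene_id = c(sig$gene, if (nN > 0) nn$gene else character(),
                rep(NA_character_, nAd)),
    site_pos = c(sig$pos, if (nN > 0) nn$pos else integer(),
                 rep(NA_integer_, nAd)),
    canonical = c(sig$canonical, if (nN > 0) nn$canonical else logical(),
                  rep(NA, nAd)),
    n_errors = c(mut$n_errors, rep(NA_integer_, nN + nAd)),
    anchor_intact = c(!mut$anchor_hit, rep(NA, nN + nAd)),
    class = c(rep("signal", nSig), rep("n_tag", nN),
              rep("adaptor_only", nAd)))
  list(raw = rawTagLibrary(sampleId, reads), truth = truth)
}

#' Simulate a complete two-condition experiment
#'
#' Convenience wrapper: seeds the generator from `cfg$seed`, simulates a
#' transcriptome, an expression truth table with planted DE, and one
#' independent raw library per condition.
#'
#' @param cfg a [simulationConfig()].
#' @param sampleIds identifiers of the two libraries.
#' @return a list with `transcriptome`, `truth` (expression truth),
#'   `libs` (list of [RawTagLibrary-class]) and `readTruth` (list of
#'   per-read provenance tables).
#' @export
simulateExperiment <- function(cfg, sampleIds = c("cond1", "cond2")) {
  stopifnot(inherits(cfg, "SimulationConfig"), length(sampleIds) == 2L)
  set.seed(cfg$seed)
  tx <- simulateTranscriptome(cfg)
  truth <- simulateExpressionTruth(cfg, names(tx))
  l1 <- simulateTagLibrary(tx, setNames(truth$abundance1, truth$gene_id),
                           cfg, sampleIds[1L])
  l2 <- simulateTagLibrary(tx, setNames(truth$abundance2, truth$gene_id),
                           cfg, sampleIds[2L])
  list(transcriptome = tx, truth = truth,
       libs = setNames(list(l1$raw, l2$raw), sampleIds),
       readTruth = setNames(list(l1$truth, l2$truth), sampleIds))
}
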