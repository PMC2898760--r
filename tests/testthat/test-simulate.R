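test_that("simulationConfig validates its parameters", {
  expect_s3_class(simulationConfig(), "SimulationConfig")
  expect_error(simulationConfig(digestion = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(nGenes = 0), "nGenes")
  expect_error(simulationConfig(minLength = 40, guaranteeCatg = TRUE), "minLength")
  expect_error(simulationConfig(fracNTags = 0.6, fracAdaptorOnly = 0.5), "sum")
  expect_error(simulationConfig(adaptor = "ACGU"), "ACGT")
})

test_that("simulated transcriptomes are reproducible and always taggable", {
  cfg <- simulationConfig(nGenes = 100, librarySize = 1000, seed = 2)
  set.seed(cfg$seed); tx1 <- simulateTranscriptome(cfg)
  set.seed(cfg$seed); tx2 <- simulateTranscriptome(cfg)
  expect_identical(as.character(tx1), as.character(tx2))
  expect_equal(length(tx1), 100L)
  vt <- virtualTags(buildTagReference(tx1))
  # guaranteed canonical site plus a planted upstream site per gene
  persite <- table(vt$gene_id)
  expect_equal(length(persite), 100L)
  expect_true(all(persite >= 2))
  # canonical site sits exactly 21 nt from the 3' end
  canon <- vt[vt$is_canonical, ]
  expect_equal(unname(canon$site_pos),
               unname(Biostrings::width(tx1)[match(canon$gene_id, names(tx1))] - 21L))
})

test_that("pooled base composition is uniform", {
  cfg <- simulationConfig(nGenes = 600, lengthMeanLog = 6.2, librarySize = 1000,
                          seed = 3, guaranteeCatg = FALSE)
  set.seed(cfg$seed)
  tx <- simulateTranscriptome(cfg)
  pooled <- paste(as.character(tx), collapse = "")
  n <- nchar(pooled)
  expect_gt(n, 2e5)
  gc <- (n - nchar(gsub("[GC]", "", pooled))) / n
  # binomial oracle: sd = sqrt(0.25/n) ~ tiny; allow 0.02 absolute
  expect_equal(gc, 0.5, tolerance = 0.04)
})

test_that("expression truth plants the configured DE fraction and fold change", {
  cfg <- simulationConfig(nGenes = 400, deFraction = 0.1, deLog2fc = 2,
                          librarySize = 1000, seed = 4)
  set.seed(cfg$seed)
  truth <- simulateExpressionTruth(cfg, sprintf("g%03d", 1:400))
  expect_equal(sum(truth$is_de), 40L)
  expect_true(all(abs(truth$log2fc[truth$is_de]) == 2))
  expect_true(all(truth$log2fc[!truth$is_de] == 0))
  expect_equal(truth$abundance2, truth$abundance1 * 2^truth$log2fc)
})

test_that("the no-error fully-digested limit emits perfect canonical tags", {
  cfg <- simulationConfig(nGenes = 60, librarySize = 20000, seed = 8,
                          digestion = 1, errorRate = 0,
                          fracNTags = 0, fracAdaptorOnly = 0)
  set.seed(cfg$seed)
  tx <- simulateTranscriptome(cfg)
  ab <- setNames(rlnorm(60, 0, 1), names(tx))
  sim <- simulateTagLibrary(tx, ab, cfg, "s")
  expect_true(all(sim$truth$canonical))
  expect_true(all(sim$truth$n_errors == 0))
  vt <- virtualTags(buildTagReference(tx))
  canon <- vt$tag_seq[vt$is_canonical]
  expect_true(all(names(tagCounts(sim$raw)) %in% canon))
  # and the mapped canonical fraction is exactly 1
  lib <- filterTags(sim$raw)
  cu <- countUnambiguous(lib, buildTagReference(tx))
  expect_equal(cu$summary$canonical_fraction, 1.0)
})

test_that("error and digestion rates are realized at their binomial expectations", {
  cfg <- simulationConfig(nGenes = 150, librarySize = 2e5, seed = 12,
                          digestion = 0.6, errorRate = 0.01,
                          fracNTags = 0, fracAdaptorOnly = 0)
  set.seed(cfg$seed)
  tx <- simulateTranscriptome(cfg)
  ab <- setNames(rlnorm(150, 0, 1.5), names(tx))
  sim <- simulateTagLibrary(tx, ab, cfg, "s")
  # fraction of error-free reads ~ (1-e)^21 within 4 binomial sd
  p0 <- (1 - cfg$errorRate)^21
  f0 <- mean(sim$truth$n_errors == 0)
  expect_lt(abs(f0 - p0), 4 * sqrt(p0 * (1 - p0) / nrow(sim$truth)))
  # canonical provenance fraction ~ d within 4 binomial sd
  fc <- mean(sim$truth$canonical)
  expect_lt(abs(fc - 0.6), 4 * sqrt(0.6 * 0.4 / nrow(sim$truth)))
})

test_that("contaminants are injected at the configured fractions with provenance", {
  cfg <- simulationConfig(nGenes = 80, librarySize = 50000, seed = 13,
                          fracNTags = 0.05, fracAdaptorOnly = 0.02)
  set.seed(cfg$seed)
  tx <- simulateTranscriptome(cfg)
  ab <- setNames(rlnorm(80, 0, 1), names(tx))
  sim <- simulateTagLibrary(tx, ab, cfg, "s")
  tab <- table(sim$truth$class)
  expect_equal(unname(tab["n_tag"]), round(0.05 * 50000))
  expect_equal(unname(tab["adaptor_only"]), round(0.02 * 50000))
  expect_equal(sum(tab), 50000)
  # every read is covered by provenance; all N-class reads carry an N
  nreads <- rep(names(tagCounts(sim$raw)), tagCounts(sim$raw))
  expect_equal(length(nreads), nrow(sim$truth))
})

test_that("identical seeds reproduce a full experiment byte for byte", {
  cfg <- simulationConfig(nGenes = 40, librarySize = 5000, seed = 14)
  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  expect_identical(as.character(s1$transcriptome), as.character(s2$transcriptome))
  expect_identical(tagCounts(s1$libs[[1]]), tagCounts(s2$libs[[1]]))
  expect_identical(s1$truth, s2$truth)
})

test_that("with no noise, pipeline TPM tracks true relative abundance", {
  cfg <- simulationConfig(nGenes = 100, librarySize = 2e5, seed = 15,
                          digestion = 1, errorRate = 0,
                          fracNTags = 0, fracAdaptorOnly = 0, deFraction = 0)
  sim <- simulateExperiment(cfg)
  ref <- buildTagReference(sim$transcriptome)
  lib <- filterTags(sim$libs[[1]])
  se <- expressionTable(list(s = lib), ref)
  tpm <- SummarizedExperiment::assay(se, "tpm")[, "s"]
  truth <- setNames(sim$truth$abundance1, sim$truth$gene_id)
  # restrict to genes with unambiguous tags and compare relative scales
  idx <- tagIndex(ref)
  unamb_genes <- idx$gene_id[idx$n_genes == 1 & idx$is_canonical %in% TRUE]
  keep <- names(tpm) %in% unamb_genes & tpm > 0
  expected <- truth[keep] / sum(truth) * 1e6
  # multinomial sampling error: compare on the log scale, generous bound
  expect_gt(cor(log(tpm[keep]), log(expected)), 0.98)
})
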