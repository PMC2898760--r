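test_that("acPvalue matches its closed forms and frozen values", {
  expect_equal(acPvalue(0, 0, 1e5, 1e5), 1.0)
  # x=20, y=0, equal totals: both-tail doubling gives 2 * 2^-21 = 2^-20
  expect_equal(acPvalue(20, 0, 1e5, 1e5), 9.5367431640625e-07, tolerance = 1e-12)
  # literal term-by-term summation oracle on a mixed small grid
  for (tt in list(c(3, 9, 1e4, 1e4), c(0, 7, 1e4, 2e4), c(25, 13, 5e4, 2.5e4),
                  c(100, 100, 1e5, 1e5), c(12, 0, 1e3, 1e3))) {
    expect_equal(acPvalue(tt[1], tt[2], tt[3], tt[4]),
                 acOracleSum(tt[1], tt[2], tt[3], tt[4]),
                 tolerance = 1e-10)
  }
})

test_that("acPvalue agrees with the negative-binomial tail oracle on a dense grid", {
  g <- expand.grid(x = 0:60, y = 0:60)
  for (ratio in c(0.5, 1, 2)) {
    p <- acPvalue(g$x, g$y, 1e5, ratio * 1e5)
    po <- acOracle(g$x, g$y, 1e5, ratio * 1e5)
    expect_lt(max(abs(p - po) / po), 1e-10)
  }
})

test_that("one-sided tails are coherent with the two-sided statistic", {
  x <- c(5, 50, 0); y <- c(25, 10, 4)
  lo <- acPvalue(x, y, 1e5, 1e5, alternative = "less")
  hi <- acPvalue(x, y, 1e5, 1e5, alternative = "greater")
  two <- acPvalue(x, y, 1e5, 1e5)
  expect_equal(two, pmin(1, 2 * pmin(lo, hi)))
  # the two one-sided tails overlap exactly in the observed point
  expect_equal(lo + hi - exp(dnbinom(y, size = x + 1, prob = 0.5, log = TRUE)),
               rep(1, 3), tolerance = 1e-12)
})

test_that("swapping libraries moves the p-value by at most the observed-point mass", {
  # with the observed point counted in both tails, the swapped statistic
  # differs by at most the larger of the two observed-point pmfs,
  # P(y|x; r) and P(x|y; 1/r) = r * P(y|x; r)
  set.seed(501)
  for (i in 1:200) {
    x <- rpois(1, 20); y <- rpois(1, 20)
    n1 <- sample(c(5e4, 1e5), 1); n2 <- sample(c(5e4, 1e5, 2e5), 1)
    r <- n2 / n1
    p1 <- acPvalue(x, y, n1, n2)
    p2 <- acPvalue(y, x, n2, n1)
    pmf <- dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
    expect_lte(abs(p1 - p2), 2 * max(1, r) * pmf + 1e-12)
  }
  # the underlying tail sums are exactly complementary under the swap:
  # sum_{x' <= x} P(x'|y; 1/r) = 1 - sum_{y' <= y} P(y'|x; r)
  x <- 13; y <- 40; n1 <- 1e5; n2 <- 2e5
  expect_equal(pnbinom(x, size = y + 1, prob = n2 / (n1 + n2)),
               pnbinom(y, size = x + 1, prob = n1 / (n1 + n2),
                       lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("acPvalue validates its inputs", {
  expect_error(acPvalue(-1, 0, 10, 10), "non-negative")
  expect_error(acPvalue(0, 0, 0, 10), ">= 1")
  expect_error(acPvalue(20, 0, 10, 10), "exceeds")
})

test_that("bhFdr reproduces the hand-computed step-up and stays monotone", {
  expect_equal(bhFdr(0.2), 0.2)
  # 3*0.01/1 = 0.03, 3*0.02/2 = 0.03, 3*0.03/3 = 0.03
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(502)
  p <- runif(500)
  q <- bhFdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_equal(q, bhFdr(p))  # order preserved on return
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("callDE computes ratios, flags one-sample genes and tallies calls", {
  ref <- buildTagReference(c(
    a = paste0("CATG", strrep("A", 8), strrep("C", 9)),
    b = paste0("CATG", strrep("G", 8), strrep("T", 9)),
    c = paste0("CATG", strrep("T", 8), strrep("A", 9)),
    d = paste0("CATG", strrep("C", 8), strrep("G", 9))))
  tgs <- setNames(tagIndex(ref)$tag_seq, tagIndex(ref)$gene_id)
  lib1 <- tagLibrary("L1", setNames(c(10L, 40L, 50L), tgs[c("a", "b", "c")]))
  lib2 <- tagLibrary("L2", setNames(c(40L, 10L, 50L), tgs[c("a", "b", "c")]))
  se <- expressionTable(list(L1 = lib1, L2 = lib2), ref)
  de <- callDE(se, "L1", "L2", alpha = 0.05)
  expect_equal(de$gene_id, c("a", "b", "c"))  # gene d (0,0) excluded
  # both totals are 100: tpm1(a)=1e5, tpm2(a)=4e5 -> log2 ratio = 2
  expect_equal(de$log2_ratio[de$gene_id == "a"], 2)
  expect_equal(de$log2_ratio[de$gene_id == "c"], 0)
  expect_false(any(de$one_sample_only))
  sm <- S4Vectors::metadata(de)$summary
  expect_equal(sm$n_up, sum(de$call == "up"))
  expect_equal(sm$n_down, sum(de$call == "down"))

  # a gene absent from one library gets the 0.001 TPM pseudo-value
  lib3 <- tagLibrary("L3", setNames(c(10L, 90L), tgs[c("a", "b")]))
  lib4 <- tagLibrary("L4", setNames(c(10L, 89L, 1e6 - 99L),
                                    tgs[c("a", "b", "c")]))
  se2 <- expressionTable(list(L3 = lib3, L4 = lib4), ref)
  de2 <- callDE(se2, "L3", "L4")
  g <- de2[de2$gene_id == "c", ]
  expect_true(g$one_sample_only)
  expect_equal(g$log2_ratio, log2(g$tpm2 / 0.001))
})

test_that("callDE results are invariant to gene order and sample direction flips sign", {
  set.seed(503)
  cfg <- simulationConfig(nGenes = 120, librarySize = 5e4, seed = 19)
  sim <- simulateExperiment(cfg)
  ref <- buildTagReference(sim$transcriptome)
  libs <- lapply(sim$libs, filterTags, adaptor = cfg$adaptor)
  se <- expressionTable(libs, ref)
  de_ab <- callDE(se, "cond1", "cond2")
  se_rev <- se[rev(seq_len(nrow(se))), ]
  de_rev <- callDE(se_rev, "cond1", "cond2")
  m <- match(de_ab$gene_id, de_rev$gene_id)
  expect_equal(de_ab$p_value, de_rev$p_value[m])
  expect_equal(de_ab$fdr, de_rev$fdr[m])
  de_ba <- callDE(se, "cond2", "cond1")
  expect_equal(de_ab$log2_ratio, -de_ba$log2_ratio)
})

test_that("tag-level testing collapses to genes with direction consistency", {
  cfg <- simulationConfig(nGenes = 100, librarySize = 1e5, seed = 37,
                          deFraction = 0.2, deLog2fc = 3)
  sim <- simulateExperiment(cfg)
  ref <- buildTagReference(sim$transcriptome)
  libs <- lapply(sim$libs, filterTags, adaptor = cfg$adaptor)
  res <- callDETags(libs[[1]], libs[[2]], ref, alpha = 0.01)
  expect_true(all(res$genes$call %in% c("up", "down", "ns", "conflict")))
  expect_equal(res$summary$n_sig_tag_entities, sum(res$tags$significant))
  # every DE-called gene carries at least one significant tag
  called <- res$genes[res$genes$call %in% c("up", "down"), ]
  expect_true(all(called$n_sig_tags >= 1))
  # planted strong DE is visible at tag level
  deg <- sim$truth$gene_id[sim$truth$is_de]
  expect_gt(mean(deg %in% called$gene_id), 0.5)
})
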