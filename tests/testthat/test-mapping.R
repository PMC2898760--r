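test_that("mapTag prefers exact hits, tolerates one substitution, rejects two", {
  ref <- buildTagReference(c(geneX = paste0("CATG", strrep("A", 17))))
  exact <- mapTag(paste0("CATG", strrep("A", 17)), ref)
  expect_equal(exact$status, "unique")
  expect_equal(exact$gene_ids, "geneX")
  expect_equal(exact$n_mismatches, 0L)

  onemm <- mapTag(paste0("CATG", strrep("A", 16), "C"), ref)
  expect_equal(onemm$status, "unique")
  expect_equal(onemm$gene_ids, "geneX")
  expect_equal(onemm$n_mismatches, 1L)

  twomm <- mapTag(paste0("CATG", "CC", strrep("A", 15)), ref)
  expect_equal(twomm$status, "unmapped")
  expect_equal(twomm$gene_ids, character())
})

test_that("a tag shared by two genes maps ambiguous and is excluded from counts", {
  ref <- toyReference()
  shared <- paste0("CATG", strrep("A", 17))
  hit <- mapTag(shared, ref)
  expect_equal(hit$status, "ambiguous")
  expect_equal(hit$gene_ids, c("gA", "gC"))

  lib <- tagLibrary("s", setNames(c(10L, 5L),
    c(paste0("CATG", strrep("C", 17)), shared)))
  res <- countUnambiguous(lib, ref)
  expect_equal(unname(res$counts["gB"]), 10L)
  expect_equal(unname(res$counts["gA"]), 0L)
  expect_equal(res$summary$n_unambiguous_total, 10)
  expect_equal(res$summary$n_ambiguous_total, 5)
  expect_equal(res$summary$n_total_tags_mapped, 15)
})

test_that("the anchor-exact policy controls where the mismatch budget applies", {
  # a reference tag whose anchor region degenerated in a second gene: with
  # anchorExact the query can only reach it through variable positions
  tx <- c(gX = paste0("CATG", strrep("A", 17)))
  ref <- buildTagReference(tx)
  qv <- paste0("CATG", "C", strrep("A", 16))
  expect_equal(mapTag(qv, ref)$status, "unique")
  expect_equal(mapTag(qv, ref, anchorExact = FALSE)$status, "unique")
  # with anchorExact=FALSE the neighborhood is 63 variants instead of 51;
  # both policies agree on CATG-anchored references because reference tags
  # always start with CATG and a query anchor substitution cannot restore it
  q2 <- paste0("CATG", "CC", strrep("A", 15))
  expect_equal(mapTag(q2, ref)$status, "unmapped")
  expect_equal(mapTag(q2, ref, anchorExact = FALSE)$status, "unmapped")
})

test_that("malformed tags are rejected with a named error", {
  ref <- toyReference()
  expect_error(mapTag("CATGAA", ref), "malformed")
  expect_error(mapTag(paste0("AAAA", strrep("A", 17)), ref), "malformed")
  expect_error(mapTag(paste0("CATG", strrep("N", 17)), ref), "malformed")
})

test_that("mapTag agrees with the brute-force Hamming oracle on random queries", {
  set.seed(301)
  seqs <- setNames(randomDNA(40, sample(40:200, 40, replace = TRUE)),
                   sprintf("t%02d", 1:40))
  ref <- buildTagReference(seqs)
  reftags <- tagIndex(ref)$tag_seq
  # queries: half random, half perturbed reference tags (0-2 substitutions)
  qs <- c(randomCleanTag(150),
          vapply(sample(reftags, 150, replace = TRUE), function(t) {
            k <- sample(0:2, 1)
            for (i in seq_len(k)) {
              p <- sample(5:21, 1)
              substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(t, p, p)), 1)
            }
            t
          }, character(1), USE.NAMES = FALSE))
  for (q in qs) {
    got <- mapTag(q, ref)
    want <- naiveMapTag(q, ref)
    expect_equal(got$status, want$status, info = q)
    expect_equal(got$gene_ids, want$gene_ids, info = q)
    if (got$status != "unmapped")
      expect_equal(got$n_mismatches, want$n_mismatches, info = q)
  }
})

test_that("a tag hitting two sites of the same gene is unambiguous, 3'-most site used", {
  tx <- c(gD = paste0("CATG", strrep("A", 17), "GG", "CATG", strrep("A", 17)))
  ref <- buildTagReference(tx)
  hit <- mapTag(paste0("CATG", strrep("A", 17)), ref)
  expect_equal(hit$status, "unique")
  expect_equal(hit$gene_ids, "gD")
  expect_true(hit$site_is_canonical)  # the 3'-most of the two identical sites
})

test_that("adding a gene to the reference never increases an existing gene's count", {
  set.seed(302)
  seqs <- setNames(randomDNA(30, sample(60:200, 30, replace = TRUE)),
                   sprintf("t%02d", 1:30))
  ref1 <- buildTagReference(seqs)
  lib <- tagLibrary("s", setNames(sample(2:20, 40, replace = TRUE),
                                  randomCleanTag(40)))
  # also include some real reference tags so counts are non-trivial
  real <- tagIndex(ref1)$tag_seq[tagIndex(ref1)$n_genes == 1]
  k <- min(20, length(real))
  lib <- tagLibrary("s", c(tagCounts(lib),
                           setNames(sample(2:20, k, replace = TRUE),
                                    sample(real, k))))
  c1 <- countUnambiguous(lib, ref1)$counts
  for (k in 1:5) {
    extra <- setNames(randomDNA(1, 150), sprintf("new%d", k))
    ref2 <- buildTagReference(c(seqs, extra))
    c2 <- countUnambiguous(lib, ref2)$counts
    expect_true(all(c2[names(c1)] <= c1))
  }
})

test_that("mapping occurrence totals are conserved", {
  set.seed(303)
  seqs <- setNames(randomDNA(25, sample(60:200, 25, replace = TRUE)),
                   sprintf("t%02d", 1:25))
  ref <- buildTagReference(seqs)
  real <- tagIndex(ref)$tag_seq
  lib <- tagLibrary("s", c(
    setNames(sample(2:30, 30, replace = TRUE), randomCleanTag(30)),
    setNames(sample(2:30, min(15, length(real)), replace = TRUE),
             sample(real, min(15, length(real))))))
  s <- countUnambiguous(lib, ref)$summary
  expect_equal(s$n_unambiguous_total + s$n_ambiguous_total + s$n_unmapped_total,
               cleanTotal(lib))
})

test_that("an empty library yields zero counts and zero summaries", {
  ref <- toyReference()
  lib <- tagLibrary("s", setNames(integer(), character()))
  res <- countUnambiguous(lib, ref)
  expect_true(all(res$counts == 0L))
  expect_equal(res$summary$n_total_tags_mapped, 0)
  expect_equal(res$summary$n_tag_mapped_genes, 0L)
})
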