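test_that("entropy track has undefined flanks and closed-form values", {
  tr <- entropy_track(seq_record("a", strrep("A", 20)), 7)
  expect_equal(length(tr$values), 20)
  expect_true(all(is.na(tr$values[1:3])))
  expect_true(all(is.na(tr$values[18:20])))
  expect_equal(tr$values[4:17], rep(0, 14))

  # alternating A/S: every full 7-window has counts {4, 3}
  alt <- seq_record("as", strrep("AS", 10))
  tra <- entropy_track(alt, 7)
  expected <- -(4 / 7) * log2(4 / 7) - (3 / 7) * log2(3 / 7)
  expect_equal(unique(round(tra$values[4:17], 10)), round(expected, 10))

  # record shorter than the window: all undefined
  short <- entropy_track(seq_record("s", "ACDEFG"), 7)
  expect_true(all(is.na(short$values)))

  # bounded and invariant under alphabet permutation
  set.seed(3)
  s <- random_protein(60)
  perm <- setNames(sample(AA), AA)
  s2 <- paste(perm[strsplit(s, "")[[1]]], collapse = "")
  t1 <- entropy_track(seq_record("p", s), 7)$values
  t2 <- entropy_track(seq_record("p", s2), 7)$values
  expect_equal(t1, t2)
  expect_true(all(t1[!is.na(t1)] >= 0 & t1[!is.na(t1)] <= log2(20)))
})

test_that("composition, comparison and enrichment behave as specified", {
  u <- aa_frequencies(seq_record("u", "ACDEFGHIKLMNPQRSTVWY"))
  expect_equal(unname(unclass(u)), rep(0.05, 20))
  a <- aa_frequencies(seq_record("a", "AAAA"))
  expect_equal(unname(a["A"]), 1)
  expect_equal(sum(a), 1)
  expect_error(aa_frequencies(seq_record("x", "XXXX")), "all 'X'")

  cmp <- compare_frequencies(u, u)
  expect_equal(cmp$difference, rep(0, 20))
  expect_equal(cmp$ratio, rep(1, 20))

  cmp2 <- compare_frequencies(a, uniform_profile())
  expect_equal(cmp2$difference[cmp2$residue == "A"], 0.95)
  expect_equal(cmp2$ratio[cmp2$residue == "A"], 20)

  zero_ref <- frequency_profile(c(A = 0.5, C = 0.5))
  cmp3 <- compare_frequencies(u, zero_ref)
  expect_true(is.na(cmp3$ratio[cmp3$residue == "D"]))

  # polyQ region against a uniform background is Q-enriched
  rec <- seq_record("q", paste0("ACDEF", strrep("Q", 10), "GHIKL"))
  reg <- lcr_regions("q", 6, 15, "SEG", -9)
  expect_equal(region_enrichment(reg, rec), "Q")
  # a region matching the background exactly is not enriched
  expect_equal(region_enrichment(lcr_regions("u", 1, 20, "SEG", 0),
                                 seq_record("u", "ACDEFGHIKLMNPQRSTVWY")),
               character())
  # the count gate blocks single occurrences
  expect_equal(region_enrichment(lcr_regions("q", 6, 6, "SEG", 0), rec),
               character())
})

test_that("consensus interval algebra matches the stated examples", {
  bym <- list(A = lcr_regions("s", 1, 10, "SEG", 0),
              B = lcr_regions("s", 5, 15, "CAST", 50, residues = "Q"))
  inter <- consensus_regions(bym, c("A", "B"), "intersection")
  expect_equal(c(inter$start, inter$end), c(5L, 10L))
  expect_equal(inter$method, "CONSENSUS")
  expect_equal(inter$score, 0)
  uni <- consensus_regions(bym, c("A", "B"), "union")
  expect_equal(c(uni$start, uni$end), c(1L, 15L))

  # consensus of a single method is that method's merged regions
  one <- consensus_regions(bym, "A", "intersection")
  expect_equal(c(one$start, one$end), c(1L, 10L))

  expect_error(consensus_regions(bym, c("A", "Z")), "not present")
  expect_error(consensus_regions(bym, character()), "no methods")
})

test_that("consensus matches a per-position membership oracle on random interval sets", {
  set.seed(101)
  for (rep in 1:60) {
    L <- sample(20:100, 1)
    n_methods <- sample(2:4, 1)
    sets <- lapply(seq_len(n_methods), function(m) {
      k <- sample(0:4, 1)
      if (k == 0) return(data.frame(start = integer(), end = integer()))
      st <- sample(seq_len(L), k, replace = TRUE)
      en <- pmin(L, st + sample(0:15, k, replace = TRUE))
      data.frame(start = st, end = en)
    })
    bym <- lapply(sets, function(iv) {
      if (nrow(iv) == 0) return(lcr_regions())
      lcr_regions(rep("s", nrow(iv)), iv$start, iv$end, "SEG", 0)
    })
    names(bym) <- paste0("M", seq_len(n_methods))
    for (mode in c("intersection", "union")) {
      got <- consensus_regions(bym, names(bym), mode)
      want <- oracle_consensus(sets, L, mode)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("coverage proportions follow union length and consensus ordering", {
  regs <- bind_regions(lcr_regions("s", 1, 10, "SEG", 0),
                       lcr_regions("s", 5, 15, "CAST", 50, residues = "Q"))
  expect_equal(coverage_stats(regs, 20), 0.75)
  expect_equal(coverage_stats(lcr_regions("s", 1, 20, "SEG", 0), 20), 1)
  expect_equal(coverage_stats(lcr_regions(), 20), 0)
  expect_error(coverage_stats(lcr_regions("s", 1, 30, "SEG", 0), 20), "beyond")

  # intersection coverage <= each method's coverage <= union coverage
  set.seed(55)
  for (rep in 1:20) {
    L <- 80
    bym <- lapply(1:3, function(m) {
      st <- sample(1:60, 3)
      lcr_regions(rep("s", 3), st, pmin(L, st + sample(5:20, 3, TRUE)), "SEG", 0)
    })
    names(bym) <- c("A", "B", "C")
    ci <- coverage_stats(consensus_regions(bym, names(bym), "intersection"), L)
    cu <- coverage_stats(consensus_regions(bym, names(bym), "union"), L)
    for (m in names(bym)) {
      cm <- coverage_stats(bym[[m]], L)
      expect_lte(ci, cm + 1e-12)
      expect_lte(cm, cu + 1e-12)
    }
  }
})
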