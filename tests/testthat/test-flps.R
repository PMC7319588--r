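test_that("binomial tail matches closed forms and direct summation", {
  expect_equal(binomial_tail(0, 10, 0.3), 1)
  expect_equal(binomial_tail(10, 10, 0.05), 0.05^10)
  expect_equal(binomial_tail(5, 10, 0.5), 638 / 1024)

  set.seed(4)
  for (i in 1:30) {
    w <- sample(5:60, 1)
    k <- sample(0:w, 1)
    p <- runif(1, 0.01, 0.9)
    expect_equal(binomial_tail(k, w, p), oracle_binom_tail(k, w, p),
                 tolerance = 1e-12)
  }
  expect_error(binomial_tail(11, 10, 0.5), "k <= w")

  # monotone: non-increasing in k, non-decreasing in p
  expect_true(all(diff(binomial_tail(0:20, 20, 0.2)) <= 1e-15))
  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(ps, function(p) binomial_tail(7, 20, p),
                              numeric(1))) >= -1e-15))
})

test_that("single-residue scan finds a planted biased tract and respects the threshold", {
  fix <- generate_fixture(list(length = 120, features = list(
    list(kind = "homorepeat", unit = "N", start = 51, length = 30))), seed = 6)
  strict <- flps_params(5, 25, 1e-5)
  regs <- single_residue_lps(fix, "N", strict)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$residues, "N")
  expect_gte(overlap_fraction(regs, 51, 80), 0.5)
  expect_lte(10^regs$score, 1e-5)

  # diverse sequence: nothing reaches the threshold for any residue
  rec <- seq_record("d", strrep("ACDEFGHIKLMNPQRSTVWY", 2))
  for (a in c("A", "Q", "S")) {
    expect_equal(nrow(single_residue_lps(rec, a, flps_params())), 0)
  }

  # record shorter than m
  expect_equal(nrow(single_residue_lps(seq_record("s", "QQQ"), "Q",
                                       flps_params(m = 5, M = 25))), 0)
})

test_that("minimization picks the window an exhaustive scan picks", {
  # exhaustive oracle over every (offset, width) pair on the whole sequence
  set.seed(12)
  params <- flps_params(5, 25, 1e-3)
  for (i in 1:10) {
    fix <- generate_fixture(list(length = 60, features = list(
      list(kind = "homorepeat", unit = "Q", start = 21, length = 15))),
      seed = 100 + i)
    regs <- single_residue_lps(fix, "Q", params)
    chars <- strsplit(fix$residues, "")[[1]]
    best <- Inf; bw <- NA; bo <- NA
    for (w in 25:5) for (o in 1:(60 - w + 1)) {
      k <- sum(chars[o:(o + w - 1)] == "Q")
      lp <- log(oracle_binom_tail(k, w, 0.05))
      if (lp < best - 1e-9) { best <- lp; bw <- w; bo <- o }
    }
    if (best <= log(1e-3)) {
      expect_equal(regs$start, bo)
      expect_equal(regs$end, bo + bw - 1)
      expect_equal(regs$score, best / log(10), tolerance = 1e-6)
    } else {
      expect_equal(nrow(regs), 0)
    }
  }
})

test_that("merging combines interleaved S/T biases when the union is less probable", {
  set.seed(40)
  fix <- generate_fixture(list(length = 90, features = list(
    list(kind = "biased", unit = "ST", start = 31, length = 30))), seed = 44)
  params <- flps_params(5, 25, 1e-4)
  s_regs <- single_residue_lps(fix, "S", params)
  t_regs <- single_residue_lps(fix, "T", params)
  merged <- merge_lps(bind_regions(s_regs, t_regs), fix, params)
  if (nrow(s_regs) == 1 && nrow(t_regs) == 1) {
    expect_equal(nrow(merged), 1)
    expect_setequal(strsplit(merged$residues, ",")[[1]], c("S", "T"))
    expect_lt(merged$score, min(s_regs$score, t_regs$score))
  }

  # distant regions stay apart
  far <- bind_regions(lcr_regions("f", 1, 10, "FLPS", -8, residues = "Q"),
                      lcr_regions("f", 60, 70, "FLPS", -8, residues = "N"))
  rec <- generate_fixture(list(length = 80, features = list(
    list(kind = "homorepeat", unit = "Q", start = 1, length = 10),
    list(kind = "homorepeat", unit = "N", start = 60, length = 11))), seed = 3)
  rec$id <- "f"
  out <- merge_lps(far, rec, flps_params(5, 25, 1e-4))
  expect_equal(nrow(out), 2)

  expect_error(merge_lps(bind_regions(
    lcr_regions("a", 1, 5, "FLPS", -3, residues = "Q"),
    lcr_regions("b", 1, 5, "FLPS", -3, residues = "N")), rec),
    "single sequence")
})

test_that("every emitted fLPS region is below threshold and locally optimal", {
  fix <- generate_fixture(list(length = 200, features = list(
    list(kind = "homorepeat", unit = "Q", start = 81, length = 25))), seed = 10)
  params <- flps_params()
  regs <- run_flps(fix, params)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$residues, "Q")
  expect_gte(overlap_fraction(regs, 81, 105), 0.8)
  chars <- strsplit(fix$residues, "")[[1]]
  for (i in seq_len(nrow(regs))) {
    rset <- strsplit(regs$residues[i], ",")[[1]]
    p <- 0.05 * length(rset)
    w <- regs$end[i] - regs$start[i] + 1
    k <- sum(chars[regs$start[i]:regs$end[i]] %in% rset)
    lp <- log(oracle_binom_tail(k, w, p))
    expect_lte(lp, log(params$t) + 1e-9)
    expect_equal(lp / log(10), regs$score[i], tolerance = 1e-6)
    # no single-residue trim or extension lowers P
    for (mv in list(c(-1, 0), c(1, 0), c(0, 1), c(0, -1))) {
      s2 <- regs$start[i] + mv[1]; e2 <- regs$end[i] + mv[2]
      if (s2 < 1 || e2 > length(chars) || s2 > e2) next
      k2 <- sum(chars[s2:e2] %in% rset)
      expect_gte(log(oracle_binom_tail(k2, e2 - s2 + 1, p)), lp - 1e-9)
    }
  }
})

test_that("fLPS presets and parameter validation are wired as published", {
  ps <- flps_preset("strict")
  expect_equal(c(ps$m, ps$M, ps$t), c(5, 25, 1e-5))
  pd <- flps_preset("default")
  expect_equal(c(pd$m, pd$M, pd$t), c(15, 500, 1e-3))
  expect_error(flps_params(10, 5), "m <= M")
  expect_error(flps_params(5, 25, 2), "0 < t < 1")
})

test_that("uniform-background results are invariant under alphabet permutation", {
  set.seed(77)
  perm <- setNames(sample(AA), AA)
  fix <- generate_fixture(list(length = 100, features = list(
    list(kind = "homorepeat", unit = "Q", start = 41, length = 20))), seed = 5)
  permuted <- seq_record(fix$id, paste(perm[strsplit(fix$residues, "")[[1]]],
                                       collapse = ""))
  p <- flps_params(5, 25, 1e-4)
  r1 <- run_flps(fix, p)
  r2 <- run_flps(permuted, p)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$end, r2$end)
  expect_equal(r1$score, r2$score, tolerance = 1e-9)
  expect_equal(vapply(strsplit(r2$residues, ","), function(x)
    paste(sort(names(perm)[match(x, perm)]), collapse = ","), character(1)) |>
      unname(),
    r1$residues)
})
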