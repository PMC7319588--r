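# Independent brute-force reference implementations used as oracles.
# These deliberately recompute everything from first principles (direct
# table counts, factorials, full dynamic programming, explicit position
# sets) and share no code with the package internals they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Direct Shannon entropy of a window, via table().
oracle_entropy <- function(window) {
  chars <- strsplit(window, "")[[1]]
  chars <- chars[chars != "X"]
  L <- nchar(window)
  if (length(chars) == 0) return(0)
  p <- as.numeric(table(chars)) / L
  -sum(p * log2(p))
}

# SEG first pass from the definition: a position belongs to a contig iff it
# is covered by a <=K2 window connected (through overlapping <=K2 windows)
# to a <=K1 window. Connected components by explicit flood fill.
oracle_seg_contigs <- function(seqstr, W, K1, K2) {
  L <- nchar(seqstr)
  if (L < W) return(data.frame(start = integer(), end = integer()))
  starts <- 1:(L - W + 1)
  H <- vapply(starts, function(s) oracle_entropy(substr(seqstr, s, s + W - 1)),
              numeric(1))
  low2 <- starts[H <= K2 + 1e-9]
  low1 <- starts[H <= K1 + 1e-9]
  if (length(low1) == 0) return(data.frame(start = integer(), end = integer()))
  comp <- rep(NA_integer_, length(low2))
  cid <- 0
  for (i in seq_along(low2)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- which(is.na(comp) & abs(low2 - low2[cur]) <= W - 1)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  covered <- rep(FALSE, L)
  for (c0 in unique(comp)) {
    ss <- low2[comp == c0]
    if (!any(ss %in% low1)) next
    for (s in ss) covered[s:(s + W - 1)] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  st <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = st[keep], end = ends[keep])
}

# Exhaustive minimum-P0 subsequence by direct factorial evaluation.
oracle_min_p0 <- function(seqstr, cs, ce) {
  best <- Inf; bi <- NA; bj <- NA
  for (i in cs:ce) for (j in i:ce) {
    chars <- strsplit(substr(seqstr, i, j), "")[[1]]
    chars <- chars[chars != "X"]
    L <- length(chars)
    counts <- as.numeric(table(factor(chars, levels = AA)))
    logF <- lgamma(L + 1) - sum(lgamma(counts + 1))
    rk <- as.numeric(table(factor(counts, levels = 0:max(c(counts, 0)))))
    logOmega <- lgamma(21) - sum(lgamma(rk + 1))
    logP0 <- logF + logOmega - L * log(20)
    len <- j - i + 1
    blen <- if (is.na(bi)) -1 else bj - bi + 1
    if (logP0 < best - 1e-12 ||
        (abs(logP0 - best) <= 1e-12 && (len > blen || (len == blen && i < bi)))) {
      best <- logP0; bi <- i; bj <- j
    }
  }
  list(start = bi, end = bj, log10P0 = best / log(10))
}

# Textbook Smith-Waterman local alignment score of seq against a
# homopolymer of `target` of the same length, with a prohibitive gap
# penalty. Full DP matrix, no shortcuts.
oracle_sw_homopolymer <- function(seqstr, target, matrix, gap = 1e6) {
  chars <- strsplit(seqstr, "")[[1]]
  n <- length(chars)
  H <- matrix(0, n + 1, n + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(n + 1)) {
    sc <- matrix[chars[i - 1], target]
    H[i, j] <- max(0, H[i - 1, j - 1] + sc, H[i - 1, j] - gap, H[i, j - 1] - gap)
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

# Positional membership consensus oracle over explicit logical vectors.
oracle_consensus <- function(interval_sets, L, mode) {
  masks <- lapply(interval_sets, function(iv) {
    m <- rep(FALSE, L)
    if (nrow(iv) > 0) for (k in seq_len(nrow(iv))) m[iv$start[k]:iv$end[k]] <- TRUE
    m
  })
  comb <- if (mode == "union") Reduce(`|`, masks) else Reduce(`&`, masks)
  r <- rle(comb)
  ends <- cumsum(r$lengths)
  st <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = st[keep], end = ends[keep])
}

# Direct nested-loop simplicity scoring: for every position and motif
# length, scan every other offset of the anchored window and compare
# substrings character by character.
oracle_simplicity <- function(chars, window, motif_lengths) {
  L <- length(chars)
  h <- (window - 1) %/% 2
  S <- numeric(L)
  for (i in seq_len(L)) {
    lo <- max(1, min(i - h, L - window + 1))
    hi <- lo + window - 1
    for (l in motif_lengths) {
      if (i + l - 1 > L) next
      motif <- chars[i:(i + l - 1)]
      if ("X" %in% motif) next
      for (j in lo:(hi - l + 1)) {
        if (j == i) next
        if (all(chars[j:(j + l - 1)] == motif)) S[i] <- S[i] + l
      }
    }
  }
  S
}

# Exact binomial upper tail by direct summation of choose() terms.
oracle_binom_tail <- function(k, w, p) {
  if (k <= 0) return(1)
  sum(choose(w, k:w) * p^(k:w) * (1 - p)^(w - (k:w)))
}

empty_regions_for_test <- function() {
  lcr_regions()
}

cli_params_for_test <- function(sub, flags) {
  lcrtools:::cli_params_for(sub, flags)
}

# A small synthetic "proteome": n fixtures with one planted homorepeat and
# one short tandem repeat each (~9% of residues), plus their composition-
# preserving shuffles. The background composition of every fixture is
# balanced against the planted residues (their background frequency is
# reduced so the expected overall composition stays near-uniform): the
# shuffle control then differs from the original only in residue
# arrangement, not in composition, which is what a shuffle is meant to
# isolate.
repeat_rich_set <- function(n = 50, len = 300, seed = 1000) {
  originals <- lapply(seq_len(n), function(i) {
    res <- AA[(i %% 20) + 1]
    others <- setdiff(AA, res)
    unit <- paste0(others[(i %% 19) + 1], others[((i + 7) %% 18) + 2])
    planted <- c(12, 8, 8)
    names(planted) <- c(res, substr(unit, 1, 1), substr(unit, 2, 2))
    comp <- setNames(rep(len / 20, 20), AA)
    comp[names(planted)] <- pmax(comp[names(planted)] - planted, 0.2)
    generate_fixture(list(id = sprintf("prot%03d", i), length = len,
                          composition = comp, features = list(
      list(kind = "homorepeat", unit = res, start = 41, length = 12),
      list(kind = "str", unit = unit, start = 151, length = 16))),
      seed = seed + i)
  })
  shuffles <- lapply(seq_len(n), function(i) {
    rec <- originals[[i]]
    chars <- strsplit(rec$residues, "")[[1]]
    set.seed(seed + 5000 + i)
    seq_record(paste0(rec$id, "_shuf"), paste(sample(chars), collapse = ""))
  })
  list(originals = originals, shuffles = shuffles)
}

run_method <- function(method, rec, simple_n_random = 50,
                       flps = flps_params()) {
  switch(method,
         SEG = run_seg(rec),
         CAST = run_cast(rec),
         FLPS = run_flps(rec, flps),
         SIMPLE = run_simple(rec, simple_params(n_random = simple_n_random)),
         GBSC = run_gbsc(rec))
}

# Positional overlap of a method's merged output with a planted interval.
overlap_fraction <- function(regions, start, end) {
  if (nrow(regions) == 0) return(0)
  covered <- rep(FALSE, max(regions$end, end))
  for (i in seq_len(nrow(regions))) covered[regions$start[i]:regions$end[i]] <- TRUE
  mean(covered[start:end])
}
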