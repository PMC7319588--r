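# fLPS: lowest-probability subsequences under a binomial composition model.
# Three stages: QUICKSCAN (flag coarse windows whose residue count is
# improbably high and merge them into contigs), MINIMIZATION (exhaustively
# scan each flank-extended contig with windows from M down to m for the
# minimal binomial tail probability) and MERGE (combine overlapping regions
# of different residues when the combined region is less probable, then
# greedily trim/extend while the probability decreases).

#' Amino-acid frequency profile
#'
#' @param freq named numeric vector of relative frequencies over the 20
#'   canonical residues (missing residues are set to 0); must be
#'   non-negative and sum to 1 within 1e-9 (use `normalize = TRUE` to
#'   rescale).
#' @param normalize rescale to sum 1.
#' @return named numeric vector of class `frequency_profile`.
#' @export
frequency_profile <- function(freq, normalize = FALSE) {
  if (is.null(names(freq)) || !all(names(freq) %in% AA20))
    stop_lcr("frequency profile names must be canonical residues")
  full <- stats::setNames(rep(0, 20), AA20)
  full[names(freq)] <- freq
  if (any(full < 0)) stop_lcr("frequencies must be non-negative")
  if (normalize) full <- full / sum(full)
  if (abs(sum(full) - 1) > 1e-9)
    stop_lcr("frequencies must sum to 1 (within 1e-9)")
  structure(full, class = c("frequency_profile", "numeric"))
}

#' Uniform background composition (1/20 per residue)
#' @return a `frequency_profile`.
#' @export
uniform_profile <- function() {
  frequency_profile(stats::setNames(rep(1 / 20, 20), AA20))
}

#' Bundled SwissProt-like reference composition
#'
#' Typical UniProtKB/Swiss-Prot amino-acid composition, shipped as a
#' plain-text table and normalized on load. Intended as a realistic
#' non-uniform background/reference; see the package vignette.
#'
#' @return a `frequency_profile`.
#' @export
swissprot_profile <- function() {
  path <- system.file("extdata", "aa_freq_swissprot_like.tsv",
                      package = "lcrtools", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  frequency_profile(stats::setNames(tab$frequency, tab$residue),
                    normalize = TRUE)
}

#' fLPS parameters
#'
#' Defaults m=15, M=500, t=1e-3 are the original fLPS defaults; the
#' published `strict` preset (m=5, M=25, t=1e-5) narrows the search to
#' short, strongly biased tracts. The background composition defaults to
#' uniform 1/20.
#'
#' @param m minimum window length (residues).
#' @param M maximum window length (residues), `m <= M`.
#' @param t bias P-value threshold in (0, 1).
#' @param background a `frequency_profile` used as the null composition.
#' @return a list of class `flps_params`.
#' @export
flps_params <- function(m = 15, M = 500, t = 1e-3,
                        background = uniform_profile()) {
  m <- as.integer(m); M <- as.integer(M)
  if (m < 1 || m > M) stop_lcr("flps: need 1 <= m <= M")
  if (t <= 0 || t >= 1) stop_lcr("flps: need 0 < t < 1")
  background <- frequency_profile(unclass(background))
  structure(list(m = m, M = M, t = t, background = background),
            class = "flps_params")
}

#' Named fLPS parameter presets
#' @param name `"default"` or `"strict"`.
#' @param background null composition passed through.
#' @return an `flps_params` object.
#' @export
flps_preset <- function(name = c("default", "strict"),
                        background = uniform_profile()) {
  name <- match.arg(name)
  switch(name,
         default = flps_params(15, 500, 1e-3, background),
         strict  = flps_params(5, 25, 1e-5, background))
}

#' Upper binomial tail probability
#'
#' `P(X >= k)` for `X ~ Binomial(w, p)`, evaluated stably in log space for
#' small tails.
#'
#' @param k observed count, `0 <= k <= w` (vectorized).
#' @param w window length.
#' @param p background success probability in (0, 1).
#' @return tail probability.
#' @export
binomial_tail <- function(k, w, p) {
  if (any(k < 0) || any(k > w)) stop_lcr("binomial_tail: need 0 <= k <= w")
  if (any(p <= 0) || any(p >= 1)) stop_lcr("binomial_tail: need 0 < p < 1")
  ifelse(k == 0, 1, stats::pbinom(k - 1, w, p, lower.tail = FALSE))
}

# Natural-log upper tail, vectorized over k (and w of equal length).
#' @noRd
log_binomial_tail <- function(k, w, p) {
  out <- stats::pbinom(k - 1, w, p, lower.tail = FALSE, log.p = TRUE)
  out[k == 0] <- 0
  out
}

#' Single-residue lowest-probability subsequences
#'
#' QUICKSCAN flags windows (step `max(1, m)`) whose count of `residue` has
#' binomial tail probability `<= t`, at two scales: coarse windows of
#' length `min(M, L)` and fine windows of length `m` (so short dense tracts
#' are not diluted away when `M` approaches the sequence length), and
#' merges overlapping flagged windows into contigs; MINIMIZATION exhaustively
#' evaluates every window of length `M` down to `m` inside each contig
#' (extended by `M - 1` on both flanks, clipped to the sequence) and keeps
#' the window minimizing the tail probability, emitted iff `P <= t`. One
#' region per contig; ties broken by longer window, then leftmost.
#'
#' @param record a `seq_record`.
#' @param residue single canonical residue letter.
#' @param params an `flps_params`.
#' @return an `lcr_regions` table (method `FLPS`, score = log10 P).
#' @export
single_residue_lps <- function(record, residue, params = flps_params()) {
  if (!(residue %in% AA20)) stop_lcr("flps: residue must be canonical")
  chars <- seq_chars(record$residues)
  L <- length(chars)
  if (L < params$m) return(empty_regions())
  p <- unclass(params$background)[residue]
  if (p <= 0) return(empty_regions())
  cs <- c(0, cumsum(chars == residue))
  step <- max(1L, params$m)
  # two pre-scan scales: the M-length coarse windows catch broad dilute
  # bias, the m-length fine windows catch short dense tracts that a
  # near-whole-sequence coarse window would dilute away; the pre-scan only
  # seeds contigs, the exhaustive minimization decides what is reported
  flagged <- list()
  for (w in unique(c(min(params$M, L), min(params$m, L)))) {
    starts <- unique(c(seq(1L, L - w + 1L, by = step), L - w + 1L))
    k <- cs[starts + w] - cs[starts]
    hit <- starts[binomial_tail(k, w, p) <= params$t]
    if (length(hit) > 0)
      flagged[[length(flagged) + 1]] <- cbind(hit, hit + w - 1L)
  }
  if (length(flagged) == 0) return(empty_regions())
  iv <- do.call(rbind, flagged)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  # merge overlapping flagged windows into contigs
  grp <- cumsum(c(1, iv[-1, 1] > cummax(iv[-nrow(iv), 2, drop = TRUE])))
  out <- lapply(split(seq_len(nrow(iv)), grp), function(rows) {
    lo <- max(1L, min(iv[rows, 1]) - (params$M - 1L))
    hi <- min(L, max(iv[rows, 2]) + (params$M - 1L))
    span <- hi - lo + 1L
    best <- list(logp = Inf, start = NA_integer_, w = NA_integer_)
    tol <- 1e-12
    for (w in seq(min(params$M, span), params$m)) {   # longest first
      off <- lo:(hi - w + 1L)
      kk <- cs[off + w] - cs[off]
      lp <- log_binomial_tail(kk, w, p)
      j <- which.min(lp)                              # leftmost minimum
      if (lp[j] < best$logp - tol) {
        best <- list(logp = lp[j], start = off[j], w = w)
      }
    }
    if (best$logp > log(params$t) + 1e-12) return(NULL)
    lcr_regions(record$id, best$start, best$start + best$w - 1L, "FLPS",
                best$logp / log(10), residues = residue)
  })
  sort_regions(do.call(bind_regions, out[!vapply(out, is.null, logical(1))]))
}

# Tail probability (natural log) of a candidate region for residue set rset.
#' @noRd
region_logp <- function(chars, start, end, rset, background) {
  w <- end - start + 1L
  k <- sum(chars[start:end] %in% rset)
  pR <- sum(unclass(background)[rset])
  if (pR >= 1) pR <- 1 - 1e-12
  log_binomial_tail(k, w, pR)
}

#' Merge, trim and extend lowest-probability subsequences
#'
#' Overlapping or near-adjacent (gap `<= m`) regions with distinct residue
#' sets are merged when the union span scored over the combined residue set
#' has a strictly smaller tail probability than both components; merging
#' repeats to a fixpoint (candidates processed by ascending combined P, ties
#' leftmost). Each surviving region is then greedily trimmed/extended one
#' residue at a time at either end while its P strictly decreases.
#'
#' @param regions `lcr_regions` for a single sequence (method `FLPS`).
#' @param record the `seq_record` they reference.
#' @param params an `flps_params`.
#' @return an `lcr_regions` table, sorted by start.
#' @export
merge_lps <- function(regions, record, params = flps_params()) {
  if (nrow(regions) == 0) return(regions)
  if (length(unique(regions$seq_id)) > 1)
    stop_lcr("merge_lps: regions must reference a single sequence")
  if (unique(regions$seq_id) != record$id)
    stop_lcr("merge_lps: regions do not reference the given record")
  chars <- seq_chars(record$residues)
  L <- length(chars)
  bg <- params$background
  tol <- 1e-12
  items <- lapply(seq_len(nrow(regions)), function(i) {
    rset <- sort(seq_chars(gsub(",", "", regions$residues[i])))
    list(start = regions$start[i], end = regions$end[i], rset = rset,
         logp = regions$score[i] * log(10))
  })
  repeat {
    n <- length(items)
    if (n < 2) break
    cand <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- items[[i]]; b <- items[[j]]
      if (setequal(a$rset, b$rset)) next
      gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
      if (gap > params$m) next
      s <- min(a$start, b$start); e <- max(a$end, b$end)
      rset <- sort(union(a$rset, b$rset))
      lp <- region_logp(chars, s, e, rset, bg)
      if (lp < a$logp - tol && lp < b$logp - tol) {
        if (is.null(cand) || lp < cand$logp - tol ||
            (abs(lp - cand$logp) <= tol && s < cand$start)) {
          cand <- list(i = i, j = j, start = s, end = e, rset = rset,
                       logp = lp)
        }
      }
    }
    if (is.null(cand)) break
    items <- c(items[-c(cand$i, cand$j)],
               list(list(start = cand$start, end = cand$end,
                         rset = cand$rset, logp = cand$logp)))
  }
  # greedy one-residue trim/extend to a local optimum
  items <- lapply(items, function(it) {
    repeat {
      moves <- list(c(it$start - 1L, it$end), c(it$start + 1L, it$end),
                    c(it$start, it$end + 1L), c(it$start, it$end - 1L))
      bestmove <- NULL
      for (mv in moves) {
        if (mv[1] < 1 || mv[2] > L || mv[1] > mv[2]) next
        lp <- region_logp(chars, mv[1], mv[2], it$rset, bg)
        if (lp < it$logp - tol &&
            (is.null(bestmove) || lp < bestmove$logp - tol)) {
          bestmove <- list(start = mv[1], end = mv[2], logp = lp)
        }
      }
      if (is.null(bestmove)) break
      it$start <- bestmove$start; it$end <- bestmove$end
      it$logp <- bestmove$logp
    }
    it
  })
  out <- do.call(bind_regions, lapply(items, function(it) {
    lcr_regions(record$id, it$start, it$end, "FLPS", it$logp / log(10),
                residues = paste(it$rset, collapse = ","))
  }))
  sort_regions(out)
}

#' Run fLPS on a sequence
#'
#' Union of [single_residue_lps()] over the 20 canonical residues, passed
#' through [merge_lps()].
#'
#' @param record a `seq_record`.
#' @param params an `flps_params`.
#' @return an `lcr_regions` table (method `FLPS`), sorted by start.
#' @export
run_flps <- function(record, params = flps_params()) {
  per <- lapply(AA20, function(a) single_residue_lps(record, a, params))
  all <- do.call(bind_regions, per)
  if (nrow(all) == 0) return(all)
  merge_lps(all, record, params)
}
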