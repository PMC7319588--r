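# SIMPLE: short-motif repetitiveness in sliding windows, with significance
# calls against composition-preserving shuffles of the same sequence.

#' SIMPLE parameters
#'
#' The toolkit defaults (window 65, motif lengths 1-3, 100 shuffles,
#' alpha 0.05, seed 42) are documented toolkit choices in the spirit of the
#' original method, not reference-faithful constants; see the vignette.
#'
#' @param window context width in residues, odd, >= 3. Windows are centered;
#'   near the sequence ends the window is shifted inward so it always spans
#'   `window` residues.
#' @param motif_lengths motif lengths considered, subset of 1:4.
#' @param n_random number of composition-preserving shuffles for the null.
#' @param alpha upper-tail significance level in (0, 1).
#' @param seed integer randomization seed.
#' @return a list of class `simple_params`.
#' @export
simple_params <- function(window = 65, motif_lengths = c(1, 2, 3),
                          n_random = 100, alpha = 0.05, seed = 42) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) stop_lcr("simple: window must be odd and >= 3")
  motif_lengths <- sort(unique(as.integer(motif_lengths)))
  if (length(motif_lengths) == 0 || !all(motif_lengths %in% 1:4))
    stop_lcr("simple: motif_lengths must be a non-empty subset of 1:4")
  if (n_random < 1) stop_lcr("simple: n_random must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_lcr("simple: alpha must be in (0, 1)")
  structure(list(window = window, motif_lengths = motif_lengths,
                 n_random = as.integer(n_random), alpha = alpha,
                 seed = as.integer(seed)), class = "simple_params")
}

# Core positional scoring. For each position i and motif length l, counts
# the additional exact occurrences of the l-mer starting at i within the
# window anchored at i (overlaps allowed, any offset, occurrence fully
# inside the window); the contribution is l per occurrence. Motifs
# containing 'X' score 0.
#' @noRd
simple_position_scores <- function(chars, window, motif_lengths) {
  L <- length(chars)
  h <- (window - 1L) %/% 2L
  lo <- pmax(1L, pmin(seq_len(L) - h, L - window + 1L))
  hi <- lo + window - 1L
  codes <- seq_codes(chars)
  S <- numeric(L)
  for (l in motif_lengths) {
    nk <- L - l + 1L
    if (nk < 1) next
    kid <- codes[seq_len(nk)]
    if (l > 1) for (d in 1:(l - 1)) kid <- kid * 21 + codes[(1 + d):(nk + d)]
    if (window - l < 1) next
    for (d in setdiff(seq.int(-(window - l), window - l), 0L)) {
      i1 <- max(1L, 1L - d)
      i2 <- min(nk, nk - d)
      if (i1 > i2) next
      idx <- i1:i2
      m <- !is.na(kid[idx]) & !is.na(kid[idx + d]) & kid[idx] == kid[idx + d] &
        (idx + d) >= lo[idx] & (idx + d + l - 1L) <= hi[idx]
      S[idx[m]] <- S[idx[m]] + l
    }
  }
  S
}

#' Per-position simplicity scores
#'
#' @param record a `seq_record` of length `>= window`.
#' @param params a `simple_params`.
#' @return a list of class `simplicity_track` with `values` (one
#'   non-negative score per position) and `mean_score` (the whole-sequence
#'   repetitiveness indicator).
#' @export
simplicity_scores <- function(record, params = simple_params()) {
  chars <- seq_chars(record$residues)
  if (length(chars) < params$window)
    stop_lcr("simple: record '", record$id, "' shorter than window")
  v <- simple_position_scores(chars, params$window, params$motif_lengths)
  structure(list(seq_id = record$id, values = v, mean_score = mean(v)),
            class = "simplicity_track")
}

#' Run SIMPLE on a sequence
#'
#' Scores the sequence, builds a pooled null distribution from the
#' positional scores of `n_random` composition-preserving shuffles, and
#' reports maximal runs of positions scoring strictly above the empirical
#' `1 - alpha` null quantile. Deterministic for a fixed seed.
#'
#' @param record a `seq_record`.
#' @param params a `simple_params`.
#' @return an `lcr_regions` table (method `SIMPLE`, score = mean simplicity
#'   score over the region), sorted by start.
#' @export
run_simple <- function(record, params = simple_params()) {
  track <- simplicity_scores(record, params)
  chars <- seq_chars(record$residues)
  null_vals <- with_seed(params$seed, {
    unlist(lapply(seq_len(params$n_random), function(r) {
      simple_position_scores(sample(chars), params$window,
                             params$motif_lengths)
    }))
  })
  threshold <- stats::quantile(null_vals, 1 - params$alpha, type = 1,
                               names = FALSE)
  sig <- track$values > threshold
  if (!any(sig)) return(empty_regions())
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lcr_regions(record$id, starts[keep], ends[keep], "SIMPLE",
                     vapply(keep, function(i)
                       mean(track$values[starts[i]:ends[i]]), numeric(1)),
                     residues = "")
  sort_regions(out)
}
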