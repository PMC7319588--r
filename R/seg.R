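#' SEG parameters
#'
#' The classic two-pass entropy segmentation is controlled by a trigger
#' window length `W` and two complexity thresholds in bits/position: the
#' strict trigger threshold `K1` and the relaxed extension threshold `K2`.
#'
#' Defaults (12 / 2.2 / 2.5) are the canonical SEG defaults. Two stricter
#' presets are available through [seg_preset()]: `intermediate`
#' (15 / 1.9 / 2.5), tuned for longer eukaryotic low-complexity regions, and
#' `strict` (15 / 1.5 / 2.8) for strongly biased yet diverse sequences.
#'
#' @param W trigger window length (residues, >= 2).
#' @param K1 trigger complexity threshold (bits/position).
#' @param K2 extension complexity threshold (bits/position), `K1 <= K2`.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(W = 12, K1 = 2.2, K2 = 2.5) {
  W <- as.integer(W)
  if (W < 2) stop_lcr("seg: W must be >= 2")
  if (K1 < 0 || K1 > K2 || K2 > log2(20) + 1e-9)
    stop_lcr("seg: need 0 <= K1 <= K2 <= log2(20)")
  structure(list(W = W, K1 = K1, K2 = K2), class = "seg_params")
}

#' Named SEG parameter presets
#'
#' @param name `"default"`, `"intermediate"` or `"strict"`.
#' @return a `seg_params` object.
#' @export
seg_preset <- function(name = c("default", "intermediate", "strict")) {
  name <- match.arg(name)
  switch(name,
         default      = seg_params(12, 2.2, 2.5),
         intermediate = seg_params(15, 1.9, 2.5),
         strict       = seg_params(15, 1.5, 2.8))
}

#' Shannon complexity of a residue window
#'
#' Returns the Shannon entropy of the window's residue composition in
#' bits/position: `sum over types i of -(n_i/L) log2(n_i/L)` with `L` the
#' window length. `X` contributes to `L` but to no residue count, so an
#' unknown-rich window scores as low complexity.
#'
#' @param window residue string (non-empty).
#' @return entropy in `[0, log2(20)]`.
#' @export
window_complexity <- function(window) {
  if (!is.character(window) || length(window) != 1 || !nzchar(window))
    stop_lcr("window_complexity: window must be a non-empty string")
  codes <- seq_codes(seq_chars(toupper(window)))
  entropy_from_counts(tabulate(codes[!is.na(codes)], 20), length(codes))
}

#' @noRd
entropy_from_counts <- function(counts, L) {
  n <- counts[counts > 0]
  if (length(n) == 0) return(0)
  p <- n / L
  -sum(p * log2(p))
}

# Entropies of all length-W windows; NA-free numeric vector of length L-W+1.
#' @noRd
window_entropies <- function(codes, W) {
  L <- length(codes)
  ns <- L - W + 1
  if (ns < 1) return(numeric(0))
  vapply(seq_len(ns), function(s) {
    entropy_from_counts(tabulate(codes[s:(s + W - 1)], 20), W)
  }, numeric(1))
}

#' First SEG pass: candidate windows and contig formation
#'
#' A position belongs to a contig iff it is covered by at least one length-W
#' window of complexity `<= K2` connected, through a chain of overlapping
#' `<= K2` windows, to at least one trigger window of complexity `<= K1`.
#' Contigs are the maximal such runs.
#'
#' @param record a `seq_record`.
#' @param params a `seg_params`.
#' @return data frame with columns `start`, `end`, one row per contig, left
#'   to right.
#' @export
find_contigs <- function(record, params = seg_params()) {
  W <- params$W
  codes <- seq_codes(seq_chars(record$residues))
  L <- length(codes)
  if (L < W) {
    message("seg: record '", record$id, "' shorter than window (", L, " < ",
            W, "); no contigs")
    return(data.frame(start = integer(), end = integer()))
  }
  H <- window_entropies(codes, W)
  eps <- 1e-9
  low2 <- which(H <= params$K2 + eps)
  if (length(low2) == 0) return(data.frame(start = integer(), end = integer()))
  # chains of mutually overlapping <=K2 windows: split where start gaps > W-1
  grp <- cumsum(c(1, diff(low2) > (W - 1)))
  out <- lapply(split(low2, grp), function(ss) {
    if (!any(H[ss] <= params$K1 + eps)) return(NULL)
    c(min(ss), max(ss) + W - 1)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
}

# Incremental brute-force minimum-P0 subsequence search within a contig.
# P0 = F * Omega / 20^L with F = L!/prod(n_i!) (sequences sharing the
# composition) and Omega = 20!/prod_k(r_k!) (compositions sharing the count
# multiset, r_k = number of residue types occurring exactly k times,
# including k = 0). All arithmetic in natural-log space; 'X' positions are
# excluded from the composition (L counts non-X residues only).
#' @noRd
min_p0_subsequence <- function(codes, cs, ce, tol = 1e-12) {
  lg20f <- lgamma(21)
  best <- Inf; bi <- cs; bj <- cs - 1L; blen <- -1L
  for (i in cs:ce) {
    counts <- integer(20)
    cc <- integer(ce - cs + 3)  # cc[k+1] = number of types with count k
    cc[1] <- 20L
    S <- lg20f                  # sum_k log(cc_k!)
    logF <- 0
    L <- 0L
    for (j in i:ce) {
      r <- codes[j]
      if (!is.na(r)) {
        k <- counts[r]
        counts[r] <- k + 1L
        L <- L + 1L
        logF <- logF + log(L) - log(k + 1)
        # move one type from count k to k+1
        S <- S - log(cc[k + 1])
        cc[k + 1] <- cc[k + 1] - 1L
        cc[k + 2] <- cc[k + 2] + 1L
        S <- S + log(cc[k + 2])
      }
      logOmega <- lg20f - S
      logP0 <- logF + logOmega - L * log(20)
      len <- j - i + 1L
      if (logP0 < best - tol ||
          (abs(logP0 - best) <= tol &&
           (len > blen || (len == blen && i < bi)))) {
        best <- logP0; bi <- i; bj <- j; blen <- len
      }
    }
  }
  list(start = bi, end = bj, logP0 = best)
}

#' Second SEG pass: minimum-probability subsequence within a contig
#'
#' Enumerates every subsequence of the contig and returns the one minimizing
#' the composition probability P0 (see Details), with ties broken by longer
#' subsequence, then smaller start.
#'
#' @details `P0 = F * Omega / 20^L`, where `F = L!/prod(n_i!)` counts the
#' sequences sharing the subsequence's composition and
#' `Omega = 20!/prod_k(r_k!)` the compositions sharing its count multiset
#' (`r_k` = number of residue types occurring exactly `k` times, including
#' `k = 0`). Computed in log space; the region score is `log10(P0)`.
#'
#' @param record a `seq_record`.
#' @param contig a length-2 numeric `(start, end)` or one-row data frame.
#' @return a one-row `lcr_regions` table with method `SEG`.
#' @export
optimize_contig <- function(record, contig) {
  if (is.data.frame(contig)) contig <- c(contig$start[1], contig$end[1])
  cs <- as.integer(contig[1]); ce <- as.integer(contig[2])
  L <- nchar(record$residues)
  if (cs < 1 || ce > L || cs > ce)
    stop_lcr("contig outside record bounds")
  codes <- seq_codes(seq_chars(record$residues))
  opt <- min_p0_subsequence(codes, cs, ce)
  lcr_regions(record$id, opt$start, opt$end, "SEG",
              opt$logP0 / log(10), residues = "")
}

#' Run SEG on a sequence
#'
#' @param record a `seq_record`.
#' @param params a `seg_params`.
#' @return an `lcr_regions` table (method `SEG`), sorted by start.
#' @export
run_seg <- function(record, params = seg_params()) {
  contigs <- find_contigs(record, params)
  if (nrow(contigs) == 0) return(empty_regions())
  out <- do.call(bind_regions, lapply(seq_len(nrow(contigs)), function(i) {
    optimize_contig(record, c(contigs$start[i], contigs$end[i]))
  }))
  sort_regions(out)
}
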