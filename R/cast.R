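# CAST: compositional bias as similarity to homopolymers.
#
# With an infinite gap penalty, Smith-Waterman local alignment of a sequence
# against an unbounded homopolymer of residue t reduces exactly to the
# maximum-sum contiguous segment of the per-position substitution scores
# s_j = matrix[seq_j, t]; the detector iterates best-segment detection and
# masking of the winning residue until no segment reaches the threshold.

.lcr_cache <- new.env(parent = emptyenv())

#' Default CAST scoring matrix (BLOSUM62)
#'
#' The BLOSUM62 substitution matrix restricted to the 20 canonical residues
#' plus `X`, with the `X` row/column set to 0 so unknown residues neither
#' reward nor penalize any homopolymer target.
#'
#' @return an integer matrix with dimnames over the 21-letter alphabet.
#' @export
default_blosum62 <- function() {
  if (!is.null(.lcr_cache$blosum62)) return(.lcr_cache$blosum62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET_FULL, AA_ALPHABET_FULL]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  .lcr_cache$blosum62 <- m
  m
}

#' Read a substitution matrix from an NCBI-format text file
#'
#' @param path path to a whitespace-separated square scoring matrix with a
#'   header row/column of residue letters; `#` comment lines are skipped.
#' @return an integer matrix.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop_lcr("not a scoring matrix: ", path)
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  rn <- vapply(rows, `[`, "", 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(vals) <- list(rn, cols)
  miss <- setdiff(AA20, intersect(rn, cols))
  if (length(miss) > 0)
    stop_lcr("scoring matrix lacks residues: ", paste(miss, collapse = ", "))
  if (!("X" %in% rn)) {
    vals <- rbind(cbind(vals[AA20, AA20], X = 0L), X = 0L)
    rownames(vals)[21] <- "X"
  }
  vals
}

#' CAST parameters
#'
#' @param threshold minimum reportable similarity score (matrix units,
#'   default 40, the original CAST default).
#' @param matrix 20x20(+X) substitution matrix; default BLOSUM62.
#' @return a list of class `cast_params`.
#' @export
cast_params <- function(threshold = 40, matrix = NULL) {
  if (threshold <= 0) stop_lcr("cast: threshold must be > 0")
  if (is.null(matrix)) matrix <- default_blosum62()
  m <- matrix[AA20, AA20]
  if (!isTRUE(all.equal(m, t(m))) || any(diag(m) <= 0))
    stop_lcr("cast: matrix must be symmetric with positive diagonal")
  structure(list(threshold = threshold, matrix = matrix),
            class = "cast_params")
}

#' Best-scoring segment against a homopolymer
#'
#' Maximum-sum contiguous segment of per-position scores against a
#' homopolymer of `target` (equivalent to Smith-Waterman with an infinite
#' gap penalty). Ties are broken by leftmost start, then shortest segment;
#' if no segment scores positive the result is an empty segment with
#' score 0.
#'
#' @param residues residue string.
#' @param target single canonical residue letter.
#' @param matrix substitution matrix (default BLOSUM62).
#' @return list with `start`, `end` (NA for the empty segment) and `score`.
#' @export
homopolymer_best_segment <- function(residues, target,
                                     matrix = default_blosum62()) {
  if (!(target %in% AA20)) stop_lcr("cast: target must be a canonical residue")
  chars <- seq_chars(toupper(residues))
  bad <- setdiff(unique(chars), AA_ALPHABET_FULL)
  if (length(bad) > 0) stop_lcr("cast: invalid residue(s): ",
                                paste(bad, collapse = ", "))
  s <- as.numeric(matrix[chars, target])
  best <- 0; bstart <- NA_integer_; bend <- NA_integer_
  cur <- 0; st <- 1L
  for (j in seq_along(s)) {
    if (cur <= 0) { cur <- s[j]; st <- j } else cur <- cur + s[j]
    if (cur > best) { best <- cur; bstart <- st; bend <- j }
  }
  list(start = bstart, end = bend, score = best)
}

#' Run CAST on a sequence
#'
#' Iteratively finds the globally best homopolymer-similarity segment over
#' the 20 residue targets (ties by alphabetical target), reports it when its
#' score reaches the threshold, masks the target residue's occurrences
#' inside the segment with `X` in a working copy, and repeats until the best
#' score falls below the threshold.
#'
#' @param record a `seq_record`.
#' @param params a `cast_params`.
#' @return an `lcr_regions` table (method `CAST`, `residues` = the bias
#'   residue), sorted by start.
#' @export
run_cast <- function(record, params = cast_params()) {
  work <- seq_chars(record$residues)
  mat <- params$matrix
  out <- list()
  repeat {
    best <- NULL
    for (t in AA20) {
      seg <- homopolymer_best_segment(paste(work, collapse = ""), t, mat)
      if (is.null(best) || seg$score > best$score) {
        best <- seg
        best$target <- t
      }
    }
    if (best$score < params$threshold) break
    out[[length(out) + 1]] <- lcr_regions(record$id, best$start, best$end,
                                          "CAST", best$score,
                                          residues = best$target)
    idx <- best$start:best$end
    if (any(work[idx] == best$target)) {
      work[idx][work[idx] == best$target] <- "X"
    } else {
      # pure cross-similarity (e.g. a V/L tract scoring against I): the
      # target never occurs in the segment, so masking only the target
      # would stall; mask the whole winning region instead.
      work[idx] <- "X"
    }
  }
  sort_regions(do.call(bind_regions, out))
}
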