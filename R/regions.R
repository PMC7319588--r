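#' Construct a table of detected regions
#'
#' Regions are the toolkit's universal currency: every detector returns a
#' `lcr_regions` data frame with one row per detected interval, 1-based
#' inclusive coordinates, the detecting method, a method-specific score and
#' (where applicable) the bias residues and repeat unit.
#'
#' Score semantics by method: `SEG` carries log10 of the composition
#' probability P0 of the optimized subsequence; `CAST` the homopolymer
#' similarity score in matrix units; `FLPS` log10 of the binomial bias
#' P-value; `SIMPLE` the mean simplicity score over the region; `GBSC` the
#' repeat-unit traversal count; `CONSENSUS` is always 0.
#'
#' @param seq_id character, sequence identifiers.
#' @param start,end 1-based inclusive interval bounds.
#' @param method one of `"SEG"`, `"CAST"`, `"FLPS"`, `"SIMPLE"`, `"GBSC"`,
#'   `"CONSENSUS"`.
#' @param score numeric method-specific score.
#' @param residues comma-joined bias residue letters (`""` when none).
#' @param unit repeat-unit string (`NA` unless method is GBSC).
#' @return a data frame of class `lcr_regions`.
#' @export
lcr_regions <- function(seq_id = character(), start = integer(),
                        end = integer(), method = character(),
                        score = numeric(), residues = "",
                        unit = NA_character_) {
  n <- length(seq_id)
  if (n == 0 || length(start) == 0) {
    df <- data.frame(seq_id = character(), start = integer(), end = integer(),
                     method = character(), score = numeric(),
                     residues = character(), unit = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("lcr_regions", "data.frame")
    return(df)
  }
  if (length(residues) == 1) residues <- rep(residues, n)
  if (length(unit) == 1) unit <- rep(unit, n)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L) || any(end < start))
    stop_lcr("invalid region coordinates: need 1 <= start <= end")
  ok <- method %in% c("SEG", "CAST", "FLPS", "SIMPLE", "GBSC", "CONSENSUS")
  if (!all(ok))
    stop_lcr("unknown method label: ", paste(unique(method[!ok]), collapse = ", "))
  df <- data.frame(seq_id = seq_id, start = start, end = end, method = method,
                   score = score, residues = residues, unit = unit,
                   stringsAsFactors = FALSE)
  class(df) <- c("lcr_regions", "data.frame")
  df
}

#' @noRd
empty_regions <- function() lcr_regions()

#' Combine several region tables into one
#'
#' @param ... `lcr_regions` tables (empty tables and NULLs are dropped).
#' @return a single `lcr_regions` table.
#' @export
bind_regions <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(dfs) == 0) return(empty_regions())
  out <- do.call(rbind, lapply(dfs, function(d) {
    class(d) <- "data.frame"
    d
  }))
  rownames(out) <- NULL
  class(out) <- c("lcr_regions", "data.frame")
  out
}

#' @noRd
sort_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions)
  o <- order(regions$seq_id, regions$start, regions$end, regions$method)
  out <- regions[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
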