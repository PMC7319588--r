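# Annotation layer: per-position entropy track, composition statistics,
# per-region residue enrichment, multi-method consensus and coverage.

#' Sliding-window Shannon entropy track
#'
#' Entropy of the window centered at each position, in bits/position; the
#' first and last `(window-1)/2` positions are undefined (`NA`).
#'
#' @param record a `seq_record`.
#' @param window odd window size >= 3 (default 7).
#' @return a list of class `position_track` with `seq_id`, `name` and
#'   `values` (length = sequence length, `NA` where undefined).
#' @export
entropy_track <- function(record, window = 7) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0)
    stop_lcr("entropy_track: window must be odd and >= 3")
  codes <- seq_codes(seq_chars(record$residues))
  L <- length(codes)
  values <- rep(NA_real_, L)
  if (L >= window) {
    h <- (window - 1L) %/% 2L
    ent <- window_entropies(codes, window)
    values[(h + 1L):(L - h)] <- ent
  }
  structure(list(seq_id = record$id, name = "shannon_entropy",
                 values = values), class = "position_track")
}

#' Format a position track as TSV lines
#'
#' @param track a `position_track`.
#' @return character vector: header plus `position<TAB>value` lines, with
#'   `NA` for undefined positions.
#' @export
write_track <- function(track) {
  c("position\tvalue",
    paste(seq_along(track$values),
          ifelse(is.na(track$values), "NA",
                 formatC(track$values, digits = 6, format = "g")),
          sep = "\t"))
}

#' Amino-acid composition of a sequence
#'
#' Relative frequency of each canonical residue over the non-`X` positions.
#'
#' @param record a `seq_record`.
#' @return a `frequency_profile`.
#' @export
aa_frequencies <- function(record) {
  codes <- seq_codes(seq_chars(record$residues))
  n <- sum(!is.na(codes))
  if (n == 0) stop_lcr("aa_frequencies: sequence is all 'X'")
  frequency_profile(stats::setNames(tabulate(codes, 20) / n, AA20))
}

#' Compare a query composition to a reference composition
#'
#' @param query,reference `frequency_profile` objects.
#' @return data frame with columns `residue`, `query`, `reference`,
#'   `difference` and `ratio` (`NA` where the reference frequency is 0).
#' @export
compare_frequencies <- function(query, reference) {
  q <- unclass(frequency_profile(unclass(query)))
  r <- unclass(frequency_profile(unclass(reference)))
  data.frame(residue = AA20, query = q[AA20], reference = r[AA20],
             difference = q[AA20] - r[AA20],
             ratio = ifelse(r[AA20] > 0, q[AA20] / r[AA20], NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Residues enriched within a region
#'
#' A residue is reported as enriched when its in-region frequency (over
#' non-`X` positions) is at least `ratio_min` times its background
#' frequency and it occurs at least `count_min` times in the region.
#'
#' @param region one region (one-row `lcr_regions` or list with
#'   `start`/`end`).
#' @param record the `seq_record` the region belongs to.
#' @param background a `frequency_profile`.
#' @param ratio_min minimum fold enrichment (default 2).
#' @param count_min minimum in-region count (default 2).
#' @return sorted character vector of enriched residue letters.
#' @export
region_enrichment <- function(region, record, background = uniform_profile(),
                              ratio_min = 2.0, count_min = 2) {
  s <- as.integer(region$start[1]); e <- as.integer(region$end[1])
  L <- nchar(record$residues)
  if (is.na(s) || s < 1 || e > L || s > e)
    stop_lcr("region outside record bounds")
  codes <- seq_codes(seq_chars(substr(record$residues, s, e)))
  n <- sum(!is.na(codes))
  if (n == 0) return(character())
  counts <- tabulate(codes, 20)
  freq <- counts / n
  bg <- unclass(frequency_profile(unclass(background)))
  hit <- freq >= ratio_min * bg[AA20] & counts >= count_min & counts > 0
  AA20[hit]
}

#' @noRd
regions_to_iranges <- function(regions) {
  IRanges::IRanges(start = regions$start, end = regions$end)
}

#' Multi-method consensus regions
#'
#' Positional consensus over the selected methods: `intersection` keeps
#' maximal runs of positions covered by at least one region of every
#' selected method (the strict definition); `union` keeps positions covered
#' by any selected method (the permissive definition).
#'
#' @param regions_by_method named list: method label -> `lcr_regions` table,
#'   all for one sequence.
#' @param selected non-empty subset of `names(regions_by_method)`.
#' @param mode `"intersection"` or `"union"`.
#' @return an `lcr_regions` table with method `CONSENSUS`, score 0, empty
#'   residue sets; sorted, non-overlapping, adjacent runs merged.
#' @export
consensus_regions <- function(regions_by_method, selected = names(regions_by_method),
                              mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (length(selected) == 0) stop_lcr("consensus: no methods selected")
  miss <- setdiff(selected, names(regions_by_method))
  if (length(miss) > 0)
    stop_lcr("consensus: method(s) not present: ", paste(miss, collapse = ", "))
  sel <- regions_by_method[selected]
  ids <- unique(unlist(lapply(sel, function(r) r$seq_id)))
  if (length(ids) > 1)
    stop_lcr("consensus: regions must all reference one sequence")
  per <- lapply(sel, function(r) IRanges::reduce(regions_to_iranges(r)))
  ir <- if (mode == "union") {
    IRanges::reduce(do.call(c, unname(per)))
  } else {
    Reduce(IRanges::intersect, per)
  }
  ir <- IRanges::reduce(ir)
  if (length(ir) == 0 || length(ids) == 0) return(empty_regions())
  sort_regions(lcr_regions(ids, IRanges::start(ir), IRanges::end(ir),
                           "CONSENSUS", 0, residues = ""))
}

#' Fraction of residues covered by regions
#'
#' Number of distinct residue positions covered by the union of the given
#' regions, divided by `total_residues`.
#'
#' @param regions an `lcr_regions` table (possibly spanning several
#'   sequences; positions are distinct per sequence).
#' @param total_residues total residue count of the underlying sequence set.
#' @return proportion in `[0, 1]`.
#' @export
coverage_stats <- function(regions, total_residues) {
  total_residues <- as.numeric(total_residues)
  if (total_residues < 1) stop_lcr("coverage: total_residues must be >= 1")
  if (nrow(regions) == 0) return(0)
  covered <- sum(vapply(split(seq_len(nrow(regions)), regions$seq_id),
                        function(idx) {
    sum(IRanges::width(IRanges::reduce(
      regions_to_iranges(regions[idx, , drop = FALSE]))))
  }, numeric(1)))
  if (covered > total_residues)
    stop_lcr("coverage: regions extend beyond the stated residue total")
  covered / total_residues
}
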