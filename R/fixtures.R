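#' Generate a synthetic protein sequence with planted features
#'
#' Builds a random background sequence and plants low-complexity features
#' into it at fixed positions: homorepeats (a single repeated residue),
#' short tandem repeats (`str`, a repeated unit, optionally corrupted) and
#' compositionally biased tracts (`biased`, positions drawn uniformly from a
#' small residue set). The planted intervals are recorded in the record's
#' description so tests can assert recovery.
#'
#' The generator is deterministic for a fixed seed and leaves the caller's
#' RNG state untouched.
#'
#' @param spec a list with elements `length` (background length),
#'   optional `composition` (named frequency vector over the 20 canonical
#'   residues; default uniform), optional `id`, and `features`: a list of
#'   feature descriptions, each a list with `kind` (`"homorepeat"`, `"str"`
#'   or `"biased"`), `unit` (the repeated residue/unit for homorepeat/str, or
#'   the residue set as a string for biased), `start`, `length`, and optional
#'   `corruption` (per-position substitution probability, default 0).
#' @param seed integer randomization seed.
#' @return a `seq_record`; its description lists the planted intervals as
#'   `planted=kind:unit:start-end;...`.
#' @export
generate_fixture <- function(spec, seed) {
  stopifnot(is.list(spec), !is.null(spec$length))
  L <- as.integer(spec$length)
  comp <- spec$composition
  if (is.null(comp)) {
    comp <- stats::setNames(rep(1 / 20, 20), AA20)
  } else {
    if (!all(names(comp) %in% AA20)) stop_lcr("composition names must be canonical residues")
    full <- stats::setNames(rep(0, 20), AA20)
    full[names(comp)] <- comp
    comp <- full / sum(full)
  }
  features <- spec$features
  if (is.null(features)) features <- list()
  # validate features
  ivs <- lapply(features, function(f) {
    stopifnot(f$kind %in% c("homorepeat", "str", "biased"))
    s <- as.integer(f$start); len <- as.integer(f$length)
    if (s < 1 || s + len - 1 > L)
      stop_lcr("planted feature exceeds sequence bounds")
    c(s, s + len - 1)
  })
  if (length(ivs) > 1) {
    m <- do.call(rbind, ivs)
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      stop_lcr("planted features overlap")
  }
  chars <- with_seed(seed, {
    bg <- sample(AA20, L, replace = TRUE, prob = comp)
    for (f in features) {
      s <- as.integer(f$start); len <- as.integer(f$length)
      idx <- s:(s + len - 1)
      unit <- toupper(f$unit)
      fill <- switch(f$kind,
        homorepeat = rep(substr(unit, 1, 1), len),
        str = seq_chars(strrep(unit, ceiling(len / nchar(unit))))[seq_len(len)],
        biased = sample(seq_chars(unit), len, replace = TRUE))
      corr <- if (is.null(f$corruption)) 0 else f$corruption
      if (corr > 0) {
        hit <- stats::runif(len) < corr
        if (any(hit))
          fill[hit] <- vapply(fill[hit], function(a)
            sample(setdiff(AA20, a), 1), character(1))
      }
      bg[idx] <- fill
    }
    bg
  })
  desc <- if (length(features) > 0) {
    paste0("planted=", paste(vapply(features, function(f) {
      sprintf("%s:%s:%d-%d", f$kind, toupper(f$unit), as.integer(f$start),
              as.integer(f$start) + as.integer(f$length) - 1L)
    }, character(1)), collapse = ";"))
  } else ""
  id <- if (is.null(spec$id)) "fixture" else spec$id
  seq_record(id, paste(chars, collapse = ""), desc)
}

#' Recover the planted intervals of a fixture record
#'
#' @param record a `seq_record` produced by [generate_fixture()].
#' @return data frame with columns `kind`, `unit`, `start`, `end`.
#' @export
planted_intervals <- function(record) {
  if (!grepl("^planted=", record$description))
    return(data.frame(kind = character(), unit = character(),
                      start = integer(), end = integer()))
  items <- strsplit(sub("^planted=", "", record$description), ";",
                    fixed = TRUE)[[1]]
  parts <- strsplit(items, ":", fixed = TRUE)
  pos <- strsplit(vapply(parts, `[`, "", 3), "-", fixed = TRUE)
  data.frame(kind = vapply(parts, `[`, "", 1),
             unit = vapply(parts, `[`, "", 2),
             start = as.integer(vapply(pos, `[`, "", 1)),
             end = as.integer(vapply(pos, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Synthetic huntingtin-like test sequence
#'
#' A programmatically generated stand-in for the N-terminal part of human
#' huntingtin: a 21-residue polyglutamine homorepeat planted at residues
#' 18-38 of a random background, followed by a proline-rich tract, mimicking
#' the polyQ/polyP architecture of huntingtin exon 1. This is a synthetic
#' sequence, not the UniProt entry; it preserves the tested property that
#' the longest glutamine run spans residues 18-38.
#'
#' @param length total sequence length.
#' @param seed randomization seed for the background.
#' @return a `seq_record` with id `synthetic_HTT_like`.
#' @export
synthetic_huntingtin_like <- function(length = 500, seed = 181) {
  # The N-terminal headpiece and the polyP tract flanking the polyQ are
  # planted from Q-free residue sets so the longest Q run is exactly 18-38
  # for every seed.
  generate_fixture(list(
    id = "synthetic_HTT_like",
    length = length,
    features = list(
      list(kind = "biased", unit = "MATLEKSF", start = 1, length = 17),
      list(kind = "homorepeat", unit = "Q", start = 18, length = 21),
      list(kind = "homorepeat", unit = "P", start = 39, length = 12),
      list(kind = "biased", unit = "PL", start = 51, length = 20)
    )), seed = seed)
}

#' Longest run of one residue in a sequence
#'
#' @param record a `seq_record`.
#' @param residue single residue letter.
#' @return list with `start`, `end`, `length` of the longest consecutive run
#'   (leftmost on ties); `length` 0 if the residue is absent.
#' @export
longest_run <- function(record, residue) {
  chars <- seq_chars(record$residues)
  r <- rle(chars == residue)
  if (!any(r$values)) return(list(start = NA_integer_, end = NA_integer_,
                                  length = 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  best <- hit[which.max(r$lengths[hit])]
  list(start = starts[best], end = ends[best],
       length = r$lengths[best])
}
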