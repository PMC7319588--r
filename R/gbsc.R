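# GBSC: graph-based detection of homorepeats and (imperfect) short tandem
# repeats. The sequence is turned into a weighted graph of consecutive
# 2-mers; short cycles whose every edge recurs often enough mark repeat
# units, and their recorded sequence positions are projected back onto the
# sequence with gap bridging, which is what tolerates substitutions and
# insertions inside imperfect repeats.

#' GBSC parameters
#'
#' Toolkit defaults (window 15, min_occ 3) bridge single-residue
#' interruptions while requiring at least three copies of a repeat unit;
#' see the vignette for the rationale.
#'
#' @param window maximum gap in residues bridged when merging repeat
#'   evidence (>= 1).
#' @param min_occ minimum occurrence count of a repetitive pattern (>= 2).
#' @return a list of class `gbsc_params`.
#' @export
gbsc_params <- function(window = 15, min_occ = 3) {
  window <- as.integer(window); min_occ <- as.integer(min_occ)
  if (window < 1) stop_lcr("gbsc: window must be >= 1")
  if (min_occ < 2) stop_lcr("gbsc: min_occ must be >= 2")
  structure(list(window = window, min_occ = min_occ), class = "gbsc_params")
}

#' Build the weighted 2-mer transition graph of a sequence
#'
#' Nodes are the distinct 2-mers observed at positions `1..L-1`; each
#' position `i <= L-2` contributes one edge from the 2-mer at `i` to the
#' 2-mer at `i+1`, accumulating weight and recording `i`. 2-mers containing
#' `X` are excluded (their incident transitions are skipped).
#'
#' @param record a `seq_record` of length >= 3.
#' @return a list of class `kmer_graph` with `nodes`, `edges` (data frame
#'   `from`, `to`, `weight`) and `positions` (named list, key
#'   `"from>to"`).
#' @export
build_kmer_graph <- function(record) {
  L <- nchar(record$residues)
  if (L < 3) stop_lcr("gbsc: record '", record$id, "' shorter than 3 residues")
  kmers <- substring(record$residues, 1:(L - 1), 2:L)
  valid <- !grepl("X", kmers, fixed = TRUE)
  i <- which(valid[-(L - 1)] & valid[-1])   # transitions i -> i+1, i <= L-2
  keys <- paste(kmers[i], kmers[i + 1], sep = ">")
  positions <- split(i, keys)
  kk <- strsplit(names(positions), ">", fixed = TRUE)
  edges <- data.frame(from = vapply(kk, `[`, "", 1),
                      to = vapply(kk, `[`, "", 2),
                      weight = lengths(positions),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = sort(unique(kmers[valid])), edges = edges,
                 positions = positions, seq_id = record$id, seq_len = L),
            class = "kmer_graph")
}

# Enumerate simple cycles with <= max_len edges among the given edges.
# Each cycle is reported once, as the node sequence starting from its
# lexicographically smallest node.
#' @noRd
enumerate_cycles <- function(edges, max_len = 4) {
  if (nrow(edges) == 0) return(list())
  adj <- split(edges$to, edges$from)
  cycles <- list()
  starts <- sort(unique(edges$from))
  for (s in starts) {
    # DFS over nodes strictly greater than s, so s is the canonical start
    walk <- function(path) {
      last <- path[length(path)]
      for (nb in adj[[last]]) {
        if (nb == s && length(path) <= max_len) {
          cycles[[length(cycles) + 1]] <<- path
        } else if (length(path) < max_len && nb > s && !(nb %in% path)) {
          walk(c(path, nb))
        }
      }
    }
    walk(s)
  }
  cycles
}

#' @noRd
smallest_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1) return(s)
  rot <- vapply(seq_len(n), function(i)
    paste0(substr(s, i, n), substr(s, 1, i - 1)), character(1))
  sort(rot)[1]
}

#' Extract repeat regions from a 2-mer graph
#'
#' Finds simple cycles of at most 4 edges (self-loops included) whose
#' minimum edge weight is at least `min_occ`, projects each qualifying
#' cycle's recorded transition positions onto the sequence, merges positions
#' separated by at most `window` residues into candidate intervals (the gap
#' bridging that admits imperfect repeats), and reports intervals whose
#' cycle traversal count (in-interval transitions divided by cycle length)
#' reaches `min_occ`.
#'
#' @param graph a `kmer_graph` built from `record`.
#' @param record the corresponding `seq_record`.
#' @param params a `gbsc_params`.
#' @return an `lcr_regions` table (method `GBSC`; `unit` = lexicographically
#'   smallest rotation of the cycle's repeat unit, score = traversal count),
#'   sorted by start.
#' @export
extract_repeats <- function(graph, record, params = gbsc_params()) {
  if (!inherits(graph, "kmer_graph") || graph$seq_id != record$id ||
      graph$seq_len != nchar(record$residues))
    stop_lcr("gbsc: graph does not match record")
  heavy <- graph$edges[graph$edges$weight >= params$min_occ, , drop = FALSE]
  cycles <- enumerate_cycles(heavy, max_len = 4)
  out <- list()
  for (cyc in cycles) {
    k <- length(cyc)
    keys <- paste(cyc, c(cyc[-1], cyc[1]), sep = ">")
    pos <- sort(unique(unlist(graph$positions[keys])))
    unit <- smallest_rotation(paste(substr(cyc, 1, 1), collapse = ""))
    grp <- cumsum(c(1, diff(pos) > params$window))
    for (g in split(pos, grp)) {
      trav <- length(g) %/% k
      if (trav < params$min_occ) next
      out[[length(out) + 1]] <- lcr_regions(
        record$id, min(g), max(g) + 2L, "GBSC", trav,
        residues = paste(sort(unique(seq_chars(unit))), collapse = ","),
        unit = unit)
    }
  }
  sort_regions(do.call(bind_regions, out))
}

#' Run GBSC on a sequence
#'
#' @param record a `seq_record`.
#' @param params a `gbsc_params`.
#' @return an `lcr_regions` table (method `GBSC`), sorted by start; records
#'   shorter than 3 residues yield an empty result with a notice.
#' @export
run_gbsc <- function(record, params = gbsc_params()) {
  if (nchar(record$residues) < 3) {
    message("gbsc: record '", record$id, "' shorter than 3 residues; skipped")
    return(empty_regions())
  }
  extract_repeats(build_kmer_graph(record), record, params)
}
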