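#' Create a validated protein sequence record
#'
#' @param id record identifier (no whitespace).
#' @param residues residue string; lowercase is uppercased, a trailing `*`
#'   stop is stripped, and the ambiguity codes B, Z, U, O are mapped to `X`
#'   (with a warning). After normalization every character must be one of the
#'   20 canonical amino-acid letters or `X`.
#' @param description free-text description (rest of the FASTA header).
#' @return a list of class `seq_record` with elements `id`, `description`,
#'   `residues`.
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1 || !nzchar(id) || grepl("\\s", id))
    stop_lcr("record id must be a non-empty token without whitespace")
  residues <- toupper(residues)
  residues <- sub("\\*$", "", residues)
  if (grepl("[BZUO]", residues)) {
    warning("record '", id, "': ambiguity codes B/Z/U/O mapped to 'X'",
            call. = FALSE)
    residues <- chartr("BZUO", "XXXX", residues)
  }
  if (!nzchar(residues))
    stop_lcr("record '", id, "': empty sequence")
  chars <- seq_chars(residues)
  bad <- which(!(chars %in% AA_ALPHABET_FULL))
  if (length(bad) > 0)
    stop_lcr("record '", id, "': invalid residue '", chars[bad[1]],
             "' at position ", bad[1])
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(">", x$id, if (nzchar(x$description)) paste0(" ", x$description), "\n",
      sep = "")
  cat(substr(x$residues, 1, 60),
      if (nchar(x$residues) > 60) "..." else "", "  (",
      nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order and normalized through [seq_record()]:
#' residues uppercased, trailing `*` stripped, B/Z/U/O mapped to `X` with a
#' warning. Duplicate identifiers and residues outside the accepted alphabet
#' are errors.
#'
#' @param source path to a FASTA file, a connection, or a character vector of
#'   FASTA-formatted lines.
#' @return a named list of `seq_record` objects.
#' @export
read_fasta <- function(source) {
  if (inherits(source, "connection")) {
    lines <- readLines(source)
  } else if (is.character(source) && length(source) == 1 &&
             !grepl("\n", source) && !startsWith(source, ">")) {
    if (!file.exists(source)) stop_lcr("cannot read '", source, "'")
    lines <- readLines(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  set <- tryCatch(Biostrings::readBStringSet(tf),
                  error = function(e) stop_lcr("FASTA parse error: ",
                                               conditionMessage(e)))
  if (length(set) == 0) stop_lcr("no records")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop_lcr("duplicate record id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs <- lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]), desc[i])
  })
  names(recs) <- ids
  recs
}

#' Write sequence records as FASTA
#'
#' @param records a `seq_record` or list of them.
#' @param path output file path or connection.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (inherits(records, "seq_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description)) paste0(">", r$id, " ", r$description)
              else paste0(">", r$id)
    body <- substring(r$residues,
                      seq(1, nchar(r$residues), by = width),
                      pmin(seq(1, nchar(r$residues), by = width) + width - 1,
                           nchar(r$residues)))
    c(header, body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Format detected regions as TSV, GFF3 or per-region FASTA
#'
#' @param regions an `lcr_regions` table.
#' @param format `"tsv"`, `"gff3"` or `"fasta"`.
#' @param sequences named list of `seq_record` (required to resolve region
#'   coordinates; mandatory for `"fasta"`).
#' @return a character vector of output lines.
#' @details TSV columns are `seq_id start end method score residues unit`
#'   with `-` for empty residue sets and absent units. GFF3 uses the method
#'   as source, type `low_complexity_region` and 1-based inclusive
#'   coordinates. FASTA emits one record per region with header
#'   `><seq_id>/<start>-<end> method=<method>`.
#' @export
write_regions <- function(regions, format = c("tsv", "gff3", "fasta"),
                          sequences = NULL) {
  if (!is.character(format) || length(format) < 1 ||
      !(format[1] %in% c("tsv", "gff3", "fasta")))
    stop_lcr("unknown region output format: ",
             paste(format[1], collapse = ""))
  format <- format[1]
  if (!is.null(sequences) || format == "fasta" || nrow(regions) > 0) {
    if (format == "fasta" && is.null(sequences))
      stop_lcr("fasta region output requires the source sequences")
  }
  if (!is.null(sequences) && nrow(regions) > 0) {
    lens <- vapply(sequences, function(r) nchar(r$residues), integer(1))
    miss <- setdiff(unique(regions$seq_id), names(sequences))
    if (length(miss) > 0)
      stop_lcr("region(s) reference unknown sequence id(s): ",
               paste(miss, collapse = ", "))
    bad <- regions$end > lens[regions$seq_id]
    if (any(bad))
      stop_lcr("region out of bounds for sequence '",
               regions$seq_id[which(bad)[1]], "'")
  }
  res_out <- ifelse(nzchar(regions$residues), regions$residues, "-")
  unit_out <- ifelse(is.na(regions$unit) | !nzchar(regions$unit), "-",
                     regions$unit)
  if (format == "tsv") {
    header <- "seq_id\tstart\tend\tmethod\tscore\tresidues\tunit"
    if (nrow(regions) == 0) return(header)
    body <- paste(regions$seq_id, regions$start, regions$end, regions$method,
                  format_score(regions$score), res_out, unit_out, sep = "\t")
    return(c(header, body))
  }
  if (format == "gff3") {
    header <- "##gff-version 3"
    if (nrow(regions) == 0) return(header)
    attrs <- paste0("ID=", regions$method, "_", regions$seq_id, "_",
                    seq_len(nrow(regions)))
    attrs <- ifelse(res_out != "-",
                    paste0(attrs, ";residues=", res_out), attrs)
    attrs <- ifelse(unit_out != "-",
                    paste0(attrs, ";unit=", unit_out), attrs)
    body <- paste(regions$seq_id, regions$method, "low_complexity_region",
                  regions$start, regions$end, format_score(regions$score),
                  ".", ".", attrs, sep = "\t")
    return(c(header, body))
  }
  # fasta
  if (nrow(regions) == 0) return(character())
  unlist(lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    subseq <- substr(sequences[[r$seq_id]]$residues, r$start, r$end)
    body <- substring(subseq, seq(1, nchar(subseq), by = 60),
                      pmin(seq(1, nchar(subseq), by = 60) + 59, nchar(subseq)))
    c(sprintf(">%s/%d-%d method=%s", r$seq_id, r$start, r$end, r$method), body)
  }))
}

#' Parse a regions TSV written by [write_regions()]
#'
#' @param path file path (or character vector of lines).
#' @return an `lcr_regions` table.
#' @export
read_regions_tsv <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  if (length(lines) == 0 || lines[1] != "seq_id\tstart\tend\tmethod\tscore\tresidues\tunit")
    stop_lcr("not a lcrtools region TSV (bad or missing header)")
  if (length(lines) == 1) return(empty_regions())
  df <- utils::read.delim(text = lines, header = TRUE,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "character"))
  lcr_regions(df$seq_id, df$start, df$end, df$method, df$score,
              ifelse(df$residues == "-", "", df$residues),
              ifelse(df$unit == "-", NA_character_, df$unit))
}

#' Mask detected regions in a sequence
#'
#' @param record a `seq_record`.
#' @param regions `lcr_regions` referencing `record$id` (rows for other
#'   sequences are ignored).
#' @param style `"x"` replaces covered positions with `X`; `"lower"`
#'   lowercases them (display only).
#' @return a new masked `seq_record`; the input is not modified.
#' @export
mask_sequence <- function(record, regions, style = c("x", "lower")) {
  style <- match.arg(style)
  regions <- regions[regions$seq_id == record$id, , drop = FALSE]
  L <- nchar(record$residues)
  if (nrow(regions) > 0 && (any(regions$start < 1) || any(regions$end > L)))
    stop_lcr("region out of bounds for sequence '", record$id, "'")
  if (nrow(regions) == 0) return(record)
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(regions)))
    covered[regions$start[i]:regions$end[i]] <- TRUE
  chars <- seq_chars(record$residues)
  if (style == "x") {
    chars[covered] <- "X"
  } else {
    chars[covered] <- tolower(chars[covered])
  }
  out <- record
  out$residues <- paste(chars, collapse = "")
  out
}
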