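# Shared constants and small internal helpers.

# The 20 canonical amino acids, alphabetical. 'X' is the unknown-residue
# placeholder: it is never a bias residue, never seeds a motif, and scores 0
# against every homopolymer target.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_ALPHABET_FULL <- c(AA20, "X")

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Integer codes 1..20 for canonical residues, NA for 'X'.
#' @noRd
seq_codes <- function(chars) {
  m <- match(chars, AA20)
  m
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so library calls never perturb a user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Number formatter for region tables: full precision up to 6 significant
# digits, always with a decimal point (so integer-valued scores print "40.0").
#' @noRd
format_score <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- format(v, digits = 6, trim = TRUE, scientific = FALSE)
    if (!grepl(".", s, fixed = TRUE)) s <- paste0(s, ".0")
    s
  }, character(1))
}

#' @noRd
stop_lcr <- function(...) stop(..., call. = FALSE)
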