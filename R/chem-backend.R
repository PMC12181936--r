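# Thin wrappers around Open Babel (via ChemmineOB). Everything here is
# vectorized over character SMILES and NA-safe: unparseable input yields NA
# rather than an error, so callers decide how strict to be.

#' @importFrom ChemmineOB convertFormat forEachMol smartsSearch_OB fingerprint_OB prop_OB
NULL

# Parse a single SMILES into an Open Babel molecule reference, or NULL.
chem_parse_one <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, function(m) m, reduce = c)),
    error = function(e) NULL
  )
}

chem_parse <- function(smiles) {
  purrr::map(smiles, chem_parse_one)
}

chem_is_parseable <- function(smiles) {
  !purrr::map_lgl(chem_parse(smiles), is.null)
}

# First whitespace-delimited token of an Open Babel conversion, or NA if the
# conversion produced nothing (parse failure).
ob_first_token <- function(x) {
  x <- trimws(x)
  if (!nzchar(x)) return(NA_character_)
  strsplit(x, "[ \t\n]+")[[1]][1]
}

#' Canonical SMILES via Open Babel
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where input could not be
#'   parsed.
#' @keywords internal
chem_canonical <- function(smiles) {
  purrr::map_chr(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    ob_first_token(out)
  })
}

#' Hashed structure keys (InChIKey)
#'
#' 27-character hashed InChIKeys used for constitutional deduplication.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of InChIKeys, `NA` where unparseable.
#' @keywords internal
chem_inchikey <- function(smiles) {
  purrr::map_chr(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHIKEY", s)),
      error = function(e) ""
    )
    key <- ob_first_token(out)
    if (!is.na(key) && nchar(key) != 27L) key <- NA_character_
    key
  })
}

# Count of SMARTS matches per SMILES (NA where unparseable).
chem_smarts_count <- function(smiles, smarts) {
  mols <- chem_parse(smiles)
  purrr::map_dbl(mols, function(m) {
    if (is.null(m)) return(NA_real_)
    tryCatch(
      as.numeric(ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE)[[1]]),
      error = function(e) NA_real_
    )
  })
}

chem_smarts_match <- function(smiles, smarts) {
  chem_smarts_count(smiles, smarts) > 0
}

# Molecular formula (e.g. "C8HF15O2"), NA where unparseable.
chem_formula <- function(smiles) {
  mols <- chem_parse(smiles)
  purrr::map_chr(mols, function(m) {
    if (is.null(m)) return(NA_character_)
    tryCatch(as.character(ChemmineOB::prop_OB(list(m))$formula), error = function(e) NA_character_)
  })
}

# Carbon count and molecular weight parsed from a formula string; used to rank
# components when stripping salts.
formula_carbon_count <- function(formula) {
  purrr::map_int(formula, function(f) {
    if (is.na(f)) return(NA_integer_)
    m <- stringr::str_match(f, "C(?![a-z])([0-9]*)")
    if (is.na(m[1, 1])) return(0L)
    n <- m[1, 2]
    if (is.na(n) || !nzchar(n)) 1L else as.integer(n)
  })
}

chem_mw <- function(smiles) {
  mols <- chem_parse(smiles)
  purrr::map_dbl(mols, function(m) {
    if (is.null(m)) return(NA_real_)
    tryCatch(as.numeric(ChemmineOB::prop_OB(list(m))$MW), error = function(e) NA_real_)
  })
}

# Raw ECFP6 (radius 3) fingerprints as a 0/1 matrix with one row per parseable
# SMILES; attribute "parsed" flags which inputs parsed. Computed by a single
# batched call to the Open Babel command-line tool (constant memory however
# large the landscape); 4096-bit vectors are folded in morgan_fingerprints().
# Input rows are realigned by numeric molecule titles, so structures the
# toolkit skips are detected rather than silently shifting rows.
chem_ecfp6 <- function(smiles) {
  n <- length(smiles)
  usable <- which(!is.na(smiles) & nzchar(smiles))
  parsed <- rep(FALSE, n)
  empty <- function() {
    out <- matrix(integer(0), nrow = 0, ncol = 4096)
    attr(out, "parsed") <- parsed
    out
  }
  if (length(usable) == 0) return(empty())
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file), add = TRUE)
  writeLines(paste(smiles[usable], usable), smi_file)
  out_lines <- suppressWarnings(system2(
    "obabel", c(smi_file, "-ofpt", "-xfECFP6", "-xh"),
    stdout = TRUE, stderr = FALSE
  ))
  headers <- grep("^>", out_lines)
  if (length(headers) == 0) return(empty())
  idx <- as.integer(sub("^>(\\S+).*$", "\\1", out_lines[headers]))
  block_end <- c(headers[-1] - 1, length(out_lines))
  rows <- matrix(0L, nrow = length(headers), ncol = 4096)
  for (h in seq_along(headers)) {
    if (block_end[h] <= headers[h]) next
    block <- trimws(out_lines[(headers[h] + 1):block_end[h]])
    block <- block[grepl("^([0-9a-fA-F]{8} ?)+$", block)]  # drop annotations
    words <- unlist(strsplit(block, "\\s+"))
    if (length(words) * 32 != ncol(rows)) {
      stop("unexpected fingerprint block size from obabel", call. = FALSE)
    }
    rows[h, ] <- decode_hex_words(words)
  }
  parsed[idx] <- TRUE
  rows <- rows[order(idx), , drop = FALSE]
  attr(rows, "parsed") <- parsed
  rows
}

# 8-hex-digit words -> 0/1 vector, 32 bits per word, low bit first within
# each 16-bit half (a fixed convention; only consistency matters).
decode_hex_words <- function(words) {
  hi <- strtoi(substr(words, 1, 4), 16L)
  lo <- strtoi(substr(words, 5, 8), 16L)
  halves <- as.vector(rbind(lo, hi))
  bits <- vapply(0:15, function(j) bitwAnd(bitwShiftR(halves, j), 1L),
                 integer(length(halves)))
  as.integer(t(bits))
}
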