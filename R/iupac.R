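# IUPAC degenerate nucleotide handling.

# Allowed letters per IUPAC code, taken from Biostrings' map so the package
# and the scanner agree on semantics (W = A/T, N = any, ...).
iupac_letters <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  strsplit(map[[code]], "")[[1]]
}

check_iupac <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L)
    stop("motif pattern must be a single non-empty string", call. = FALSE)
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- setdiff(unique(chars), names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop(sprintf("invalid IUPAC code(s) in motif pattern: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  pattern
}

# Draw a concrete ACGT realization of an IUPAC pattern (uniform over the
# letters each code allows). Uses the current RNG stream.
realize_iupac <- function(pattern) {
  chars <- strsplit(check_iupac(pattern), "")[[1]]
  paste(vapply(chars, function(cc) {
    letters <- iupac_letters(cc)
    if (length(letters) == 1L) letters else sample(letters, 1L)
  }, character(1)), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
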