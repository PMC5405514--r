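# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET_STRICT <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
  "P", "S", "T", "W", "Y", "V"
)
AA_ALPHABET <- c(AA_ALPHABET_STRICT, "X", "*")
NT_ALPHABET <- c(
  "A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M", "B", "D", "H",
  "V", "N"
)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Split a sequence string into single characters
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_alphabet <- function(seq, moltype, id = "<sequence>") {
  cs <- unique(chars(toupper(seq)))
  ok <- switch(moltype,
    nt = cs %in% NT_ALPHABET,
    aa = cs %in% AA_ALPHABET
  )
  if (!all(ok)) {
    stopf(
      "sequence '%s' contains characters invalid for moltype '%s': %s",
      id, moltype, paste(cs[!ok], collapse = ", ")
    )
  }
  invisible(TRUE)
}

#' Reverse-complement a nucleotide string
#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Translate one codon; any codon containing an ambiguity code gives 'X'.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

is_gap <- function(x) x == "-" | x == "."

# sample() that never falls into the 1:x expansion for length-1 input
resample <- function(x, size = 1L, ...) x[sample.int(length(x), size, ...)]

#' Degap an aligned string
#' @noRd
degap <- function(x) gsub("[-.]", "", x)
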