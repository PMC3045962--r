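NT <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide strings to amino acids
#'
#' Sequences must have length divisible by 3 and contain no N.
#' Stop codons are rendered as `*`.
#'
#' @param x character vector of in-frame DNA sequences.
#' @return character vector of amino-acid strings.
#' @export
translate_nt <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x)))
}

## decode a phred string to integer qualities
decode_quals <- function(qual, offset = 33L) {
  utf8ToInt(qual) - as.integer(offset)
}

encode_quals <- function(q, offset = 33L) {
  intToUtf8(as.integer(q) + as.integer(offset))
}

## minimum phred over a quality string; vectorised
min_qual <- function(qual, offset = 33L) {
  vapply(qual, function(s) {
    if (nchar(s) == 0L) return(NA_integer_)
    min(utf8ToInt(s)) - as.integer(offset)
  }, integer(1), USE.NAMES = FALSE)
}

## reverse each string in a character vector
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

is_nt_string <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}
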