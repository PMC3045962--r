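#' Read a FASTQ file
#'
#' Reads standard 4-line FASTQ records. Qualities are kept as the raw
#' quality string; decode with the chosen offset downstream (phred+33 is the
#' modern default; a phred+64 switch is provided for legacy instruments).
#'
#' @param path FASTQ file, plain or gzipped.
#' @return data.frame with columns `read_id`, `seq`, `qual`, `lane`,
#'   `sample_path` (lane/sample are `NA` unless encoded elsewhere).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ: ", n, " lines is not a multiple of 4")
  if (n == 0L)
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), lane = integer(0),
                      sample_path = character(0)))
  hdr <- seq(1L, n, by = 4L)
  bad <- which(substr(lines[hdr], 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ record: header at line ", hdr[bad[1]],
         " does not start with '@'")
  plus <- hdr + 2L
  bad <- which(substr(lines[plus], 1L, 1L) != "+")
  if (length(bad))
    stop("malformed FASTQ record: separator at line ", plus[bad[1]],
         " does not start with '+'")
  seq <- lines[hdr + 1L]
  qual <- lines[hdr + 3L]
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record: sequence/quality length mismatch at line ",
         hdr[bad[1]])
  data.frame(
    read_id = sub("\\s.*$", "", substring(lines[hdr], 2L)),
    seq = seq, qual = qual, lane = NA_integer_,
    sample_path = NA_character_, stringsAsFactors = FALSE)
}

#' Trim exact adapter sequences from read ends
#'
#' Removes a single exact occurrence of each 5' adapter at the read start and
#' each 3' adapter at the read end; qualities are trimmed in lockstep. Reads
#' without a terminal exact match are returned unchanged.
#'
#' @param reads data.frame with `seq` and `qual` columns (as from
#'   [read_fastq()]).
#' @param adapter_5p,adapter_3p adapter strings (`""` disables).
#' @return the reads data.frame with trimmed `seq`/`qual`.
#' @export
trim_adapters <- function(reads, adapter_5p = "", adapter_3p = "") {
  if (nzchar(adapter_5p)) {
    k <- nchar(adapter_5p)
    hit <- nchar(reads$seq) >= k &
      substr(reads$seq, 1L, k) == adapter_5p
    reads$seq[hit] <- substring(reads$seq[hit], k + 1L)
    reads$qual[hit] <- substring(reads$qual[hit], k + 1L)
  }
  if (nzchar(adapter_3p)) {
    k <- nchar(adapter_3p)
    len <- nchar(reads$seq)
    hit <- len >= k & substr(reads$seq, len - k + 1L, len) == adapter_3p
    reads$seq[hit] <- substr(reads$seq[hit], 1L, len[hit] - k)
    reads$qual[hit] <- substr(reads$qual[hit], 1L, len[hit] - k)
  }
  reads
}
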