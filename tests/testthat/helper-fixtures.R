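# small template for fast tests: 6 nt CDR3 in a 40 nt amplicon
tiny_template <- function() {
  template_spec("tiny", v_flank = "GCTTGT", cdr3 = "GCAACA",
                j_flank = "TTTGGAGCAGGA", read_length = 40L)
}

noerr_model <- function(...) {
  error_model(sub_rate = 0, indel_rate = c(deletion = 0, insertion = 0), ...)
}

# rate matrix that is zero outside the CDR3 window (keeps acceptance ~100%)
cdr3_only_matrix <- function(template, rate) {
  m <- matrix(0, nrow = template$length, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  win <- seq.int(template$cdr3_start + 1L, template$cdr3_end)
  m[win, ] <- rate
  ref <- strsplit(template$seq, "")[[1]]
  m[cbind(seq_len(nrow(m)), match(ref, c("A", "C", "G", "T")))] <- 0
  m
}

# brute-force all-pairs Hamming-distance-1 scan (oracle for the indexed search)
brute_hamming1_pairs <- function(seqs) {
  n <- length(seqs)
  out_i <- integer(0); out_j <- integer(0)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (nchar(seqs[i]) != nchar(seqs[j])) next
    if (sum(utf8ToInt(seqs[i]) != utf8ToInt(seqs[j])) == 1L) {
      out_i <- c(out_i, i); out_j <- c(out_j, j)
    }
  }
  data.frame(i = out_i, j = out_j)
}

# direct pmf-summation oracle for the exact binomial boundaries
boundaries_oracle <- function(n, p, tail = 0.01) {
  pmf <- dbinom(0:n, n, p)
  cdf <- cumsum(pmf)
  upper <- 0L
  while (upper < n && sum(pmf[(upper + 2L):(n + 1L)]) >= tail)
    upper <- upper + 1L
  lower <- n
  while (lower > 0L && cdf[lower] >= tail) lower <- lower - 1L
  c(lower = lower, upper = upper)
}

# parse simulator truth error tokens into a long data.frame
parse_truth_errors <- function(truth) {
  rows <- which(truth$errors != "")
  if (!length(rows))
    return(data.frame(read_id = character(0), position = integer(0),
                      from = character(0), to = character(0)))
  tok <- strsplit(truth$errors[rows], ";", fixed = TRUE)
  rid <- rep(truth$read_id[rows], lengths(tok))
  tok <- unlist(tok)
  m <- regmatches(tok, regexec("^(\\d+):([ACGT])>([ACGT])$", tok))
  data.frame(read_id = rid,
             position = as.integer(vapply(m, `[`, character(1), 2L)),
             from = vapply(m, `[`, character(1), 3L),
             to = vapply(m, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}
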