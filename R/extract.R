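REJECTION_REASONS <- c("no_flank_match", "v_mismatch", "j_mismatch",
                       "out_of_frame", "stop_codon", "contains_N",
                       "motif_fail", "low_quality")

#' Define the V/J mapping flanks
#'
#' The mapping segments immediately external to the CDR3: the V-side segment
#' ends with the conserved cysteine codon and the J-side segment begins with
#' the conserved F/H codon of an FGXG, FAXG or HGXG motif. Extraction demands
#' 100% identity with both segments, so the conserved-residue criterion is
#' enforced structurally through flank identity; set `check_motif = FALSE`
#' only for flanks that do not carry the conserved codons.
#'
#' @param v_segment V-side mapping segment (typically 25-30 nt).
#' @param j_segment J-side mapping segment (typically 27 nt).
#' @param check_motif validate the conserved C / FGXG-family codons at
#'   construction (default TRUE).
#' @return object of class `flank_spec`.
#' @export
flank_spec <- function(v_segment, j_segment, check_motif = TRUE) {
  stopifnot(nzchar(v_segment), nzchar(j_segment),
            is_nt_string(v_segment), is_nt_string(j_segment))
  if (check_motif) {
    if (nchar(v_segment) < 3L || nchar(j_segment) < 12L)
      stop("flanks carrying the conserved codons need >= 3 / >= 12 nt")
    v_last <- substr(v_segment, nchar(v_segment) - 2L, nchar(v_segment))
    if (translate_nt(v_last) != "C")
      stop("v_segment does not end in a cysteine codon")
    if (!grepl("^(F[GA].G|HG.G)$", translate_nt(substr(j_segment, 1L, 12L))))
      stop("j_segment does not begin with an FGXG/FAXG/HGXG motif")
  }
  structure(list(v_segment = v_segment, j_segment = j_segment,
                 check_motif = check_motif), class = "flank_spec")
}

#' Flanks matching a simulation template
#'
#' @param template a `template_spec`.
#' @return `flank_spec` using the template's full V/J flanks.
#' @export
template_flanks <- function(template) {
  flank_spec(template$v_flank, template$j_flank)
}

#' Locate V/J flanks and infer read orientation
#'
#' Searches the read for an exact occurrence of the V segment followed
#' (non-overlapping, 5'-to-3') by an exact occurrence of the J segment; if
#' neither orientation matches, the read is unassignable. Exact matching
#' means any N inside a flank fails. Leftmost matches are taken.
#'
#' @param seq a single read sequence.
#' @param flanks a `flank_spec`.
#' @return list with `orientation` (`"forward"`/`"reverse"`), `v_end` and
#'   `j_start` (0-based half-open CDR3-bounding indices in the oriented
#'   read), and `oriented_seq`; or `NULL` if no orientation matches.
#' @export
orient_and_match <- function(seq, flanks) {
  .try <- function(s) {
    v <- as.integer(regexpr(flanks$v_segment, s, fixed = TRUE))
    if (v < 0L) return(NULL)
    v_end <- v + nchar(flanks$v_segment) - 1L      # 1-based inclusive
    rest <- substring(s, v_end + 1L)
    j <- as.integer(regexpr(flanks$j_segment, rest, fixed = TRUE))
    if (j < 0L) return(NULL)
    list(v_end = v_end, j_start = v_end + j - 1L)  # 0-based
  }
  m <- .try(seq)
  if (!is.null(m))
    return(list(orientation = "forward", v_end = m$v_end,
                j_start = m$j_start, oriented_seq = seq))
  rc <- revcomp(seq)
  m <- .try(rc)
  if (!is.null(m))
    return(list(orientation = "reverse", v_end = m$v_end,
                j_start = m$j_start, oriented_seq = rc))
  NULL
}

#' Extract and validate CDR3 sequences from reads
#'
#' Applies, in order: flank matching with orientation detection (100%
#' identity required for both V and J segments), reading-frame check on the
#' inter-flank span, N check, stop-codon check, and (when the flanks do not
#' carry the conserved codons) the conserved C / FGXG-family motif check on
#' the flank-adjacent codons. Each read yields exactly one row, either a
#' CDR3 record or a rejection with the first failing criterion.
#'
#' @param reads data.frame from [read_fastq()] or a `cdr3_sim$reads`.
#' @param flanks a `flank_spec`.
#' @param phred_offset quality encoding offset (33 modern, 64 legacy).
#' @return list with `records` (data.frame: read_id, cdr3_nt, cdr3_qual,
#'   orientation, lane, sample_path, min_q) and `rejects` (data.frame:
#'   read_id, reason).
#' @export
extract_cdr3 <- function(reads, flanks, phred_offset = 33L) {
  stopifnot(inherits(flanks, "flank_spec"))
  n <- nrow(reads)
  match_batch <- function(seqs) {
    v <- regexpr(flanks$v_segment, seqs, fixed = TRUE)
    v_end <- ifelse(v > 0L, v + nchar(flanks$v_segment) - 1L, NA_integer_)
    rest <- ifelse(v > 0L, substring(seqs, v_end + 1L), "")
    j <- regexpr(flanks$j_segment, rest, fixed = TRUE)
    # v_end doubles as the 0-based CDR3 start; j_start is its 0-based end
    data.frame(v_end = v_end,
               j_start = ifelse(v > 0L & j > 0L, v_end + as.integer(j) - 1L,
                                NA_integer_))
  }
  mf <- match_batch(reads$seq)
  rc <- if (n) revcomp(reads$seq) else character(0)
  mr <- match_batch(rc)
  is_fwd <- !is.na(mf$j_start)
  is_rev <- !is_fwd & !is.na(mr$j_start)
  orient <- ifelse(is_fwd, "forward", ifelse(is_rev, "reverse", NA))
  oseq <- ifelse(is_fwd, reads$seq, rc)
  v_end <- ifelse(is_fwd, mf$v_end, mr$v_end)
  j_start <- ifelse(is_fwd, mf$j_start, mr$j_start)

  reason <- rep(NA_character_, n)
  reason[!is_fwd & !is_rev] <- "no_flank_match"
  live <- is.na(reason)
  span <- rep(NA_character_, n)
  span[live] <- substring(oseq[live], v_end[live] + 1L, j_start[live])
  fail <- live & nchar(span) %% 3L != 0L
  reason[fail] <- "out_of_frame"; live <- live & !fail
  fail <- live & grepl("N", span, fixed = TRUE)
  reason[fail] <- "contains_N"; live <- live & !fail
  tr_idx <- which(live & nchar(span) > 0L)
  if (length(tr_idx)) {
    fail <- tr_idx[grepl("\\*", translate_nt(span[tr_idx]))]
    reason[fail] <- "stop_codon"; live[fail] <- FALSE
  }
  if (!flanks$check_motif) {
    # conserved codons live on the read, adjacent to the matched flanks
    for (i in which(live)) {
      cctx <- substring(oseq[i], v_end[i] - 2L, v_end[i])
      jctx <- substring(oseq[i], j_start[i] + 1L, j_start[i] + 12L)
      if (nchar(cctx) < 3L || nchar(jctx) < 12L ||
          grepl("N", paste0(cctx, jctx), fixed = TRUE) ||
          translate_nt(cctx) != "C" ||
          !grepl("^(F[GA].G|HG.G)$", translate_nt(jctx))) {
        reason[i] <- "motif_fail"; live[i] <- FALSE
      }
    }
  }
  ok <- live
  cdr3 <- span
  q <- reads$qual
  rev_ok <- which(ok & orient == "reverse")
  q[rev_ok] <- str_rev(q[rev_ok])
  cq <- rep(NA_character_, n)
  cq[ok] <- substring(q[ok], v_end[ok] + 1L, j_start[ok])
  records <- data.frame(
    read_id = reads$read_id[ok], cdr3_nt = cdr3[ok], cdr3_qual = cq[ok],
    orientation = orient[ok], lane = reads$lane[ok],
    sample_path = reads$sample_path[ok], stringsAsFactors = FALSE)
  records$min_q <- min_qual(records$cdr3_qual, offset = phred_offset)
  rejects <- data.frame(read_id = reads$read_id[!ok], reason = reason[!ok],
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Filter CDR3 records at a phred cutoff
#'
#' A record passes when every base of its CDR3 window has quality at or
#' above the cutoff; a cutoff of 0 passes everything.
#'
#' @param records CDR3 records (from [extract_cdr3()]).
#' @param q_cutoff non-negative integer phred cutoff (0, 10, 20 and 30 are
#'   the conventional grid).
#' @return list with `records` (passing rows) and `n_rejected`.
#' @export
phred_filter <- function(records, q_cutoff) {
  stopifnot(q_cutoff >= 0)
  pass <- records$min_q >= q_cutoff
  list(records = records[pass, , drop = FALSE], n_rejected = sum(!pass))
}
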