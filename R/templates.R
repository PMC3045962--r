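#' Define an amplicon template for simulation
#'
#' A template is the error-free 125 bp amplicon from which reads are drawn:
#' `pad_5p | v_flank | cdr3 | j_flank | pad_3p`. By construction the V flank
#' ends with the codon of the conserved cysteine and the J flank begins with
#' the codon of the conserved phenylalanine (or histidine) of an FGXG, FAXG or
#' HGXG motif, so the CDR3 proper (between, exclusive of, the C and F codons)
#' is `cdr3`.
#'
#' @param name template label.
#' @param v_flank V-segment flank; must end in a cysteine codon (TGT/TGC).
#' @param cdr3 CDR3 nucleotide sequence; length divisible by 3, in frame with
#'   no stop codon. Monoclonal TCR CDR3s are typically 30 or 36 nt.
#' @param j_flank J-segment flank; its first four codons must translate to
#'   FGXG, FAXG or HGXG.
#' @param pad_5p,pad_3p padding bringing the amplicon to `read_length`. When
#'   `NULL`, deterministic filler is added (5' side first).
#' @param read_length target amplicon/read length (default 125).
#' @return object of class `template_spec`.
#' @export
template_spec <- function(name, v_flank, cdr3, j_flank,
                          pad_5p = NULL, pad_3p = NULL, read_length = 125L) {
  stopifnot(is.character(name), length(name) == 1L)
  for (s in c(v_flank, cdr3, j_flank)) {
    if (!is_nt_string(s)) stop("template sequences must be over A/C/G/T")
  }
  if (nchar(v_flank) < 3L || nchar(j_flank) < 12L)
    stop("v_flank must be >= 3 nt and j_flank >= 12 nt")
  if (nchar(cdr3) %% 3L != 0L)
    stop("invalid TemplateSpec: cdr3 length not divisible by 3")
  v_last <- substr(v_flank, nchar(v_flank) - 2L, nchar(v_flank))
  if (translate_nt(v_last) != "C")
    stop("invalid TemplateSpec: v_flank does not end in a cysteine codon")
  j_start_aa <- translate_nt(substr(j_flank, 1L, 12L))
  if (!grepl("^(F[GA].G|HG.G)$", j_start_aa))
    stop("invalid TemplateSpec: j_flank does not begin with FGXG/FAXG/HGXG")
  ctx <- translate_nt(paste0(v_last, cdr3, substr(j_flank, 1L, 12L)))
  if (grepl("\\*", ctx))
    stop("invalid TemplateSpec: stop codon in CDR3 context")

  core_len <- nchar(v_flank) + nchar(cdr3) + nchar(j_flank)
  if (is.null(pad_5p) || is.null(pad_3p)) {
    pad_needed <- max(0L, read_length - core_len)
    filler <- function(n) {
      if (n == 0L) return("")
      paste(rep_len(c("A", "C", "G", "T"), n), collapse = "")
    }
    n5 <- ceiling(pad_needed / 2)
    pad_5p <- filler(n5)
    pad_3p <- filler(pad_needed - n5)
  }
  seq <- paste0(pad_5p, v_flank, cdr3, j_flank, pad_3p)

  structure(list(
    name = name, v_flank = v_flank, cdr3 = cdr3, j_flank = j_flank,
    pad_5p = pad_5p, pad_3p = pad_3p, seq = seq, length = nchar(seq),
    # 0-based half-open CDR3 window in template coordinates
    cdr3_start = nchar(pad_5p) + nchar(v_flank),
    cdr3_end = nchar(pad_5p) + nchar(v_flank) + nchar(cdr3)
  ), class = "template_spec")
}

#' @export
print.template_spec <- function(x, ...) {
  cat("<template_spec>", x$name, "\n")
  cat("  amplicon:", x$length, "nt; CDR3:", nchar(x$cdr3),
      "nt at [", x$cdr3_start, ",", x$cdr3_end, ")\n")
  cat("  cdr3:", x$cdr3, "\n")
  invisible(x)
}

#' Built-in monoclonal templates
#'
#' Two synthetic monoclonal amplicon templates emulating the study system:
#' a 36 nt CDR3 (as for 5C.C7/DO11.10-class receptors) and a 30 nt CDR3
#' (OT-1-class), each centred in a 125 bp amplicon with 27 nt V/J flanks.
#' The sequences are synthetic constructs, not database V/J alleles.
#'
#' @param which `"cdr3_36"`, `"cdr3_30"`, or `"both"`.
#' @return a `template_spec`, or a list of them for `"both"`.
#' @export
builtin_templates <- function(which = c("cdr3_36", "cdr3_30", "both")) {
  which <- match.arg(which)
  t36 <- template_spec(
    name = "mono36",
    v_flank = "GGCTCAGGGCTGCTGTTTCTCTGTGC",
    cdr3 = "GCCAGCAGTTTATCGGGACAGGGGGCTGAGCAGTTC",
    j_flank = "TTTGGGGCAGGGACCAGACTTTCAGTC"
  )
  t30 <- template_spec(
    name = "mono30",
    v_flank = "CAGTCTGCAGAGAAGGGCAGAGCTTTGT",
    cdr3 = "GCCAGCTCCGGAGGGTCAAACGAGCGATTC",
    j_flank = "TTTGGAGCAGGAACCAGACTGTCTGTG"
  )
  switch(which, cdr3_36 = t36, cdr3_30 = t30, both = list(t36, t30))
}

#' Generate a synthetic polyclonal template set
#'
#' Derives `n_clones` templates from a base template by substituting random
#' in-frame codons inside the CDR3 (avoiding stop codons), with power-law
#' clone abundances emulating a skewed polyclonal repertoire.
#'
#' @param n_clones number of clonotypes.
#' @param base base `template_spec` (default the built-in 36 nt template).
#' @param alpha power-law exponent for abundances (`freq_i` proportional to
#'   `i^-alpha`); default 1.2.
#' @param n_var number of CDR3 codons randomised per clone (default 4).
#' @return list with `templates` (list of `template_spec`) and `abundances`
#'   (numeric, sums to 1). Uses the current RNG state; call `set.seed()`
#'   first for reproducibility.
#' @export
polyclonal_templates <- function(n_clones, base = builtin_templates("cdr3_36"),
                                 alpha = 1.2, n_var = 4L) {
  stopifnot(n_clones >= 1L)
  n_codons <- nchar(base$cdr3) / 3L
  codons <- apply(expand.grid(NT, NT, NT, stringsAsFactors = FALSE), 1L,
                  paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  seen <- character(0)
  templates <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    repeat {
      cdr3 <- substring(base$cdr3,
                        3L * (seq_len(n_codons) - 1L) + 1L,
                        3L * seq_len(n_codons))
      idx <- sample.int(n_codons - 2L, min(n_var, n_codons - 2L)) + 1L
      cdr3[idx] <- sample(codons, length(idx), replace = TRUE)
      cdr3 <- paste(cdr3, collapse = "")
      if (!(cdr3 %in% seen)) break
    }
    seen <- c(seen, cdr3)
    templates[[i]] <- template_spec(
      name = sprintf("clone%04d", i),
      v_flank = base$v_flank, cdr3 = cdr3, j_flank = base$j_flank,
      pad_5p = base$pad_5p, pad_3p = base$pad_3p
    )
  }
  ab <- seq_len(n_clones)^(-alpha)
  list(templates = templates, abundances = ab / sum(ab))
}
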