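#' Specify the read error process
#'
#' Describes how substitutions, indels and base qualities are injected into
#' simulated amplicon reads. Substitution rates are per read, per template
#' position and per alternative base, optionally modulated by flow-cell lane
#' and by read orientation; base qualities are drawn from a low distribution
#' at error positions and a high one elsewhere, reproducing the association
#' between low phred scores and miscalls that makes phred filtering selective.
#'
#' @param sub_rate either a single per-position/per-alternative probability,
#'   or an `L x 4` matrix (columns A,C,G,T) of per-read substitution
#'   probabilities for a template of length `L`; entries at the template base
#'   are ignored.
#' @param direction_bias multiplier applied to substitution rates on
#'   reverse-orientation reads: a scalar or an `L x 4` matrix. Values other
#'   than 1 make the error process strand-asymmetric.
#' @param lane_multipliers list (one element per lane) of scalars or
#'   `L x 4` matrices multiplying `sub_rate`; `NULL` means no lane effect.
#' @param indel_rate named vector `c(deletion=, insertion=)`: per-read
#'   probabilities of a 1 nt deletion / insertion inside the CDR3 window.
#'   Defaults (1e-4 each) keep indels below 1% of all injected errors.
#' @param p_forward probability a read is sequenced in forward orientation.
#' @param qual_error range of phred scores drawn at error positions
#'   (uniform; default 2-25).
#' @param qual_correct_high,qual_correct_low,qual_correct_high_mass phred
#'   model at correct positions: with probability `qual_correct_high_mass`
#'   (default 0.94) a draw from `qual_correct_high` (default 30-40), else
#'   from `qual_correct_low` (default 2-29).
#' @param burst_prob probability a read is a "burst" read whose substitution
#'   rates are inflated by `burst_factor`; the default 0 gives fully
#'   independent per-position errors. A positive value correlates errors
#'   within reads, producing an excess of multi-substitution reads over the
#'   independence expectation.
#' @param burst_factor rate multiplier for burst reads (default 50).
#' @return object of class `error_model`.
#' @export
error_model <- function(sub_rate = 1e-3,
                        direction_bias = 1,
                        lane_multipliers = NULL,
                        indel_rate = c(deletion = 1e-4, insertion = 1e-4),
                        p_forward = 0.5,
                        qual_error = c(2L, 25L),
                        qual_correct_high = c(30L, 40L),
                        qual_correct_low = c(2L, 29L),
                        qual_correct_high_mass = 0.94,
                        burst_prob = 0,
                        burst_factor = 50) {
  stopifnot(all(sub_rate >= 0), all(sub_rate <= 1),
            p_forward >= 0, p_forward <= 1,
            all(indel_rate >= 0), all(indel_rate <= 1),
            burst_prob >= 0, burst_prob <= 1, burst_factor >= 0)
  if (is.null(names(indel_rate))) names(indel_rate) <- c("deletion", "insertion")
  structure(list(
    sub_rate = sub_rate, direction_bias = direction_bias,
    lane_multipliers = lane_multipliers, indel_rate = indel_rate,
    p_forward = p_forward, qual_error = as.integer(qual_error),
    qual_correct_high = as.integer(qual_correct_high),
    qual_correct_low = as.integer(qual_correct_low),
    qual_correct_high_mass = qual_correct_high_mass,
    burst_prob = burst_prob, burst_factor = burst_factor
  ), class = "error_model")
}

#' Default position-heterogeneous substitution-rate matrix
#'
#' Draws per-(position, alternative-base) rates log-uniformly over
#' `rate_range`, giving the several-hundred-fold spread between the hottest
#' and coldest position/substitution cells seen in real amplicon data, and
#' optionally boosts the four transitions (C>T, G>A, A>G, T>C) so they
#' dominate the substitution spectrum.
#'
#' @param template a `template_spec`.
#' @param rate_range range of per-cell rates (default `c(1e-5, 5e-3)`).
#' @param transition_boost multiplier applied to transition cells
#'   (default 1 = no boost).
#' @return `L x 4` rate matrix (columns A,C,G,T; template-base cells 0).
#'   Uses the current RNG state.
#' @export
random_sub_matrix <- function(template, rate_range = c(1e-5, 5e-3),
                              transition_boost = 1) {
  L <- template$length
  m <- matrix(exp(runif(L * 4L, log(rate_range[1]), log(rate_range[2]))),
              nrow = L, ncol = 4L, dimnames = list(NULL, NT))
  ref <- strsplit(template$seq, "")[[1]]
  m[cbind(seq_len(L), match(ref, NT))] <- 0
  if (transition_boost != 1) {
    partner <- c(A = "G", C = "T", G = "A", T = "C")
    m[cbind(seq_len(L), match(partner[ref], NT))] <-
      m[cbind(seq_len(L), match(partner[ref], NT))] * transition_boost
    m <- pmin(m, 0.25)
  }
  m
}

## expand a model's sub_rate to an L x 4 matrix with template-base cells zeroed
.rate_matrix <- function(model, template) {
  L <- template$length
  m <- model$sub_rate
  if (is.matrix(m)) {
    stopifnot(nrow(m) == L, ncol(m) == 4L)
    colnames(m) <- NT
  } else {
    m <- matrix(m, nrow = L, ncol = 4L, dimnames = list(NULL, NT))
  }
  ref <- strsplit(template$seq, "")[[1]]
  m[cbind(seq_len(L), match(ref, NT))] <- 0
  m
}

.apply_multiplier <- function(m, mult) {
  if (is.null(mult)) return(m)
  if (is.matrix(mult)) m * mult else m * as.numeric(mult)
}

.draw_quals <- function(n, model) {
  hi <- runif(n) < model$qual_correct_high_mass
  q <- integer(n)
  q[hi] <- sample.int(model$qual_correct_high[2] - model$qual_correct_high[1] + 1L,
                      sum(hi), replace = TRUE) + model$qual_correct_high[1] - 1L
  q[!hi] <- sample.int(model$qual_correct_low[2] - model$qual_correct_low[1] + 1L,
                       sum(!hi), replace = TRUE) + model$qual_correct_low[1] - 1L
  q
}

#' Simulate amplicon reads with ground truth
#'
#' Draws `n_reads` single-end reads from one or more templates, injecting
#' substitutions (position-, lane- and direction-specific), rare 1 nt indels,
#' and quality strings in which error bases carry low phred scores. Reads in
#' reverse orientation are emitted reverse-complemented with reversed
#' qualities; the orientation is not recorded in the read id, so downstream
#' extraction must infer it. A ground-truth row is emitted per read.
#'
#' @param templates a `template_spec` or list of them.
#' @param model an `error_model`.
#' @param n_reads total number of reads (ignored when `design` has an
#'   `n_reads` column).
#' @param abundances template sampling weights (default uniform; must sum
#'   to 1 after normalisation).
#' @param n_lanes number of lanes when no `design` is given.
#' @param design optional data.frame with columns `sample_path`, `lane` and
#'   optionally `n_reads`, one row per sequencing reaction (see
#'   [preset_study_design()]).
#' @param seed integer seed; identical seeds and configuration give
#'   byte-identical output.
#' @return object of class `cdr3_sim`: list with `reads` (data.frame:
#'   read_id, seq, qual, lane, sample_path) and `truth` (data.frame: read_id,
#'   template, orientation, lane, sample_path, errors, indels). Error tokens
#'   are `pos:from>to` with 0-based template coordinates, semicolon-joined.
#' @export
simulate_reads <- function(templates, model = error_model(), n_reads = 1000L,
                           abundances = NULL, n_lanes = 1L, design = NULL,
                           seed = 1L) {
  if (inherits(templates, "template_spec")) templates <- list(templates)
  stopifnot(length(templates) >= 1L,
            all(vapply(templates, inherits, logical(1), "template_spec")))
  if (is.null(abundances)) abundances <- rep(1 / length(templates), length(templates))
  stopifnot(length(abundances) == length(templates), all(abundances >= 0))
  abundances <- abundances / sum(abundances)
  set.seed(as.integer(seed))

  if (is.null(design)) {
    design <- data.frame(
      sample_path = "S1", lane = seq_len(n_lanes),
      n_reads = tabulate(rep_len(seq_len(n_lanes), n_reads), n_lanes))
  } else if (is.null(design$n_reads)) {
    design$n_reads <- rep_len(
      diff(round(seq(0, n_reads, length.out = nrow(design) + 1L))), nrow(design))
  }
  stopifnot(all(design$n_reads >= 0), sum(design$n_reads) > 0)
  n_total <- sum(design$n_reads)

  reads_l <- vector("list", nrow(design))
  truth_l <- vector("list", nrow(design))
  next_id <- 1L
  for (d in seq_len(nrow(design))) {
    n_d <- design$n_reads[d]
    if (n_d == 0L) next
    lane <- design$lane[d]
    spath <- design$sample_path[d]
    tmpl_idx <- sample.int(length(templates), n_d, replace = TRUE,
                           prob = abundances)
    ids <- sprintf("r%08d", seq.int(next_id, length.out = n_d))
    next_id <- next_id + n_d
    fwd <- stats::runif(n_d) < model$p_forward
    burst <- if (model$burst_prob > 0) stats::runif(n_d) < model$burst_prob
             else rep(FALSE, n_d)

    seqs <- character(n_d); quals <- character(n_d)
    errs <- character(n_d); indels <- character(n_d)
    for (ti in unique(tmpl_idx)) {
      tmpl <- templates[[ti]]
      L <- tmpl$length
      ref <- strsplit(tmpl$seq, "")[[1]]
      base_m <- .rate_matrix(model, tmpl)
      lm <- if (!is.null(model$lane_multipliers)) model$lane_multipliers[[lane]]
      base_m <- .apply_multiplier(base_m, lm)
      for (or_fwd in c(TRUE, FALSE)) for (bu in unique(burst)) {
        sel <- which(tmpl_idx == ti & fwd == or_fwd & burst == bu)
        if (length(sel) == 0L) next
        m <- base_m
        if (!or_fwd) m <- .apply_multiplier(m, model$direction_bias)
        if (bu) m <- m * model$burst_factor
        m <- pmin(m, 0.999)
        p_tot <- rowSums(m)
        if (any(p_tot >= 1)) stop("per-position total substitution probability >= 1")
        n_s <- length(sel)
        # per-position Bernoulli draws across the subgroup
        err_read <- integer(0); err_pos <- integer(0)
        for (j in which(p_tot > 0)) {
          hit <- which(stats::runif(n_s) < p_tot[j])
          if (length(hit)) {
            err_read <- c(err_read, hit)
            err_pos <- c(err_pos, rep.int(j, length(hit)))
          }
        }
        to_nt <- character(length(err_pos))
        for (k in seq_along(err_pos)) {
          j <- err_pos[k]
          to_nt[k] <- sample(NT, 1L, prob = m[j, ] / p_tot[j])
        }
        # assemble sequences and truth for this subgroup
        sub_seq <- rep.int(tmpl$seq, n_s)
        sub_err <- rep.int("", n_s)
        if (length(err_read)) {
          ord <- order(err_read, err_pos)
          err_read <- err_read[ord]; err_pos <- err_pos[ord]; to_nt <- to_nt[ord]
          for (k in seq_along(err_read)) {
            i <- err_read[k]; j <- err_pos[k]
            substr(sub_seq[i], j, j) <- to_nt[k]
          }
          tok <- sprintf("%d:%s>%s", err_pos - 1L, ref[err_pos], to_nt)
          sub_err <- vapply(split(tok, factor(err_read, levels = seq_len(n_s))),
                            paste, character(1), collapse = ";")
        }
        # qualities: correct distribution everywhere, low draws at error bases
        qmat <- matrix(.draw_quals(n_s * L, model), nrow = L)
        if (length(err_read)) {
          qmat[cbind(err_pos, err_read)] <-
            sample.int(model$qual_error[2] - model$qual_error[1] + 1L,
                       length(err_read), replace = TRUE) + model$qual_error[1] - 1L
        }
        # bulk-encode quality strings (column-major: read i at [(i-1)L+1, iL])
        long_q <- encode_quals(as.vector(qmat))
        sub_qual <- substring(long_q, (seq_len(n_s) - 1L) * L + 1L,
                              seq_len(n_s) * L)
        # rare 1 nt indels inside the CDR3 window
        sub_ind <- rep.int("", n_s)
        del <- which(stats::runif(n_s) < model$indel_rate[["deletion"]])
        ins <- setdiff(which(stats::runif(n_s) < model$indel_rate[["insertion"]]),
                       del)
        for (i in del) {
          j <- sample(seq.int(tmpl$cdr3_start + 1L, tmpl$cdr3_end), 1L)
          sub_seq[i] <- paste0(substr(sub_seq[i], 1L, j - 1L),
                               substr(sub_seq[i], j + 1L, L))
          sub_qual[i] <- encode_quals(qmat[-j, i])
          sub_ind[i] <- sprintf("del@%d", j - 1L)
        }
        for (i in ins) {
          j <- sample(seq.int(tmpl$cdr3_start + 1L, tmpl$cdr3_end), 1L)
          sub_seq[i] <- paste0(substr(sub_seq[i], 1L, j),
                               substr(sub_seq[i], j, j),
                               substr(sub_seq[i], j + 1L, L))
          sub_qual[i] <- encode_quals(
            qmat[c(seq_len(j), j, seq.int(j + 1L, L)), i])
          sub_ind[i] <- sprintf("ins@%d", j - 1L)
        }
        if (!or_fwd) {
          sub_seq <- revcomp(sub_seq)
          sub_qual <- str_rev(sub_qual)
        }
        seqs[sel] <- sub_seq; quals[sel] <- sub_qual
        errs[sel] <- sub_err; indels[sel] <- sub_ind
      }
    }
    tnames <- vapply(templates, `[[`, character(1), "name")
    reads_l[[d]] <- data.frame(
      read_id = ids, seq = seqs, qual = quals, lane = lane,
      sample_path = spath, stringsAsFactors = FALSE)
    truth_l[[d]] <- data.frame(
      read_id = ids, template = tnames[tmpl_idx],
      orientation = ifelse(fwd, "forward", "reverse"), lane = lane,
      sample_path = spath, errors = errs, indels = indels,
      stringsAsFactors = FALSE)
  }
  out <- list(reads = do.call(rbind, reads_l), truth = do.call(rbind, truth_l))
  rownames(out$reads) <- rownames(out$truth) <- NULL
  stopifnot(nrow(out$reads) == n_total, nrow(out$truth) == n_total)
  class(out) <- "cdr3_sim"
  out
}

#' @export
print.cdr3_sim <- function(x, ...) {
  n_err <- sum(x$truth$errors != "" | x$truth$indels != "")
  cat("<cdr3_sim>", nrow(x$reads), "reads,",
      length(unique(x$truth$template)), "template(s),",
      length(unique(x$reads$lane)), "lane(s);",
      n_err, "reads carry injected errors\n")
  invisible(x)
}

#' Trifurcated 27-reaction study design
#'
#' Emulates a design in which cDNA is split into 3 preparations, each split
#' into 3 ligation paths, each sequenced in 3 flow-cell lanes: 27 independent
#' sequencing reactions per template (9 samples per lane, 3 lanes). Only the
#' lane factor carries a systematic rate multiplier, reproducing a lane
#' effect larger than sample-preparation effects.
#'
#' @param n_reads_per_reaction reads per reaction (default 1000).
#' @param lane_multipliers numeric length-3 vector of per-lane substitution
#'   rate multipliers (default `c(1, 1.6, 0.6)`).
#' @return list with `design` (27-row data.frame: sample_path, lane,
#'   n_reads) and `lane_multipliers` (list form, for [error_model()]).
#' @export
preset_study_design <- function(n_reads_per_reaction = 1000L,
                                lane_multipliers = c(1, 1.6, 0.6)) {
  stopifnot(length(lane_multipliers) == 3L)
  g <- expand.grid(prep = 1:3, ligation = 1:3, lane = 1:3)
  design <- data.frame(
    sample_path = sprintf("P%d.L%d", g$prep, g$ligation),
    lane = g$lane, n_reads = n_reads_per_reaction)
  list(design = design, lane_multipliers = as.list(lane_multipliers))
}

#' Write simulated reads as FASTQ (and truth as TSV)
#'
#' @param sim a `cdr3_sim`.
#' @param fastq_path output FASTQ path (phred+33; `.gz` transparently).
#' @param truth_path optional path for the ground-truth TSV.
#' @return invisibly, `fastq_path`.
#' @export
write_sim <- function(sim, fastq_path, truth_path = NULL) {
  stopifnot(inherits(sim, "cdr3_sim"))
  con <- if (grepl("\\.gz$", fastq_path)) gzfile(fastq_path, "w")
         else file(fastq_path, "w")
  on.exit(close(con))
  writeLines(paste0("@", sim$reads$read_id, "\n", sim$reads$seq, "\n+\n",
                    sim$reads$qual), con)
  if (!is.null(truth_path)) {
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fastq_path)
}
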