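#' Classify a CDR3 sequence against a monoclonal reference
#'
#' Length-equal sequences are compared position-wise (Hamming); shorter
#' sequences are `truncated` and longer ones `elongated` (no attempt is made
#' to localise the indel). Positions are 0-based within the CDR3.
#'
#' @param cdr3_nt a single CDR3 nucleotide string.
#' @param reference the true CDR3 nucleotide string.
#' @return list with `category` (`correct`/`substitution`/`truncated`/
#'   `elongated`), `n_subs` (NA unless length-equal) and `subs`
#'   (data.frame: position, from, to, ordered by position).
#' @export
classify <- function(cdr3_nt, reference) {
  empty <- data.frame(position = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE)
  if (nchar(cdr3_nt) < nchar(reference))
    return(list(category = "truncated", n_subs = NA_integer_, subs = empty))
  if (nchar(cdr3_nt) > nchar(reference))
    return(list(category = "elongated", n_subs = NA_integer_, subs = empty))
  a <- strsplit(cdr3_nt, "")[[1]]
  b <- strsplit(reference, "")[[1]]
  d <- which(a != b)
  if (length(d) == 0L)
    return(list(category = "correct", n_subs = 0L, subs = empty))
  list(category = "substitution", n_subs = length(d),
       subs = data.frame(position = d - 1L, from = b[d], to = a[d],
                         stringsAsFactors = FALSE))
}

## vectorised classification of a record set; returns records with added
## category/n_subs columns plus a long substitution table (one row per
## mismatched base, record index `row`)
classify_records <- function(records, reference) {
  n <- nrow(records)
  len_ref <- nchar(reference)
  len <- nchar(records$cdr3_nt)
  category <- ifelse(len < len_ref, "truncated",
                     ifelse(len > len_ref, "elongated", "substitution"))
  n_subs <- rep(NA_integer_, n)
  eq <- which(len == len_ref)
  subs <- data.frame(row = integer(0), position = integer(0),
                     from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  if (length(eq)) {
    refc <- strsplit(reference, "")[[1]]
    # compare position-by-position across all length-equal records
    mm_row <- integer(0); mm_pos <- integer(0); mm_to <- character(0)
    seqs <- records$cdr3_nt[eq]
    for (j in seq_len(len_ref)) {
      cj <- substr(seqs, j, j)
      hit <- which(cj != refc[j])
      if (length(hit)) {
        mm_row <- c(mm_row, eq[hit])
        mm_pos <- c(mm_pos, rep.int(j - 1L, length(hit)))
        mm_to <- c(mm_to, cj[hit])
      }
    }
    n_subs[eq] <- 0L
    if (length(mm_row)) {
      tab <- table(factor(mm_row, levels = eq))
      n_subs[eq] <- as.integer(tab)
      ord <- order(mm_row, mm_pos)
      subs <- data.frame(row = mm_row[ord], position = mm_pos[ord],
                         from = refc[mm_pos[ord] + 1L], to = mm_to[ord],
                         stringsAsFactors = FALSE)
    }
    category[eq] <- ifelse(n_subs[eq] == 0L, "correct", "substitution")
  }
  records$category <- category
  records$n_subs <- n_subs
  list(records = records, subs = subs)
}

#' Summarise error rates across phred cutoffs
#'
#' For each phred cutoff, filters the records and tallies: total and
#' erroneous sequences, percent erroneous, unique erroneous nt sequences
#' (pooled, and per sample), the length-class composition of errors
#' (correct-length / truncated / elongated), the multi-substitution spectrum
#' among correct-length errors, and the percent of correct and of erroneous
#' sequences excluded by the cutoff relative to the unfiltered (q = 0) set.
#'
#' @param records CDR3 records from [extract_cdr3()].
#' @param reference the true CDR3 nt sequence (monoclonal mode).
#' @param q_cutoffs phred cutoffs (default `c(0, 10, 20, 30)`).
#' @return object of class `cdr3_profile`: list with `summary` (one row per
#'   cutoff), `spectrum` (per cutoff x number-of-substitutions M), and
#'   `unique_errant_by_sample`.
#' @export
profile_errors <- function(records, reference, q_cutoffs = c(0, 10, 20, 30)) {
  cl <- classify_records(records, reference)
  rec <- cl$records
  rows <- vector("list", length(q_cutoffs))
  spec_rows <- list()
  uniq_rows <- list()
  for (i in seq_along(q_cutoffs)) {
    q <- q_cutoffs[i]
    keep <- rec$min_q >= q
    r <- rec[keep, , drop = FALSE]
    total <- nrow(r)
    err <- r[r$category != "correct", , drop = FALSE]
    n_err <- nrow(err)
    cat_tab <- table(factor(err$category,
                            levels = c("substitution", "truncated", "elongated")))
    sub_err <- err[err$category == "substitution", , drop = FALSE]
    if (nrow(sub_err)) {
      sp <- table(sub_err$n_subs)
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        q_cutoff = q, m = as.integer(names(sp)), count = as.integer(sp),
        fraction = as.integer(sp) / nrow(sub_err))
    }
    if (nrow(err)) {
      us <- tapply(err$cdr3_nt, err$sample_path,
                   function(x) length(unique(x)))
      uniq_rows[[length(uniq_rows) + 1L]] <- data.frame(
        q_cutoff = q, sample_path = names(us), unique_errant = as.integer(us))
    }
    rows[[i]] <- data.frame(
      q_cutoff = q, total = total, erroneous = n_err,
      error_percent = if (total > 0) 100 * n_err / total else NA_real_,
      unique_errant = length(unique(err$cdr3_nt)),
      pct_errors_correct_length =
        if (n_err > 0) 100 * cat_tab[["substitution"]] / n_err else NA_real_,
      pct_errors_truncated =
        if (n_err > 0) 100 * cat_tab[["truncated"]] / n_err else NA_real_,
      pct_errors_elongated =
        if (n_err > 0) 100 * cat_tab[["elongated"]] / n_err else NA_real_)
  }
  summary <- do.call(rbind, rows)
  # exclusion relative to the least stringent cutoff
  q0 <- which.min(summary$q_cutoff)
  n_corr0 <- summary$total[q0] - summary$erroneous[q0]
  summary$pct_correct_excluded <- if (n_corr0 > 0)
    100 * (1 - (summary$total - summary$erroneous) / n_corr0) else NA_real_
  summary$pct_errors_excluded <- if (summary$erroneous[q0] > 0)
    100 * (1 - summary$erroneous / summary$erroneous[q0]) else NA_real_
  structure(list(
    summary = summary,
    spectrum = if (length(spec_rows)) do.call(rbind, spec_rows) else
      data.frame(q_cutoff = numeric(0), m = integer(0), count = integer(0),
                 fraction = numeric(0)),
    unique_errant_by_sample = if (length(uniq_rows)) do.call(rbind, uniq_rows)
      else data.frame(q_cutoff = numeric(0), sample_path = character(0),
                      unique_errant = integer(0)),
    reference = reference
  ), class = "cdr3_profile")
}

#' @export
print.cdr3_profile <- function(x, ...) {
  cat("<cdr3_profile> reference CDR3:", nchar(x$reference), "nt\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Position-by-substitution error-rate matrix
#'
#' Tallies every mismatched base of substitution-class records into
#' (position, to-base) cells, stratified by the requested record columns
#' (lane, direction and/or sample), with the stratum's total accepted
#' sequence count as denominator. Reverse-orientation records were already
#' mapped to reference coordinates at extraction, so both directions share
#' a coordinate system.
#'
#' @param records CDR3 records.
#' @param reference true CDR3 nt sequence.
#' @param by record columns to stratify by: subset of
#'   `c("lane", "orientation", "sample_path")` (default lane + orientation).
#' @return object of class `substitution_matrix`: long-format data.frame
#'   with stratum columns, `position` (0-based), `from`, `to`, `count`,
#'   `denominator`, `rate`. Cells with zero counts are included, so every
#'   (position, alternative-base) cell is present in every stratum.
#' @export
substitution_matrix <- function(records, reference,
                                by = c("lane", "orientation")) {
  stopifnot(all(by %in% c("lane", "orientation", "sample_path")))
  cl <- classify_records(records, reference)
  rec <- cl$records
  subs <- cl$subs
  len <- nchar(reference)
  refc <- strsplit(reference, "")[[1]]
  strata <- if (length(by)) unique(rec[by]) else data.frame(.all = 1)
  if (nrow(strata) == 0L) strata <- data.frame(.all = 1)[0, , drop = FALSE]
  grid <- expand.grid(position = 0:(len - 1L), to = NT,
                      stringsAsFactors = FALSE)
  grid$from <- refc[grid$position + 1L]
  grid <- grid[grid$from != grid$to, c("position", "from", "to")]
  out <- list()
  for (s in seq_len(nrow(strata))) {
    sel <- rep(TRUE, nrow(rec))
    for (col in by) sel <- sel & rec[[col]] == strata[s, col]
    denom <- sum(sel)
    ss <- subs[subs$row %in% which(sel), , drop = FALSE]
    key <- paste(ss$position, ss$to)
    cnt <- table(factor(key, levels = paste(grid$position, grid$to)))
    g <- grid
    g$count <- as.integer(cnt)
    g$denominator <- denom
    g$rate <- if (denom > 0) g$count / denom else NA_real_
    for (col in rev(by)) g[[col]] <- strata[s, col]
    out[[s]] <- g[, c(by, "position", "from", "to", "count",
                      "denominator", "rate")]
  }
  if (length(out) == 0L) {
    res <- grid[0, , drop = FALSE]
    res$count <- integer(0); res$denominator <- integer(0)
    res$rate <- numeric(0)
  } else {
    res <- do.call(rbind, out)
  }
  rownames(res) <- NULL
  structure(res, reference = reference, class = c("substitution_matrix",
                                                  "data.frame"))
}

#' Per-origin-base substitution rates by read direction
#'
#' Averages matrix cell rates over all positions whose reference base is the
#' origin base, for each of the 12 ordered substitutions, separately per
#' direction stratum. Origin bases absent from the reference yield `NA`
#' rates flagged `undefined`.
#'
#' @param mat a `substitution_matrix` stratified by `orientation` (other
#'   strata are averaged over).
#' @return data.frame: orientation, from, to, rate, n_positions, undefined.
#' @export
per_nt_substitution_rates <- function(mat) {
  stopifnot(inherits(mat, "substitution_matrix"))
  if (!"orientation" %in% names(mat)) mat$orientation <- "all"
  combos <- expand.grid(from = NT, to = NT, stringsAsFactors = FALSE)
  combos <- combos[combos$from != combos$to, ]
  out <- list()
  for (dir in unique(mat$orientation)) {
    md <- mat[mat$orientation == dir, , drop = FALSE]
    # average over any residual strata (e.g. lanes) first: mean rate per cell
    cell <- stats::aggregate(rate ~ position + from + to, data = md, FUN = mean)
    r <- vapply(seq_len(nrow(combos)), function(k) {
      rows <- cell$from == combos$from[k] & cell$to == combos$to[k]
      if (!any(rows)) NA_real_ else mean(cell$rate[rows])
    }, numeric(1))
    np <- vapply(seq_len(nrow(combos)), function(k) {
      length(unique(cell$position[cell$from == combos$from[k]]))
    }, integer(1))
    out[[length(out) + 1L]] <- data.frame(
      orientation = dir, from = combos$from, to = combos$to, rate = r,
      n_positions = np, undefined = is.na(r))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lane-wise coefficient of variation of substitution rates
#'
#' For every (position, substitution) cell, computes the CV (sd/mean) of the
#' per-sample rates within each lane, and summarises these cell CVs as a
#' composite mean and sd. For contrast, the same is computed ignoring lane
#' (CV across all samples). Cells with zero mean rate are excluded and
#' counted.
#'
#' @param rates_by_sample a `substitution_matrix` stratified by
#'   `c("lane", "sample_path")`.
#' @return list with `cell_cv` (per cell per lane), `composite`
#'   (data.frame: grouping, mean_cv, sd_cv, n_cells, n_excluded).
#' @export
lane_cv <- function(rates_by_sample) {
  m <- as.data.frame(rates_by_sample)
  stopifnot(all(c("lane", "sample_path") %in% names(m)))
  cv <- function(x) stats::sd(x) / mean(x)
  within_lane <- stats::aggregate(
    rate ~ lane + position + from + to, data = m,
    FUN = function(x) if (mean(x) > 0) cv(x) else NA_real_)
  names(within_lane)[names(within_lane) == "rate"] <- "cv"
  across <- stats::aggregate(
    rate ~ position + from + to, data = m,
    FUN = function(x) if (mean(x) > 0) cv(x) else NA_real_)
  names(across)[names(across) == "rate"] <- "cv"
  comp <- function(v, label) data.frame(
    grouping = label, mean_cv = mean(v, na.rm = TRUE),
    sd_cv = stats::sd(v, na.rm = TRUE), n_cells = sum(!is.na(v)),
    n_excluded = sum(is.na(v)))
  list(cell_cv = within_lane,
       composite = rbind(comp(within_lane$cv, "within_lane"),
                         comp(across$cv, "across_all_samples")))
}

#' Per-cell one-way ANOVA of substitution rates across lanes
#'
#' For every (position, substitution) cell, fits a one-way fixed-effects
#' ANOVA of the per-sample rates grouped by lane and reports the F-test
#' p-value, plus the fraction of cells significant at `alpha`. Cells with no
#' variance at all (all rates identical) are assigned p = 1 by convention.
#'
#' @param rates_by_sample a `substitution_matrix` stratified by
#'   `c("lane", "sample_path")`.
#' @param alpha significance level for the reported fraction (default 0.05).
#' @return list with `cells` (position, from, to, f, p) and
#'   `fraction_significant`.
#' @export
lane_anova <- function(rates_by_sample, alpha = 0.05) {
  m <- as.data.frame(rates_by_sample)
  stopifnot(all(c("lane", "sample_path") %in% names(m)))
  cells <- unique(m[c("position", "from", "to")])
  cells <- cells[order(cells$position, cells$to), ]
  f <- p <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- m$position == cells$position[i] & m$to == cells$to[i]
    x <- m$rate[sel]
    g <- factor(m$lane[sel])
    if (length(x) < 2L || stats::var(x) == 0) { f[i] <- 0; p[i] <- 1; next }
    fit <- stats::anova(stats::lm(x ~ g))
    f[i] <- fit[["F value"]][1]
    p[i] <- fit[["Pr(>F)"]][1]
  }
  cells$f <- f
  cells$p <- p
  rownames(cells) <- NULL
  list(cells = cells, fraction_significant = mean(cells$p < alpha),
       alpha = alpha)
}
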