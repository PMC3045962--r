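#' Abundance-based coverage estimator (ACE) of clonotype richness
#'
#' Classic bias-corrected ACE (Chao & Lee): clonotypes with counts at or
#' below `rare_cutoff` (default 10) form the rare group, from which sample
#' coverage `C_ace = 1 - F1/N_rare` and the squared coefficient of variation
#' `gamma2 = max(S_rare/C_ace * sum(i(i-1)F_i) / (N_rare(N_rare-1)) - 1, 0)`
#' are estimated; then
#' `ACE = S_abund + S_rare/C_ace + F1/C_ace * gamma2`.
#' When every rare clonotype is a singleton (`C_ace = 0`) the estimator is
#' undefined and the Chao1 estimate `S_obs + F1(F1-1)/2` is returned with a
#' fallback flag.
#'
#' @param abundances integer vector of clonotype counts (all >= 1).
#' @param rare_cutoff rare/abundant group boundary (default 10).
#' @return object of class `ace_result`: list with `estimate`, `method`
#'   (`"ACE"` or `"Chao1"`), `s_obs`, `s_rare`, `s_abund`, `f1`, `n_rare`,
#'   `c_ace`, `gamma2`, `fallback`.
#' @export
ace <- function(abundances, rare_cutoff = 10L) {
  if (length(abundances) == 0L) stop("empty abundance vector")
  stopifnot(all(abundances >= 1), rare_cutoff >= 1)
  x <- as.integer(round(abundances))
  s_obs <- length(x)
  rare <- x[x <= rare_cutoff]
  s_rare <- length(rare)
  s_abund <- s_obs - s_rare
  f1 <- sum(rare == 1L)
  n_rare <- sum(rare)
  if (s_rare == 0L) {
    return(structure(list(estimate = as.numeric(s_obs), method = "ACE",
                          s_obs = s_obs, s_rare = 0L, s_abund = s_abund,
                          f1 = 0L, n_rare = 0L, c_ace = NA_real_,
                          gamma2 = NA_real_, fallback = FALSE),
                     class = "ace_result"))
  }
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    est <- s_obs + f1 * (f1 - 1) / 2
    return(structure(list(estimate = est, method = "Chao1", s_obs = s_obs,
                          s_rare = s_rare, s_abund = s_abund, f1 = f1,
                          n_rare = n_rare, c_ace = 0, gamma2 = NA_real_,
                          fallback = TRUE), class = "ace_result"))
  }
  fi <- tabulate(rare, nbins = rare_cutoff)
  sum_ii1 <- sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1L) * fi)
  gamma2 <- if (n_rare > 1L)
    max(s_rare / c_ace * sum_ii1 / (n_rare * (n_rare - 1)) - 1, 0) else 0
  est <- s_abund + s_rare / c_ace + f1 / c_ace * gamma2
  structure(list(estimate = est, method = "ACE", s_obs = s_obs,
                 s_rare = s_rare, s_abund = s_abund, f1 = f1,
                 n_rare = n_rare, c_ace = c_ace, gamma2 = gamma2,
                 fallback = FALSE), class = "ace_result")
}

#' @export
print.ace_result <- function(x, ...) {
  cat("<ace_result>", x$method, "estimate:", format(x$estimate, digits = 6),
      if (x$fallback) "(coverage 0: Chao1 fallback)" else "", "\n")
  cat("  S_obs:", x$s_obs, " S_rare:", x$s_rare, " S_abund:", x$s_abund,
      " F1:", x$f1, " N_rare:", x$n_rare, "\n")
  invisible(x)
}

#' Richness and diversity report across phred filters
#'
#' Compares clonotype tables built from the same reads at different phred
#' cutoffs (typically unfiltered q = 0 versus q = 30): total reads, unique
#' clonotypes, ACE richness, and percent reductions relative to the first
#' table.
#'
#' @param tables named list of `clone_table`s; the first is the baseline.
#' @param rare_cutoff passed to [ace()].
#' @return data.frame with one row per table: label, total_reads,
#'   unique_clonotypes, ace, and percent reductions vs the baseline.
#' @export
richness_report <- function(tables, rare_cutoff = 10L) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  labels <- names(tables)
  if (is.null(labels)) labels <- paste0("table_", seq_along(tables))
  rows <- lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    data.frame(label = labels[i],
               total_reads = sum(tb$total_count),
               unique_clonotypes = nrow(tb),
               ace = if (nrow(tb)) ace(tb$total_count, rare_cutoff)$estimate
                     else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$pct_reduction_total <- 100 * (1 - out$total_reads / out$total_reads[1])
  out$pct_reduction_unique <-
    100 * (1 - out$unique_clonotypes / out$unique_clonotypes[1])
  out$pct_reduction_ace <- 100 * (1 - out$ace / out$ace[1])
  out
}
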