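#' Independence expectation for multi-substitution reads
#'
#' Under independent per-position errors at single-error rate `ser`, the
#' expected frequency of sequences carrying exactly `m` substitutions in an
#' `n` nt sequence is `C(n, m) * ser^m` with `C(n, m) = n!/(m!(n-m)!)`.
#' The survival factor `(1 - ser)^(n - m)` is omitted by default (it is
#' negligible for the small rates where the model applies); set
#' `include_survival = TRUE` for the full binomial probability.
#'
#' @param ser per-position single-error rate, in `[0, 1]`.
#' @param m number of substituted positions, `0 < m <= n`.
#' @param n sequence length in nt.
#' @param include_survival include the `(1-ser)^(n-m)` factor (default
#'   FALSE).
#' @return expected frequency (numeric, vectorised over `m`). A value above
#'   1 signals model breakdown (rate too large) and raises a warning.
#' @export
expected_multi_error_rate <- function(ser, m, n, include_survival = FALSE) {
  stopifnot(ser >= 0, ser <= 1, all(m >= 0), all(m <= n), n >= 1)
  lp <- lchoose(n, m) + ifelse(m == 0 & ser == 0, 0, m * log(ser))
  if (include_survival) lp <- lp + (n - m) * log1p(-ser)
  p <- exp(lp)
  p[ser == 0 & m > 0] <- 0
  if (any(p > 1)) warning("expected frequency exceeds 1: model breakdown ",
                          "(single-error rate too large for the approximation)")
  p
}

#' Observed versus expected multi-substitution frequencies
#'
#' Compares the observed multi-substitution spectrum with the independence
#' expectation `C(n, m) * ser^m`. When `ser` is not supplied it is estimated
#' from the spectrum as the per-position rate
#' `(fraction of sequences with exactly one substitution) / n`. Ratios near
#' 1 indicate independent errors; ratios above 1 an excess of
#' multi-substitution reads over independence (error complementation).
#'
#' @param spectrum data.frame with columns `m` (number of substitutions, with
#'   m = 0 rows allowed) and `count`, over all accepted sequences; or a named
#'   integer vector (names = m).
#' @param n CDR3 length in nt.
#' @param ser optional per-position single-error rate; estimated from the
#'   spectrum when `NULL`.
#' @param m_range values of m to report (default 2:10).
#' @param include_survival passed to [expected_multi_error_rate()].
#' @return data.frame: m, observed_count, observed_freq, expected_freq,
#'   ratio (NA when the expectation is 0), plus attributes `ser` and `n`.
#' @export
complementation_test <- function(spectrum, n, ser = NULL, m_range = 2:10,
                                 include_survival = FALSE) {
  if (!is.data.frame(spectrum)) {
    spectrum <- data.frame(m = as.integer(names(spectrum)),
                           count = as.integer(spectrum))
  }
  stopifnot(all(c("m", "count") %in% names(spectrum)), n >= 1)
  m_range <- m_range[m_range <= n]
  total <- sum(spectrum$count)
  if (total == 0) stop("empty spectrum")
  if (is.null(ser)) {
    n1 <- sum(spectrum$count[spectrum$m == 1L])
    ser <- (n1 / total) / n
  }
  obs <- vapply(m_range, function(mm)
    sum(spectrum$count[spectrum$m == mm]), numeric(1))
  obs_freq <- obs / total
  exp_freq <- expected_multi_error_rate(ser, m_range, n,
                                        include_survival = include_survival)
  ratio <- ifelse(exp_freq > 0, obs_freq / exp_freq, NA_real_)
  if (ser == 0 && any(obs > 0))
    warning("zero single-error rate with nonzero multi-error counts: ",
            "ratios undefined")
  out <- data.frame(m = m_range, observed_count = obs,
                    observed_freq = obs_freq, expected_freq = exp_freq,
                    ratio = ratio)
  attr(out, "ser") <- ser
  attr(out, "n") <- n
  out
}

#' Exact binomial read-direction boundaries
#'
#' For `n` reads of a sequence and forward-read probability `p_fwd`, returns
#' the integer bounds such that the probability of observing more forward
#' reads than `upper`, or fewer than `lower`, is each strictly below `tail`
#' under Binomial(n, p_fwd). With the default 1% per tail, at least 98% of
#' direction-neutral sequences fall within `[lower, upper]`. Exact CDF; no
#' normal approximation; ties broken toward wider intervals by the strict
#' inequality.
#'
#' @param n number of reads (vectorised).
#' @param p_fwd forward-read probability, in (0, 1).
#' @param tail per-tail probability bound (default 0.01).
#' @return data.frame with columns `n`, `lower`, `upper`.
#' @export
binom_boundaries <- function(n, p_fwd, tail = 0.01) {
  stopifnot(all(n >= 1), p_fwd > 0, p_fwd < 1, tail > 0, tail < 0.5)
  lower <- upper <- integer(length(n))
  for (i in seq_along(n)) {
    ni <- n[i]
    # upper: smallest k with P(X > k) < tail
    k <- stats::qbinom(1 - tail, ni, p_fwd)
    while (k > 0L && 1 - stats::pbinom(k - 1L, ni, p_fwd) < tail) k <- k - 1L
    while (1 - stats::pbinom(k, ni, p_fwd) >= tail) k <- k + 1L
    upper[i] <- k
    # lower: largest k with P(X < k) < tail
    k <- stats::qbinom(tail, ni, p_fwd)
    while (k <= ni && stats::pbinom(k, ni, p_fwd) < tail) k <- k + 1L
    while (k > 0L && stats::pbinom(k - 1L, ni, p_fwd) >= tail) k <- k - 1L
    lower[i] <- k
  }
  data.frame(n = n, lower = lower, upper = upper)
}

#' Culling-count threshold for low-frequency mismatch sequences
#'
#' Given an index sequence observed `index_count` times and a relative
#' frequency cutoff, the naive threshold is `index_count * cutoff` (e.g.
#' 200 reads at a 0.5% cutoff give 1). Because a sequence whose true
#' frequency equals the cutoff fluctuates binomially, the binomially
#' adjusted threshold is the smallest integer `k` such that
#' `P(X <= k) >= confidence` under Binomial(index_count, cutoff): culling
#' everything observed `k` or fewer times removes, with at least the stated
#' confidence, any sequence whose true frequency is at or below the cutoff
#' (e.g. k = 3 for 200 reads, 0.5%, 95%).
#'
#' @param index_count reads of the index sequence (>= 1).
#' @param cutoff relative frequency cutoff, in `[0, 1]`.
#' @param confidence target confidence for the binomial mode (default 0.95).
#' @param mode `"binomial"` (default) or `"naive"`.
#' @return the threshold: an integer count for `"binomial"`, a possibly
#'   fractional count for `"naive"`.
#' @export
cull_threshold <- function(index_count, cutoff, confidence = 0.95,
                           mode = c("binomial", "naive")) {
  mode <- match.arg(mode)
  stopifnot(index_count >= 1, confidence > 0, confidence < 1)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  if (mode == "naive") return(index_count * cutoff)
  k <- 0L
  while (stats::pbinom(k, index_count, cutoff) < confidence) k <- k + 1L
  k
}
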