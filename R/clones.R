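#' Build a clonotype abundance table
#'
#' Groups validated CDR3 records by exact nucleotide sequence, counting
#' totals, forward/reverse reads and per-lane reads. Rows are ordered by
#' decreasing count, ties broken lexicographically by sequence.
#'
#' @param records CDR3 records from [extract_cdr3()].
#' @return object of class `clone_table`: data.frame with `cdr3_nt`,
#'   `total_count`, `forward_count`, `reverse_count`, one `lane_<l>` column
#'   per lane, and `frequency`.
#' @export
build_clone_table <- function(records) {
  if (nrow(records) == 0L) {
    out <- data.frame(cdr3_nt = character(0), total_count = integer(0),
                      forward_count = integer(0), reverse_count = integer(0),
                      frequency = numeric(0))
    class(out) <- c("clone_table", "data.frame")
    return(out)
  }
  seqs <- factor(records$cdr3_nt)
  total <- as.integer(table(seqs))
  fwd <- as.integer(table(seqs[records$orientation == "forward"]))
  out <- data.frame(cdr3_nt = levels(seqs), total_count = total,
                    forward_count = fwd, reverse_count = total - fwd,
                    stringsAsFactors = FALSE)
  lanes <- sort(unique(records$lane))
  if (length(lanes) && !all(is.na(lanes))) {
    for (l in lanes) {
      out[[paste0("lane_", l)]] <-
        as.integer(table(seqs[!is.na(records$lane) & records$lane == l]))
    }
  }
  out$frequency <- out$total_count / sum(out$total_count)
  out <- out[order(-out$total_count, out$cdr3_nt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clone_table", "data.frame")
  out
}

#' @export
print.clone_table <- function(x, ...) {
  cat("<clone_table>", nrow(x), "clonotypes,", sum(x$total_count), "reads\n")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

## all unordered pairs of equal-length sequences at Hamming distance 1,
## found by single-position wildcard keys. Returns a data.frame (i, j) of
## row indices into `seqs` with i < j.
hamming1_pairs <- function(seqs) {
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    if (length(idx) < 2L) next
    ss <- seqs[idx]
    for (pos in seq_len(L)) {
      key <- paste0(substr(ss, 1L, pos - 1L), ".", substring(ss, pos + 1L))
      grp <- split(idx, key)
      grp <- grp[lengths(grp) > 1L]
      for (g in grp) {
        cmb <- utils::combn(sort(g), 2L)
        pairs_i <- c(pairs_i, cmb[1L, ])
        pairs_j <- c(pairs_j, cmb[2L, ])
      }
    }
  }
  # two sequences share a key at exactly one position iff Hamming distance 1,
  # so each pair is found exactly once and no dedup is needed
  data.frame(i = pairs_i, j = pairs_j)
}

#' Lower-frequency single-mismatch neighbors
#'
#' For each clonotype, lists the clonotypes of equal length at Hamming
#' distance 1 that are present at strictly lower count. Equal-count pairs
#' are mutually non-neighbors, keeping the relation antisymmetric.
#'
#' @param table a `clone_table`.
#' @return data.frame with one row per (index, neighbor) pair: `index_seq`,
#'   `neighbor_seq`, `index_count`, `neighbor_count`. The per-index tally of
#'   such neighbors (and its total) is the global single-mismatch burden of
#'   the repertoire.
#' @export
single_mismatch_neighbors <- function(table) {
  p <- hamming1_pairs(table$cdr3_nt)
  if (nrow(p) == 0L)
    return(data.frame(index_seq = character(0), neighbor_seq = character(0),
                      index_count = integer(0), neighbor_count = integer(0)))
  ci <- table$total_count[p$i]
  cj <- table$total_count[p$j]
  keep <- ci != cj
  hi <- ifelse(ci > cj, p$i, p$j)[keep]
  lo <- ifelse(ci > cj, p$j, p$i)[keep]
  out <- data.frame(index_seq = table$cdr3_nt[hi],
                    neighbor_seq = table$cdr3_nt[lo],
                    index_count = table$total_count[hi],
                    neighbor_count = table$total_count[lo],
                    stringsAsFactors = FALSE)
  out[order(-out$index_count, out$index_seq, out$neighbor_seq), ,
      drop = FALSE]
}

#' Cull single-mismatch sequences around a known true sequence
#'
#' Monoclonal mode: removes every clonotype at Hamming distance 1 from the
#' true sequence whose count is at or below `cutoff` times the true
#' sequence's count. A cutoff of 0 removes nothing; a cutoff of 1 removes
#' all distance-1 clonotypes at or below the true sequence's own count. The
#' residual erroneous fraction is the share of non-true reads among the
#' reads remaining after culling.
#'
#' @param table a `clone_table`.
#' @param true_seq the known true CDR3 nt sequence (must be in the table).
#' @param cutoff relative frequency cutoff in `[0, 1]`.
#' @return object of class `cull_report`: list with `culled` (data.frame),
#'   `table` (after culling), `residual_error_fraction`, `cutoff`.
#' @export
cull_monoclonal <- function(table, true_seq, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ti <- match(true_seq, table$cdr3_nt)
  if (is.na(ti)) stop("true sequence not present in the clone table")
  index_count <- table$total_count[ti]
  len_eq <- which(nchar(table$cdr3_nt) == nchar(true_seq))
  tsi <- utf8ToInt(true_seq)
  d1 <- len_eq[vapply(table$cdr3_nt[len_eq], function(s)
    sum(utf8ToInt(s) != tsi) == 1L, logical(1), USE.NAMES = FALSE)]
  cull <- d1[cutoff > 0 & table$total_count[d1] <= cutoff * index_count]
  culled <- data.frame(
    sequence = table$cdr3_nt[cull], count = table$total_count[cull],
    index_seq = rep_len(true_seq, length(cull)),
    index_count = rep_len(index_count, length(cull)),
    ratio = table$total_count[cull] / index_count, stringsAsFactors = FALSE)
  remaining <- if (length(cull)) table[-cull, , drop = FALSE] else table
  n_rem <- sum(remaining$total_count)
  n_err <- n_rem - remaining$total_count[match(true_seq, remaining$cdr3_nt)]
  structure(list(
    culled = culled, table = remaining,
    residual_error_fraction = if (n_rem > 0) n_err / n_rem else NA_real_,
    cutoff = cutoff, mode = "monoclonal"), class = "cull_report")
}

#' Tally single-mismatch sequences below a cutoff around top clonotypes
#'
#' Polyclonal mode: takes the `top_k` most frequent clonotypes as index
#' sequences (ties broken lexicographically) and, for each relative
#' frequency cutoff, counts the strictly-lower-count distance-1 clonotypes
#' whose count is strictly below `cutoff` times the index count. Indexes are
#' processed in descending count order and a clonotype counted for one index
#' is not re-counted for another. The all-sequence lower-frequency
#' single-mismatch tally is also reported.
#'
#' @param table a `clone_table`.
#' @param cutoffs relative frequency cutoffs (default 0.1% to 1%).
#' @param top_k number of index sequences (default 20; tables with fewer
#'   rows use all rows).
#' @return object of class `cull_report`: list with `tallies` (data.frame:
#'   cutoff, n_culled), `per_index` (cutoff x index counts),
#'   `global_mismatch_tally` (total lower-frequency distance-1 pairs over
#'   all sequences), `top_k`.
#' @export
cull_polyclonal <- function(table, cutoffs = seq(0.001, 0.01, by = 0.001),
                            top_k = 20L) {
  stopifnot(all(cutoffs >= 0), all(cutoffs <= 1))
  k <- min(top_k, nrow(table))
  nb <- single_mismatch_neighbors(table)
  # table rows are already sorted by descending count then sequence
  idx_seqs <- table$cdr3_nt[seq_len(k)]
  per_index <- list()
  tallies <- numeric(length(cutoffs))
  for (ci in seq_along(cutoffs)) {
    cut <- cutoffs[ci]
    assigned <- character(0)
    n_cull <- integer(k)
    for (ii in seq_len(k)) {
      rows <- nb$index_seq == idx_seqs[ii] &
        nb$neighbor_count < cut * nb$index_count &
        !(nb$neighbor_seq %in% assigned)
      hits <- nb$neighbor_seq[rows]
      assigned <- c(assigned, hits)
      n_cull[ii] <- length(hits)
    }
    per_index[[ci]] <- data.frame(cutoff = cut, index_seq = idx_seqs,
                                  n_culled = n_cull,
                                  stringsAsFactors = FALSE)
    tallies[ci] <- sum(n_cull)
  }
  structure(list(
    tallies = data.frame(cutoff = cutoffs, n_culled = tallies),
    per_index = do.call(rbind, per_index),
    global_mismatch_tally = nrow(nb),
    top_k = k, mode = "polyclonal"), class = "cull_report")
}

#' @export
print.cull_report <- function(x, ...) {
  cat("<cull_report>", x$mode, "mode\n")
  if (x$mode == "monoclonal") {
    cat("  cutoff:", x$cutoff, "- culled", nrow(x$culled),
        "sequences; residual erroneous fraction:",
        format(x$residual_error_fraction, digits = 4), "\n")
  } else {
    print(x$tallies, row.names = FALSE)
    cat("  global lower-frequency single-mismatch tally:",
        x$global_mismatch_tally, "\n")
  }
  invisible(x)
}

#' Screen clonotypes for read-direction skew
#'
#' Flags, for every clonotype with at least `min_reads` reads, whether its
#' forward-read count lies inside the exact-binomial boundaries
#' ([binom_boundaries()]) around the forward-read probability of the
#' dominant (or known true) sequence. Direction-neutral clonotypes should
#' fall within the boundaries about 98% of the time at the default 1% tails.
#'
#' @param table a `clone_table`.
#' @param p_fwd forward-read probability; default: forward fraction of the
#'   most frequent clonotype.
#' @param min_reads minimum total reads for a clonotype to be assessed
#'   (default 20).
#' @param tail per-tail probability (default 0.01).
#' @param exclude_top drop the clonotype supplying `p_fwd` from the
#'   assessment (default TRUE).
#' @return list with `flags` (data.frame: cdr3_nt, n, forward_count, lower,
#'   upper, within), `fraction_within`, `p_fwd`.
#' @export
direction_skew_screen <- function(table, p_fwd = NULL, min_reads = 20L,
                                  tail = 0.01, exclude_top = TRUE) {
  if (is.null(p_fwd)) {
    p_fwd <- table$forward_count[1] / table$total_count[1]
  }
  if (!(p_fwd > 0 && p_fwd < 1))
    stop("p_fwd must be strictly inside (0, 1)")
  rows <- which(table$total_count >= min_reads)
  if (exclude_top) rows <- setdiff(rows, 1L)
  if (length(rows) == 0L)
    return(list(flags = data.frame(cdr3_nt = character(0), n = integer(0),
                                   forward_count = integer(0),
                                   lower = integer(0), upper = integer(0),
                                   within = logical(0)),
                fraction_within = NA_real_, p_fwd = p_fwd))
  b <- binom_boundaries(table$total_count[rows], p_fwd, tail)
  flags <- data.frame(
    cdr3_nt = table$cdr3_nt[rows], n = table$total_count[rows],
    forward_count = table$forward_count[rows],
    lower = b$lower, upper = b$upper,
    within = table$forward_count[rows] >= b$lower &
      table$forward_count[rows] <= b$upper,
    stringsAsFactors = FALSE)
  list(flags = flags, fraction_within = mean(flags$within), p_fwd = p_fwd)
}
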