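ref6 <- "GCAACA"

mkrec <- function(cdr3, min_q = 40L, lane = 1L, sample = "S1",
                  orientation = "forward") {
  data.frame(read_id = sprintf("r%03d", seq_along(cdr3)), cdr3_nt = cdr3,
             cdr3_qual = strrep("I", nchar(cdr3)), orientation = orientation,
             lane = lane, sample_path = sample, min_q = min_q,
             stringsAsFactors = FALSE)
}

test_that("classification distinguishes correct, substituted and indel reads", {
  expect_equal(classify(ref6, ref6)$category, "correct")
  expect_equal(classify(ref6, ref6)$n_subs, 0L)
  expect_equal(classify("GCAAC", ref6)$category, "truncated")
  expect_true(is.na(classify("GCAAC", ref6)$n_subs))
  expect_equal(classify("GCAACAA", ref6)$category, "elongated")
  expect_equal(classify("", ref6)$category, "truncated")

  # positions from a brute-force scan oracle on a 36-mer
  ref36 <- builtin_templates("cdr3_36")$cdr3
  mut <- ref36
  substr(mut, 5, 5) <- "T"    # 0-based position 4
  substr(mut, 18, 18) <- "C"  # 0-based position 17
  oracle <- which(strsplit(mut, "")[[1]] != strsplit(ref36, "")[[1]]) - 1L
  cl <- classify(mut, ref36)
  expect_equal(cl$category, "substitution")
  expect_equal(cl$n_subs, 2L)
  expect_equal(cl$subs$position, oracle)
  expect_equal(cl$subs$to, c("T", "C"))
})

test_that("batch classification agrees with the single-record path", {
  set.seed(1)
  muts <- vapply(1:50, function(i) {
    s <- ref6
    k <- sample(0:3, 1)
    for (p in sample(6, k)) substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    s
  }, character(1))
  rec <- mkrec(muts)
  cl <- classify_records <- cdr3err:::classify_records(rec, ref6)
  for (i in seq_len(nrow(rec))) {
    single <- classify(rec$cdr3_nt[i], ref6)
    expect_equal(cl$records$category[i], single$category)
    expect_equal(cl$records$n_subs[i], single$n_subs)
    ss <- cl$subs[cl$subs$row == i, c("position", "from", "to")]
    rownames(ss) <- NULL
    expect_equal(ss, single$subs)
  }
})

test_that("error summaries respond correctly to phred cutoffs", {
  # all-correct input: zero error percent everywhere
  p <- profile_errors(mkrec(rep(ref6, 10)), ref6)
  expect_true(all(p$summary$error_percent == 0))

  # erroneous bases all low quality, correct all high: q30 error percent 0
  rec <- rbind(mkrec(rep(ref6, 90)), mkrec(rep("GCAACT", 10), min_q = 5L))
  p <- profile_errors(rec, ref6)
  s <- p$summary
  expect_equal(s$error_percent[s$q_cutoff == 0], 10)
  expect_equal(s$error_percent[s$q_cutoff == 30], 0)
  expect_equal(s$pct_errors_excluded[s$q_cutoff == 30], 100)
  expect_equal(s$pct_correct_excluded[s$q_cutoff == 30], 0)
  expect_equal(s$unique_errant[s$q_cutoff == 0], 1L)
})

test_that("unfiltered error percent matches the per-read complement oracle", {
  t <- tiny_template()
  rate <- 4e-3
  m <- error_model(sub_rate = cdr3_only_matrix(t, rate),
                   indel_rate = c(deletion = 0, insertion = 0))
  n <- 20000L
  s <- simulate_reads(t, m, n_reads = n, seed = 23)
  ex <- extract_cdr3(s$reads, template_flanks(t))
  p <- profile_errors(ex$records, t$cdr3, q_cutoffs = 0)
  # per-read error probability: 1 - prod(1 - per-position total rate)
  p_read <- 1 - (1 - 3 * rate)^nchar(t$cdr3)
  se <- sqrt(p_read * (1 - p_read) / n)
  expect_lt(abs(p$summary$error_percent / 100 - p_read), 3 * se)
})

test_that("substitution matrix counts every mismatch with stratum totals", {
  rec <- mkrec(c("TCAACA", rep(ref6, 9)))
  sm <- substitution_matrix(rec, ref6, by = character(0))
  expect_equal(sum(sm$count), 1L)
  hit <- sm[sm$count > 0, ]
  expect_equal(hit$position, 0L)
  expect_equal(hit$from, "G")
  expect_equal(hit$to, "T")
  expect_equal(hit$rate, 0.1)
  expect_true(all(sm$denominator == 10L))

  # conservation: total matrix counts equal total substituted bases
  set.seed(2)
  muts <- vapply(1:200, function(i) {
    s <- ref6
    for (p in sample(6, sample(0:2, 1)))
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    s
  }, character(1))
  rec2 <- mkrec(muts)
  cl <- cdr3err:::classify_records(rec2, ref6)
  sm2 <- substitution_matrix(rec2, ref6, by = character(0))
  expect_equal(sum(sm2$count),
               sum(cl$records$n_subs[cl$records$category == "substitution"]))
})

test_that("simulated hot cells surface as the matrix argmax", {
  t <- tiny_template()
  m <- cdr3_only_matrix(t, 1e-3)
  hot_pos <- t$cdr3_start + 3L                 # 0-based template coordinate
  hot_to <- setdiff(c("A", "C", "G", "T"),
                    substr(t$seq, hot_pos + 1L, hot_pos + 1L))[1]
  m[hot_pos + 1L, hot_to] <- 0.03
  em <- error_model(sub_rate = m, indel_rate = c(deletion = 0, insertion = 0))
  s <- simulate_reads(t, em, n_reads = 20000, seed = 29)
  ex <- extract_cdr3(s$reads, template_flanks(t))
  sm <- substitution_matrix(ex$records, t$cdr3, by = character(0))
  top <- sm[which.max(sm$count), ]
  expect_equal(top$position, hot_pos - t$cdr3_start)  # CDR3-window coords
  expect_equal(top$to, hot_to)
  # SimTruth tally agrees with the matrix count for the hot cell
  errs <- parse_truth_errors(s$truth)
  acc <- errs$read_id %in% ex$records$read_id
  expect_equal(top$count,
               sum(errs$position[acc] == hot_pos & errs$to[acc] == hot_to))
})

test_that("per-origin-base rates average matrix cells by direction", {
  rec <- mkrec(rep(ref6, 10))
  sm <- substitution_matrix(rec, ref6, by = "orientation")
  r <- per_nt_substitution_rates(sm)
  # reference GCAACA has no T: all T>. rates undefined
  expect_true(all(r$undefined[r$from == "T"]))
  expect_true(all(r$rate[r$from != "T"] == 0))
  expect_equal(nrow(r[r$orientation == "forward", ]), 12L)
})

test_that("lane CV matches hand arithmetic and zero-variance cases", {
  # two samples with rates r and 3r: CV = sd/mean = sqrt(2)/2
  base <- expand.grid(position = 0L, from = "G", to = c("A", "C", "T"),
                      stringsAsFactors = FALSE)
  mk_sm <- function(rates) {
    rows <- do.call(rbind, lapply(seq_along(rates), function(i) {
      b <- base
      b$lane <- 1L
      b$sample_path <- paste0("P", i)
      b$count <- NA_integer_
      b$denominator <- 100L
      b$rate <- rates[i]
      b
    }))
    structure(rows, class = c("substitution_matrix", "data.frame"))
  }
  cv <- lane_cv(mk_sm(c(0.01, 0.03)))
  expect_equal(cv$composite$mean_cv[1], sqrt(2) / 2, tolerance = 1e-12)
  cv0 <- lane_cv(mk_sm(c(0.02, 0.02)))
  expect_equal(cv0$composite$mean_cv[1], 0)
})

test_that("per-cell ANOVA matches the direct oracle and conventions", {
  # groups (1,2,3), (2,3,4), (3,4,5): SSB=6 (df 2), SSW=6 (df 6) -> F = 3
  m <- expand.grid(sample_path = paste0("P", 1:3), lane = 1:3,
                   stringsAsFactors = FALSE)
  m$position <- 0L; m$from <- "G"; m$to <- "A"
  m$count <- NA_integer_; m$denominator <- 100L
  m$rate <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)  # lane-major: lane 1 = (1,2,3) etc.
  res <- lane_anova(structure(m, class = c("substitution_matrix",
                                           "data.frame")))
  expect_equal(res$cells$f, 3, tolerance = 1e-12)
  oracle <- anova(lm(rate ~ factor(lane), data = m))
  expect_equal(res$cells$p, oracle[["Pr(>F)"]][1], tolerance = 1e-12)

  # all rates identical: p = 1 by convention
  m$rate <- 0.5
  res0 <- lane_anova(structure(m, class = c("substitution_matrix",
                                            "data.frame")))
  expect_equal(res0$cells$p, 1)
  expect_equal(res0$fraction_significant, 0)
})

test_that("null lane effect yields ~5% significant cells", {
  t <- tiny_template()
  m <- error_model(sub_rate = cdr3_only_matrix(t, 5e-3),
                   indel_rate = c(deletion = 0, insertion = 0))
  p <- preset_study_design(n_reads_per_reaction = 400L)
  s <- simulate_reads(t, m, design = p$design, seed = 37)  # no lane effect
  ex <- extract_cdr3(s$reads, template_flanks(t))
  bs <- substitution_matrix(ex$records, t$cdr3, by = c("lane", "sample_path"))
  res <- lane_anova(bs)
  # 18 cells; type-I calibration is coarse but must stay near alpha
  expect_lt(res$fraction_significant, 0.3)
})
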