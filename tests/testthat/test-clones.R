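mkrec2 <- function(cdr3, orientation = "forward", lane = 1L) {
  n <- length(cdr3)
  data.frame(read_id = sprintf("r%04d", seq_len(n)), cdr3_nt = cdr3,
             cdr3_qual = strrep("I", nchar(cdr3)),
             orientation = rep_len(orientation, n), lane = rep_len(lane, n),
             sample_path = rep_len("S1", n), min_q = rep_len(40L, n),
             stringsAsFactors = FALSE)
}

clone_tab <- function(counts) {
  # synthesise a clone table from a named count vector
  build_clone_table(mkrec2(rep(names(counts), counts)))
}

test_that("clone tables count totals, directions and lanes", {
  rec <- mkrec2(rep("AAA", 3), orientation = c("forward", "forward", "reverse"))
  tab <- build_clone_table(rec)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$total_count, 3L)
  expect_equal(tab$forward_count, 2L)
  expect_equal(tab$reverse_count, 1L)
  expect_equal(tab$frequency, 1)
  expect_equal(nrow(build_clone_table(mkrec2(character(0)))), 0L)
})

test_that("clone table totals agree with the simulator ground truth", {
  t <- tiny_template()
  s <- simulate_reads(t, error_model(sub_rate = 5e-3), n_reads = 3000,
                      seed = 47)
  ex <- extract_cdr3(s$reads, template_flanks(t))
  tab <- build_clone_table(ex$records)
  expect_equal(sum(tab$total_count), nrow(ex$records))
  expect_equal(sum(tab$forward_count),
               sum(ex$records$orientation == "forward"))
  # per-sequence totals equal direct grouping of the records
  direct <- table(ex$records$cdr3_nt)
  expect_equal(tab$total_count[match(names(direct), tab$cdr3_nt)],
               as.integer(direct))
})

test_that("neighbor search equals the brute-force all-pairs oracle", {
  tab <- clone_tab(c(AAA = 10, AAT = 2, TTT = 5, AAAA = 7, AATA = 3))
  nb <- single_mismatch_neighbors(tab)
  expect_equal(sort(nb$neighbor_seq[nb$index_seq == "AAA"]), "AAT")
  expect_equal(sum(nb$index_seq == "TTT"), 0L)         # no d1 partner
  expect_equal(nb$neighbor_seq[nb$index_seq == "AAAA"], "AATA")

  # randomised table against the oracle
  set.seed(53)
  seqs <- unique(vapply(1:300, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    character(1)))
  counts <- sample(1:50, length(seqs), replace = TRUE)
  names(counts) <- seqs
  tab2 <- clone_tab(counts)
  nb2 <- single_mismatch_neighbors(tab2)
  oracle <- brute_hamming1_pairs(tab2$cdr3_nt)
  ci <- tab2$total_count[oracle$i]; cj <- tab2$total_count[oracle$j]
  keep <- ci != cj
  o_pairs <- sort(paste(ifelse(ci > cj, oracle$i, oracle$j)[keep],
                        ifelse(ci > cj, oracle$j, oracle$i)[keep]))
  n_pairs <- sort(paste(match(nb2$index_seq, tab2$cdr3_nt),
                        match(nb2$neighbor_seq, tab2$cdr3_nt)))
  expect_equal(n_pairs, o_pairs)
})

test_that("sequences of different length or equal count are never neighbors", {
  tab <- clone_tab(c(AAA = 5, AAT = 5, AAAA = 2))
  nb <- single_mismatch_neighbors(tab)
  expect_equal(nrow(nb), 0L)
})

test_that("monoclonal culling follows the stated cutoff semantics", {
  tab <- clone_tab(c(AAAAAA = 1000, AAAAAT = 5, AAAATT = 3))
  # cutoff 0 filters nothing
  r0 <- cull_monoclonal(tab, "AAAAAA", 0)
  expect_equal(nrow(r0$culled), 0L)
  expect_equal(r0$residual_error_fraction, 8 / 1008)
  # cutoff 0.01: the d1 sequence (5 <= 10) is culled, the d2 one stays
  r <- cull_monoclonal(tab, "AAAAAA", 0.01)
  expect_equal(r$culled$sequence, "AAAAAT")
  expect_equal(r$residual_error_fraction, 3 / 1003)
  # cutoff 1 removes every d1 sequence at or below the index count
  tabx <- clone_tab(c(AAAAAA = 10, AAAAAT = 10, TTAAAA = 12))
  r1 <- cull_monoclonal(tabx, "AAAAAA", 1)
  expect_equal(r1$culled$sequence, "AAAAAT")    # at index frequency: culled
  expect_true("TTAAAA" %in% r1$table$cdr3_nt)   # d2: untouched
  expect_true("AAAAAA" %in% r1$table$cdr3_nt)   # index never culled
  expect_error(cull_monoclonal(tab, "CCCCCC", 0.5), "not present")
})

test_that("residual error is non-increasing in the culling cutoff", {
  t <- tiny_template()
  s <- simulate_reads(t, error_model(sub_rate = 5e-3), n_reads = 4000,
                      seed = 59)
  ex <- extract_cdr3(s$reads, template_flanks(t))
  tab <- build_clone_table(ex$records)
  res <- vapply(c(0, 0.001, 0.01, 0.1, 1), function(ct)
    cull_monoclonal(tab, t$cdr3, ct)$residual_error_fraction, numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("culling at 1% removes at least the distance-1 single errors", {
  t <- tiny_template()
  m <- error_model(sub_rate = cdr3_only_matrix(t, 1e-3),
                   indel_rate = c(deletion = 0, insertion = 0))
  s <- simulate_reads(t, m, n_reads = 20000, seed = 61)
  ex <- extract_cdr3(s$reads, template_flanks(t))
  tab <- build_clone_table(ex$records)
  r <- cull_monoclonal(tab, t$cdr3, 0.01)
  cl <- cdr3err:::classify_records(ex$records, t$cdr3)
  err <- cl$records$category != "correct"
  # ground truth: fraction of errors that are distance-1 singles
  singles <- sum(cl$records$n_subs == 1L, na.rm = TRUE)
  culled_reads <- sum(r$culled$count)
  expect_gte(culled_reads / sum(err), 0.9 * singles / sum(err))
  expect_lt(r$residual_error_fraction, sum(err) / nrow(cl$records))
})

test_that("polyclonal tallies are monotone and zero for a single clone", {
  expect_equal(cull_polyclonal(clone_tab(c(AAA = 50)))$tallies$n_culled,
               rep(0L, 10))
  tab <- clone_tab(c(AAAAAA = 5000, AAAAAT = 20, AAAATA = 4, AAATAA = 1,
                     CCCCCC = 800, CCCCCT = 3))
  cp <- cull_polyclonal(tab, cutoffs = c(0.001, 0.005, 0.01), top_k = 20)
  expect_true(all(diff(cp$tallies$n_culled) >= 0))
  # strict "<" semantics: 20/5000 = 0.004 is NOT below cutoff 0.004
  cp2 <- cull_polyclonal(tab, cutoffs = 0.004)
  expect_equal(cp2$tallies$n_culled, 3L)  # AAAATA, AAATAA, CCCCCT; not AAAAAT
  # single-assignment: AAAAAC is d1 of both indexes but counted once
  tab3 <- clone_tab(c(AAAAAA = 1000, AAAAAT = 900, AAAAAC = 1))
  cp3 <- cull_polyclonal(tab3, cutoffs = 0.01)
  expect_equal(sum(cp3$per_index$n_culled), 1L)
  expect_equal(cp3$per_index$n_culled[cp3$per_index$index_seq == "AAAAAA"], 1L)
})

test_that("global single-mismatch tally matches the neighbor relation", {
  tab <- clone_tab(c(AAA = 10, AAT = 2, ATT = 2, TTT = 5))
  cp <- cull_polyclonal(tab)
  expect_equal(cp$global_mismatch_tally,
               nrow(single_mismatch_neighbors(tab)))
})

test_that("direction skew screening flags extremes and passes neutrals", {
  tab <- clone_tab(c(AAAAAA = 2000))
  tab$forward_count <- 1000L; tab$reverse_count <- 1000L
  skewed <- clone_tab(c(CCCCCC = 50))
  skewed$forward_count <- 50L; skewed$reverse_count <- 0L
  neutral <- clone_tab(c(GGGGGG = 50))
  neutral$forward_count <- 25L; neutral$reverse_count <- 25L
  tab_all <- rbind(tab, skewed, neutral)
  class(tab_all) <- c("clone_table", "data.frame")
  res <- direction_skew_screen(tab_all, min_reads = 20)
  expect_equal(res$p_fwd, 0.5)
  f <- res$flags
  expect_false(f$within[f$cdr3_nt == "CCCCCC"])   # 100% forward at n = 50
  expect_true(f$within[f$cdr3_nt == "GGGGGG"])    # at round(n * p_fwd)
})

test_that("direction-neutral simulated errors mostly fall inside boundaries", {
  t <- tiny_template()
  m <- error_model(sub_rate = cdr3_only_matrix(t, 8e-3),
                   indel_rate = c(deletion = 0, insertion = 0))
  s <- simulate_reads(t, m, n_reads = 50000, seed = 67)
  ex <- extract_cdr3(s$reads, template_flanks(t))
  tab <- build_clone_table(ex$records)
  res <- direction_skew_screen(tab, min_reads = 20)
  expect_gte(res$fraction_within, 0.9)
})
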