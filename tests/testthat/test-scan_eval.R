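test_that("window_length_rule", {
  expect_equal(window_length_rule(c(87, 90, 94)), 114L)
  expect_equal(window_length_rule(26), 46L)
  expect_equal(window_length_rule(100, pad = 0), 100L)
  expect_error(window_length_rule(integer(0)), "empty")
})

test_that("scan: window arithmetic, self-hit, shift invariance", {
  set.seed(41)
  q <- "GGGAAACCC"; db <- "(((...)))"
  genome <- paste0(rand_seq(30), q, rand_seq(30))
  rec <- scan(q, db, genome, window_len = 15, step = 1)
  expect_equal(nrow(rec), nchar(genome) - 15 + 1)
  expect_equal(rec$window_end - rec$window_start, rep(14L, nrow(rec)))
  self_score <- align_local(q, db, q, traceback = FALSE)
  expect_equal(max(rec$score), self_score)
  # the alignment target coordinates are genome-absolute
  bestrow <- rec[which.max(rec$score), ]
  expect_equal(substr(genome, bestrow$t_begin, bestrow$t_end), q)
  # translating the embedded member shifts the best window by the same amount
  genome_shift <- paste0(rand_seq(7), genome)
  rec2 <- scan(q, db, genome_shift, window_len = 15, step = 1)
  best1 <- rec$window_start[which.max(rec$score)]
  best2 <- rec2$window_start[which.max(rec2$score)]
  expect_equal(best2, best1 + 7L)
  expect_equal(max(rec2$score), max(rec$score))
})

test_that("scan degenerate windows and local floor", {
  set.seed(42)
  expect_warning(rec <- scan("ACGU", "....", "ACG", window_len = 10),
                 "truncated")
  expect_equal(nrow(rec), 1L)
  # decoy-only window: local score floored at 0
  rec <- scan("AAAA", "....", strrep("C", 12), window_len = 6, step = 2)
  expect_true(all(rec$score >= 0))
  expect_equal(rec$window_start, c(1L, 3L, 5L, 7L))
})

test_that("reverse-complement scanning finds a minus-strand member", {
  set.seed(43)
  q <- "GGGGAAACCCC"
  rc <- as.character(reverse_complement(q))
  genome <- paste0(rand_seq(20), rc, rand_seq(20))
  fwd <- scan(q, "...........", genome, window_len = 15)
  both <- scan(q, "...........", genome, window_len = 15, revcomp = TRUE)
  expect_gt(max(both$score), max(fwd$score))
  expect_true(any(both$strand == "-"))
})

test_that("evaluate_thresholds: zero-FP rule, FPR levels, pAUC", {
  # perfect separation
  ev <- evaluate_thresholds(c(10, 9, 8), c(5, 4))
  expect_equal(ev$zero_fp_threshold, 5)
  expect_equal(ev$misses_zero_fp, 0L)
  expect_equal(ev$pauc, 1)
  # a real score equal to the threshold is missed ("smaller than or equal")
  ev <- evaluate_thresholds(c(3), c(5))
  expect_equal(ev$misses_zero_fp, 1L)
  ev <- evaluate_thresholds(c(5, 7), c(5))
  expect_equal(ev$misses_zero_fp, 1L)
  expect_error(evaluate_thresholds(numeric(0), 1), "empty")
})

test_that("pAUC equals a rank-based computation and is scale invariant", {
  set.seed(44)
  # independent oracle: average over false scores of the clipped
  # indicator contribution, i.e. direct rectangle integration of the
  # empirical ROC restricted to FPR <= cap
  rank_pauc <- function(real, false, cap = 0.1) {
    nf <- length(false)
    thr <- sort(unique(c(real, false)), decreasing = TRUE)
    fpr <- vapply(thr, function(t) mean(false > t), numeric(1))
    tpr <- vapply(thr, function(t) mean(real > t), numeric(1))
    fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
    straln:::partial_auc(fpr, tpr, cap)
  }
  for (i in 1:10) {
    real <- round(stats::rnorm(20, 2), 2)
    false <- round(stats::rnorm(50), 2)
    ev <- evaluate_thresholds(real, false)
    expect_equal(ev$pauc, rank_pauc(real, false), tolerance = 1e-12)
    expect_gte(ev$pauc, 0); expect_lte(ev$pauc, 1)
    # strictly monotone transform leaves all metrics' ranks unchanged
    tr <- function(x) exp(x / 2)
    ev2 <- evaluate_thresholds(tr(real), tr(false))
    expect_equal(ev2$pauc, ev$pauc, tolerance = 1e-12)
    expect_equal(ev2$misses_zero_fp, ev$misses_zero_fp)
    expect_equal(ev2$levels$misses, ev$levels$misses)
  }
  # identical score lists: ties handled by the "> t" rule
  ev <- evaluate_thresholds(c(1, 2), c(1, 2))
  expect_equal(ev$pauc, rank_pauc(c(1, 2), c(1, 2)), tolerance = 1e-12)
})

test_that("fixture construction contract", {
  members <- lapply(1:5, function(i) rna_sequence(rand_seq(100), paste0("m", i)))
  fx <- make_fixture(members, genome_length_factor = 10, seed = 7)
  expect_equal(nchar(fx$genome$residues), 5000L)
  # all members embedded verbatim at the recorded coordinates
  for (i in 1:5) {
    mem <- members[[which(vapply(members, `[[`, "", "id") == fx$truth$member_id[i])]]
    expect_equal(substr(fx$genome$residues, fx$truth$start[i], fx$truth$end[i]),
                 mem$residues)
  }
  # truth intervals are disjoint, in bounds, ordered
  expect_true(all(diff(fx$truth$start) > 0))
  expect_true(all(fx$truth$start[-1] > fx$truth$end[-5]))
  expect_true(all(fx$truth$start >= 1 & fx$truth$end <= 5000))
  # determinism
  fx2 <- make_fixture(members, genome_length_factor = 10, seed = 7)
  expect_identical(fx$genome$residues, fx2$genome$residues)
  expect_identical(fx$truth, fx2$truth)
  fx3 <- make_fixture(members, genome_length_factor = 10, seed = 8)
  expect_false(identical(fx$genome$residues, fx3$genome$residues))
})

test_that("mutate_member respects structure", {
  set.seed(45)
  st <- random_regular_structure(30, pair_prob = 0.4, seed = 2)
  seqc <- random_compatible_sequence(st, seed = 3)
  # identity when nothing is allowed to change
  expect_equal(mutate_member(seqc, st, point_rate = 0, loop_indel_max = 0)$residues,
               seqc$residues)
  # determinism under a fixed seed
  m1 <- mutate_member(seqc, st, 0.3, 4, seed = 9)
  m2 <- mutate_member(seqc, st, 0.3, 4, seed = 9)
  expect_identical(m1$residues, m2$residues)
  # substitutions at paired positions stay complementary (compensatory)
  comp <- c("AU", "UA", "CG", "GC", "GU", "UG")
  for (k in 1:10) {
    mm <- mutate_member(seqc, st, point_rate = 0.5, loop_indel_max = 0, seed = k)
    ch <- strsplit(mm$residues, "")[[1]]
    duo <- paste0(ch[st$pairs[, 1]], ch[st$pairs[, 2]])
    expect_true(all(duo %in% comp))
  }
  # indel only changes length within the allowed bound
  lens <- vapply(1:20, function(k)
    length(mutate_member(seqc, st, 0, 5, seed = k)), integer(1))
  expect_true(all(abs(lens - 30) <= 5))
})

test_that("labelling scan hits against truth", {
  rec <- data.frame(query_id = "q", target_id = "g",
                    window_start = c(1L, 11L, 21L), window_end = c(10L, 20L, 30L),
                    score = c(1, 9, 2), q_begin = 1L, q_end = 1L,
                    t_begin = 1L, t_end = 1L, strand = "+")
  truth <- data.frame(member_id = "m1", start = 12L, end = 19L)
  lab <- label_scan_hits(rec, truth)
  expect_equal(lab$real_scores, 9)
  expect_equal(lab$false_scores, c(1, 2))
  expect_equal(lab$records$is_real_hit, c(FALSE, TRUE, FALSE))
})
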