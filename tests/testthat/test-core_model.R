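test_that("rna_sequence normalizes input and rejects bad residues", {
  x <- rna_sequence("acgt", "q1")
  expect_equal(x$residues, "ACGU")
  expect_equal(length(x), 4L)
  expect_equal(rna_sequence("")$residues, "")
  expect_error(rna_sequence("ACXU", "bad"), "position 3.*'bad'")
  expect_error(rna_sequence("ACGN"), "illegal residue 'N'")
})

test_that("secondary_structure enforces Definition-1 regularity", {
  st <- secondary_structure(rbind(c(1, 7), c(2, 6)), 7)
  expect_equal(nrow(st$pairs), 2L)
  # pair order is normalized to i < j
  st2 <- secondary_structure(rbind(c(6, 2)), 7)
  expect_equal(unname(st2$pairs[1, ]), c(2L, 6L))
  expect_error(secondary_structure(rbind(c(1, 3), c(2, 4)), 4), "crossing")
  expect_error(secondary_structure(rbind(c(1, 3), c(3, 4)), 4), "share position")
  expect_error(secondary_structure(rbind(c(0, 3)), 4), "outside")
})

test_that("restriction keeps only fully contained pairs", {
  st <- secondary_structure(rbind(c(1, 8), c(3, 6)), 8)
  r <- restrict_structure(st, 2, 7)   # (1,8) dropped, (3,6) -> (2,5)
  expect_equal(unname(r$pairs), matrix(c(2L, 5L), 1))
  expect_equal(r$seq_length, 6L)
  expect_equal(restrict_structure(st, 5, 2)$seq_length, 0L)
})

test_that("validate_structure flags non-complementary pairs, errors on demand", {
  seqc <- rna_sequence("GAAC")
  expect_length(validate_structure(secondary_structure(rbind(c(1, 4)), 4), seqc), 0)
  warnpair <- secondary_structure(rbind(c(1, 4)), 4)
  msgs <- validate_structure(warnpair, rna_sequence("GAAA"))
  expect_length(msgs, 1)
  expect_match(msgs, "G-A")
  expect_error(validate_structure(warnpair, rna_sequence("GAAA"), strict = TRUE))
  expect_error(validate_structure(warnpair, rna_sequence("GAAAA")), "length")
})

test_that("alignment invariants: gap runs, eta, bad columns", {
  a <- rna_alignment("G---C", "GAAAC", c(1, 2), c(1, 5))
  expect_equal(a$gap_count, 1L)
  expect_equal(a$gap_total, 3L)
  expect_equal(a$eta, c(1L, NA, NA, NA, 2L))
  b <- rna_alignment("AC-G", "A-UG", c(1, 3), c(1, 3))
  expect_equal(b$gap_count, 2L)   # one run per string
  expect_equal(b$gap_total, 2L)
  expect_error(rna_alignment("A-", "A-", c(1, 1), c(1, 1)), "both")
  expect_error(rna_alignment("AX", "AC", c(1, 2), c(1, 2)))
})

test_that("reference_score: gaps, pairs, broken pairs", {
  sch <- default_scheme()              # h = 5, s = 0.1
  st0 <- secondary_structure(NULL, 1)
  # single space costs h + s
  a <- rna_alignment("A", "-", c(1, 1), c(1, 0))
  expect_equal(reference_score(a, st0, sch), -5.1)
  # no gaps, no pairs: plain gamma sum
  st4 <- secondary_structure(NULL, 4)
  a <- rna_alignment("ACGU", "ACGU", c(1, 4), c(1, 4))
  expect_equal(reference_score(a, st4, sch), 4)
  # one pair fully aligned + one 3-space gap
  stp <- secondary_structure(rbind(c(1, 2)), 2)
  a <- rna_alignment("G---C", "GAAAC", c(1, 2), c(1, 5))
  dexp <- sch$delta["G", "C", "G", "C"]
  expect_equal(reference_score(a, stp, sch), dexp - (5 + 3 * 0.1))
  # broken pair: endpoint opposite a space scores gamma for the survivor
  a <- rna_alignment("GC", "G-", c(1, 2), c(1, 1))
  expect_equal(reference_score(a, stp, sch),
               sch$gamma["G", "G"] - (5 + 0.1))
  # partner excluded from the aligned substring: gamma as well
  a <- rna_alignment("C", "C", c(2, 2), c(1, 1))
  expect_equal(reference_score(a, stp, sch), sch$gamma["C", "C"])
})

test_that("reference_score properties: penalty monotonicity and gap splitting", {
  set.seed(101)
  st <- random_regular_structure(6, pair_prob = 0.5, min_loop = 0)
  a <- rna_alignment("ACG--U", "AC-GUU", c(1, 5), c(1, 5))
  # note query range 1..5 of a length-6 structure: restriction applies
  base <- reference_score(a, st, scoring_scheme(gap_open = 2, gap_extend = 0.5))
  more_h <- reference_score(a, st, scoring_scheme(gap_open = 3, gap_extend = 0.5))
  more_s <- reference_score(a, st, scoring_scheme(gap_open = 2, gap_extend = 1))
  expect_lt(more_h, base)
  expect_lt(more_s, base)
  # splitting one gap of length 2 into two runs of length 1 costs one more h
  sch <- default_scheme()
  st4 <- secondary_structure(NULL, 4)
  a1 <- rna_alignment("AAAA", "A--A", c(1, 4), c(1, 2))   # k = 1, l = 2
  a2 <- rna_alignment("AAAA", "A-A-", c(1, 4), c(1, 2))   # k = 2, l = 2
  expect_equal(reference_score(a1, st4, sch) - reference_score(a2, st4, sch), 5)
})
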