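test_that("brute force handles degenerate inputs literally", {
  sch <- default_scheme()
  # single characters: gamma when positive, else empty alignment
  expect_equal(brute_force_local("A", ".", "A", sch)$score, 1)
  expect_equal(brute_force_local("A", ".", "C", sch)$score, 0)
  # any query against empty target: empty-empty wins
  expect_equal(brute_force_local("ACGU", "....", "", sch)$score, 0)
  expect_error(brute_force_local(strrep("A", 9), strrep(".", 9), "A", sch),
               "max_size")
})

test_that("brute force returns an alignment achieving its own score", {
  set.seed(21)
  for (i in 1:20) {
    inst <- rand_instance(max_m = 5, max_n = 5)
    sch <- test_schemes()[[sample(3, 1)]]
    bf <- brute_force_local(inst$q, inst$st, inst$t, sch)
    expect_equal(reference_score(bf$alignment, inst$st, sch), bf$score,
                 tolerance = 1e-9)
  }
})

test_that("the two independent enumerators agree exactly", {
  set.seed(22)
  for (i in 1:10) {
    inst <- rand_instance(max_m = 3, max_n = 3)
    sch <- test_schemes()[[sample(3, 1)]]
    r_enum <- straln:::enumerate_alignments_r(inst$q, inst$st, inst$t, sch)
    cpp_enum <- brute_force_local(inst$q, inst$st, inst$t, sch)
    expect_equal(r_enum$score, max(cpp_enum$score, 0), tolerance = 1e-9)
  }
})

test_that("gotoh_local equals brute force on structure-free instances", {
  set.seed(23)
  expect_equal(gotoh_local("ACGU", "ACGU", default_scheme()), 4)
  expect_equal(gotoh_local("AAAA", "CCCC", default_scheme()), 0)
  for (i in 1:25) {
    m <- sample(0:5, 1); n <- sample(0:5, 1)
    q <- rand_seq(m); t <- rand_seq(n)
    sch <- test_schemes()[[sample(3, 1)]]
    bf <- brute_force_local(q, strrep(".", m), t, sch)$score
    expect_equal(gotoh_local(q, t, sch), max(bf, 0), tolerance = 1e-9)
  }
})
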