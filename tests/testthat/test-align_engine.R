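test_that("closed forms and trivial base cases", {
  sch <- default_scheme()   # h = 5, s = 0.1
  # whole query against empty target: one gap spanning S
  a <- align_global("A", ".", "", sch)
  expect_equal(a$score, -5.1, tolerance = 1e-12)
  expect_equal(a$s_prime, "A")
  expect_equal(a$t_prime, "-")
  expect_equal(align_global("ACG", "...", "", sch)$score, -(5 + 3 * 0.1),
               tolerance = 1e-12)
  # identical sequences, no structure
  a <- align_local("ACGU", "....", "ACGU", sch)
  expect_equal(a$score, 4)
  expect_equal(a$s_prime, "ACGU")
  expect_equal(a$query_range, c(1L, 4L))
  # all mismatches: local floor at zero, empty alignment
  a <- align_local("AAAA", "....", "CCCC", sch)
  expect_equal(a$score, 0)
  expect_equal(a$s_prime, "")
  expect_true(a$query_range[1] > a$query_range[2])
  # empty target: semi-global picks the empty substring
  expect_equal(align_semiglobal("ACGU", "....", "", sch)$score, 0)
  # single-pair query on matching pair: delta scored
  a <- align_global("GC", "()", "GC", sch)
  expect_equal(a$score, unname(sch$delta["G", "C", "G", "C"]))
  # exact unpaired submatch inside a larger query
  a <- align_semiglobal("GGAAACC", ".......", "AAA", sch)
  expect_equal(a$score, 3)
})

test_that("hairpin identity aligns pair columns without gaps", {
  sch <- default_scheme()
  q <- "GGGAAACCC"; db <- "(((...)))"
  a <- align_local(q, db, q, sch)
  expect_equal(a$s_prime, q)
  expect_equal(a$t_prime, q)
  expect_equal(a$gap_count, 0L)
  d <- sch$delta
  expect_equal(a$score,
               3 * unname(d["G", "C", "G", "C"]) + 3 * unname(sch$gamma["A", "A"]))
  st <- parse_dot_bracket(db)
  expect_equal(reference_score(a, st, sch), a$score)
})

test_that("compensatory mutations outscore pairing-breaking ones", {
  # both targets differ from the query at the same six stem positions,
  # but one conserves base pairing (compensatory) and the other breaks it
  sch <- default_scheme()
  q <- "GGGAAACCC"; db <- "(((...)))"
  comp <- "CCCAAAGGG"      # G-C stems become C-G: pairing conserved
  noncomp <- "CCCAAAUUU"   # same mutated positions, pairing destroyed
  s_comp <- align_global(q, db, comp, sch, traceback = FALSE)
  s_noncomp <- align_global(q, db, noncomp, sch, traceback = FALSE)
  expect_gt(s_comp, s_noncomp)
  # and the conserved structure scores above plain character identity
  expect_equal(s_comp, 3 * unname(sch$delta["G", "C", "C", "G"]) + 3)
})

test_that("ordering and floor invariants across random instances", {
  set.seed(71)
  for (i in 1:40) {
    inst <- rand_instance(max_m = 8, max_n = 8)
    sch <- test_schemes()[[sample(3, 1)]]
    lo <- align_local(inst$q, inst$st, inst$t, sch, traceback = FALSE)
    sg <- align_semiglobal(inst$q, inst$st, inst$t, sch, traceback = FALSE)
    gl <- align_global(inst$q, inst$st, inst$t, sch, traceback = FALSE)
    expect_gte(lo, 0)
    expect_lte(gl, sg + 1e-12)
    expect_lte(sg, lo + 1e-12)
  }
})

test_that("appending target characters never decreases the local score", {
  set.seed(72)
  for (i in 1:15) {
    inst <- rand_instance(max_m = 8, max_n = 8, min_m = 1)
    sch <- default_scheme()
    s1 <- align_local(inst$q, inst$st, inst$t, sch, traceback = FALSE)
    s2 <- align_local(inst$q, inst$st, paste0(inst$t, rand_seq(3)), sch,
                      traceback = FALSE)
    expect_gte(s2, s1 - 1e-12)
  }
})

test_that("workspace tables satisfy the four-way maximum and match enumeration", {
  set.seed(73)
  for (i in 1:12) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    q <- rand_seq(m); t <- rand_seq(n)
    st <- random_regular_structure(m, pair_prob = 0.6, min_loop = 0)
    sch <- test_schemes()[[sample(3, 1)]]
    ws <- align_semiglobal_tables(q, st, t, sch)
    # A = max(A1, A2, A3, A4) cell-wise (the Lemma-1 four-way maximum)
    comp <- c(ws$A1, ws$A2, ws$A3, list(ws$A4))
    stacked <- do.call(pmax, c(comp, list(na.rm = FALSE)))
    idx <- !is.na(ws$A)
    expect_equal(ws$A[idx], stacked[idx], tolerance = 1e-9)
    # every component equals its brute-force enumeration bucket
    bt <- straln:::brute_force_tables(q, st, t, sch)
    flat <- function(x) { x[is.infinite(x)] <- -1e9; x }
    for (cs in 1:9) expect_equal(flat(ws$A1[[cs]]), flat(bt$A1[[cs]]),
                                 tolerance = 1e-9)
    for (cs in 1:4) expect_equal(flat(ws$A2[[cs]]), flat(bt$A2[[cs]]),
                                 tolerance = 1e-9)
    for (cs in 1:4) expect_equal(flat(ws$A3[[cs]]), flat(bt$A3[[cs]]),
                                 tolerance = 1e-9)
    expect_equal(flat(ws$A4), flat(bt$A4), tolerance = 1e-9)
    expect_equal(flat(ws$A), flat(bt$A), tolerance = 1e-9)
  }
})

test_that("traceback from workspace cells reproduces cell scores", {
  set.seed(74)
  for (i in 1:8) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    q <- rand_seq(m); t <- rand_seq(n)
    st <- random_regular_structure(m, pair_prob = 0.6, min_loop = 0)
    sch <- test_schemes()[[sample(3, 1)]]
    ws <- align_semiglobal_tables(q, st, t, sch)
    for (e in 1:(n + 1)) for (f in (e - 1):n) {
      v <- ws$A[e, f + 1]
      if (!is.na(v) && is.finite(v)) {
        aln <- traceback(ws, "A", e = e, f = f)
        expect_equal(aln$score, v, tolerance = 1e-12)
        expect_equal(reference_score(aln, st, sch), v, tolerance = 1e-9)
      }
      for (cs in 1:9) {
        v <- ws$A1[[cs]][e, f + 1]
        if (!is.na(v) && is.finite(v)) {
          aln <- traceback(ws, "A1", case = cs, e = e, f = f)
          expect_equal(reference_score(aln, st, sch), v, tolerance = 1e-9)
        }
      }
    }
  }
  # empty-empty cell gives the empty alignment with score 0
  ws <- align_semiglobal_tables("ACG", "...", "ACG", default_scheme())
  aln <- traceback(ws, "A", e = 2, f = 1)
  expect_equal(aln$score, 0)
  expect_equal(nchar(aln$s_prime), 0L)
})

test_that("tie-breaking is deterministic: identical runs, identical output", {
  set.seed(75)
  inst <- rand_instance(max_m = 8, max_n = 8, min_m = 2)
  a1 <- align_local(inst$q, inst$st, inst$t)
  a2 <- align_local(inst$q, inst$st, inst$t)
  expect_identical(a1$s_prime, a2$s_prime)
  expect_identical(a1$t_prime, a2$t_prime)
  expect_identical(a1$score, a2$score)
})
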