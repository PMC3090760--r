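test_that("decompose applies the three dependency cases", {
  # nested stem: PAIRED chain down to the loop
  d <- decompose(secondary_structure(rbind(c(1, 6), c(2, 5)), 6))
  key <- paste(d$p, d$q, d$case)
  expect_true(all(c("1 6 PAIRED", "2 5 PAIRED", "3 4 UNPAIRED",
                    "4 4 UNPAIRED") %in% key))
  expect_true(any(d$case == "EMPTY"))
  # two hairpins: SPLIT nodes with the recorded split point
  d <- decompose(secondary_structure(rbind(c(2, 4), c(5, 7)), 8))
  expect_equal(d$case[d$p == 1 & d$q == 8], "UNPAIRED")
  expect_equal(d$split_at[d$p == 2 & d$q == 8], 4L)
  expect_equal(d$case[d$p == 2 & d$q == 8], "SPLIT")
  expect_equal(d$case[d$p == 2 & d$q == 4], "PAIRED")
  expect_equal(d$split_at[d$p == 5 & d$q == 8], 7L)
  expect_equal(d$case[d$p == 5 & d$q == 7], "PAIRED")
  expect_equal(d$case[d$p == 8 & d$q == 8], "UNPAIRED")
})

test_that("structure-free query degenerates to the suffix chain", {
  d <- decompose(secondary_structure(NULL, 4))
  nonempty <- d[d$case != "EMPTY", ]
  expect_equal(nonempty$p[order(nonempty$p)], 1:4)
  expect_true(all(nonempty$q == 4))
  expect_true(all(nonempty$case == "UNPAIRED"))
  expect_equal(nrow(d), 5L)   # m + 1 including the base case
})

test_that("children precede parents and shrink properly", {
  set.seed(31)
  for (i in 1:20) {
    m <- sample(2:60, 1)
    st <- random_regular_structure(m, pair_prob = 0.5, min_loop = 0)
    d <- decompose(st)
    seen <- character(0)
    for (r in seq_len(nrow(d))) {
      seen <- c(seen, paste(d$p[r], d$q[r]))
      if (d$case[r] %in% c("PAIRED", "UNPAIRED", "SPLIT")) {
        expect_true(paste(d$child1_p[r], d$child1_q[r]) %in% seen)
        if (d$case[r] == "SPLIT") {
          expect_true(paste(d$child2_p[r], d$child2_q[r]) %in% seen)
          # split children partition the parent
          expect_equal(d$child1_q[r] + 1L, d$child2_p[r])
          expect_equal(d$child1_p[r], d$p[r])
          expect_equal(d$child2_q[r], d$q[r])
        } else {
          sz_parent <- d$q[r] - d$p[r] + 1L
          sz_child <- d$child1_q[r] - d$child1_p[r] + 1L
          expect_lt(sz_child, sz_parent)
        }
      }
    }
  }
})

test_that("node count bound and pair coverage hold over random structures", {
  set.seed(32)
  for (i in 1:200) {
    m <- sample(1:200, 1)
    st <- random_regular_structure(m, pair_prob = stats::runif(1, 0, 0.6),
                                   min_loop = sample(0:3, 1))
    d <- decompose(st)
    expect_lte(nrow(d), 2 * m + 1)
    expect_true(paste(1, m) %in% paste(d$p, d$q))
    # every reachable base pair appears as a PAIRED node's (p, q)
    if (nrow(st$pairs)) {
      paired <- d[d$case == "PAIRED", c("p", "q")]
      expect_true(all(paste(st$pairs[, 1], st$pairs[, 2]) %in%
                        paste(paired$p, paired$q)))
    }
  }
})
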