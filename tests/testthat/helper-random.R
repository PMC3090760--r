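# shared generators for randomized / property-style tests

ALPH <- c("A", "C", "G", "U")

rand_seq <- function(n) paste0(sample(ALPH, n, replace = TRUE), collapse = "")

# random dense scheme; values on a coarse grid to keep magnitudes tame
rand_scheme <- function(dense_delta = FALSE,
                        h = sample(c(0, 1, 5), 1),
                        s = sample(c(0, 0.1, 0.5), 1)) {
  g <- matrix(round(stats::runif(16, -2, 2), 2), 4, 4,
              dimnames = list(ALPH, ALPH))
  d <- if (dense_delta) array(round(stats::runif(256, -3, 4), 2), c(4, 4, 4, 4))
       else NULL
  scoring_scheme(gamma = g, delta = d, gap_open = h, gap_extend = s)
}

# schemes covering the acceptance requirement: the h = 5, s = 0.1 default,
# a gap-free scheme, and a dense random delta
test_schemes <- function() {
  list(default_scheme(),                      # h = 5, s = 0.1
       rand_scheme(dense_delta = FALSE, h = 1, s = 0.5),
       rand_scheme(dense_delta = TRUE))
}

# one random instance: sequences + random regular structure
rand_instance <- function(max_m = 6, max_n = 6, min_m = 0,
                          pair_prob = 0.6, min_loop = 0) {
  m <- sample(min_m:max_m, 1)
  n <- sample(0:max_n, 1)
  list(q = rand_seq(m), t = rand_seq(n), m = m, n = n,
       st = random_regular_structure(m, pair_prob = pair_prob,
                                     min_loop = min_loop))
}

expect_score_equal <- function(a, b, tol = 1e-9, info = NULL) {
  expect_true(is.finite(a) == is.finite(b) &&
                (!is.finite(a) || abs(a - b) <= tol), info = info)
}
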