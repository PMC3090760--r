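test_that("read_fasta normalizes and errors precisely", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACGT"), f)
  x <- read_fasta(f)
  expect_length(x, 1)
  expect_equal(x[[1]]$residues, "ACGU")
  writeLines(c(">a", "AC", ">b", "GU"), f)
  expect_equal(vapply(read_fasta(f), `[[`, "", "id"), c("a", "b"))
  writeLines(c(">q", "ACXU"), f)
  expect_error(read_fasta(f), "position 3")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("FASTA round-trips modulo T/U and case normalization", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- list(rna_sequence("ACGUACGU", "s1"), rna_sequence("", "empty"),
               rna_sequence(strrep("ACGU", 40), "long"))
  write_fasta(seqs, f, width = 50)
  back <- read_fasta(f)
  expect_equal(lapply(back, `[[`, "residues"), lapply(seqs, `[[`, "residues"))
})

test_that("dot-bracket parser matches innermost-first and reports errors", {
  expect_equal(unname(parse_dot_bracket("((...))")$pairs),
               matrix(c(1L, 2L, 7L, 6L), 2))
  expect_equal(nrow(parse_dot_bracket(".....")$pairs), 0L)
  expect_error(parse_dot_bracket("(.)("), "position 4")
  expect_error(parse_dot_bracket("())"), "position 3")
  expect_error(parse_dot_bracket("(.["), "illegal structure character")
})

test_that("write_dot_bracket is the inverse of parse_dot_bracket", {
  expect_equal(write_dot_bracket(secondary_structure(rbind(c(1, 7), c(2, 6)), 7)),
               "((...))")
  expect_equal(write_dot_bracket(secondary_structure(NULL, 3)), "...")
  expect_equal(write_dot_bracket(secondary_structure(rbind(c(2, 4)), 5)), ".(.).")
  # property: round trip over random regular structures
  set.seed(5)
  for (i in 1:25) {
    st <- random_regular_structure(sample(1:40, 1), pair_prob = 0.5)
    back <- parse_dot_bracket(write_dot_bracket(st))
    expect_equal(back$pairs[order(back$pairs[, 1]), , drop = FALSE], st$pairs)
  }
})

test_that("structure file reader accepts both dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "((..))"), f)
  expect_equal(write_dot_bracket(read_structure_file(f)), "((..))")
  writeLines(c(">q", "GGAACC", "((..))"), f)
  expect_equal(write_dot_bracket(read_structure_file(f)), "((..))")
})

test_that("scoring config round-trips and defaults apply", {
  f <- withr::local_tempfile(fileext = ".json")
  sch <- scoring_scheme(gap_open = 3, gap_extend = 0.25)
  write_scoring_config(sch, f)
  back <- read_scoring_config(f)
  expect_equal(back$gamma, sch$gamma)
  expect_equal(back$delta, sch$delta)
  expect_equal(back$gap_open, 3)
  expect_equal(back$gap_extend, 0.25)
  # dense delta round-trip
  set.seed(9)
  dense <- scoring_scheme(gamma = matrix(stats::runif(16), 4, 4,
                                         dimnames = list(c("A","C","G","U"),
                                                         c("A","C","G","U"))),
                          delta = array(stats::runif(256), c(4, 4, 4, 4)),
                          gap_open = 1, gap_extend = 0.5)
  write_scoring_config(dense, f)
  back <- read_scoring_config(f)
  expect_equal(back$delta, dense$delta, tolerance = 1e-12, ignore_attr = TRUE)
  # absent keys fall back to the default scheme
  writeLines('{"gap_open": 7}', f)
  part <- read_scoring_config(f)
  expect_equal(part$gap_open, 7)
  expect_equal(part$gamma, default_scheme()$gamma)
  expect_equal(part$gap_extend, 0.1)
})

test_that("write_results: ordering, header-only, canonical columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rec <- data.frame(query_id = "q", target_id = "t",
                    window_start = c(5L, 1L), window_end = c(9L, 5L),
                    score = c(2, 1), q_begin = 1L, q_end = 3L,
                    t_begin = 1L, t_end = 3L)
  write_results(rec, f, comments = "prov")
  back <- read_results(f)
  expect_equal(back$window_start, c(1L, 5L))   # sorted by window start
  expect_equal(readLines(f, n = 1), "# prov")
  write_results(rec[0, ], f)
  back <- read_results(f)
  expect_equal(nrow(back), 0L)
  expect_equal(names(back)[1:5],
               c("query_id", "target_id", "window_start", "window_end", "score"))
  expect_error(write_results(rec, file.path(tempdir(), "no/such/dir/x.tsv")),
               "cannot write")
})
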