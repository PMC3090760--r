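Package: straln
Title: Local Structural Alignment of RNA with Affine Gap Penalties
Version: 0.1.0
Authors@R:
    person("straln", "developers", email = "straln@example.org", role = c("aut", "cre"))
Description: Optimal local, global and semi-global structural alignment
    between a query RNA with known pseudoknot-free secondary structure and
    a target sequence of unknown structure, under an affine gap penalty
    model (a gap of length L costs h + s*L).  The dynamic programming
    engine decomposes the query by its base-pair structure into O(m)
    intervals and fills boundary-case-resolved score tables over all
    target substrings, yielding the optimum in O(m*n^3) time.  Includes
    exhaustive brute-force oracles for certification on small inputs, a
    genome scanning mode with the l+20 windowing rule, threshold and
    partial-AUC evaluation of scan results, a synthetic-family fixture
    generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
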