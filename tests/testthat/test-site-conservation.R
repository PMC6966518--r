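test_that("site predictions are validated against the sequences", {
  seqs <- c(seqA = "MKSVTGLY", seqB = "MKS-TGLY")
  txt <- paste("id\tposition\tresidue\tscore\tkinase",
               "seqA\t3\tS\t0.90\tunsp",      # Ser at 3: accepted
               "seqA\t5\tT\t0.70\tunsp",      # Thr at 5: accepted
               "seqB\t4\tT\t0.80\tunsp",      # degapped seqB has T at 4
               "seqA\t6\tT\t0.50\tunsp",      # Gly at 6 claimed Thr: rejected
               "seqA\t2\tK\t0.50\tunsp",      # Lys is not an acceptor
               "seqA\t99\tS\t0.50\tunsp",     # beyond sequence
               sep = "\n")
  expect_warning(calls <- load_site_predictions(txt, seqs), "skipped 3")
  expect_equal(nrow(calls), 3)
  expect_setequal(attr(calls, "rejected")$reason,
                  c("residue-mismatch", "not-an-acceptor",
                    "position-beyond-sequence"))
})

test_that("empty site prediction input yields an empty table, not an error", {
  expect_equal(nrow(load_site_predictions("", c(a = "MKS"))), 0)
  expect_equal(nrow(load_site_predictions("id\tposition\tresidue\tscore",
                                          c(a = "MKS"))), 0)
})

test_that("site predictions round-trip through the writer", {
  calls <- data.frame(id = "seqA", position = 3L, residue = "S",
                      score = 0.9, kinase = "PKC", stringsAsFactors = FALSE)
  back <- load_site_predictions(write_site_predictions(calls),
                                c(seqA = "MKSVTGLY"))
  expect_equal(back$position, 3L)
  expect_equal(back$score, 0.9)
  expect_equal(back$kinase, "PKC")
})

test_that("minimum conservation counts follow the ceiling rule", {
  expect_identical(min_count_for_fraction(208, 0.97), 202L)
  expect_identical(min_count_for_fraction(208, 0.99), 206L)
  expect_identical(min_count_for_fraction(10, 0.97), 10L)
  for (n in c(1, 7, 50, 300)) {
    expect_identical(min_count_for_fraction(n, 1.0), as.integer(n))
  }
  # against an exhaustive scan of candidate counts
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:250, 1)
    f <- runif(1, 0.01, 1)
    scan <- which(vapply(1:n, function(cc) cc / n >= f, logical(1)))[1]
    expect_identical(min_count_for_fraction(n, f), as.integer(scan))
  }
  expect_error(min_count_for_fraction(0, 0.5), class = "gelmap_parameter_error")
  expect_error(min_count_for_fraction(10, 0), class = "gelmap_parameter_error")
})

test_that("tier assignment distinguishes the 100/99/97% bands", {
  p <- conservation_params()
  t1 <- tier_sites(c(208, 206, 205, 202, 201), 208, p)
  # 205/208 = 98.6% misses the 99% band (needs 206) but makes 97%
  expect_equal(t1$tier, c("100%", "99%", "97%", "97%", "below"))
  expect_equal(unname(t1$min_counts), c(208L, 206L, 202L))
  expect_equal(unname(t1$cumulative), c(1L, 2L, 4L))      # monotone
  expect_equal(unname(t1$bands), c(1L, 1L, 2L, 1L))
  expect_error(tier_sites(c(5, 9), 8, p), class = "gelmap_validation_error")
})

test_that("conservation params validate thresholds and tiers", {
  expect_error(conservation_params(score_threshold = 1.2),
               class = "gelmap_parameter_error")
  expect_error(conservation_params(tier_fractions = c(0.97, 0.99)),
               class = "gelmap_parameter_error")
})

test_that("a fully planted site lands in the 100% tier; 0.65 is excluded", {
  aln <- setNames(rep("MKSVTGLY", 10), sprintf("s%02d", 1:10))
  maps <- gapmaps_of(aln)
  calls <- data.frame(id = names(aln), position = 3L, residue = "S",
                      score = 0.9, stringsAsFactors = FALSE)
  cs <- conservation_tally(calls, maps, "s01")
  expect_equal(cs$fraction, 1.0)
  expect_equal(cs$tier, "100%")
  expect_equal(cs$count, 10L)

  # a score exactly at the threshold does not count ("higher than 0.65")
  calls$score <- 0.65
  cs <- conservation_tally(calls, maps, "s01")
  expect_equal(nrow(cs), 0)
})

test_that("orthologues are counted once per reference position", {
  aln <- c(ref = "SKSSY", o1 = "SKSSY")
  maps <- gapmaps_of(aln)
  # o1 contributes two calls that land on the same reference serine
  calls <- data.frame(id = c("o1", "o1", "ref"), position = c(3L, 3L, 3L),
                      residue = "S", score = c(0.9, 0.95, 0.8),
                      stringsAsFactors = FALSE)
  cs <- conservation_tally(calls, maps, "ref")
  expect_equal(cs$count, 2L)  # ref + o1, not 3 calls
})

test_that("sites landing on reference gaps are excluded and recorded", {
  aln <- c(ref = "PKSPV-Y", o1 = "PKS-VQY")
  maps <- gapmaps_of(aln)
  calls <- data.frame(id = "o1", position = 5L, residue = "S", score = 0.9,
                      stringsAsFactors = FALSE)  # Q column, ref gapped
  calls$residue <- "S"  # acceptor for validation; liftover is what matters
  cs <- conservation_tally(calls, maps, "ref")
  expect_equal(nrow(cs), 0)
  expect_equal(nrow(attr(cs, "unmappable")), 1)
})

test_that("residue-match modes differ when acceptors disagree", {
  aln <- c(ref = "MKSVA", o1 = "MKTVA")   # ref has Ser, orthologue Thr
  maps <- gapmaps_of(aln)
  calls <- data.frame(id = c("ref", "o1"), position = 3L,
                      residue = c("S", "T"), score = 0.9,
                      stringsAsFactors = FALSE)
  exact <- conservation_tally(calls, maps, "ref", conservation_params())
  expect_equal(exact$count, 1L)           # only the reference's own Ser
  cls <- conservation_tally(calls, maps, "ref",
                            conservation_params(residue_match = "acceptor-class"))
  expect_equal(cls$count, 2L)             # Thr call supports the position too
})

test_that("conservation tally equals the brute-force triple loop", {
  set.seed(21)
  for (i in 1:8) {
    fam <- simulate_orthologue_family(family_sim_params(
      n_orthologues = sample(8:20, 1), ref_length = 50,
      planted_sites = data.frame(pos = c(10L, 25L, 40L),
                                 residue = c("S", "T", "Y"),
                                 presence = runif(3)),
      seed = sample.int(1e6, 1)))
    maps <- gapmaps_of(fam$alignment)
    cs <- conservation_tally(fam$calls, maps, fam$reference_id)
    oracle <- brute_conservation_counts(fam$calls, fam$alignment,
                                        fam$reference_id)
    expect_equal(setNames(cs$count, cs$ref_pos), oracle)
    # permuting the call rows changes nothing
    cs2 <- conservation_tally(fam$calls[sample(nrow(fam$calls)), ],
                              maps, fam$reference_id)
    for (col in c("ref_pos", "residue", "count", "fraction", "tier",
                  "supporting")) {
      expect_equal(cs2[[col]], cs[[col]])
    }
  }
})

test_that("domain annotation uses closed 1-based intervals", {
  expect_equal(annotate_domains(c(1, 29, 30, 107, 110, 118, 446, 447, 463, 657, 700)),
               c("signal", "signal", "propeptide", "propeptide",
                 "inter-domain", "catalytic", "catalytic", "inter-domain",
                 "hemopexin", "hemopexin", "inter-domain"))
  expect_error(annotate_domains(0), class = "gelmap_validation_error")
})

test_that("conserved sites export as TSV with tier and domain columns", {
  aln <- setNames(rep(paste(rep("S", 40), collapse = ""), 5),
                  sprintf("s%d", 1:5))
  maps <- gapmaps_of(aln)
  calls <- data.frame(id = rep(names(aln), each = 1), position = 30L,
                      residue = "S", score = 0.99, stringsAsFactors = FALSE)
  cs <- conservation_tally(calls, maps, "s1")
  tsv <- strsplit(write_conserved_sites(cs), "\n")[[1]]
  expect_match(tsv[1], "^ref_pos\tresidue\tcount")
  expect_match(tsv[2], "^30\tS\t5\t1\t100%\tpropeptide")
})
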