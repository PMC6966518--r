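test_that("family simulation is byte-identical under a fixed seed", {
  p <- family_sim_params(n_orthologues = 15, ref_length = 60, seed = 101)
  a <- simulate_orthologue_family(p)
  b <- simulate_orthologue_family(p)
  expect_identical(a$fasta, b$fasta)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_orthologue_family(family_sim_params(
    n_orthologues = 15, ref_length = 60, seed = 102))
  expect_false(identical(a$fasta, c2$fasta))
})

test_that("planted presence fractions are realised in the truth table", {
  # presence 1.0: every orthologue carries a high-scoring site
  fam <- simulate_orthologue_family(family_sim_params(
    n_orthologues = 10, ref_length = 40,
    planted_sites = data.frame(pos = 20L, residue = "S", presence = 1.0),
    seed = 3))
  expect_true(all(fam$truth$site_presence))
  high <- fam$calls$score > 0.65
  expect_equal(sum(high), 10)

  # presence 0.5 at n = 208: empirical fraction within 3 * sqrt(0.25/208)
  fam2 <- simulate_orthologue_family(family_sim_params(
    n_orthologues = 208, ref_length = 60,
    planted_sites = data.frame(pos = 30L, residue = "T", presence = 0.5),
    seed = 4))
  emp <- mean(fam2$truth$site_presence)
  expect_lt(abs(emp - 0.5), 3 * sqrt(0.25 / 208))
})

test_that("the reference row is never gapped and planted sites are mappable", {
  fam <- simulate_orthologue_family(family_sim_params(
    n_orthologues = 25, ref_length = 80, indel_rate = 0.15, seed = 5))
  ref_row <- fam$alignment[[fam$reference_id]]
  expect_false(grepl("-", ref_row, fixed = TRUE))
  # every emitted call passes residue validation against its own sequence
  expect_silent(calls <- load_site_predictions(fam$calls, fam$alignment))
  expect_equal(nrow(calls), nrow(fam$calls))
  # and every planted column lifts onto the reference
  maps <- gapmaps_of(fam$alignment)
  lifted <- liftover_table(fam$calls, maps, fam$reference_id)
  expect_false(anyNA(lifted$ref_pos))
  expect_true(all(lifted$ref_pos %in% fam$params$planted_sites$pos))
})

test_that("family simulation emits files its own readers accept", {
  fam <- simulate_orthologue_family(family_sim_params(
    n_orthologues = 12, ref_length = 50, seed = 6))
  recs <- read_fasta(fam$fasta)
  expect_equal(recs$id, names(fam$alignment))
  expect_equal(recs$sequence, unname(fam$alignment))
  back <- load_site_predictions(write_site_predictions(fam$calls),
                                fam$alignment)
  expect_equal(nrow(back), nrow(fam$calls))
  expect_equal(back$position, fam$calls$position)
})

test_that("family simulation validates its parameters", {
  expect_error(family_sim_params(planted_sites = data.frame(
    pos = 500L, residue = "S", presence = 0.5)),
    class = "gelmap_parameter_error")
  expect_error(family_sim_params(planted_sites = data.frame(
    pos = 10L, residue = "S", presence = 1.5)),
    class = "gelmap_parameter_error")
  expect_error(family_sim_params(planted_sites = data.frame(
    pos = 10L, residue = "G", presence = 0.5)),
    class = "gelmap_parameter_error")
  expect_error(family_sim_params(n_orthologues = 1),
               class = "gelmap_parameter_error")
})

test_that("signal score samples hit the requested mean and bounds", {
  fams <- data.frame(family = "MMP2", n = 10000, mean = 0.795, spread = 0.06)
  recs <- simulate_signal_scores(fams, seed = 11)
  expect_lt(abs(mean(recs$smean) - 0.795), 0.01)
  expect_true(all(recs$smean > 0 & recs$smean < 1))
  expect_true(all(recs$cmax >= 0 & recs$cmax <= 1))

  # degenerate spread: all samples equal the mean
  d <- simulate_signal_scores(
    data.frame(family = "X", n = 50, mean = 0.7, spread = 0), seed = 1)
  expect_true(all(d$smean == 0.7))

  # reproducibility across calls
  two <- data.frame(family = c("A", "B"), n = c(20, 20),
                    mean = c(0.4, 0.9), spread = c(0.1, 0.02))
  expect_identical(simulate_signal_scores(two, seed = 5),
                   simulate_signal_scores(two, seed = 5))

  expect_error(simulate_signal_scores(
    data.frame(family = "A", n = 5, mean = 1.2, spread = 0.1)),
    class = "gelmap_parameter_error")
  expect_error(simulate_signal_scores(
    data.frame(family = "A", n = 5, mean = 0.5, spread = 0.9)),
    class = "gelmap_parameter_error")
})

test_that("signal score tables round-trip through the summary dialect", {
  fams <- data.frame(family = c("MMP2", "Vtn"), n = c(6, 6),
                     mean = c(0.8, 0.95), spread = c(0.05, 0.02))
  recs <- simulate_signal_scores(fams, seed = 2)
  back <- parse_signalp_summary(write_signalp_summary(recs))
  expect_equal(back$name, recs$name)
  expect_equal(back$family, recs$family)
  expect_equal(back$smean, recs$smean, tolerance = 5e-4)  # 3-decimal dialect
})

test_that("degradome simulation controls the myosin fraction and ratio tail", {
  # myosin_fraction 0: no record mentions myosin
  none <- simulate_degradome(degradome_sim_params(
    n_peptides = 200, myosin_fraction = 0, seed = 21))
  expect_false(any(grepl("myosin", none$records$protein_description,
                         ignore.case = TRUE)))
  expect_false(any(none$truth$is_myosin))

  # myosin_fraction 0.24 at n = 1000: binomially consistent with 240
  sim <- simulate_degradome(degradome_sim_params(
    n_peptides = 1000, myosin_fraction = 0.24, seed = 22))
  cnt <- sum(sim$truth$is_myosin)
  expect_lt(abs(cnt - 240), 3 * sqrt(1000 * 0.24 * 0.76))
  # truth aligns with descriptions one-to-one
  expect_equal(grepl("myosin", sim$records$protein_description),
               sim$truth$is_myosin)

  # analytic log-normal tail: choose meanlog so P(ratio > 3) = 0.15
  sdlog <- 0.8
  meanlog <- log(3) - qnorm(0.85) * sdlog
  sim2 <- simulate_degradome(degradome_sim_params(
    n_peptides = 4000, log_ratio_mean = meanlog, log_ratio_sd = sdlog,
    seed = 23))
  frac <- mean(sim2$records$hl_ratio > 3)
  expect_lt(abs(frac - 0.15), 3 * sqrt(0.15 * 0.85 / 4000))
})

test_that("degradome simulation honours a P1' bias and round-trips", {
  sim <- simulate_degradome(degradome_sim_params(
    n_peptides = 600, p1prime_bias = c(I = 5, L = 5, V = 5, A = 1),
    seed = 24))
  p1 <- p1_prime(sim$records$peptide)
  expect_true(all(p1 %in% c("I", "L", "V", "A")))
  expect_gt(mean(p1 %in% c("I", "L", "V")), 0.8)
  back <- parse_peptide_table(write_peptide_table(sim$records))
  expect_equal(nrow(back), 600)
  expect_equal(back$hl_ratio, sim$records$hl_ratio, tolerance = 1e-6)
})
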