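test_that("SignalP-style summaries parse with family labels and validation", {
  txt <- paste("# SignalP-4.1-like summary",
               "MMP2_001  0.35 26  0.45 26  0.795  0.52",
               "Vtn_001   0.80 22  0.85 22  0.950  0.90",
               sep = "\n")
  recs <- parse_signalp_summary(txt)
  expect_equal(recs$smean, c(0.795, 0.950))
  expect_equal(recs$family, c("MMP2", "Vtn"))
  expect_equal(recs$cpos, c(26L, 22L))

  # comment-only file yields an empty table
  expect_equal(nrow(parse_signalp_summary("# nothing here\n")), 0)

  # out-of-range score and ragged lines are format errors with line numbers
  err <- expect_error(
    parse_signalp_summary("MMP2_001  0.35 26  0.45 26  1.200  0.52"),
    class = "gelmap_format_error")
  expect_match(conditionMessage(err), "line 1")
  expect_error(parse_signalp_summary("MMP2_001 0.3 26 0.4"),
               class = "gelmap_format_error")
})

test_that("rank-sum test matches its exact enumeration on worked cases", {
  # symmetric case: a sample against itself
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # complete separation of 3 vs 3: U = 0, two-sided p = 2/20
  out <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(out$statistic), 0)
  expect_equal(out$p.value, 0.1)
  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "gelmap_validation_error")
})

test_that("rank-sum test equals the permutation oracle for all small sizes", {
  set.seed(31)
  for (na in 1:8) {
    for (nb in 1:(10 - na)) {
      if (nb < 1) next
      a <- round(rnorm(na), 2)
      b <- round(rnorm(nb), 2)
      expect_equal(rank_sum_test(a, b)$p.value, perm_rank_sum_p(a, b),
                   tolerance = 1e-12)
      # and with heavy ties
      a2 <- sample(1:3, na, replace = TRUE)
      b2 <- sample(1:3, nb, replace = TRUE)
      expect_equal(rank_sum_test(a2, b2)$p.value, perm_rank_sum_p(a2, b2),
                   tolerance = 1e-12)
    }
  }
})

test_that("large-sample path matches the closed-form normal approximation", {
  set.seed(32)
  a <- rnorm(40); b <- rnorm(35, mean = 0.6)
  out <- rank_sum_test(a, b)
  # independent hand computation of the tie-free z statistic
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- length(a) * length(b) / 2
  sigma <- sqrt(length(a) * length(b) * (length(a) + length(b) + 1) / 12)
  p_hand <- 2 * pnorm(-(abs(U - mu) - 0.5) / sigma)
  expect_equal(out$p.value, p_hand, tolerance = 1e-12)
  # and agrees with the standard implementation used as cross-check
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(out$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("exact path agrees with the reference exact test when tie-free", {
  set.seed(33)
  a <- rnorm(6); b <- rnorm(7, 1)
  expect_equal(rank_sum_test(a, b)$p.value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), class = "gelmap_validation_error")
})

test_that("compact letter display satisfies its axioms on canonical cases", {
  fam <- c("MMP2", "MMP9", "Vtn")
  none <- matrix(FALSE, 3, 3, dimnames = list(fam, fam))
  expect_equal(unname(compact_letter_display(none)), c("a", "a", "a"))

  all_diff <- !diag(3)
  dimnames(all_diff) <- list(fam, fam)
  expect_equal(unname(compact_letter_display(all_diff)), c("a", "b", "c"))

  one <- none; one[1, 3] <- one[3, 1] <- TRUE
  expect_equal(unname(compact_letter_display(one)), c("a", "ab", "b"))

  bad <- none; bad[1, 2] <- TRUE
  expect_error(compact_letter_display(bad), class = "gelmap_validation_error")
  bad2 <- none; diag(bad2) <- TRUE
  expect_error(compact_letter_display(bad2), class = "gelmap_validation_error")
})

test_that("compact letter display axioms hold on random matrices", {
  set.seed(34)
  for (i in 1:60) {
    k <- sample(2:8, 1)
    m <- random_signif_matrix(k)
    letters <- compact_letter_display(m)
    expect_true(cld_axioms_hold(letters, m))
  }
})

test_that("family comparison flags indistinguishability from a reference", {
  set.seed(35)
  fams <- data.frame(family = c("MMP2", "MMP9", "Vtn"),
                     n = c(80, 80, 80),
                     mean = c(0.78, 0.945, 0.95),
                     spread = c(0.05, 0.02, 0.02))
  recs <- simulate_signal_scores(fams, seed = 7)
  cmp <- family_comparison(recs, reference_family = "Vtn")
  s <- cmp$summary
  expect_true(s$like_reference[s$family == "Vtn"])
  expect_false(s$like_reference[s$family == "MMP2"])   # well-separated means
  expect_true(all(nchar(s$letters) >= 1))
  expect_true(cld_axioms_hold(setNames(s$letters, s$family), cmp$signif))
  # p-value matrices symmetric with unit diagonal
  expect_equal(cmp$p_adj, t(cmp$p_adj))
  expect_equal(unname(diag(cmp$p_raw)), rep(1, 3))
})

test_that("families below n = 2 are excluded; fewer than two is an error", {
  recs <- data.frame(family = c("A", "A", "B"), smean = c(0.5, 0.6, 0.7))
  expect_error(expect_warning(family_comparison(recs), "n < 2"),
               class = "gelmap_validation_error")
  recs1 <- data.frame(family = "A", smean = c(0.5, 0.6))
  expect_error(family_comparison(recs1), class = "gelmap_validation_error")
})

test_that("equal-distribution families usually share a letter; separated ones never do", {
  share <- logical(100)
  differ <- logical(100)
  for (s in 1:100) {
    same <- simulate_signal_scores(
      data.frame(family = c("F1", "F2"), n = c(100, 100),
                 mean = c(0.85, 0.85), spread = c(0.05, 0.05)), seed = s)
    cmp <- family_comparison(same)
    share[s] <- cmp$summary$letters[1] == cmp$summary$letters[2]

    apart <- simulate_signal_scores(
      data.frame(family = c("F1", "F2"), n = c(100, 100),
                 mean = c(0.80, 0.95), spread = c(0.02, 0.02)), seed = s)
    cmp2 <- family_comparison(apart)
    differ[s] <- cmp2$summary$letters[1] != cmp2$summary$letters[2]
  }
  expect_gte(mean(share), 0.90)   # type-I control near the nominal level
  expect_equal(mean(differ), 1)   # power ~ 1 at this separation
})
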