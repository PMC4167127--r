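test_that("success probability is M/N with strict bounds", {
  expect_equal(success_probability(10, 100), 0.1)
  expect_equal(success_probability(7, 7), 1)
  expect_error(success_probability(0, 10), "M <= N")
  expect_error(success_probability(11, 10), "M <= N")
})

test_that("binomial tail p-values match direct pmf summation", {
  expect_equal(binomial_pvalue(0, 10, 0.3), 1)
  expect_equal(binomial_pvalue(10, 10, 0.3), 0.3^10)
  expect_equal(binomial_pvalue(5, 10, 0.2), oracle_binom_tail(5, 10, 0.2),
               tolerance = 1e-12)
  withr::with_seed(41, {
    for (i in 1:50) {
      S <- sample(1:80, 1)
      s <- sample(0:S, 1)
      r <- runif(1, 0.01, 0.99)
      expect_equal(binomial_pvalue(s, S, r), oracle_binom_tail(s, S, r),
                   tolerance = 1e-10)
    }
  })
  expect_error(binomial_pvalue(5, 4, 0.5), "s <= S")
})

test_that("the multiple-region adjustment is exact, stable and monotone", {
  expect_equal(adjust_pvalue(0.37, 1), 0.37)
  expect_equal(adjust_pvalue(0, 50), 0)
  expect_equal(adjust_pvalue(1, 50), 1)
  # frozen 40-digit reference for 1 - 0.99^100
  expect_equal(adjust_pvalue(0.01, 100), 0.6339676587267704950693839734,
               tolerance = 1e-12)
  # tiny p-values fall back to the n*p regime without losing the magnitude
  expect_equal(adjust_pvalue(1e-300, 1e4), 1e-296, tolerance = 1e-10)

  ps <- c(0, 1e-12, 1e-6, 0.01, 0.1, 0.5, 0.9, 1)
  ns <- c(1, 2, 10, 1e3, 1e6)
  grid <- outer(ps, ns, adjust_pvalue)
  expect_true(all(grid >= 0 & grid <= 1))
  expect_true(all(apply(grid, 2, diff) >= 0))  # monotone in p_raw
  expect_true(all(apply(grid, 1, diff) >= 0))  # monotone in n
})

test_that("E-values scale the adjusted p-value by the compendium size", {
  expect_equal(motif_evalue(1, 884), 884)
  expect_equal(motif_evalue(0, 884), 0)
  expect_equal(motif_evalue(0.5, 2), 1)
  expect_error(motif_evalue(0.5, 0), "n_motifs")
})

test_that("region enumeration covers the width grid in both modes", {
  cen <- enumerate_regions(5, "central", min_width = 1, width_step = 1)
  expect_equal(cen$width, c(1L, 3L, 5L))
  expect_equal(cen$start, c(2L, 1L, 0L))

  loc <- enumerate_regions(4, "local", min_width = 2, max_width = 2)
  expect_equal(loc$start, 0:2)
  expect_equal(loc$width, rep(2L, 3))

  expect_error(enumerate_regions(4, "local", min_width = 6), "min_width")
  # every feasible (start, width) appears exactly once in local mode
  all4 <- enumerate_regions(10, "local", min_width = 1, width_step = 1)
  expect_equal(nrow(all4), sum(10 - (1:10) + 1))
  expect_false(anyDuplicated(all4[c("start", "width")]) > 0)
})

test_that("region counting is a plain half-open interval count", {
  scan <- scan_result(c(0L, 3L, 3L, 7L), N = 10)
  expect_equal(count_in_region(scan, 3, 2), 2L)
  expect_equal(count_in_region(scan, 0, 10), 4L)
  expect_equal(count_in_region(scan_result(integer(0), N = 10), 0, 10), 0L)
})

test_that("greedy selection drops overlaps in p-value order", {
  res <- tibble::tibble(start = c(0, 5, 20), width = c(10, 10, 10),
                        p_raw = c(1e-5, 1e-4, 1e-3),
                        evalue = c(1e-3, 1e-2, 1e-1))
  out <- select_nonoverlapping(res, alpha_evalue = 10)
  expect_equal(out$start, c(0, 20))
  expect_equal(nrow(select_nonoverlapping(res[0, ], 10)), 0L)

  withr::with_seed(42, {
    for (i in 1:20) {
      n <- 50
      df <- tibble::tibble(start = sample(0:80, n, replace = TRUE),
                           width = sample(1:15, n, replace = TRUE),
                           p_raw = runif(n), evalue = runif(n) * 12)
      ours <- select_nonoverlapping(df, alpha_evalue = 10)
      ref <- oracle_greedy(df, alpha_evalue = 10)
      expect_equal(as.data.frame(ours), as.data.frame(ref))
      ends <- ours$start + ours$width
      if (nrow(ours) > 1) {
        ord <- order(ours$start)
        expect_true(all(ends[ord][-nrow(ours)] <= ours$start[ord][-1]))
      }
    }
  })
})

test_that("a perfectly centered pile-up gets the closed-form p-value", {
  N <- 11
  S <- 6
  scan <- scan_result(rep(5L, S), N = N)
  enr <- enrich_local(scan, mode = "central", min_width = 1, width_step = 1,
                      alpha_evalue = Inf)
  expect_equal(enr$width[1], 1L)
  expect_equal(enr$p_raw[1], (1 / N)^S, tolerance = 1e-12)
  expect_equal(enr$s[1], S)
  # adjusted for the 6 centered candidates (widths 1,3,...,11)
  expect_equal(enr$n_tests[1], 6L)
  expect_equal(enr$p_adj[1], adjust_pvalue((1 / N)^S, 6))
  # central mode reports the single best sub-region
  expect_equal(nrow(enr), 1L)
})

test_that("an empty scan yields an empty enrichment with a skip message", {
  scan <- scan_result(integer(0), N = 50, n_seq = 10)
  expect_message(enr <- enrich_local(scan, mode = "central"), "skipped")
  expect_equal(nrow(enr), 0L)
})

test_that("central mode equals local mode restricted to centered candidates", {
  withr::with_seed(43, {
    for (i in 1:10) {
      N <- sample(10:60, 1)
      S <- sample(5:50, 1)
      starts <- sample(0:(N - 1), S, replace = TRUE)
      scan <- scan_result(starts, N = N)
      mw <- sample(1:4, 1)
      step <- sample(1:3, 1)
      loc <- enrich_local(scan, mode = "local", min_width = mw,
                          width_step = step, all_regions = TRUE)
      cen <- tryCatch(
        enrich_local(scan, mode = "central", min_width = mw,
                     width_step = step, all_regions = TRUE),
        error = function(e) NULL)
      if (is.null(cen)) next  # grid and N parities never meet
      centered <- loc[loc$start == (N - loc$width) / 2, , drop = FALSE]
      expect_equal(centered$p_raw, cen$p_raw)
      expect_equal(centered$s, cen$s)
      expect_equal(adjust_pvalue(centered$p_raw, nrow(cen)), cen$p_adj,
                   tolerance = 1e-12)
    }
  })
})

test_that("reported sub-regions for a motif never overlap", {
  withr::with_seed(44, {
    starts <- pmin(pmax(round(rnorm(200, 100, 12)), 0), 199)
    extra <- sample(0:199, 100, replace = TRUE)
  })
  scan <- scan_result(c(starts, extra), N = 200)
  enr <- enrich_local(scan, mode = "local", min_width = 5, width_step = 5,
                      alpha_evalue = 10, n_motifs = 1)
  expect_gt(nrow(enr), 0L)
  if (nrow(enr) > 1) {
    ord <- order(enr$start)
    expect_true(all((enr$start + enr$width)[ord][-nrow(enr)] <=
                      enr$start[ord][-1]))
  }
  expect_true(all(enr$p_raw <= enr$p_adj))
  expect_true(all(enr$evalue == enr$p_adj * 1))
})
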