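small_run <- function(control = TRUE, seed = 71, ...) {
  fx <- make_paired_fixture("differential-central", n_seq = 120, L = 200,
                            seed = seed)
  motifs <- as.list(c(list(fx$motif), decoy_motifs(3, seed = seed)))
  class(motifs) <- "mz_motif_list"
  run_enrichment(fx$primary, motifs,
                 control = if (control) fx$control, seed = seed, ...)
}

test_that("the end-to-end run reports one row per motif with coherent columns", {
  run <- small_run()
  expect_s3_class(run, "mz_run")
  expect_equal(nrow(run$report), 4L)
  expect_named(run$report,
               c("motif_id", "motif_name", "consensus", "evalue",
                 "adj_pvalue", "log_adj_pvalue", "region_center",
                 "region_width", "sites_in_region", "total_sites",
                 "control_sites_in_region", "control_total_sites",
                 "fisher_adj_pvalue", "fisher_evalue", "odds_ratio"))
  # column 6 is the natural log of column 5
  ok <- run$report$adj_pvalue > 0
  expect_equal(run$report$log_adj_pvalue[ok], log(run$report$adj_pvalue[ok]),
               tolerance = 1e-6)
  # the planted motif dominates both rankings
  expect_equal(run$report$motif_id[1], "PLANT1")
  expect_equal(family_rank(run$report, "AP1", "fisher_evalue")$rank, 1L)
  expect_lt(run$report$fisher_evalue[1], 0.05)
})

test_that("runs without a control leave the differential columns empty", {
  run <- small_run(control = FALSE)
  expect_true(all(is.na(run$report$fisher_evalue)))
  expect_true(all(is.na(run$report$control_total_sites)))
  expect_false(any(is.na(run$report$evalue)))
  g <- glance(run)
  expect_true(is.na(g$n_control))
  expect_identical(tidy(run), tibble::as_tibble(run$report))
})

test_that("an identical control shows no differential enrichment", {
  fx <- make_paired_fixture("differential-central", n_seq = 100, L = 200,
                            seed = 72)
  ctl <- fx$primary
  attr(ctl, "role") <- "control"
  run <- run_enrichment(fx$primary, fx$motif, control = ctl, seed = 72)
  expect_true(all(run$report$fisher_evalue >= 1, na.rm = TRUE))
})

test_that("expected intersection under independence is the product", {
  expect_equal(expected_intersection(0.34, 0.22), 0.0748)
  expect_equal(expected_intersection(0, 0.9), 0)
  expect_equal(expected_intersection(1, 1), 1)
  expect_error(expected_intersection(1.2, 0.5), "0, 1")

  st <- intersection_stats(c("a", "b", "c"), c("b", "c", "d"), 10)
  expect_equal(st$expected, 0.3 * 0.3)
  expect_equal(st$observed, 0.2)
})

test_that("site probability curves are normalized and smoothable", {
  scan <- scan_result(rep(10L, 8), N = 21, motif_width = 5, L = 25)
  cv <- site_probability_curve(scan, smooth_bp = 1)
  expect_equal(sum(cv$prob_raw), 1)
  expect_equal(cv$prob[cv$offset == 0], 1)  # unit spike at the center
  expect_error(site_probability_curve(scan, smooth_bp = 4), "odd")

  sm <- site_probability_curve(scan, smooth_bp = 5)
  expect_equal(sum(sm$prob_raw), 1)
  expect_equal(max(sm$prob), 1 / 5)

  withr::with_seed(73, unif <- scan_result(sample(0:399, 10000, TRUE), N = 400))
  cu <- site_probability_curve(unif, smooth_bp = 1)
  expect_lte(max(cu$prob), 3 / 400)
})

test_that("family ranking searches names case-insensitively with stable ties", {
  rep_ <- tibble::tibble(motif_id = c("M1", "M2", "M3"),
                         motif_name = c("Fos", "Mycn", "STAT1"),
                         evalue = c(2, 3, 1),
                         log_adj_pvalue = c(-1, -0.5, -4),
                         fisher_evalue = c(0.2, 0.2, 5))
  expect_equal(family_rank(rep_, "stat")$rank, 1L)
  expect_equal(family_rank(rep_, "stat")$motif_id, "M3")
  expect_false(family_rank(rep_, "kappa")$found)
  # tie on the sort column: stable order by motif id
  tie <- family_rank(rep_, "myc", "fisher_evalue")
  expect_equal(tie$rank, 2L)
})

test_that("TSV reports round-trip at the serialized precision", {
  run <- small_run(seed = 74)
  dir <- withr::local_tempdir()
  files <- write_report(run, dir)
  expect_true(all(file.exists(files)))
  first <- readLines(files["report_tsv"], n = 1)
  expect_true(startsWith(first, "#motif_id"))

  back <- read_report(files["report_tsv"])
  expect_equal(nrow(back), nrow(run$report))
  expect_equal(back$motif_id, run$report$motif_id)
  for (cc in c("evalue", "adj_pvalue", "log_adj_pvalue", "fisher_evalue",
               "odds_ratio")) {
    orig <- run$report[[cc]]
    ok <- is.finite(orig)
    expect_equal(back[[cc]][ok], orig[ok], tolerance = 1e-5)
  }
  expect_equal(back$total_sites, run$report$total_sites)
  # write -> parse -> write is a fixed point
  dir2 <- withr::local_tempdir()
  run2 <- run
  run2$report <- back
  write_report(run2, dir2)
  expect_identical(readLines(file.path(dir2, "report.tsv")),
                   readLines(files["report_tsv"]))

  js <- jsonlite::read_json(files["report_json"])
  expect_equal(js$params$seed, 74)
  expect_true(length(js$regions) >= 1)
})

test_that("sorting by Fisher E-value supports the differential-only query", {
  run <- small_run(seed = 75, alpha_evalue = 10)
  rep_ <- run$report
  ord <- rep_[order(rep_$fisher_evalue), , drop = FALSE]
  hits <- ord[ord$fisher_evalue < 0.05, , drop = FALSE]
  expect_true(all(hits$motif_id == "PLANT1"))
})
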