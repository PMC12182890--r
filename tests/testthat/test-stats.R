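test_that("Mann-Whitney matches the closed cases and handles ties", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_identical(res$method, "exact")

  # identical multisets: U = n1 n2 / 2 and a tie-handled p near 1
  x <- c(2, 2, 5, 7, 7)
  res2 <- mann_whitney(x, x)
  expect_equal(res2$U, length(x)^2 / 2)
  expect_gte(res2$p_value, 0.99)

  expect_error(mann_whitney(numeric(0), 1:3), "observation")
})

test_that("percent difference reproduces the group-mean arithmetic", {
  expect_equal(round(percent_difference(248754, 299242), 2), 20.30)
  expect_equal(round(percent_difference(61.91, 66.23), 2), 6.98)
  expect_equal(percent_difference(5, 5), 0)
  # reference-swap identity: (1 + d_ab/100) * (1 + d_ba/100) = 1
  d_ab <- percent_difference(248754, 299242)
  d_ba <- percent_difference(299242, 248754)
  expect_equal((1 + d_ab / 100) * (1 + d_ba / 100), 1, tolerance = 1e-12)
  expect_error(percent_difference(0, 1), "nonzero")
})

test_that("group summaries report mean, SEM with pooled n, and test results", {
  f <- tibble::tibble(
    volume = c(1, 2, 3, 11, 12, 13), nod = c(5, 6, 7, 5, 6, 7),
    equiv_diameter = 1:6, sphericity = seq(0.8, 0.9, length.out = 6),
    sample_id = rep(c("a", "b"), each = 3),
    group = rep(c("healthy", "obese"), each = 3)
  )
  gs <- group_summary(f, reference = "healthy")
  expect_equal(gs$mean_healthy[gs$feature == "volume"], 2)
  expect_equal(gs$sem_healthy[gs$feature == "volume"], 1 / sqrt(3))
  expect_equal(gs$sem_healthy[gs$feature == "volume"], 0.5774, tolerance = 1e-4)
  expect_identical(gs$n_healthy, rep(3L, 4))
  expect_equal(gs$percent_difference[gs$feature == "volume"],
               percent_difference(2, 12))
  expect_equal(gs$p_value[gs$feature == "nod"], 1, tolerance = 0.01)

  expect_error(group_summary(dplyr::mutate(f, group = NA)), "group")
  expect_error(group_summary(f[c(1, 4:6), ]), ">= 2")

  td <- generics::tidy(gs)
  expect_identical(nrow(td), 8L)
  gl <- generics::glance(gs)
  expect_identical(gl$n_cells, 6L)
  expect_s3_class(ggplot2::autoplot(gs), "ggplot")
})

test_that("group ordering of a calibrated two-group study is preserved", {
  d <- study_design(c("healthy", "obese"), 2, 25)
  pg <- list(
    healthy = tiny_params(volume_mean = 150000),
    obese = tiny_params(volume_mean = 200000)
  )
  pg$healthy$domain_size <- pg$obese$domain_size <- c(400, 400, 200)
  study <- generate_study(d, pg, master_seed = 5)
  gt <- study_ground_truth(study)
  f <- dplyr::rename(gt, volume = true_volume)
  f$nod <- f$equiv_diameter <- f$sphericity <- 1
  gs <- group_summary(f, reference = "healthy")
  expect_gt(gs$mean_obese[gs$feature == "volume"],
            gs$mean_healthy[gs$feature == "volume"])
  expect_gt(gs$percent_difference[gs$feature == "volume"], 0)
})

test_that("step-up FDR procedures match their definitions", {
  p <- c(0.001, 0.02, 0.04, 0.8)
  res <- fdr_step_up(p, Q = 0.05, method = "bh")
  expect_identical(res$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(res$reject, bh_oracle(p, 0.05))
  expect_equal(res$q, stats::p.adjust(p, "BH"))

  expect_false(any(fdr_step_up(rep(1, 6), 0.05, "bh")$reject))
  expect_false(any(fdr_step_up(rep(1, 6), 0.05, "two_stage")$reject))

  # random p-vectors: BH route always equals the literal step-up definition
  set.seed(42)
  for (i in 1:50) {
    pv <- round(runif(sample(3:20, 1))^2, 3)
    expect_identical(fdr_step_up(pv, 0.05, "bh")$reject, bh_oracle(pv, 0.05))
  }

  # two-stage never discovers less than BH at the same Q and both are
  # monotone in Q
  set.seed(43)
  for (i in 1:20) {
    pv <- runif(15)^3
    r_bh <- fdr_step_up(pv, 0.05, "bh")$reject
    r_ts <- fdr_step_up(pv, 0.05, "two_stage")$reject
    expect_true(all(r_bh <= r_ts))
    for (m in c("bh", "two_stage")) {
      r_lo <- fdr_step_up(pv, 0.02, m)$reject
      r_hi <- fdr_step_up(pv, 0.10, m)$reject
      expect_true(all(r_lo <= r_hi))
    }
  }
})

test_that("binned distributions follow the left-closed convention and conserve counts", {
  f <- tibble::tibble(
    volume = c(1, 5, 9), sample_id = "s1", group = "g1"
  )
  specs <- bin_spec("volume", width = 5, lo = 0, hi = 10)
  d <- binned_distribution(f, specs)
  # 5 falls in the second bin (left-closed); 9 < 10 keeps range; an overflow
  # bin may be appended but stays empty
  core <- d[d$bin_lo < 10, ]
  expect_identical(core$count[order(core$bin_lo)][1:2], c(1L, 2L))
  expect_identical(sum(d$count), 3L)

  # empty table gives all-zero counts
  d0 <- binned_distribution(f[0, ], specs)
  expect_identical(sum(d0$count), 0L)

  # per-sample conservation on a synthetic feature table
  set.seed(9)
  f2 <- tibble::tibble(
    volume = runif(300, 0, 1.4e6),
    sample_id = rep(paste0("s", 1:6), each = 50),
    group = rep(c("h", "o"), each = 150)
  )
  d2 <- binned_distribution(f2, bin_spec("volume", 5e4, 0, 1e6))
  per_sample <- dplyr::count(d2, .data$sample_id, wt = .data$count)
  expect_true(all(per_sample$n == 50))
  # values beyond the range land in appended overflow bins
  expect_identical(sum(d2$count[d2$bin_lo >= 1e6]),
                   sum(f2$volume >= 1e6))
  expect_error(bin_spec("volume", -1, 0, 10), "increasing")
})

test_that("multiple Mann-Whitney with FDR flags enriched bins and skips empty ones", {
  set.seed(31)
  mk <- function(group, shift) tibble::tibble(
    volume = rep(c(100, 200, 300), times = c(20, 30 + shift, 10)) + runif(60 + shift, -40, 40),
    sample_id = NA_character_, group = group
  )
  f <- dplyr::bind_rows(
    dplyr::mutate(mk("h", 0), sample_id = rep(paste0("h", 1:3), 20)),
    dplyr::mutate(mk("o", 0), sample_id = rep(paste0("o", 1:3), 20))
  )
  d <- binned_distribution(f, bin_spec("volume", 100, 0, 400))
  res <- suppressMessages(multiple_mw_fdr(d, Q = 0.05))
  expect_true(all(res$p_value[res$tested] >= 0 & res$p_value[res$tested] <= 1))
  expect_identical(nrow(res), length(unique(paste(d$bin_lo))))
  # empty bins (no cells at all) are skipped
  d2 <- binned_distribution(f, bin_spec("volume", 100, 0, 800))
  res2 <- suppressMessages(multiple_mw_fdr(d2))
  expect_true(any(!res2$tested))
  expect_true(all(is.na(res2$p_value[!res2$tested])))
})

test_that("Mann-Whitney type-I error is calibrated under a seeded null", {
  set.seed(2024)
  reps <- 1000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(500); y <- rnorm(500)
    rej[i] <- mann_whitney(x, y)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("FDR keeps the false-discovery proportion controlled under the global null", {
  set.seed(77)
  reps <- 200
  fdp <- numeric(reps)
  for (i in seq_len(reps)) {
    counts <- matrix(rpois(20 * 6, lambda = 20), nrow = 20) # 20 bins x 6 samples
    p <- apply(counts, 1, function(r) mann_whitney(r[1:3], r[4:6])$p_value)
    res <- fdr_step_up(p, Q = 0.05, method = "two_stage")
    fdp[i] <- if (any(res$reject)) 1 else 0 # all discoveries false under the null
  }
  mc_err <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(fdp), 0.05 + 2 * mc_err)
})
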