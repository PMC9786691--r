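test_that("the SPSS-convention asymptotic p reproduces the forced cells", {
  ## 5 pairs, all post < pre with distinct magnitudes:
  ## W+ = 0, z = -7.5 / sqrt(13.75)
  w <- wilcoxon_signed_rank(pre = c(31, 42, 28, 40, 36),
                            post = c(30, 39, 23, 33, 25))
  expect_equal(w$n_effective, 5L)
  expect_equal(w$w_plus, 0)
  expect_equal(w$w_minus, 15)
  expect_equal(w$z, -7.5 / sqrt(13.75), tolerance = 1e-12)
  expect_equal(round(w$p_two_sided, 3), 0.043)
  ## only the largest-magnitude difference positive: W+ = 5
  w2 <- wilcoxon_signed_rank(pre = c(31, 42, 28, 40, 36),
                             post = c(30, 40, 25, 36, 46))
  expect_equal(w2$w_plus, 5)
  expect_equal(w2$z, (5 - 7.5) / sqrt(13.75), tolerance = 1e-12)
  expect_equal(round(w2$p_two_sided, 3), 0.500)
})

test_that("a balanced sign pattern gives z = 0 and p = 1", {
  w <- wilcoxon_signed_rank(pre = c(10, 10, 10, 10),
                            post = c(11, 14, 9, 6))
  expect_equal(w$w_plus, w$w_minus)
  expect_equal(w$z, 0)
  expect_equal(w$p_two_sided, 1.0)
})

test_that("zeros are dropped and degenerate input errors", {
  w <- wilcoxon_signed_rank(pre = c(5, 5, 10, 20, 30),
                            post = c(5, 5, 9, 18, 27))
  expect_equal(w$n_effective, 3L)
  expect_error(wilcoxon_signed_rank(pre = c(1, 2), post = c(1, 2)),
               "nonzero")
  expect_error(wilcoxon_signed_rank(pre = 1:3, post = 1:2), "paired")
})

test_that("the asymptotic p matches the SPSS-style z from wilcox.test", {
  ## independent cross-check: R's normal-approximation path without
  ## continuity correction uses the same tie-corrected variance
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    pre <- rnorm(n, 30, 8)
    post <- pre - rnorm(n, 1.2, 4)
    ours <- wilcoxon_signed_rank(pre, post)$p_two_sided
    ref <- suppressWarnings(stats::wilcox.test(
      post, pre, paired = TRUE, exact = FALSE, correct = FALSE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("the exact method equals full 2^n brute-force enumeration", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n), if (i %% 3 == 0) 0 else 3)  # some runs with ties
    d <- d[d != 0]
    if (length(d) < 2) next
    ours <- wilcoxon_signed_rank(rep(0, length(d)), d,
                                 method = "exact")$p_two_sided
    expect_equal(ours, brute_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("asymptotic and exact p agree in the no-ties regime", {
  set.seed(33)
  worst <- 0
  for (i in 1:200) {
    n <- sample(6:10, 1)
    pre <- rnorm(n, 30, 10)
    post <- pre - rnorm(n, 2, 5)
    a <- wilcoxon_signed_rank(pre, post)
    e <- wilcoxon_signed_rank(pre, post, method = "exact")
    ## same data, same W+: direction always agrees
    expect_equal(sign(a$w_plus - a$w_minus), sign(e$w_plus - e$w_minus))
    ## the uncorrected normal z estimates the mid-p tail of the exact
    ## enumeration; the inclusive doubling convention exceeds it by half
    ## the observed point mass, which is large at these n by construction
    worst <- max(worst, abs(a$p_two_sided - e$p_mid))
  }
  expect_lte(worst, 0.05)
})

test_that("p is invariant under monotone transforms of the magnitudes", {
  set.seed(34)
  pre <- rnorm(8, 30, 5)
  post <- pre - rnorm(8, 1, 4)
  d <- post - pre
  p0 <- wilcoxon_signed_rank(pre, post)$p_two_sided
  ## cube the magnitudes, keep the signs: ranks unchanged
  d2 <- sign(d) * abs(d)^3
  p1 <- wilcoxon_signed_rank(rep(0, 8), d2)$p_two_sided
  expect_equal(p1, p0, tolerance = 1e-12)
})

test_that("W+ + W- always equals n(n+1)/2 without zero differences", {
  set.seed(35)
  for (i in 1:50) {
    n <- sample(3:15, 1)
    d <- rnorm(n)
    w <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(w$w_plus + w$w_minus, n * (n + 1) / 2)
  }
})

test_that("cohort summaries have the right moments, order and edge cases", {
  mom <- reference_cohort_moments()
  co <- simulate_cohort(mom, c(mild = 8, severe = 5), seed = 44)
  s <- cohort_summary(co)
  ## fixed state ordering within each group x measure block
  first_block <- s[s$group == s$group[1] & s$measure == s$measure[1], ]
  expect_equal(first_block$state, acquisition_states())
  expect_true(all(s$n[s$group == "mild"] == 8))
  expect_true(all(s$n[s$group == "severe"] == 5))
  expect_true(all(s$p >= 0 & s$p <= 1, na.rm = TRUE))
  ## identical patients give SD 0
  gp <- data.frame(group = "g", state = "flexion_0", measure = "tilt",
                   pre_mean = 30, pre_sd = 0, post_mean = 20, post_sd = 0)
  s0 <- cohort_summary(simulate_cohort(gp, c(g = 4), seed = 1))
  expect_equal(s0$pre_sd, 0)
  expect_equal(s0$post_sd, 0)
  ## a single-patient cell is skipped with a warning
  one <- co[co$patient == "mild_1" & co$measure == "tilt", ]
  expect_warning(cohort_summary(one), "fewer than 2")
  ## Holm adjustment is available but off by default
  expect_false("p_holm" %in% names(s))
  sh <- cohort_summary(co, adjust = "holm")
  expect_true(all(sh$p_holm >= sh$p, na.rm = TRUE))
})

test_that("summary means track the simulated inputs within 3 SE", {
  mom <- reference_cohort_moments()
  row <- mom[mom$group == "severe" & mom$measure == "tilt" &
               mom$state == "flexion_0", ]
  means <- vapply(1:200, function(s) {
    co <- simulate_cohort(row, c(severe = 5), seed = 100 + s)
    ss <- cohort_summary(co)
    c(ss$pre_mean, ss$post_mean)
  }, numeric(2))
  expect_lt(abs(mean(means[1, ]) - row$pre_mean),
            3 * row$pre_sd / sqrt(5 * 200))
  expect_lt(abs(mean(means[2, ]) - row$post_mean),
            3 * row$post_sd / sqrt(5 * 200))
})

test_that("cohort CSVs round-trip and render as text tables", {
  mom <- reference_cohort_moments()
  co <- simulate_cohort(mom[mom$measure == "cca", ], c(mild = 3, severe = 3),
                        seed = 5)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  rt <- read_cohort_csv(path)
  expect_equal(rt$pre, co$pre, tolerance = 1e-12)
  expect_s3_class(rt, "pf_cohort")
  expect_error(read_cohort_csv(write_cohort_csv(
    structure(data.frame(a = 1), class = c("pf_cohort", "data.frame")),
    tempfile(fileext = ".csv"))), "columns")
  lines <- format_summary_table(cohort_summary(co))
  expect_true(any(grepl("cca", lines)))
  expect_true(any(grepl("p=", lines)))
})
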