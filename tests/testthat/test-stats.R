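# hand-coded Welch-Satterthwaite oracle, independent of stats::t.test
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  # two-tailed p by numerical integration of the t density
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p <- 2 * integrate(dens, abs(t), Inf, rel.tol = 1e-10)$value
  list(t = t, df = df, p = p)
}

spec1m_ct <- c(1.30, 1.30, 1.37, 1.03)
spec1m_us <- c(0.56, 0.51, 0.61, 0.83)

test_that("summaries reproduce the transcribed per-region table", {
  rec <- osteophyte_rms_example()
  expect_equal(nrow(rec), 36)

  ov <- summarize_rms(rec)
  ct <- ov[ov$modality_pair == "CT-SLS", ]
  us <- ov[ov$modality_pair == "3DUS-SLS", ]
  expect_equal(ct$n, 18)
  expect_equal(round(ct$mean_mm, 2), 0.95)
  expect_equal(round(ct$sd_mm, 2), 0.32)
  expect_equal(round(us$mean_mm, 2), 0.87)
  expect_equal(round(us$sd_mm, 2), 0.33)
  # population (n denominator) SD would NOT reproduce the printed values
  ct_vals <- rec$rms_mm[rec$modality_pair == "CT-SLS"]
  expect_false(round(sqrt(mean((ct_vals - mean(ct_vals))^2)), 2) == 0.32)

  # a single-record group has mean but undefined SD
  one <- summarize_rms(rec[1, ], "specimen_side")
  expect_equal(one$mean_mm, rec$rms_mm[1])
  expect_true(is.na(one$sd_mm))
  expect_error(summarize_rms(rec[0, ]), "empty")
})

test_that("Welch test matches the independent formula and simulation oracles", {
  w <- welch_test(spec1m_ct, spec1m_us)
  o <- welch_oracle(spec1m_ct, spec1m_us)
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-8)

  # Monte-Carlo of the null at n = (4, 4): the Welch p is well calibrated
  # (slightly conservative at this sample size, never anti-conservative)
  set.seed(202)
  nmc <- 2e5
  A <- matrix(rnorm(4 * nmc), nmc)
  B <- matrix(rnorm(4 * nmc), nmc)
  va <- apply(A, 1, var) / 4
  vb <- apply(B, 1, var) / 4
  tstar <- (rowMeans(A) - rowMeans(B)) / sqrt(va + vb)
  dfs <- (va + vb)^2 / (va^2 / 3 + vb^2 / 3)
  p_null <- 2 * pt(abs(tstar), dfs, lower.tail = FALSE)
  expect_gt(mean(p_null <= 0.05), 0.03)
  expect_lt(mean(p_null <= 0.05), 0.06)
  expect_gt(mean(p_null <= 0.01), 0.004)
  expect_lt(mean(p_null <= 0.01), 0.014)
})

test_that("Welch p is invariant to group swap and location shift, monotone in separation", {
  a <- c(0.9, 1.1, 1.0, 1.3)
  b <- c(0.5, 0.7, 0.6)
  expect_equal(welch_test(a, b)$p, welch_test(b, a)$p, tolerance = 1e-12)
  expect_equal(welch_test(a + 5, b + 5)$p, welch_test(a, b)$p, tolerance = 1e-12)
  deltas <- c(0, 0.2, 0.4, 0.8)
  ps <- vapply(deltas, function(d) welch_test(a + d, b)$p, numeric(1))
  expect_true(all(diff(ps) < 0))

  # identical groups: t = 0, p = 1
  w0 <- welch_test(a, a)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # zero variance everywhere with equal means: p = 1 by convention
  expect_equal(welch_test(c(1, 1), c(1, 1))$p, 1)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(c(1, NA, 2), c(1, 2)), "finite")
})

test_that("the Welch form, not the paired form, reproduces the printed p value", {
  w <- welch_test(spec1m_ct, spec1m_us)
  expect_equal(round(w$p, 3), 0.001)
  wp <- welch_test(spec1m_ct, spec1m_us, paired = TRUE)
  expect_false(round(wp$p, 3) == 0.001)
  expect_gt(wp$p, 0.01) # paired variant lands near 0.02
})

test_that("compare_report assembles summaries, tests and flags", {
  rec <- osteophyte_rms_example()
  rep <- compare_report(rec)
  expect_s3_class(rep, "modality_comparison")
  # only specimen-1 medial is significant; the pooled comparison is not
  sig <- rep$tests[rep$tests$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$specimen, "specimen1")
  ov <- rep$tests[rep$tests$specimen == "ALL", ]
  expect_gt(ov$p_value, 0.05)
  expect_equal(nrow(rep$summary), 5)
  g <- glance(rep)
  expect_false(g$overall_significant)
  # writes summary.csv + tests.json
  d <- withr::local_tempdir()
  write_comparison(rep, d)
  expect_true(file.exists(file.path(d, "summary.csv")))
  expect_true(file.exists(file.path(d, "tests.json")))
  # a single modality pair is refused
  expect_error(compare_report(rec[rec$modality_pair == "CT-SLS", ]),
               "only one")
})

test_that("type-I error stays near nominal for same-distribution records", {
  set.seed(314)
  hits <- vapply(1:400, function(i) {
    a <- rnorm(4, 0.9, 0.15)
    b <- rnorm(4, 0.9, 0.15)
    welch_test(a, b)$p <= 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.92)
})
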