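test_that("cosinor_signal evaluates the 24-h cosine model", {
  expect_equal(cosinor_signal(0, 0.5, 0.3, 0), 0.8)
  expect_equal(cosinor_signal(12, 0.5, 0.3, 0), 0.2)
  # at its own acrophase the curve attains M + A
  expect_equal(cosinor_signal(12 * 2.0 / pi, 0.54, 0.36, 2.0), 0.90)
  # 24-h periodicity
  t <- runif(20, 0, 24)
  expect_equal(cosinor_signal(t + 24, 1, 0.4, 1.3),
               cosinor_signal(t, 1, 0.4, 1.3))
})

test_that("acrophase_to_zt converts radians to Zeitgeber hours mod 24", {
  expect_equal(acrophase_to_zt(0), 0)
  expect_equal(acrophase_to_zt(pi), 12)
  expect_equal(acrophase_to_zt(5.37), 20.51, tolerance = 0.001)
  expect_equal(acrophase_to_zt(2 * pi + 1), acrophase_to_zt(1))
  expect_true(all(acrophase_to_zt(runif(50, -20, 20)) >= 0))
  expect_true(all(acrophase_to_zt(runif(50, -20, 20)) < 24))
})

test_that("fit_cosinor handles constant and pure-basis series", {
  zt <- rep(design_zts(), each = 2)
  f <- fit_cosinor(zt, rep(3.7, length(zt)))
  expect_equal(f$mesor, 3.7)
  expect_lt(f$amplitude, 1e-10)
  expect_false(f$rhythmic)  # A ~ 0 maps to P = Inf
  expect_true(is.infinite(f$p_ns))

  f2 <- fit_cosinor(design_zts(), cos(pi * design_zts() / 12))
  expect_equal(f2$mesor, 0, tolerance = 1e-9)
  expect_equal(f2$amplitude, 1, tolerance = 1e-9)
  expect_equal(f2$acrophase_rad, 0, tolerance = 1e-9)
})

test_that("noiseless generated data recover (M, A, phi) to 1e-6", {
  g <- gene_spec("g", mesor = 0.5, amplitude = 0.3, acrophase = 2.0,
                 noise_sd = 0)
  d <- generate_expression_dataset(list(g), study_design(seed = 11))
  f <- fit_cosinor(d$zt, d$value)
  expect_equal(f$mesor, 0.5, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.3, tolerance = 1e-6)
  expect_equal(f$acrophase_rad, 2.0, tolerance = 1e-6)
  expect_equal(f$acrophase_zt, acrophase_to_zt(2.0), tolerance = 1e-6)
  expect_equal(f$se_amplitude, 0, tolerance = 1e-9)
  expect_equal(f$p_ns, 0, tolerance = 1e-8)
})

test_that("fit_cosinor rejects degenerate designs", {
  expect_error(fit_cosinor(c(0, 3, 6), c(1, 2, 3)), "at least 4")
  expect_error(fit_cosinor(c(0, 24, 48, 72), c(1, 2, 3, 4)), "degenerate")
})

test_that("fit matches brute-force grid least squares on random instances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(9:30, 1)
    tt <- runif(n, 0, 24)
    yy <- cosinor_signal(tt, runif(1, 0.5, 2), runif(1, 0.1, 0.5),
                         runif(1, 0, 2 * pi)) + rnorm(n, 0, 0.2)
    f <- fit_cosinor(tt, yy)
    o <- oracle_cosinor(tt, yy)
    expect_equal(f$mesor, o$mesor, tolerance = 1e-4)
    expect_equal(f$beta, o$beta, tolerance = 1e-4)
    expect_equal(f$gamma, o$gamma, tolerance = 1e-4)
  }
})

test_that("delta-method SE(A) matches closed-form and Monte-Carlo scatter", {
  # balanced nine-ZT design: the cos/sin columns are near-orthogonal, so
  # SE(A) ~ SE(beta) from the OLS covariance
  zt <- rep(design_zts(), each = 6)
  set.seed(5)
  y <- cosinor_signal(zt, 1, 0.4, 1.0) + rnorm(length(zt), 0, 0.1)
  f <- fit_cosinor(zt, y)
  cosb <- cos(pi * zt / 12); sinb <- sin(pi * zt / 12)
  vc <- stats::vcov(stats::lm(y ~ cosb + sinb))
  expect_equal(amplitude_se(f), sqrt(vc[2, 2]), tolerance = 0.05)

  # Monte-Carlo: SD of fitted A over repeated noise draws within 15% of the
  # delta-method SE
  mu <- cosinor_signal(zt, 1, 0.4, 1.0)
  set.seed(99)
  amps <- replicate(2000, {
    yy <- mu * 2^rnorm(length(zt), 0, 0.1)
    fit_cosinor(zt, yy)$amplitude
  })
  ses <- replicate(200, {
    yy <- mu * 2^rnorm(length(zt), 0, 0.1)
    amplitude_se(fit_cosinor(zt, yy))
  })
  expect_equal(sd(amps), mean(ses), tolerance = 0.15)
})

test_that("rhythmicity classification is strict at the threshold", {
  expect_true(classify_rhythmic(0.21))
  expect_false(classify_rhythmic(0.46))
  expect_false(classify_rhythmic(0.3))
  expect_false(classify_rhythmic(Inf))
  expect_true(classify_rhythmic(0.49, threshold = 0.5))
})

test_that("acrophase is phase-equivariant and fit is scale-equivariant", {
  zt <- rep(design_zts(), each = 3)
  set.seed(8)
  y <- cosinor_signal(zt, 1, 0.4, 2.5) + rnorm(length(zt), 0, 0.15)
  f0 <- fit_cosinor(zt, y)
  for (delta in c(1.5, 6, 13.25)) {
    fd <- fit_cosinor(zt + delta, y)
    expect_equal(fd$acrophase_zt %% 24, (f0$acrophase_zt + delta) %% 24,
                 tolerance = 1e-9)
    expect_equal(fd$amplitude, f0$amplitude, tolerance = 1e-9)
    expect_equal(fd$mesor, f0$mesor, tolerance = 1e-9)
    expect_equal(fd$p_ns, f0$p_ns, tolerance = 1e-9)
  }
  for (c in c(0.2, 7)) {
    fc <- fit_cosinor(zt, c * y)
    expect_equal(fc$mesor, c * f0$mesor, tolerance = 1e-9)
    expect_equal(fc$amplitude, c * f0$amplitude, tolerance = 1e-9)
    expect_equal(fc$se_amplitude, c * f0$se_amplitude, tolerance = 1e-9)
    expect_equal(fc$p_ns, f0$p_ns, tolerance = 1e-9)
    expect_equal(fc$acrophase_rad, f0$acrophase_rad, tolerance = 1e-9)
  }
})

test_that("rhythm_table flags exactly the generated rhythmic genes", {
  # 10 strongly rhythmic (A/M >= 0.4) + 5 flat genes, low noise
  rhythmic_names <- sprintf("rg%02d", 1:10)
  flat_names <- sprintf("fg%02d", 1:5)
  genes <- c(
    lapply(seq_along(rhythmic_names), function(i)
      gene_spec(rhythmic_names[i], mesor = 1, amplitude = 0.45,
                acrophase = i * 0.6, noise_sd = 0.1)),
    lapply(flat_names, function(nm)
      gene_spec(nm, mesor = 1, amplitude = 0, noise_sd = 0.1)))
  d <- generate_expression_dataset(genes, study_design(seed = 303))
  tab <- rhythm_table(d)
  expect_equal(nrow(tab), 15)
  expect_setequal(tab$gene[tab$rhythmic], rhythmic_names)
})

test_that("rhythm_table flags fit failures per gene without aborting", {
  d <- data.frame(sample_id = c("a", "b", "c", "d", "e", "f"),
                  gene = c(rep("ok", 4), rep("short", 2)),
                  zt = c(0, 6, 12, 18, 0, 6), replicate = 1,
                  value = c(1, 2, 1, 0.5, 1, 1))
  tab <- rhythm_table(d)
  expect_equal(tab$note[tab$gene == "ok"], "")
  expect_true(nzchar(tab$note[tab$gene == "short"]))
  expect_true(is.na(tab$amplitude[tab$gene == "short"]))
})

test_that("timepoint-mean fitting agrees with replicate fitting when noiseless", {
  g <- gene_spec("g", 0.6, 0.25, 1.1, noise_sd = 0)
  d <- generate_expression_dataset(list(g), study_design(seed = 2))
  t_rep <- rhythm_table(d, fit_on = "replicates")
  t_mean <- rhythm_table(d, fit_on = "timepoint_means")
  expect_equal(t_rep$amplitude, t_mean$amplitude, tolerance = 1e-9)
  expect_equal(t_rep$acrophase, t_mean$acrophase, tolerance = 1e-9)
})

test_that("count_rhythmic counts strictly and validates genes", {
  tab <- data.frame(gene = c("a", "b", "c"), p_value = c(0.1, 0.3, 0.29))
  expect_equal(count_rhythmic(tab, c("a", "b", "c")), 2L)
  expect_equal(count_rhythmic(tab, character(0)), 0L)
  expect_error(count_rhythmic(tab, c("a", "zz")), "zz")
})
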