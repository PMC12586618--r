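# Function-on-scalar regression: recovery, identities, inference behavior.

test_that("the unpenalized limit recovers noise-free truth to machine precision", {
  fx <- fosrTruthFixture()
  ts <- assembleTrajectories(fx$long)
  fit <- fitFosr(ts, "LA", fosrSpec(n_basis = 10L, subject_effect = FALSE,
                                    sp = c(0, 0)))
  cv <- fosrCurves(fit)
  expect_lt(sqrt(mean((cv$beta0 - fx$beta0)^2)), 1e-6)
  expect_lt(sqrt(mean((cv$beta1 - fx$beta1)^2)), 1e-6)
})

test_that("group prediction difference is identically the group curve", {
  fx <- fosrTruthFixture(seed = 4)
  ts <- assembleTrajectories(fx$long)
  fit <- fitFosr(ts, "LA", fosrSpec(n_basis = 8L))
  pg <- predictCurves(fit, "group")
  expect_equal(pg$value[pg$unit == "AWS"] - pg$value[pg$unit == "FS"],
               fosrCurves(fit)$beta1, tolerance = 1e-10)
  expect_error(predictCurves(fit, "trial"), "arg")
})

test_that("without subject effects the subject predictions collapse onto groups", {
  set.seed(1)
  subj <- sprintf("S%02d", 1:8); grp <- rep(c("FS", "AWS"), each = 4)
  long <- makeLong(subj, grp, 3, function(s, g, r, site)
    5 + 2 * sin(seq(0, 2 * pi, length.out = 40)) +
      (g == "AWS") * cos(seq(0, pi, length.out = 40)) + rnorm(40, 0, 0.2))
  ts <- assembleTrajectories(long)
  fit <- fitFosr(ts, "LA", fosrSpec(n_basis = 8L, n_basis_subject = 5L))
  ps <- predictCurves(fit, "subject"); pg <- predictCurves(fit, "group")
  for (s in subj) {
    g <- grp[match(s, subj)]
    expect_lt(max(abs(ps$value[ps$unit == s] - pg$value[pg$unit == g])), 0.1)
  }
})

test_that("predictions agree with an independent basis-expansion evaluation", {
  fx <- fosrTruthFixture(seed = 6)
  ts <- assembleTrajectories(fx$long)
  fit <- fitFosr(ts, "LA", fosrSpec(n_basis = 8L, subject_effect = FALSE))
  m <- fit@model
  nd <- data.frame(t = seq_len(fit@t_star), x = 0)
  X0 <- mgcv::PredictMat(m$smooth[[1]], nd)
  idx0 <- with(m$smooth[[1]], first.para:last.para)
  ref <- as.numeric(coef(m)[1] + X0 %*% coef(m)[idx0])
  expect_equal(fit@beta0, ref, tolerance = 1e-10)
  X1 <- mgcv::PredictMat(m$smooth[[2]], transform(nd, x = 1))
  idx1 <- with(m$smooth[[2]], first.para:last.para)
  expect_equal(fit@beta1, as.numeric(X1 %*% coef(m)[idx1]), tolerance = 1e-10)
})

test_that("swapping the reference group flips the sign of the group curve", {
  fx <- fosrTruthFixture(seed = 8)
  ts <- assembleTrajectories(fx$long)
  # exact invariance requires the same penalty on the group curve and a free
  # intercept curve (penalizing beta0 vs beta0 + beta1 breaks the symmetry)
  s1 <- fosrSpec(n_basis = 8L, reference = "FS", subject_effect = FALSE,
                 sp = c(0, 0.5))
  s2 <- fosrSpec(n_basis = 8L, reference = "AWS", subject_effect = FALSE,
                 sp = c(0, 0.5))
  f1 <- fitFosr(ts, "LA", s1)
  f2 <- fitFosr(ts, "LA", s2)
  expect_equal(fosrCurves(f1)$beta1, -fosrCurves(f2)$beta1, tolerance = 1e-6)
  expect_equal(fosrCurves(f1)$beta0,
               fosrCurves(f2)$beta0 + fosrCurves(f2)$beta1, tolerance = 1e-6)
})

test_that("an infinite penalty drives the group curve into the penalty null space", {
  set.seed(3)
  subj <- sprintf("S%02d", 1:6); grp <- rep(c("FS", "AWS"), each = 3)
  long <- makeLong(subj, grp, 2, function(s, g, r, site)
    6 + (g == "AWS") * 2 * sin(seq(0, 2 * pi, length.out = 40)) + rnorm(40, 0, 0.3))
  ts <- assembleTrajectories(long)
  fit <- fitFosr(ts, "LA", fosrSpec(n_basis = 10L, subject_effect = FALSE,
                                    sp = c(0, 1e10)))
  b1 <- fosrCurves(fit)$beta1
  # second-order difference penalty: null space = linear functions
  expect_lt(max(abs(diff(b1, differences = 2))), 1e-6)
})

test_that("the group-term edf grows with the true effect roughness", {
  set.seed(1)
  subj <- sprintf("S%02d", 1:8); grp <- rep(c("FS", "AWS"), each = 4)
  edfs <- sapply(c(1, 3, 6), function(k) {
    long <- makeLong(subj, grp, 2, function(s, g, r, site)
      8 + (g == "AWS") * 2 * sin(k * pi * seq(0, 1, length.out = 40)) +
        rnorm(40, 0, 0.3))
    ts <- assembleTrajectories(long)
    f <- fitFosr(ts, "LA", fosrSpec(n_basis = 12L, n_basis_subject = 4L))
    unname(f@edf[grep(":x", names(f@edf))])
  })
  expect_true(all(diff(edfs) > 0))
})

test_that("Wald and permutation inference agree on a strong-effect fixture", {
  b <- genTrajectories(fosrSimDesign(3, n_per_group = 4, n_reps = 3,
                                     ttr_amp_aws = 0.2))
  ts <- assembleTrajectories(bundleData(b))
  fit <- fitFosr(ts, "TTR", fosrSpec(n_basis = 7L, n_basis_subject = 5L))
  w <- testGroupEffect(fit, "wald")
  p <- testGroupEffect(fit, "permutation", n_perm = 49, seed = 4)
  expect_lt(w$p, 0.02)
  expect_equal(p$p, 1 / 50)  # at the permutation resolution floor
  expect_error(testGroupEffect(fit, "permutation", n_perm = 10), "n_perm")
})

test_that("the fitted group-curve peak lands on the true bump location", {
  set.seed(12)
  subj <- sprintf("S%02d", 1:8); grp <- rep(c("FS", "AWS"), each = 4)
  hits <- sapply(1:20, function(rep_i) {
    bump <- 3 * exp(-(seq_len(40) - 20)^2 / (2 * 3^2))
    long <- makeLong(subj, grp, 2, function(s, g, r, site)
      6 + (g == "AWS") * bump + rnorm(40, 0, 0.4))
    ts <- assembleTrajectories(long)
    f <- fitFosr(ts, "LA", fosrSpec(n_basis = 12L, n_basis_subject = 4L))
    which.max(fosrCurves(f)$beta1)
  })
  expect_true(all(abs(hits - 20) <= 2))
})

test_that("degenerate designs are rejected", {
  long <- makeLong(c("A", "B"), c("FS", "FS"), 2, function(s, g, r, site)
    rep(4, 30))
  ts <- assembleTrajectories(long)
  expect_error(fitFosr(ts, "LA"), "model error")
})
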