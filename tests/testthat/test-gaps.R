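# Mixture segmentation, thresholding and gap tracking.

test_that("constrained GMM recovers three known classes", {
  set.seed(42)
  v <- c(rnorm(3334, 30, 10), rnorm(3333, 110, 10), rnorm(3333, 200, 10))
  fit <- fitGmm3(v, seed = 1)
  expect_true(fit@converged)
  expect_true(all(abs(fit@means - c(30, 110, 200)) <= 2))
  expect_true(all(diff(fit@means) > 0))
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
  thr <- thresholdFromDark(fit)
  expect_gt(as.numeric(thr), 30)
  expect_lt(as.numeric(thr), 110)
  # seed-determinism
  fit2 <- fitGmm3(v, seed = 1)
  expect_identical(fit@means, fit2@means)
})

test_that("degenerate grey values are rejected or flagged", {
  expect_error(fitGmm3(rep(100, 50)), "manual threshold")
  expect_error(fitGmm3(c(1, 2, 3)), "at least 30")
  # two-class data: converges with a near-zero weight, threshold still defined
  set.seed(7)
  v2 <- c(rnorm(500, 40, 5), rnorm(500, 190, 5))
  fit <- suppressWarnings(fitGmm3(v2))
  expect_true(min(fit@weights) < 0.2)
  thr <- thresholdFromDark(fit)
  expect_true(is.finite(as.numeric(thr)))
  expect_gt(as.numeric(thr), 40)
  expect_lt(as.numeric(thr), 190)
})

test_that("crossover threshold sits midway between symmetric components", {
  fit <- new("MixtureFit", weights = c(0.5, 0.5 - 1e-9, 1e-9),
             means = c(0, 4, 1000), sds = c(1, 1, 1), loglik = 0,
             n_iter = 1L, converged = TRUE, flags = character())
  thr <- thresholdFromDark(fit)
  expect_equal(as.numeric(thr), 2, tolerance = 1e-3)
  expect_false(attr(thr, "fallback"))
  # vanished dark weight takes the logged fallback path
  fit0 <- new("MixtureFit", weights = c(0, 0.5, 0.5),
              means = c(10, 100, 200), sds = c(2, 10, 10), loglik = 0,
              n_iter = 1L, converged = TRUE, flags = character())
  thr0 <- thresholdFromDark(fit0)
  expect_true(attr(thr0, "fallback"))
  expect_equal(as.numeric(thr0), 10 + 6, tolerance = 1e-9)
})

test_that("binarization is elementwise and monotone in the threshold", {
  m <- matrix(c(10, 50, 90, 130), 2)
  expect_true(all(binarizeProfile(m, 200) == 1))
  expect_true(all(binarizeProfile(m, 10) == 0))   # threshold at min: no air
  set.seed(3)
  v <- matrix(runif(600, 0, 255), 30)
  b1 <- binarizeProfile(v, 80); b2 <- binarizeProfile(v, 120)
  runlen <- function(b) sapply(seq_len(ncol(b)), function(f) {
    r <- rle(b[, f]); sum(r$lengths[r$values == 1])
  })
  expect_true(all(runlen(b2) >= runlen(b1)))
})

test_that("gap tracking follows a drifting gap and survives closures", {
  # single gap drifting 1 px per frame
  b <- matrix(0L, 30, 10)
  for (f in 1:10) b[(5 + f):(9 + f), f] <- 1L
  tr <- trackGap(b)
  expect_equal(widthPx(tr), rep(5, 10))
  expect_equal(tr@start, as.integer(5 + 1:10))
  # closes for 3 frames then reopens at the same place
  b2 <- matrix(0L, 30, 10)
  for (f in c(1:3, 7:10)) b2[10:14, f] <- 1L
  tr2 <- trackGap(b2)
  expect_equal(widthPx(tr2), c(5, 5, 5, 0, 0, 0, 5, 5, 5, 5))
  expect_equal(tr2@start[7], 10L)
})

test_that("overlap keeps the original gap unless an override forces a switch", {
  b <- matrix(0L, 30, 5)
  b[10:14, ] <- 1L
  b[20:28, 3] <- 1L             # spurious longer second run at frame 3
  tr <- trackGap(b)
  expect_equal(widthPx(tr), rep(5, 5))
  ov <- data.frame(frame = 3, run_index = 2)
  tr2 <- trackGap(b, overrides = ov)
  expect_equal(widthPx(tr2)[3], 9)
  expect_identical(nrow(tr2@overrides), 1L)
  expect_error(trackGap(b, overrides = data.frame(frame = 2, run_index = 5)),
               "configuration error")
})

test_that("reopening picks the run nearest the last open gap", {
  b <- matrix(0L, 40, 4)
  b[10:14, 1] <- 1L
  # frame 2 closed; frame 3 reopens with two candidates
  b[30:34, 3] <- 1L; b[11:13, 3] <- 1L
  b[11:13, 4] <- 1L
  tr <- trackGap(b)
  expect_equal(widthPx(tr), c(5, 0, 3, 3))
  expect_equal(tr@start[3], 11L)
})

test_that("TTR is the tissue run from the origin to the first air pixel", {
  b <- matrix(0L, 31, 3)
  b[13:31, 1] <- 1L          # 12 tissue px then air
  b[, 2] <- 0L               # fully tissue
  b[1, 3] <- 1L              # origin in air
  tr <- suppressWarnings(measureTTR(b))
  expect_equal(widthPx(tr), c(12, 31, 0))
  expect_true(any(grepl("no tip found", tr@flags)))
  expect_true(any(grepl("origin lies in air", tr@flags)))
  expect_warning(measureTTR(b[, 3, drop = FALSE]), "origin")
})
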