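# Grid geometry and line-profile extraction.

lm_ax <- list(posterior = c(64, 90), anterior = c(64, 30))
lips <- list(upper = c(50, 22), lower = c(78, 22))

test_that("axis-aligned baseline gives the documented line geometry", {
  g <- buildGrid(lm_ax, lips)
  expect_equal(g@midpoint, c(64, 60))
  ln <- gridLines(g)
  ttr <- ln[ln$site == "TTR", ]
  # 0 degrees: from the midpoint toward the anterior landmark
  expect_equal(c(ttr$dir_r, ttr$dir_c), c(0, -1))
  expect_equal(ttr$length_px, 30)
  # 90 degrees clockwise: toward the image top (palate, supine head)
  tb2 <- ln[ln$site == "TB-PD2", ]
  expect_equal(c(tb2$dir_r, tb2$dir_c), c(-1, 0), tolerance = 1e-12)
  # lip line connects the lip centers
  la <- ln[ln$site == "LA", ]
  expect_equal(la$length_px, 28)
  expect_equal(c(la$dir_r, la$dir_c), c(1, 0))
})

test_that("angled lines are exactly half the baseline length", {
  g <- buildGrid(list(posterior = c(64, 91), anterior = c(64, 30)), lips)
  ln <- gridLines(g)
  expect_true(all(ln$length_px[ln$site != "LA"] == 61 / 2))
})

test_that("grid construction is equivariant under landmark translation and rotation", {
  g0 <- buildGrid(lm_ax, lips)
  shift <- function(p) p + c(2, 2)
  g1 <- buildGrid(lapply(lm_ax, shift), lapply(lips, shift))
  expect_equal(gridLines(g1)$origin_r, gridLines(g0)$origin_r + 2)
  expect_equal(gridLines(g1)$origin_c, gridLines(g0)$origin_c + 2)
  expect_equal(gridLines(g1)[, c("dir_r", "dir_c", "length_px")],
               gridLines(g0)[, c("dir_r", "dir_c", "length_px")])

  # independent rotation oracle: clockwise on screen, (x, y) = (col, row)
  phi <- 23 * pi / 180
  rot <- function(p, ctr = c(64, 64)) {
    v <- p - ctr
    c(ctr[1] + v[2] * sin(phi) + v[1] * cos(phi),
      ctr[2] + v[2] * cos(phi) - v[1] * sin(phi))
  }
  g2 <- buildGrid(lapply(lm_ax, rot), lapply(lips, rot))
  for (i in seq_len(nrow(gridLines(g0)))) {
    d0 <- c(gridLines(g0)$dir_r[i], gridLines(g0)$dir_c[i])
    d2 <- c(gridLines(g2)$dir_r[i], gridLines(g2)$dir_c[i])
    dr <- c(d0[2] * sin(phi) + d0[1] * cos(phi),
            d0[2] * cos(phi) - d0[1] * sin(phi))
    expect_equal(d2, dr, tolerance = 1e-10)
  }
  expect_equal(gridLines(g2)$length_px, gridLines(g0)$length_px,
               tolerance = 1e-10)
})

test_that("degenerate landmarks and bad angles are rejected", {
  expect_error(buildGrid(list(posterior = c(64, 30), anterior = c(64, 30)), lips),
               "coincident")
  expect_error(buildGrid(lm_ax, lips, angles_deg = c(TTR = -5, `TT-TD` = 7.5,
               `TT-ARD` = 15, `TB-PD1` = 60, `TB-PD2` = 90)), "angles")
})

test_that("profile extraction reproduces constant, step and ramp images", {
  g <- buildGrid(lm_ax, lips)
  const <- ImageSequence(array(7, dim = c(128, 128, 3)))
  p <- extractProfile(const, g, "TTR")
  expect_true(all(profileValues(p) == 7))
  expect_equal(ncol(profileValues(p)), 3L)

  # axis-aligned vertical line over a horizontal step image
  img <- matrix(10, 128, 128); img[40:128, ] <- 200
  stepseq <- ImageSequence(array(img, dim = c(128, 128, 1)))
  pv <- profileValues(extractProfile(stepseq, g, "TB-PD2"))  # upward from (64, 60)
  # positions 0..24 reach rows 64..40 (bright); position 25 crosses to row 39
  expect_true(all(pv[1:25, 1] == 200))
  expect_equal(pv[26, 1], 10)

  # 45-degree line through a linear ramp: bilinear must be exact
  ramp <- outer(seq_len(128), seq_len(128), function(r, c) 0.3 * r + 1.7 * c)
  rseq <- ImageSequence(array(ramp, dim = c(128, 128, 1)))
  g45 <- buildGrid(list(posterior = c(100, 100), anterior = c(40, 40)), lips)
  ln <- gridLines(g45); ttr <- ln[ln$site == "TTR", ]
  pv45 <- profileValues(extractProfile(rseq, g45, "TTR"))[, 1]
  tpos <- seq_along(pv45) - 1
  expected <- 0.3 * (ttr$origin_r + tpos * ttr$dir_r) +
              1.7 * (ttr$origin_c + tpos * ttr$dir_c)
  expect_equal(pv45, expected, tolerance = 1e-9)
})

test_that("profile extraction is linear in image intensities", {
  g <- buildGrid(lm_ax, lips)
  set.seed(4)
  a1 <- array(runif(128 * 128 * 2, 0, 255), dim = c(128, 128, 2))
  a2 <- array(runif(128 * 128 * 2, 0, 255), dim = c(128, 128, 2))
  p1 <- profileValues(extractProfile(ImageSequence(a1), g, "TB-PD1"))
  p2 <- profileValues(extractProfile(ImageSequence(a2), g, "TB-PD1"))
  p12 <- profileValues(extractProfile(ImageSequence(2 * a1 + 3 * a2), g, "TB-PD1"))
  expect_equal(p12, 2 * p1 + 3 * p2, tolerance = 1e-10)
})

test_that("out-of-bounds sampling raises a geometry error naming the position", {
  g <- buildGrid(lm_ax, lips)
  tiny <- ImageSequence(array(0, dim = c(50, 128, 1)))  # TB-PD2 starts below row 50
  expect_error(extractProfile(tiny, g, "TB-PD2"), "geometry error")
})

test_that("per-trial regridding rebuilds grids from the landmark table", {
  tab <- data.frame(
    trial = rep(c("t1", "t2"), each = 4),
    point = rep(c("posterior", "anterior", "upper_lip", "lower_lip"), 2),
    row = c(64, 64, 50, 78, 66, 66, 52, 80),
    col = c(90, 30, 22, 22, 92, 32, 24, 24))
  g1 <- regridPerTrial(tab, "t1")
  g1b <- regridPerTrial(tab, "t1")
  expect_equal(gridLines(g1), gridLines(g1b))
  g2 <- regridPerTrial(tab, "t2")  # t2 = t1 translated by (+2, +2)
  expect_equal(gridLines(g2)$origin_r, gridLines(g1)$origin_r + 2)
  expect_equal(gridLines(g2)$origin_c, gridLines(g1)$origin_c + 2)
  expect_error(regridPerTrial(tab, "t3"), "configuration error")
})
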