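# Simpson-rule L2, energy distances, clustering, C-index, Fisher, PCA,
# allocation and the TTR-only variant.

test_that("Simpson L2 matches closed forms", {
  expect_equal(simpsonL2(rep(2, 11), rep(2, 11)), 0)
  expect_equal(simpsonL2(rep(1, 11), rep(0, 11), dt = 1 / 10), 1)
  tt <- seq(0, pi, length.out = 101)
  expect_equal(simpsonL2(sin(tt), 0 * tt, dt = pi / 100), sqrt(pi / 2),
               tolerance = 1e-6)
  expect_error(simpsonL2(1:5, 1:4), "equal length")
})

test_that("Simpson L2 satisfies the metric axioms on random triples", {
  set.seed(21)
  for (i in 1:300) {
    n <- sample(c(3:12, 20, 51), 1)
    f <- runif(n); g <- runif(n); h <- runif(n)
    dfg <- simpsonL2(f, g); dgh <- simpsonL2(g, h); dfh <- simpsonL2(f, h)
    expect_equal(dfg, simpsonL2(g, f))
    expect_gte(dfg, 0)
    expect_lte(dfh, dfg + dgh + 1e-12)
    expect_equal(simpsonL2(f, f), 0)
  }
})

test_that("energy distance reduces to closed forms and a brute-force oracle", {
  A <- matrix(c(0, 0), 1)
  B <- matrix(c(3, 4), 1)
  expect_equal(energyDistance(A, B), 10)  # 2 * ||x - y||
  set.seed(5)
  X <- matrix(rnorm(6), 3, 2); Y <- matrix(rnorm(6), 3, 2)
  expect_equal(energyDistance(X, X), 0)
  # explicit double-loop oracle
  dd <- function(a, b) sqrt(sum((a - b)^2))
  cross <- mean(sapply(1:3, function(i) sapply(1:3, function(j) dd(X[i, ], Y[j, ]))))
  wX <- mean(sapply(1:3, function(i) sapply(1:3, function(j) dd(X[i, ], X[j, ]))))
  wY <- mean(sapply(1:3, function(i) sapply(1:3, function(j) dd(Y[i, ], Y[j, ]))))
  expect_equal(energyDistance(X, Y), 2 * cross - wX - wY, tolerance = 1e-12)
  expect_gte(energyDistance(X, Y), 0)
  expect_error(energyDistance(X, matrix(1, 2, 3)), "dimension mismatch")
})

test_that("energy distance vanishes iff the empirical distributions match", {
  set.seed(6)
  X <- matrix(rnorm(10), 5, 2)
  expect_lt(abs(energyDistance(X, X[sample(5), ])), 1e-12)
  expect_gt(energyDistance(X, X + 1), 0)
})

test_that("pairwise dissimilarity table has 15 columns and composes simpsonL2", {
  long <- makeLong(c("A", "B"), c("FS", "AWS"), 1, function(s, g, r, site)
    if (s == "A") rep(2, 21) else seq(0, 4, length.out = 21) + (site == "TTR"))
  ts <- assembleTrajectories(long)
  tab <- pairDissim(ts)
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(grepl("\\|", names(tab))), 15L)
  # subject A: all sites share one curve -> all 15 dissimilarities 0
  expect_true(all(tab[tab$subject == "A", grepl("\\|", names(tab))] == 0))
  # compositional oracle for subject B
  W <- trajMatrix(ts); idx <- trajIndex(ts)
  bTTR <- W[, idx$subject == "B" & idx$site == "TTR"]
  bLA <- W[, idx$subject == "B" & idx$site == "LA"]
  expect_equal(tab[tab$subject == "B", "LA|TTR"], simpsonL2(bLA, bTTR))
})

test_that("subject averaging matches a naive group-by mean", {
  long <- makeLong(c("A", "B"), c("FS", "AWS"), 3, function(s, g, r, site)
    rep(r + (site == "LA") * 2, 21))
  ts <- assembleTrajectories(long)
  tab <- pairDissim(ts)
  avg <- subjectAverage(tab)
  expect_identical(nrow(avg), 2L)
  pn <- names(tab)[grepl("\\|", names(tab))]
  for (s in c("A", "B"))
    expect_equal(unlist(avg[avg$subject == s, pn]),
                 colMeans(tab[tab$subject == s, pn]))
  # {2, 4} averages to 3
  t2 <- tab[tab$repetition <= 2, ]
  t2[t2$repetition == 1, pn] <- 2; t2[t2$repetition == 2, pn] <- 4
  expect_true(all(subjectAverage(t2)[, pn] == 3))
})

test_that("subject distance matrix modes agree where they must", {
  long <- makeLong(c("A", "B", "C"), c("FS", "AWS", "FS"), 1,
                   function(s, g, r, site)
                     rep(match(s, LETTERS) + (site == "TTR") * 2, 21))
  ts <- assembleTrajectories(long)
  tab <- pairDissim(ts)
  Dr <- subjectDistanceMatrix(tab, mode = "repetition")
  Dm <- subjectDistanceMatrix(tab, mode = "mean")
  expect_equal(Dr, Dm)  # singletons: E = 2 ||x - y||
  expect_true(isSymmetric(unname(Dr)))
  expect_true(all(diag(Dr) == 0))
  # identical repetition sets -> zero distance
  pn <- names(tab)[grepl("\\|", names(tab))]
  t2 <- rbind(tab[rep(1, 2), ], tab[rep(1, 2), ])
  t2$subject <- rep(c("A", "B"), each = 2)
  t2$group <- rep(c("FS", "AWS"), each = 2)
  t2$repetition <- rep(1:2, 2)
  t2[, pn] <- matrix(rep(as.numeric(seq_len(2 * length(pn))), 2),
                     nrow = 4, byrow = FALSE)[, seq_along(pn)]
  t2[3:4, pn] <- t2[1:2, pn]
  D0 <- subjectDistanceMatrix(t2)
  expect_equal(D0["A", "B"], 0)
})

test_that("hierarchical clustering recovers constructed separation", {
  # three tight triplets on a line
  x <- c(0, 0.1, 0.2, 5, 5.1, 5.2, 10, 10.1, 10.2)
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("S", 1:9), paste0("S", 1:9))
  truth <- rep(1:3, each = 3)
  for (link in c("ward", "complete")) {
    lab <- cutree(clusterSubjects(D, link), 3)
    expect_equal(ari(lab, truth), 1)
  }
  # n = 2: single merge at D(1, 2)
  D2 <- matrix(c(0, 3, 3, 0), 2)
  tr <- clusterSubjects(D2, "complete")
  expect_equal(tr$height, 3)
})

test_that("complete-linkage merge heights match a hand Lance-Williams computation", {
  # d(1,2)=1, d(1,3)=4, d(1,4)=6, d(2,3)=3, d(2,4)=7, d(3,4)=2
  D <- matrix(0, 4, 4)
  D[1, 2] <- 1; D[1, 3] <- 4; D[1, 4] <- 6; D[2, 3] <- 3; D[2, 4] <- 7; D[3, 4] <- 2
  D <- D + t(D)
  tr <- clusterSubjects(D, "complete")
  # by hand: merge {1,2} at 1; merge {3,4} at 2; complete-linkage distance
  # between the pairs = max(4, 6, 3, 7) = 7
  expect_equal(tr$height, c(1, 2, 7))
})

test_that("C-index hits its extremes and a brute-force oracle", {
  x <- c(0, 0.1, 5, 5.1)
  D <- as.matrix(dist(x))
  expect_equal(as.numeric(cIndex(D, c(1, 1, 2, 2))), 0)  # perfect separation
  # worst labeling: clusters along the diagonals of a square, so the two
  # within-cluster distances are exactly the two largest distances
  sq <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_equal(as.numeric(cIndex(as.matrix(dist(sq)), c(1, 1, 2, 2))), 1)
  # 5-point mixed labels vs exhaustive computation
  set.seed(31)
  P <- matrix(rnorm(10), 5, 2)
  D5 <- as.matrix(dist(P))
  lab <- c(1, 1, 2, 2, 1)
  pairs <- t(combn(5, 2))
  d <- D5[pairs]
  within <- lab[pairs[, 1]] == lab[pairs[, 2]]
  Nw <- sum(within)
  Sw <- sum(d[within])
  Smin <- sum(sort(d)[1:Nw]); Smax <- sum(sort(d, decreasing = TRUE)[1:Nw])
  expect_equal(as.numeric(cIndex(D5, lab)), (Sw - Smin) / (Smax - Smin))
  # all distances equal -> defined as 0
  De <- matrix(1, 4, 4); diag(De) <- 0
  expect_equal(as.numeric(cIndex(De, c(1, 1, 2, 2))), 0)
})

test_that("C-index selection finds planted cluster counts", {
  x3 <- c(0, 0.1, 0.2, 5, 5.1, 5.2, 10, 10.1, 10.2)
  D3 <- as.matrix(dist(x3))
  expect_identical(as.integer(selectK(D3, 2:6)), 3L)
  x2 <- c(0, 0.1, 0.2, 0.3, 7, 7.1, 7.2, 7.3)
  expect_identical(as.integer(selectK(as.matrix(dist(x2)), 2:6)), 2L)
  # a single diffuse blob must not crash
  set.seed(8)
  Db <- as.matrix(dist(runif(12)))
  expect_true(as.integer(suppressWarnings(selectK(Db, 2:5))) %in% 2:5)
})

test_that("Fisher exact r x c matches closed forms and brute-force enumeration", {
  expect_equal(as.numeric(fisherExactRxC(matrix(c(3, 0, 0, 3), 2))), 0.1,
               tolerance = 1e-12)
  # proportional rows -> independence, p = 1
  expect_equal(as.numeric(fisherExactRxC(matrix(c(2, 4, 3, 6), 2))), 1,
               tolerance = 1e-9)
  # 3 x 2 vs exhaustive enumeration over all tables with the observed margins
  tab <- matrix(c(5, 4, 0, 0, 1, 5), 3, 2)
  rs <- rowSums(tab); cs <- colSums(tab)
  logp <- function(m) sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
  obs <- logp(tab)
  ptot <- 0
  for (a in 0:min(rs[1], cs[1])) for (b in 0:min(rs[2], cs[1] - a)) {
    cc <- cs[1] - a - b
    if (cc < 0 || cc > rs[3]) next
    m <- cbind(c(a, b, cc), rs - c(a, b, cc))
    if (logp(m) <= obs + 1e-7) ptot <- ptot + exp(logp(m))
  }
  expect_equal(as.numeric(fisherExactRxC(tab)), ptot, tolerance = 1e-7)
  expect_error(fisherExactRxC(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("PCA of dissimilarities behaves on degenerate and isotropic data", {
  # data on an exact line -> PC1 share 1
  t <- seq(-1, 1, length.out = 10)
  X <- outer(t, c(1, 2, 3))
  p <- pcaDissim(X)
  expect_equal(p$shares[1], 1)
  # reconstruction from all components reproduces the centered data
  Xc <- scale(X, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), unclass(Xc), tolerance = 1e-10,
               ignore_attr = TRUE)
  # isotropic Gaussian -> roughly equal shares
  set.seed(13)
  G <- matrix(rnorm(2000 * 3), 2000, 3)
  pg <- pcaDissim(G)
  expect_true(all(abs(pg$shares - 1 / 3) < 0.05))
})

test_that("allocation accuracy counts majorities, ties and fractions", {
  expect_equal(allocationAccuracy(c(1, 1, 2, 2), c("FS", "FS", "AWS", "AWS"))$fraction, 1)
  lab <- rep(1:2, each = 5)
  grp <- c(rep("AWS", 4), "FS", rep("FS", 4), "AWS")
  expect_equal(allocationAccuracy(lab, grp)$fraction, 0.8)
  # tie -> ambiguous members excluded from the denominator
  a <- allocationAccuracy(c(1, 1, 2, 2), c("FS", "AWS", "FS", "FS"))
  expect_true(all(a$flags$status[1:2] == "ambiguous"))
  expect_equal(a$fraction, 1)
  # brute-force oracle on random labelings
  set.seed(17)
  for (i in 1:20) {
    lab <- sample(1:3, 20, replace = TRUE)
    grp <- sample(c("AWS", "FS"), 20, replace = TRUE)
    res <- allocationAccuracy(lab, grp)
    correct <- 0; total <- 0
    for (j in seq_along(lab)) {
      cnt <- table(grp[lab == lab[j]])
      top <- names(cnt)[cnt == max(cnt)]
      if (length(top) == 1) {
        total <- total + 1
        if (grp[j] == top) correct <- correct + 1
      }
    }
    expect_equal(res$fraction, if (total) correct / total else NA_real_)
  }
})

test_that("TTR-only features equal the Simpson L2 norm against zero", {
  long <- makeLong(c("A", "B"), c("FS", "AWS"), 2, function(s, g, r, site)
    if (s == "A") rep(0, 21) else rep(3, 21))
  ts <- assembleTrajectories(long)
  f <- ttrOnlyFeatures(ts, dt = 1 / 20)
  expect_equal(f$ttr_l2[f$subject == "A"], c(0, 0))
  expect_equal(f$ttr_l2[f$subject == "B"], c(3, 3))  # constant c on [0, 1] -> c
  W <- trajMatrix(ts); idx <- trajIndex(ts)
  j <- which(idx$subject == "B" & idx$site == "TTR")[1]
  expect_equal(f$ttr_l2[f$subject == "B"][1],
               simpsonL2(W[, j], numeric(21), dt = 1 / 20))
})
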