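# Inter-articulator spatiotemporal dissimilarities (Simpson-rule L2 metric),
# energy distances between subjects, hierarchical clustering with C-index
# model selection, Fisher exact test of cluster/group independence, PCA with
# loadings, allocation scoring, and the TTR-only variant.

#' Simpson-rule L2 distance between two sampled curves
#'
#' `sqrt( integral (f - g)^2 dt )` with the integral approximated by Simpson's
#' rule on the sampling grid. Odd point counts use composite Simpson; even
#' counts use Simpson on the first n-1 points plus a trapezoid on the final
#' interval. All quadrature weights are positive, so this is a weighted
#' Euclidean norm on the grid (a true metric).
#'
#' @param f,g numeric vectors of equal length (>= 3).
#' @param dt grid spacing (default 1 frame).
#' @return nonnegative scalar.
#' @export
#' @examples
#' tt <- seq(0, pi, length.out = 101)
#' simpsonL2(sin(tt), 0 * tt, dt = pi / 100)  # sqrt(pi / 2)
simpsonL2 <- function(f, g, dt = 1) {
  if (length(f) != length(g)) stop("curves must have equal length")
  n <- length(f)
  if (n < 3L) stop("need at least 3 points for Simpson's rule")
  if (dt <= 0) stop("dt must be positive")
  d2 <- (f - g)^2
  simp <- function(v) {
    k <- length(v)                     # odd
    wts <- c(1, rep(c(4, 2), length.out = k - 2L), 1)
    wts[k] <- 1
    sum(wts * v) * dt / 3
  }
  I <- if (n %% 2L == 1L) simp(d2)
       else simp(d2[1:(n - 1L)]) + dt * (d2[n - 1L] + d2[n]) / 2
  sqrt(I)
}

.pairNames <- function(sites = .SITES) {
  cmb <- utils::combn(sites, 2)
  paste(cmb[1, ], cmb[2, ], sep = "|")
}

#' Pairwise inter-site dissimilarities per subject and repetition
#'
#' For every trial, the Simpson-rule L2 distance between each of the 15
#' unordered pairs of site trajectories. Trials missing a site are skipped
#' with a log entry (attribute `"skipped"`).
#'
#' @param ts a [TrajectorySet-class].
#' @param dt time step (default 1 frame; absolute scaling cancels from all
#'   label-level results).
#' @return data.frame: subject, group, repetition, then one column per site
#'   pair ("A|B").
#' @export
pairDissim <- function(ts, dt = 1) {
  idx <- trajIndex(ts)
  W <- trajMatrix(ts)
  trials <- unique(idx[, c("subject", "group", "repetition")])
  pn <- .pairNames()
  cmb <- utils::combn(.SITES, 2)
  out <- list(); skipped <- list()
  for (i in seq_len(nrow(trials))) {
    sel <- idx$subject == trials$subject[i] & idx$repetition == trials$repetition[i]
    sites_here <- idx$site[sel]
    if (!all(.SITES %in% sites_here)) {
      skipped[[length(skipped) + 1L]] <- trials[i, ]
      next
    }
    cols <- which(sel)[match(.SITES, sites_here)]
    names(cols) <- .SITES
    v <- vapply(seq_len(ncol(cmb)), function(j)
      simpsonL2(W[, cols[cmb[1, j]]], W[, cols[cmb[2, j]]], dt = dt),
      numeric(1))
    row <- cbind(trials[i, ], as.data.frame(as.list(stats::setNames(v, pn)),
                                            check.names = FALSE))
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) stop("no complete trials for pairwise dissimilarities")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame()
  res
}

#' Average the pair-dissimilarity table per subject
#'
#' @param tab output of [pairDissim()].
#' @return data.frame: subject, group, then the 15 pair means.
#' @export
subjectAverage <- function(tab) {
  pn <- .pairNames()
  subs <- unique(tab[, c("subject", "group")])
  rows <- lapply(seq_len(nrow(subs)), function(i) {
    sel <- tab$subject == subs$subject[i]
    cbind(subs[i, ],
          as.data.frame(as.list(colMeans(tab[sel, pn, drop = FALSE])),
                        check.names = FALSE))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Euclidean cross-distance matrix between row sets. Computed from explicit
# differences (not the expanded-square identity, which loses precision).
.crossDist <- function(A, B) {
  D <- matrix(0, nrow(A), nrow(B))
  tB <- t(B)
  for (i in seq_len(nrow(A)))
    D[i, ] <- sqrt(colSums((tB - A[i, ])^2))
  D
}

#' Energy distance between two empirical distributions
#'
#' `E = 2 mean||a - b|| - mean||a - a'|| - mean||b - b'||`, with Euclidean
#' norms and means over all ordered pairs (the within terms average over the
#' full n^2 pairs, self-pairs contributing 0).
#'
#' @param A,B numeric matrices (rows = observations) or vectors (single
#'   observations), sharing a column dimension.
#' @return nonnegative scalar; 0 iff the empirical distributions coincide.
#' @export
#' @examples
#' energyDistance(c(0, 0), c(3, 4))  # 2 * 5
energyDistance <- function(A, B) {
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  if (is.vector(B)) B <- matrix(B, nrow = 1)
  if (ncol(A) != ncol(B)) stop("dimension mismatch between the two sets")
  if (!nrow(A) || !nrow(B)) stop("sets must be nonempty")
  2 * mean(.crossDist(A, B)) - mean(.crossDist(A, A)) - mean(.crossDist(B, B))
}

#' Energy-distance matrix between subjects
#'
#' `mode = "repetition"` (default) treats each subject as the empirical
#' distribution of its repetition-level 15-vectors. `mode = "mean"` is the
#' literal degenerate reading: twice the Euclidean distance between subject
#' means (the two modes coincide exactly for single-repetition subjects).
#'
#' @param tab output of [pairDissim()] (repetition level), or any data.frame
#'   with subject, group, repetition and feature columns (e.g.
#'   [ttrOnlyFeatures()]).
#' @param mode "repetition" or "mean".
#' @param features feature column names; default the 15 site pairs.
#' @return symmetric distance matrix with subject dimnames and a `groups`
#'   attribute.
#' @export
subjectDistanceMatrix <- function(tab, mode = c("repetition", "mean"),
                                  features = .pairNames()) {
  mode <- match.arg(mode)
  pn <- features
  subs <- unique(tab[, c("subject", "group")])
  if (nrow(subs) < 2L) stop("need at least 2 subjects")
  sets <- lapply(subs$subject, function(s)
    as.matrix(tab[tab$subject == s, pn, drop = FALSE]))
  n <- nrow(subs)
  D <- matrix(0, n, n, dimnames = list(subs$subject, subs$subject))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- if (mode == "repetition")
      energyDistance(sets[[i]], sets[[j]])
    else 2 * sqrt(sum((colMeans(sets[[i]]) - colMeans(sets[[j]]))^2))
  }
  attr(D, "groups") <- stats::setNames(subs$group, subs$subject)
  D
}

#' Hierarchical clustering of the subject distance matrix
#'
#' Agglomerative clustering by the Lance-Williams recurrence: Ward's minimum
#' variance method (`"ward"`) or complete linkage.
#'
#' @param D symmetric distance matrix.
#' @param linkage "ward" or "complete".
#' @return a `stats::hclust` tree.
#' @export
clusterSubjects <- function(D, linkage = c("ward", "complete")) {
  linkage <- match.arg(linkage)
  stats::hclust(stats::as.dist(D),
                method = if (linkage == "ward") "ward.D2" else "complete")
}

#' C-index of a clustering
#'
#' With N_w within-cluster pairs of summed distance S_w, and S_min / S_max the
#' sums of the N_w smallest / largest pairwise distances overall:
#' `C = (S_w - S_min) / (S_max - S_min)`, in [0, 1], lower is better. If all
#' pairwise distances are equal the index is defined as 0 (flagged via
#' attribute `degenerate`).
#'
#' @param D symmetric distance matrix.
#' @param labels integer cluster labels (>= 2 nonempty clusters).
#' @return C-index in [0, 1].
#' @export
cIndex <- function(D, labels) {
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L)
    stop("C-index needs at least 2 nonempty clusters")
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  within <- labels[iu[, 1]] == labels[iu[, 2]]
  Nw <- sum(within)
  if (Nw == 0L) return(0)
  Sw <- sum(d[within])
  ds <- sort(d)
  Smin <- sum(ds[seq_len(Nw)])
  Smax <- sum(ds[seq.int(length(ds) - Nw + 1L, length(ds))])
  if (Smax - Smin < .Machine$double.eps^0.5 * max(1, Smax)) {
    res <- 0
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  (Sw - Smin) / (Smax - Smin)
}

#' Choose the number of clusters by minimizing the C-index
#'
#' @param D symmetric distance matrix.
#' @param k_range candidate cluster counts (within [2, n-1]).
#' @param linkage linkage passed to [clusterSubjects()].
#' @return integer k* (ties broken toward the smallest k), with attribute
#'   `cindex` (the curve). A spread of the C-index curve below 0.05 triggers a
#'   weak-structure warning.
#' @export
selectK <- function(D, k_range = 2:6, linkage = "ward") {
  n <- nrow(D)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("empty candidate range for k")
  tree <- clusterSubjects(D, linkage)
  cvals <- vapply(k_range, function(k)
    as.numeric(cIndex(D, stats::cutree(tree, k))), numeric(1))
  names(cvals) <- k_range
  if (max(cvals) - min(cvals) < 0.05 && min(cvals) > 0.05)
    warning("weak cluster structure: C-index spread < 0.05 across k range")
  k_star <- k_range[which.min(cvals)]
  attr(k_star, "cindex") <- cvals
  k_star
}

#' Fisher exact test for an r x c contingency table
#'
#' Exact enumeration (network algorithm) of all tables with the observed
#' margins for totals up to `exact_max`; beyond that a seeded Monte-Carlo
#' p-value on 2e5 sampled tables. Zero-margin rows and columns are dropped
#' (logged via attribute `dropped`).
#'
#' @param tab integer matrix or table of counts.
#' @param exact_max largest total for exact enumeration (default 200).
#' @param B Monte-Carlo draws beyond `exact_max`.
#' @param seed RNG seed for the Monte-Carlo fallback.
#' @return p-value.
#' @export
#' @examples
#' fisherExactRxC(matrix(c(3, 0, 0, 3), 2))  # 0.1
fisherExactRxC <- function(tab, exact_max = 200L, B = 2e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold nonnegative integer counts")
  dropped <- c(rownames(tab)[rowSums(tab) == 0], colnames(tab)[colSums(tab) == 0])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    p <- 1
    attr(p, "dropped") <- dropped
    return(p)
  }
  p <- if (sum(tab) <= exact_max)
    stats::fisher.test(tab, workspace = 2e7)$p.value
  else .withSeed(seed,
    stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value)
  attr(p, "dropped") <- dropped
  p
}

#' PCA of the subject dissimilarity profiles
#'
#' Column-centered (optionally standardized) singular value decomposition of
#' the subjects x 15-pairs matrix, with per-component variance shares and the
#' loadings of the pair features.
#'
#' @param S output of [subjectAverage()] (or a plain numeric matrix).
#' @param scale. standardize columns (default FALSE: all 15 features share
#'   units). Constant columns are dropped when scaling (logged via attribute).
#' @return list with `scores`, `shares`, `loadings`, `sdev`, `dropped`.
#' @export
pcaDissim <- function(S, scale. = FALSE) {
  X <- if (is.data.frame(S)) as.matrix(S[, .pairNames(), drop = FALSE]) else as.matrix(S)
  if (nrow(X) < 3L) stop("PCA needs at least 3 subjects")
  dropped <- character()
  if (scale.) {
    const <- apply(X, 2, function(v) stats::sd(v) < .Machine$double.eps^0.5)
    dropped <- colnames(X)[const]
    X <- X[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  shares <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, shares = shares, loadings = pc$rotation,
       sdev = pc$sdev, dropped = dropped)
}

#' Allocation accuracy of a clustering against the group labels
#'
#' Each cluster's predominant group is its majority label; a subject is
#' correctly allocated iff its group matches its cluster's majority. Clusters
#' with tied majorities have all members flagged ambiguous and excluded from
#' the denominator.
#'
#' @param labels integer cluster labels.
#' @param groups group labels, aligned with `labels`.
#' @return list with `flags` (per-subject data.frame), `fraction` and
#'   `majority` (per-cluster predominant group, NA when tied).
#' @export
allocationAccuracy <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  ks <- sort(unique(labels))
  majority <- stats::setNames(rep(NA_character_, length(ks)), ks)
  for (k in ks) {
    cnt <- table(groups[labels == k])
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) == 1L) majority[as.character(k)] <- top
  }
  maj <- majority[as.character(labels)]
  status <- ifelse(is.na(maj), "ambiguous",
                   ifelse(groups == maj, "correct", "incorrect"))
  flags <- data.frame(cluster = labels, group = groups, status = status)
  denom <- sum(status != "ambiguous")
  list(flags = flags,
       fraction = if (denom) sum(status == "correct") / denom else NA_real_,
       majority = majority)
}

#' TTR-only feature: integral of the tongue-tip-retraction profile
#'
#' The spatiotemporal dissimilarity between the TTR trajectory and a
#' hypothetical gap staying closed throughout the utterance: the Simpson-rule
#' L2 norm of the TTR curve itself, one scalar per (subject, repetition).
#'
#' @param ts a [TrajectorySet-class].
#' @param dt time step.
#' @return data.frame: subject, group, repetition, ttr_l2.
#' @export
ttrOnlyFeatures <- function(ts, dt = 1) {
  idx <- trajIndex(ts)
  W <- trajMatrix(ts)
  sel <- which(idx$site == "TTR")
  if (!length(sel)) stop("TTR trajectories missing")
  out <- data.frame(subject = idx$subject[sel], group = idx$group[sel],
                    repetition = idx$repetition[sel],
                    ttr_l2 = vapply(sel, function(j)
                      simpsonL2(W[, j], numeric(nrow(W)), dt = dt), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Full subject-clustering report
#'
#' Runs the clustering chain on a subject distance matrix: hierarchical tree,
#' C-index selection of k (unless `k` is fixed), cluster x group contingency,
#' Fisher exact test and allocation scoring.
#'
#' @param D symmetric subject distance matrix with a `groups` attribute (as
#'   returned by [subjectDistanceMatrix()]), or pass `groups` explicitly.
#' @param groups group label per subject.
#' @param linkage "ward" or "complete".
#' @param k_range candidate k values for C-index selection.
#' @param k fixed number of clusters (skips selection).
#' @return a [ClusterResult-class].
#' @export
clusterReport <- function(D, groups = attr(D, "groups"),
                          linkage = c("ward", "complete"), k_range = 2:6,
                          k = NULL) {
  linkage <- match.arg(linkage)
  if (is.null(groups)) stop("group labels are required")
  tree <- clusterSubjects(D, linkage)
  if (is.null(k)) {
    ks <- selectK(D, k_range, linkage)
    curve <- attr(ks, "cindex")
    k <- as.integer(ks)
  } else {
    k <- as.integer(k)
    curve <- stats::setNames(as.numeric(cIndex(D, stats::cutree(tree, k))), k)
  }
  labels <- stats::cutree(tree, k)
  cont <- table(cluster = labels, group = groups)
  fp <- as.numeric(fisherExactRxC(cont))
  alloc <- allocationAccuracy(labels, groups)
  new("ClusterResult", dist = unname(D), linkage = linkage, tree = tree,
      k = k, labels = as.integer(labels), cindex_curve = curve,
      contingency = cont, fisher_p = fp, allocation = alloc)
}
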