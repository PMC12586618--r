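# Penalized function-on-scalar regression of site trajectories on group with
# a random time-varying subject effect:
#
#   y_ij(t) = beta0(t) + x_i * beta1(t) + b_i(t) + eps_ij(t)
#
# x_i = 1 for AWS, 0 for the reference group, so beta1(t) is the group mean
# difference curve (difference coding of the two-level ordinal factor: its
# test is a test for a difference in the mean course). Curves are expanded in
# P-splines (B-splines with difference penalties); subject curves use a
# factor-smooth (ridge-penalized) basis; smoothing parameters by REML on the
# mixed-model representation. Fitting is done through mgcv::gam.

#' FosrSpec: settings of the function-on-scalar regression
#'
#' @slot n_basis basis dimension for the fixed curves; NA = automatic
#'   (min(25, floor(T*/4)), floored at spline_order + 2).
#' @slot spline_order B-spline order (4 = cubic).
#' @slot penalty_order difference-penalty order.
#' @slot method smoothing selection, "REML" or "GCV" (mgcv "GCV.Cp").
#' @slot reference reference group level (x = 0).
#' @slot n_basis_subject basis dimension of the subject factor-smooths.
#' @slot subject_effect include the random time-varying subject effect.
#' @slot sp optional fixed smoothing parameters (bypasses selection; sp = 0
#'   gives the unpenalized limit).
#' @export
setClass("FosrSpec",
  representation(n_basis = "integer", spline_order = "integer",
                 penalty_order = "integer", method = "character",
                 reference = "character", n_basis_subject = "integer",
                 subject_effect = "logical", sp = "ANY")
)

setValidity("FosrSpec", function(object) {
  msg <- NULL
  if (!is.na(object@n_basis) && object@n_basis < object@spline_order + 2L)
    msg <- c(msg, "n_basis must be >= spline_order + 2")
  if (!is.na(object@n_basis) && object@penalty_order >= object@n_basis)
    msg <- c(msg, "penalty_order must be < n_basis")
  if (!object@method %in% c("REML", "GCV"))
    msg <- c(msg, "method must be 'REML' or 'GCV'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FosrSpec
#'
#' @param n_basis fixed-curve basis dimension (NA = automatic).
#' @param spline_order B-spline order (default cubic).
#' @param penalty_order difference-penalty order (default 2).
#' @param method smoothing-parameter selection criterion.
#' @param reference reference group (default "FS").
#' @param n_basis_subject subject-curve basis dimension.
#' @param subject_effect include random subject curves (default TRUE).
#' @param sp optional fixed smoothing parameters.
#' @return a [FosrSpec-class].
#' @export
fosrSpec <- function(n_basis = NA_integer_, spline_order = 4L,
                     penalty_order = 2L, method = "REML", reference = "FS",
                     n_basis_subject = 8L, subject_effect = TRUE, sp = NULL) {
  new("FosrSpec", n_basis = as.integer(n_basis),
      spline_order = as.integer(spline_order),
      penalty_order = as.integer(penalty_order), method = method,
      reference = reference, n_basis_subject = as.integer(n_basis_subject),
      subject_effect = subject_effect, sp = sp)
}

setMethod("show", "FosrSpec", function(object) {
  cat(sprintf("FosrSpec: order-%d B-splines, %s basis fns, penalty order %d, %s, reference %s\n",
              object@spline_order,
              if (is.na(object@n_basis)) "auto" else object@n_basis,
              object@penalty_order, object@method, object@reference))
})

.fosrData <- function(ts, site, reference) {
  idx <- trajIndex(ts)
  sel <- idx$site == site
  if (!any(sel)) stop(sprintf("model error: site '%s' not in trajectory set", site))
  W <- trajMatrix(ts)[, sel, drop = FALSE]
  idx <- idx[sel, ]
  t_star <- nrow(W)
  grp <- idx$group
  if (length(unique(grp)) < 2L)
    stop("model error: both groups must be present (singular design)")
  per_group <- table(unique(idx[, c("subject", "group")])$group)
  if (any(per_group < 2L))
    stop("model error: need at least 2 subjects per group")
  data.frame(
    y = as.vector(W),
    t = rep(seq_len(t_star), times = ncol(W)),
    x = rep(as.numeric(grp != reference), each = t_star),
    subject = factor(rep(idx$subject, each = t_star)))
}

# s(t) and s(t, by = x) are deliberately two smooths of the same covariate
# (intercept and group-difference curve); mgcv's side-condition check warns
# about that pattern even though the numeric by-variable makes it identifiable.
.quietGam <- function(...) {
  withCallingHandlers(mgcv::gam(...),
    warning = function(w) {
      if (grepl("repeated 1-d smooths", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

.fosrFormula <- function(spec, nb) {
  m_fixed <- c(spec@spline_order - 2L, spec@penalty_order)
  rhs <- sprintf("s(t, bs = 'ps', k = %d, m = c(%d, %d)) + s(t, by = x, bs = 'ps', k = %d, m = c(%d, %d))",
                 nb, m_fixed[1], m_fixed[2], nb, m_fixed[1], m_fixed[2])
  if (spec@subject_effect)
    rhs <- paste0(rhs, sprintf(" + s(t, subject, bs = 'fs', k = %d, m = 1)",
                               spec@n_basis_subject))
  stats::as.formula(paste("y ~", rhs))
}

#' Fit the function-on-scalar regression for one site
#'
#' @param ts a [TrajectorySet-class].
#' @param site site label to model.
#' @param spec a [FosrSpec-class].
#' @return a [FosrFit-class].
#' @export
#' @examples
#' \donttest{
#' b <- genTrajectories(cohortDesign(c(FS = 4, AWS = 4), n_repetitions = 3,
#'                                   n_frames_mean = 40, duration_jitter_sd = 2))
#' ts <- assembleTrajectories(bundleData(b))
#' fit <- fitFosr(ts, "LA", fosrSpec())
#' }
fitFosr <- function(ts, site, spec = fosrSpec()) {
  stopifnot(is(ts, "TrajectorySet"), is(spec, "FosrSpec"))
  dat <- .fosrData(ts, site, spec@reference)
  t_star <- max(dat$t)
  nb <- if (is.na(spec@n_basis))
    max(spec@spline_order + 2L, min(25L, t_star %/% 4L)) else spec@n_basis
  form <- .fosrFormula(spec, nb)
  method <- if (spec@method == "REML") "REML" else "GCV.Cp"
  m <- if (is.null(spec@sp)) .quietGam(form, data = dat, method = method)
       else .quietGam(form, data = dat, sp = spec@sp, method = method)

  sm <- summary(m)
  st <- sm$s.table
  grp_row <- grep(":x$", rownames(st))
  edf <- st[, "edf"]; names(edf) <- rownames(st)
  tgrid <- data.frame(t = seq_len(t_star), x = 1,
                      subject = factor(levels(dat$subject)[1],
                                       levels = levels(dat$subject)))
  excl <- if (spec@subject_effect) "s(t,subject)" else NULL
  trm <- stats::predict(m, newdata = tgrid, type = "terms", exclude = excl)
  cn <- colnames(trm)
  beta1 <- as.numeric(trm[, grep(":x$", cn)])
  beta0 <- as.numeric(attr(trm, "constant") +
                      trm[, setdiff(grep("^s\\(t\\)", cn), grep(":x$", cn))])
  new("FosrFit", site = site, model = m, beta0 = beta0, beta1 = beta1,
      edf = edf, p_group = unname(st[grp_row, "p-value"]),
      reference = spec@reference, t_star = as.integer(t_star))
}

#' Intercept and group-difference curves of a fit
#' @param fit a `FosrFit`
#' @return data.frame with frame, beta0, beta1.
#' @export
fosrCurves <- function(fit) {
  data.frame(frame = seq_len(fit@t_star), beta0 = fit@beta0, beta1 = fit@beta1)
}

#' Test the group effect of a fitted model
#'
#' `"wald"` reports the approximate F-test of `beta1 == 0` using the term's
#' effective degrees of freedom. `"permutation"` refits the model under
#' subject-level permutations of the group labels, holding the smoothing
#' parameters at their fitted values, and reports
#' `p = (1 + #\{perm stat >= observed\}) / (1 + n_perm)` — the calibrated
#' primary inference.
#'
#' @param fit a [FosrFit-class].
#' @param method "wald" or "permutation".
#' @param n_perm number of permutations (>= 19).
#' @param seed RNG seed for the permutations.
#' @return list with `edf`, `statistic` and `p`.
#' @export
testGroupEffect <- function(fit, method = c("wald", "permutation"),
                            n_perm = 199L, seed = 1L) {
  method <- match.arg(method)
  m <- fit@model
  st <- summary(m)$s.table
  grp_row <- grep(":x$", rownames(st))
  obs <- unname(st[grp_row, "F"])
  edf <- unname(st[grp_row, "edf"])
  if (method == "wald")
    return(list(edf = edf, statistic = obs, p = unname(st[grp_row, "p-value"])))

  if (n_perm < 19L) stop("permutation test needs n_perm >= 19")
  dat <- m$model
  subj <- levels(dat$subject)
  x_subj <- vapply(subj, function(s) dat$x[dat$subject == s][1], numeric(1))
  form <- stats::formula(m)
  sp <- m$sp
  stat_one <- function(xs) {
    d <- dat
    d$x <- xs[as.character(d$subject)]
    mp <- .quietGam(form, data = d, sp = sp, method = "REML")
    stp <- summary(mp)$s.table
    unname(stp[grep(":x$", rownames(stp)), "F"])
  }
  perm <- .withSeed(seed, vapply(seq_len(n_perm), function(i) {
    xs <- x_subj
    names(xs) <- sample(names(x_subj))
    stat_one(xs)
  }, numeric(1)))
  list(edf = edf, statistic = obs,
       p = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Predicted movement curves at subject or group level
#'
#' Subject level: `beta0 + x_i beta1 + b_i`; group level: `beta0` for the
#' reference group and `beta0 + beta1` for the other.
#'
#' @param fit a [FosrFit-class].
#' @param level "subject" or "group".
#' @return tidy data.frame: site, level, unit, frame, value.
#' @export
predictCurves <- function(fit, level = c("subject", "group")) {
  level <- match.arg(level)
  m <- fit@model
  t_star <- fit@t_star
  other <- if (fit@reference == "FS") "AWS" else "FS"
  if (level == "group") {
    out <- rbind(
      data.frame(site = fit@site, level = "group", unit = fit@reference,
                 frame = seq_len(t_star), value = fit@beta0),
      data.frame(site = fit@site, level = "group", unit = other,
                 frame = seq_len(t_star), value = fit@beta0 + fit@beta1))
    return(out)
  }
  dat <- m$model
  subj <- levels(dat$subject)
  has_fs <- "s(t,subject)" %in% vapply(m$smooth, function(s) s$label, character(1))
  out <- lapply(subj, function(s) {
    xi <- dat$x[dat$subject == s][1]
    nd <- data.frame(t = seq_len(t_star), x = xi,
                     subject = factor(s, levels = subj))
    pr <- as.numeric(stats::predict(m, newdata = nd))
    data.frame(site = fit@site, level = "subject", unit = s,
               frame = seq_len(t_star), value = pr)
  })
  do.call(rbind, out)
}
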