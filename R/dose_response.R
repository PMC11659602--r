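#' Activity plate
#'
#' Normalized enzyme-activity measurements on a grid of inhibitor
#' concentrations by quench times. Activities are fractions of the
#' DMSO-control activity (control = 1); mild overshoot from noise is
#' tolerated but values must lie in [-0.2, 1.5].
#'
#' @param inhibitor_concs final inhibitor concentrations, uM.
#' @param quench_times quench times, min (strictly increasing).
#' @param activity numeric matrix, `length(inhibitor_concs)` rows by
#'   `length(quench_times)` columns.
#' @param replicate replicate identifier.
#' @return an object of class `activity_plate`.
#' @export
activity_plate <- function(inhibitor_concs, quench_times, activity,
                           replicate = "r1") {
  activity <- as.matrix(activity)
  stopifnot(is.numeric(inhibitor_concs), is.numeric(quench_times),
            all(is.finite(activity)))
  if (any(inhibitor_concs < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(quench_times, strictly = TRUE))
    stop("quench_times must be strictly increasing")
  if (nrow(activity) != length(inhibitor_concs) ||
      ncol(activity) != length(quench_times))
    stop("activity matrix must be |concs| x |times|")
  if (any(activity < -0.2) || any(activity > 1.5))
    stop("normalized activities outside the tolerated [-0.2, 1.5] range")
  structure(list(inhibitor_concs = inhibitor_concs,
                 quench_times = quench_times,
                 activity = activity, replicate = replicate),
            class = "activity_plate")
}

# residuals of the 4PL curve at parameter vector theta
# theta = (top, bottom, log ic50, log hill); `fix` pins top=1, bottom=0
.fourpl_pred <- function(conc, top, bottom, ic50, hill) {
  frac <- ifelse(conc == 0, 0, (conc / ic50)^hill)
  bottom + (top - bottom) / (1 + frac)
}

#' Four-parameter logistic (4PL) dose-response fit
#'
#' Least-squares fit of `y = bottom + (top - bottom)/(1 + (x/ic50)^hill)`
#' to activity fractions, by Levenberg-Marquardt with a deterministic
#' multistart over the tested concentration range and positivity of
#' `ic50` and `hill` enforced through log-parameterization. A curve whose
#' fitted IC50 exceeds the highest tested concentration is flagged
#' `incomplete` (reported as "> cmax"), mirroring how weak inhibitors
#' with incomplete inhibition curves are tabulated.
#'
#' @param concs inhibitor concentrations, uM (>= 4 distinct values).
#' @param activities normalized activity fractions, same length.
#' @param fix_limits if `TRUE`, pin `top = 1` and `bottom = 0`
#'   (control-normalized data); default leaves both free, started near
#'   1 and 0.
#' @param min_amplitude smallest fitted `top - bottom` accepted as a
#'   real dose response; flatter curves (a weak inhibitor leaving
#'   activity near 1 everywhere) are flagged `incomplete`.
#' @return an object of class `fourpl_fit` with fields `ic50`, `hill`,
#'   `top`, `bottom`, `rss`, `converged`, `incomplete`, `cmax`.
#' @export
fit_four_pl <- function(concs, activities, fix_limits = FALSE,
                        min_amplitude = 0.2) {
  stopifnot(is.numeric(concs), is.numeric(activities),
            length(concs) == length(activities))
  if (!all(is.finite(activities))) stop("activities must be finite")
  if (length(unique(concs)) < 4L) stop("need >= 4 distinct concentrations")
  if (diff(range(activities)) < 1e-10)
    stop("degenerate data: all activities identical")
  cmax <- max(concs)
  pos <- concs[concs > 0]
  resid_fn <- function(theta) {
    if (fix_limits) {
      top <- 1; bottom <- 0
      ic50 <- exp(theta[1L]); hill <- exp(theta[2L])
    } else {
      top <- theta[1L]; bottom <- theta[2L]
      ic50 <- exp(theta[3L]); hill <- exp(theta[4L])
    }
    activities - .fourpl_pred(concs, top, bottom, ic50, hill)
  }
  starts_ic50 <- exp(stats::quantile(log(pos), c(0.1, 0.35, 0.5, 0.65, 0.9),
                                     names = FALSE))
  best <- NULL
  for (s in starts_ic50) {
    theta0 <- if (fix_limits) c(log(s), 0) else c(1, 0, log(s), 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, rss = NA_real_,
                          converged = FALSE, incomplete = TRUE, cmax = cmax),
                     class = "fourpl_fit"))
  }
  th <- best$fit$par
  if (fix_limits) {
    top <- 1; bottom <- 0; ic50 <- exp(th[1L]); hill <- exp(th[2L])
  } else {
    top <- th[1L]; bottom <- th[2L]; ic50 <- exp(th[3L]); hill <- exp(th[4L])
  }
  converged <- best$fit$info %in% 1:3
  incomplete <- !converged || ic50 > cmax || (top - bottom) < min_amplitude
  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                 rss = best$rss, converged = converged,
                 incomplete = incomplete, cmax = cmax),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$incomplete) {
    cat(sprintf("4PL fit: incomplete curve, IC50 > %.3g uM\n", x$cmax))
  } else {
    cat(sprintf("4PL fit: IC50 = %.4g uM, hill = %.3g, top = %.3g, bottom = %.3g\n",
                x$ic50, x$hill, x$top, x$bottom))
  }
  invisible(x)
}

#' Apparent IC50 at each quench time of an activity plate
#'
#' Fits one 4PL curve per quench-time column. Points whose fit did not
#' converge or whose curve is incomplete (IC50 beyond the tested range)
#' are marked unusable and excluded from downstream Krippendorff
#' fitting. A warning is emitted when a fitted IC50 approaches the
#' enzyme concentration (IC50 < 5 [E]), where the tight-binding
#' assumption `[I] >> [E]` of the model starts to fail.
#'
#' @param plate an [activity_plate].
#' @param fix_limits passed to [fit_four_pl].
#' @param enzyme_conc_uM assay enzyme concentration, uM, used only for
#'   the tight-binding warning (default 0.05 uM = 50 nM).
#' @return an `ic50_series`: data frame with columns `t`, `ic50`,
#'   `usable`; attribute `fits` holds the per-time [fit_four_pl] objects
#'   and attribute `unfittable` is `TRUE` when fewer than two points are
#'   usable.
#' @export
ic50_timecourse <- function(plate, fix_limits = FALSE, enzyme_conc_uM = 0.05) {
  stopifnot(inherits(plate, "activity_plate"))
  times <- plate$quench_times
  fits <- vector("list", length(times))
  ic50 <- rep(NA_real_, length(times))
  usable <- rep(FALSE, length(times))
  for (j in seq_along(times)) {
    f <- tryCatch(fit_four_pl(plate$inhibitor_concs, plate$activity[, j],
                              fix_limits = fix_limits),
                  error = function(e) NULL)
    fits[[j]] <- f
    if (!is.null(f) && f$converged && !f$incomplete) {
      ic50[j] <- f$ic50
      usable[j] <- TRUE
    }
  }
  if (any(ic50[usable] < 5 * enzyme_conc_uM))
    warning("fitted IC50 within 5x enzyme concentration: ",
            "tight-binding assumption ([I] >> [E]) questionable")
  out <- data.frame(t = times, ic50 = ic50, usable = usable)
  attr(out, "fits") <- fits
  attr(out, "unfittable") <- sum(usable) < 2L
  class(out) <- c("ic50_series", "data.frame")
  out
}

#' Fit the Krippendorff IC50(t) model to an IC50 series
#'
#' Least-squares minimization of
#' `sum_j (IC50_j - IC50_model(t_j; K_I, k_inact))^2` over the usable
#' points of the series, with both parameters kept positive through
#' log-parameterization and a deterministic multistart grid derived from
#' the data. Standard errors come from the Jacobian at the optimum.
#'
#' @param series an `ic50_series` from [ic50_timecourse], or a data
#'   frame with columns `t`, `ic50` (and optionally `usable`).
#' @param context a [substrate_context].
#' @return a `covalent_fit`: list with `params` ([covalent_params]),
#'   `se` (named standard errors), `rss`, `n_points`, `converged`,
#'   `at_bound`.
#' @export
fit_krippendorff <- function(series, context) {
  stopifnot(is.data.frame(series), inherits(context, "substrate_context"))
  if (isTRUE(attr(series, "unfittable")))
    stop("series is unfittable: fewer than 2 usable IC50 points")
  use <- if ("usable" %in% names(series)) series$usable else
    rep(TRUE, nrow(series))
  t_j <- series$t[use]
  y_j <- series$ic50[use]
  if (length(t_j) < 2L) stop("need >= 2 usable IC50 points")
  comp <- 1 + context$S / context$K_M

  model_ic50 <- function(K_I, k) {
    m <- krippendorff_model(covalent_params(K_I, k), context)
    krippendorff_ic50(t_j, m)
  }
  obj <- function(theta) {
    p <- exp(theta)
    sum((y_j - model_ic50(p[1L], p[2L]))^2)
  }
  # data-driven starts: at t -> 0 the model tends to K_I(1+S/K_M);
  # at late t, IC50 ~ A u*/(k t) with u* = 1.5936 the root of g
  KI_est <- max(y_j) / comp
  k_est <- max(1e-3, comp * KI_est * 1.5936 / (min(y_j) * max(t_j)))
  grid <- expand.grid(KI = KI_est * c(0.5, 1, 2),
                      k = k_est * c(0.3, 1, 3))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    op <- tryCatch(stats::optim(log(c(grid$KI[i], grid$k[i])), obj,
                                method = "Nelder-Mead",
                                control = list(maxit = 500, reltol = 1e-14)),
                   error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value - 1e-16) best <- op
  }
  if (is.null(best)) stop("Krippendorff fit failed from every start")
  # polish with BFGS
  op <- tryCatch(stats::optim(best$par, obj, method = "BFGS",
                              control = list(maxit = 500, reltol = 1e-15)),
                 error = function(e) best)
  if (op$value > best$value) op <- best
  p <- exp(op$par)
  at_bound <- any(abs(op$par) > 25)

  # standard errors from the Jacobian on the natural scale
  J <- matrix(NA_real_, length(t_j), 2L)
  h <- p * 1e-6
  for (q in 1:2) {
    pp <- p; pm <- p
    pp[q] <- pp[q] + h[q]; pm[q] <- pm[q] - h[q]
    J[, q] <- (model_ic50(pp[1L], pp[2L]) - model_ic50(pm[1L], pm[2L])) /
      (2 * h[q])
  }
  rss <- op$value
  dof <- max(length(t_j) - 2L, 1L)
  se <- tryCatch({
    covm <- rss / dof * solve(crossprod(J))
    sqrt(diag(covm))
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(params = covalent_params(p[1L], p[2L]),
                 se = c(K_I = se[1L], k_inact = se[2L]),
                 rss = rss, n_points = length(t_j),
                 converged = op$convergence == 0 || !is.null(best),
                 at_bound = at_bound),
            class = "covalent_fit")
}

#' @export
print.covalent_fit <- function(x, ...) {
  cat(sprintf("Krippendorff fit (%d points): K_I = %.4g +/- %.2g uM, k_inact = %.4g +/- %.2g min^-1\n",
              x$n_points, x$params$K_I, x$se[["K_I"]],
              x$params$k_inact, x$se[["k_inact"]]))
  cat(sprintf("  k_inact/K_I = %.4g M^-1 min^-1; RSS = %.3g%s\n",
              kinact_over_KI(x$params), x$rss,
              if (x$at_bound) " [at parameter bound]" else ""))
  invisible(x)
}
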