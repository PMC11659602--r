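#' Two-state SPR reaction-model parameters
#'
#' Rate constants of the scheme `A + B <-> AB -> AB*` used to describe
#' covalent analyte binding in surface plasmon resonance: `k_plus1`
#' (association, M^-1 s^-1), `k_minus1` (dissociation, s^-1), `k_plus2`
#' (the irreversible chemical step, s^-1) and `k_minus2` (the reverse of
#' the second step, fixed at zero for covalent binders). The reversible
#' affinity is `K_i = k_minus1/k_plus1` and the inactivation rate is
#' `k_inact = k_plus2` (reported per minute).
#'
#' @param k_plus1 association rate, M^-1 s^-1; >= 0.
#' @param k_minus1 dissociation rate, s^-1; >= 0.
#' @param k_plus2 covalent inactivation rate, s^-1; >= 0.
#' @param k_minus2 reverse second step, s^-1; default 0 (irreversible).
#' @param Rmax surface capacity, response units; > 0.
#' @return an object of class `two_state_params`.
#' @export
two_state_params <- function(k_plus1, k_minus1, k_plus2, k_minus2 = 0,
                             Rmax = 100) {
  vals <- c(k_plus1, k_minus1, k_plus2, k_minus2)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals < 0)) stop("rate constants must be non-negative")
  if (!is.numeric(Rmax) || Rmax <= 0) stop("Rmax must be positive")
  structure(list(k_plus1 = k_plus1, k_minus1 = k_minus1,
                 k_plus2 = k_plus2, k_minus2 = k_minus2, Rmax = Rmax),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf("Two-state SPR parameters: k+1 = %.3g M^-1 s^-1, k-1 = %.3g s^-1, k+2 = %.3g s^-1, k-2 = %.3g s^-1, Rmax = %.3g RU\n",
              x$k_plus1, x$k_minus1, x$k_plus2, x$k_minus2, x$Rmax))
  if (x$k_plus1 > 0)
    cat(sprintf("  K_i = %.4g uM, k_inact = %.4g min^-1\n",
                M_to_uM(x$k_minus1 / x$k_plus1),
                per_s_to_per_min(x$k_plus2)))
  invisible(x)
}

#' Single-cycle injection scheme
#'
#' Ordered analyte-injection segments (concentration, start, stop in
#' seconds) followed by a final dissociation phase, as in single-cycle
#' kinetics where ascending concentrations are injected without surface
#' regeneration.
#'
#' @param concs analyte concentrations, M, one per injection.
#' @param contact_s contact time per injection, s.
#' @param dissoc_s dissociation time between injections, s.
#' @param final_dissoc_s final dissociation after the last injection, s.
#' @param segments alternatively, a data frame with columns `conc_M`,
#'   `start_s`, `stop_s` (overrides the regular scheme).
#' @return an object of class `injection_scheme` with a `segments` data
#'   frame and `final_dissociation` duration.
#' @export
injection_scheme <- function(concs = NULL, contact_s = 120, dissoc_s = 300,
                             final_dissoc_s = 1800, segments = NULL) {
  if (is.null(segments)) {
    stopifnot(is.numeric(concs), length(concs) >= 1L, all(concs >= 0))
    start <- (seq_along(concs) - 1L) * (contact_s + dissoc_s)
    segments <- data.frame(conc_M = concs, start_s = start,
                           stop_s = start + contact_s)
  }
  stopifnot(all(c("conc_M", "start_s", "stop_s") %in% names(segments)))
  if (any(segments$conc_M < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(segments$start_s, strictly = TRUE) ||
      any(segments$stop_s <= segments$start_s) ||
      any(utils::head(segments$stop_s, -1) > utils::tail(segments$start_s, -1)))
    stop("injection segments must be ordered and non-overlapping")
  structure(list(segments = segments, final_dissociation = final_dissoc_s),
            class = "injection_scheme")
}

#' Default single-cycle scheme around a target affinity
#'
#' Five ascending concentrations spanning 0.1-10 times `K_i_M`, 120 s
#' contact, 300 s dissociation, 1800 s final dissociation — chosen so
#' that the reversible affinity and the covalent rate are jointly
#' identifiable from one sensorgram.
#'
#' @param K_i_M anticipated reversible affinity, M.
#' @return an [injection_scheme].
#' @export
default_scheme <- function(K_i_M) {
  injection_scheme(concs = K_i_M * c(0.1, 0.3, 1, 3, 10))
}

# time boundaries and per-interval concentrations of a scheme
.scheme_intervals <- function(scheme) {
  seg <- scheme$segments
  t0 <- 0
  bounds <- c()
  concs <- c()
  for (i in seq_len(nrow(seg))) {
    if (seg$start_s[i] > t0) {
      bounds <- c(bounds, seg$start_s[i]); concs <- c(concs, 0)
    }
    bounds <- c(bounds, seg$stop_s[i]); concs <- c(concs, seg$conc_M[i])
    t0 <- seg$stop_s[i]
  }
  bounds <- c(bounds, t0 + scheme$final_dissociation)
  concs <- c(concs, 0)
  data.frame(start = c(0, utils::head(bounds, -1)), stop = bounds,
             conc = concs)
}

# Exact solution of the two-state linear system on one constant-C
# segment. State x = (AB, AB*); with k-2 = 0:
#   AB'  = k1 C (Rmax - AB - AB*) - (k-1 + k2) AB
#   AB*' = k2 AB
.segment_solution <- function(x0, conc, p, tau) {
  k1C <- p$k_plus1 * conc
  a <- k1C + p$k_minus1 + p$k_plus2
  if (length(tau) == 0L) return(matrix(numeric(0), 0, 2))
  if (k1C == 0) {
    # pure decay: AB falls at (k-1 + k2); a fraction k2/(k-1+k2) converts
    d <- p$k_minus1 + p$k_plus2
    AB <- x0[1L] * exp(-d * tau)
    ABs <- if (d == 0) rep(x0[2L], length(tau)) else
      x0[2L] + x0[1L] * p$k_plus2 / d * (1 - exp(-d * tau))
    return(cbind(AB, ABs))
  }
  if (p$k_plus2 == 0) {
    # Langmuir limit: AB* frozen, AB relaxes to its equilibrium
    ABs <- rep(x0[2L], length(tau))
    ABeq <- k1C * (p$Rmax - x0[2L]) / (k1C + p$k_minus1)
    AB <- ABeq + (x0[1L] - ABeq) * exp(-(k1C + p$k_minus1) * tau)
    return(cbind(AB, ABs))
  }
  # general case: x' = M x + b, M = [[-a, -k1C], [k2, 0]], b = (k1C Rmax, 0)
  disc <- a^2 - 4 * k1C * p$k_plus2
  if (disc < 1e-12 * a^2) return(NULL)  # near-defective; caller falls back
  sq <- sqrt(disc)
  lam <- c(-(a - sq) / 2, -(a + sq) / 2)
  # particular solution xp = -M^-1 b
  detM <- k1C * p$k_plus2
  xp <- c(0, p$Rmax)  # solves M xp + b = 0: -a*0 - k1C*Rmax + k1C*Rmax = 0; k2*0 = 0
  # eigenvectors of M for lambda: (lambda, k2) direction from row 2: k2*v1 = lambda*v2
  v1 <- c(lam[1L], p$k_plus2)
  v2 <- c(lam[2L], p$k_plus2)
  V <- cbind(v1, v2)
  cvec <- solve(V, x0 - xp)
  AB <- xp[1L] + cvec[1L] * v1[1L] * exp(lam[1L] * tau) +
    cvec[2L] * v2[1L] * exp(lam[2L] * tau)
  ABs <- xp[2L] + cvec[1L] * v1[2L] * exp(lam[1L] * tau) +
    cvec[2L] * v2[2L] * exp(lam[2L] * tau)
  cbind(AB, ABs)
}

#' Simulate a two-state SPR sensorgram
#'
#' Integrates the two-state reaction model
#' `d[AB]/dt = k+1 C(t) (Rmax - AB - AB*) - k-1 AB - k+2 AB + k-2 AB*`,
#' `d[AB*]/dt = k+2 AB - k-2 AB*`, with piecewise-constant analyte
#' concentration from the injection scheme; the response is `AB + AB*`.
#' Within each constant-concentration segment the system is linear and
#' is solved in closed form (eigen-decomposition), restarting at segment
#' boundaries so injection edges are sharp; `k_minus2 > 0` or
#' near-degenerate eigenvalues fall back to a stiff-capable numerical
#' integrator.
#'
#' @param params a [two_state_params].
#' @param scheme an [injection_scheme].
#' @param times output times, s (within the scheme's span).
#' @return an object of class `sensorgram`: list with `times`,
#'   `response`, `scheme`, and the bound/converted components `AB`,
#'   `ABstar`.
#' @export
simulate_two_state <- function(params, scheme, times = NULL) {
  stopifnot(inherits(params, "two_state_params"),
            inherits(scheme, "injection_scheme"))
  iv <- .scheme_intervals(scheme)
  if (is.null(times)) times <- seq(0, max(iv$stop), by = 1)
  stopifnot(is.numeric(times), !is.unsorted(times))
  if (min(times) < 0 || max(times) > max(iv$stop) + 1e-9)
    stop("output times outside the scheme span")
  x <- c(0, 0)
  AB <- numeric(length(times)); ABs <- numeric(length(times))
  t_prev <- 0
  for (i in seq_len(nrow(iv))) {
    sel <- which(times >= iv$start[i] - 1e-12 & times <= iv$stop[i] + 1e-12)
    tau_out <- times[sel] - iv$start[i]
    sol <- if (params$k_minus2 == 0)
      .segment_solution(x, iv$conc[i], params, c(tau_out, iv$stop[i] - iv$start[i]))
    else NULL
    if (is.null(sol)) {
      deriv <- function(t, y, parms) {
        C <- iv$conc[i]
        dAB <- params$k_plus1 * C * (params$Rmax - y[1] - y[2]) -
          params$k_minus1 * y[1] - params$k_plus2 * y[1] +
          params$k_minus2 * y[2]
        dABs <- params$k_plus2 * y[1] - params$k_minus2 * y[2]
        list(c(dAB, dABs))
      }
      tt <- sort(unique(c(0, tau_out, iv$stop[i] - iv$start[i])))
      out <- deSolve::lsoda(y = x, times = tt, func = deriv, parms = NULL,
                            rtol = 1e-10, atol = 1e-12)
      if (attr(out, "istate")[1L] < 0)
        stop("stiff integration failed; params: ",
             paste(unlist(params), collapse = ", "))
      idx <- match(round(tau_out, 12), round(out[, 1], 12))
      AB[sel] <- out[idx, 2]; ABs[sel] <- out[idx, 3]
      x <- as.numeric(out[nrow(out), 2:3])
    } else {
      n_out <- length(tau_out)
      if (n_out > 0) { AB[sel] <- sol[seq_len(n_out), 1L]
        ABs[sel] <- sol[seq_len(n_out), 2L] }
      x <- as.numeric(sol[n_out + 1L, ])
    }
    t_prev <- iv$stop[i]
  }
  structure(list(times = times, response = AB + ABs, scheme = scheme,
                 AB = AB, ABstar = ABs),
            class = "sensorgram")
}

#' Fit the two-state covalent model to a sensorgram
#'
#' Least squares over `(k+1, k-1, k+2, Rmax)` with the reverse second
#' step `k-2` fixed at zero, positivity enforced by log-parameterization
#' and a deterministic multistart. Standard errors come from the
#' Jacobian at the optimum.
#'
#' @param gram a [sensorgram] (its embedded scheme drives the model).
#' @param starts optional matrix of starting values (rows of
#'   `k_plus1, k_minus1, k_plus2, Rmax`); a deterministic default grid
#'   is used otherwise.
#' @return a `two_state_fit`: list with `params` ([two_state_params]),
#'   `se`, `rss`, `converged`.
#' @export
fit_two_state <- function(gram, starts = NULL) {
  stopifnot(inherits(gram, "sensorgram"))
  y <- gram$response
  scheme <- gram$scheme
  Rmax0 <- max(y) * 1.2
  cmid <- stats::median(scheme$segments$conc_M)
  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(
      k_plus1 = c(1e4, 1e5, 1e6),
      k_minus1 = cmid * c(1e4, 1e5),
      k_plus2 = c(1e-4, 3e-3),
      Rmax = Rmax0))
  }
  resid_fn <- function(theta) {
    p <- two_state_params(exp(theta[1L]), exp(theta[2L]), exp(theta[3L]),
                          0, exp(theta[4L]))
    sim <- simulate_two_state(p, scheme, gram$times)
    y - sim$response
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(starts[i, ]), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-10))
      best <- list(fit = fit, rss = rss)
    if (best$rss < 1e-16 * sum(y^2)) break
  }
  if (is.null(best)) stop("two-state fit failed from every start")
  th <- unname(best$fit$par)
  p <- two_state_params(exp(th[1L]), exp(th[2L]), exp(th[3L]), 0, exp(th[4L]))
  if (max(y) > 1.1 * p$Rmax)
    warning("responses exceed fitted Rmax by > 10%")
  # SEs on the log scale from the LM Jacobian, delta-method to natural scale
  se <- tryCatch({
    J <- best$fit$hessian  # J'J approximation from nls.lm
    dof <- max(length(y) - 4L, 1L)
    covm <- best$rss / dof * solve(J)
    sqrt(diag(covm)) * exp(th)
  }, error = function(e) rep(NA_real_, 4L))
  names(se) <- c("k_plus1", "k_minus1", "k_plus2", "Rmax")
  structure(list(params = p, se = se, rss = best$rss,
                 converged = best$fit$info %in% 1:3),
            class = "two_state_fit")
}

#' Covalent constants from two-state SPR parameters
#'
#' `K_i = k-1/k+1` (reversible affinity, M), `k_inact = k+2` converted
#' to min^-1, and the second-order efficiency `k_inact/K_i` in
#' M^-1 min^-1.
#'
#' @param params a [two_state_params] with `k_plus1 > 0`.
#' @return list with `K_i_M`, `K_i_uM`, `k_inact_per_min`,
#'   `ratio_M_min`.
#' @export
derive_covalent_constants <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  if (params$k_plus1 <= 0) stop("k_plus1 must be positive")
  K_i_M <- params$k_minus1 / params$k_plus1
  k_inact <- per_s_to_per_min(params$k_plus2)
  list(K_i_M = K_i_M, K_i_uM = M_to_uM(K_i_M), k_inact_per_min = k_inact,
       ratio_M_min = kinact_over_KI(M_to_uM(K_i_M), k_inact))
}

#' Steady-state affinity fit
#'
#' Fits the single-site binding isotherm `Req = Rmax C/(K_D + C)` to
#' plateau responses, for reversible analytes. When the responses show
#' no curvature over the tested range the affinity is not determined
#' and the result is flagged as a lower bound ("> cmax").
#'
#' @param concs analyte concentrations, M (>= 3 values).
#' @param plateau_responses steady-state responses, RU.
#' @return a `steady_state_fit`: list with `K_D_M`, `Rmax`,
#'   `lower_bound` flag and `cmax_M`.
#' @export
fit_steady_state <- function(concs, plateau_responses) {
  stopifnot(is.numeric(concs), is.numeric(plateau_responses),
            length(concs) == length(plateau_responses))
  if (length(concs) < 3L) stop("need >= 3 concentrations")
  cmax <- max(concs)
  resid_fn <- function(theta) {
    plateau_responses - exp(theta[2L]) * concs / (exp(theta[1L]) + concs)
  }
  best <- NULL
  for (kd0 in cmax * c(0.01, 0.1, 1, 10)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(c(kd0, max(plateau_responses) * 1.5)),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("steady-state fit failed")
  K_D <- exp(best$fit$par[1L])
  Rmax <- exp(best$fit$par[2L])
  structure(list(K_D_M = K_D, Rmax = Rmax, rss = best$rss,
                 lower_bound = K_D > cmax, cmax_M = cmax),
            class = "steady_state_fit")
}
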