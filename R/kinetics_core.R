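#' Covalent inhibition parameters
#'
#' Container for the two parameters that characterise a covalent
#' (irreversible) inhibitor: `K_I`, the inhibitor concentration giving
#' half-maximal inactivation rate (reversible-binding affinity, uM), and
#' `k_inact`, the maximal first-order inactivation rate (min^-1). Their
#' ratio `k_inact/K_I` is the second-order efficiency constant by which
#' covalent inhibitors are ranked.
#'
#' @param K_I reversible affinity, uM; must be > 0.
#' @param k_inact maximal inactivation rate, min^-1; must be >= 0.
#' @return an object of class `covalent_params`.
#' @export
covalent_params <- function(K_I, k_inact) {
  stopifnot(is.numeric(K_I), length(K_I) == 1L, is.finite(K_I),
            is.numeric(k_inact), length(k_inact) == 1L, is.finite(k_inact))
  if (K_I <= 0) stop("K_I must be positive (uM)")
  if (k_inact < 0) stop("k_inact must be non-negative (min^-1)")
  structure(list(K_I = K_I, k_inact = k_inact), class = "covalent_params")
}

#' @export
print.covalent_params <- function(x, ...) {
  cat(sprintf("Covalent inhibition parameters: K_I = %.4g uM, k_inact = %.4g min^-1\n",
              x$K_I, x$k_inact))
  cat(sprintf("  k_inact/K_I = %.4g M^-1 min^-1\n", kinact_over_KI(x)))
  invisible(x)
}

#' Substrate competition context
#'
#' Substrate concentration and Michaelis constant of the activity assay.
#' A competing substrate raises the apparent affinity of a competitive
#' covalent inhibitor by the factor `(1 + S/K_M)`.
#'
#' @param S substrate concentration, mM; >= 0.
#' @param K_M Michaelis constant, mM; > 0. 1.36 mM applies to PADI4 with
#'   BAEE, 10.8 mM to PADI3 with BAME.
#' @return an object of class `substrate_context`.
#' @export
substrate_context <- function(S = 10, K_M = 1.36) {
  stopifnot(is.numeric(S), length(S) == 1L, is.finite(S),
            is.numeric(K_M), length(K_M) == 1L, is.finite(K_M))
  if (S < 0) stop("S must be non-negative (mM)")
  if (K_M <= 0) stop("K_M must be positive (mM)")
  structure(list(S = S, K_M = K_M), class = "substrate_context")
}

#' Krippendorff time-dependent IC50 model
#'
#' Combines covalent inhibition parameters with the substrate context of
#' the assay. The model predicts the apparent IC50 after incubation time
#' `t` through the implicit relation
#' \deqn{IC_{50}(t) = K_I(1 + S/K_M)\left(\frac{2 - 2e^{-\eta k_{inact} t}}
#'   {\eta k_{inact} t} - 1\right),\quad
#'   \eta = \frac{IC_{50}(t)}{K_I(1 + S/K_M) + IC_{50}(t)}}
#'
#' @param params a [covalent_params] object.
#' @param context a [substrate_context] object.
#' @return an object of class `krippendorff_model`.
#' @export
krippendorff_model <- function(params, context) {
  stopifnot(inherits(params, "covalent_params"),
            inherits(context, "substrate_context"))
  structure(list(params = params, context = context),
            class = "krippendorff_model")
}

#' Apparent K_I under substrate competition
#'
#' @param model a [krippendorff_model].
#' @return `K_I * (1 + S/K_M)` in uM.
#' @export
apparent_KI <- function(model) {
  stopifnot(inherits(model, "krippendorff_model"))
  model$params$K_I * (1 + model$context$S / model$context$K_M)
}

#' Pseudo-first-order inactivation rate
#'
#' Observed inactivation rate at inhibitor concentration `I`:
#' `kobs = k_inact * I / (K_I (1 + S/K_M) + I)`. Saturates at `k_inact`.
#'
#' @param I inhibitor concentration(s), uM; >= 0.
#' @param model a [krippendorff_model].
#' @return rates in min^-1, same length as `I`.
#' @export
kobs_covalent <- function(I, model) {
  stopifnot(inherits(model, "krippendorff_model"), is.numeric(I))
  if (any(I < 0)) stop("inhibitor concentration must be non-negative")
  A <- apparent_KI(model)
  model$params$k_inact * I / (A + I)
}

#' Closed-form progress curve under covalent inhibition
#'
#' Product formation for the standard covalent-competition model:
#' reversible binding is instantaneous and scales the initial rate by
#' `1/(1 + I/K_I^app)`, while active enzyme decays exponentially at
#' `kobs`, giving `P(t) = (v0/kobs) (1 - exp(-kobs t))` (and `v0 t`
#' in the `kobs -> 0` limit). This is the generative model from which
#' the implicit IC50(t) relation derives.
#'
#' @param I inhibitor concentration, uM (scalar).
#' @param model a [krippendorff_model].
#' @param v0_uninhibited uninhibited initial velocity, product units per
#'   minute; >= 0.
#' @param times quench times, min; >= 0.
#' @return product amounts at `times`.
#' @export
progress_curve <- function(I, model, v0_uninhibited, times) {
  stopifnot(inherits(model, "krippendorff_model"),
            is.numeric(I), length(I) == 1L, is.numeric(times))
  if (I < 0) stop("inhibitor concentration must be non-negative")
  if (!is.numeric(v0_uninhibited) || v0_uninhibited < 0)
    stop("v0_uninhibited must be non-negative")
  if (any(times < 0)) stop("times must be non-negative")
  A <- apparent_KI(model)
  v0 <- v0_uninhibited / (1 + I / A)
  kobs <- kobs_covalent(I, model)
  if (kobs == 0) v0 * times else v0 * (-expm1(-kobs * times)) / kobs
}

# Bracketed factor of the implicit IC50(t) equation:
# g(u) = (2 - 2 exp(-u))/u - 1, with g(0) = 1; series branch avoids 0/0.
.kripp_g <- function(u) {
  small <- u < 1e-8
  out <- u
  out[small] <- 1 - u[small] / 2 + u[small]^2 / 6
  ub <- u[!small]
  out[!small] <- 2 * (-expm1(-ub)) / ub - 1
  out
}

#' Time-dependent IC50 of a covalent inhibitor
#'
#' Solves the implicit Krippendorff relation (see [krippendorff_model])
#' for the apparent IC50 after incubation time `t`. The root is bracketed
#' on `(0, K_I(1+S/K_M)]` — guaranteed by the limit laws of the
#' equation — and located by bisection followed by one Newton polish.
#' For `k_inact = 0` the inhibitor is purely reversible and the apparent
#' K_I is returned.
#'
#' @param t incubation time(s), min; > 0.
#' @param model a [krippendorff_model].
#' @return IC50 value(s), uM; strictly decreasing in `t`.
#' @export
krippendorff_ic50 <- function(t, model) {
  stopifnot(inherits(model, "krippendorff_model"), is.numeric(t))
  if (any(t <= 0)) stop("incubation time must be positive")
  A <- apparent_KI(model)
  k <- model$params$k_inact
  if (k == 0) return(rep(A, length(t)))
  # F(x) = x - A g(eta(x) k t); F(0+) = -A < 0, F(A) = A(1 - g(kt/2)) > 0
  f <- function(x) x - A * .kripp_g(x / (A + x) * k * t)
  lo <- rep(1e-12 * A, length(t))
  hi <- rep(A, length(t))
  flo <- f(lo)
  if (any(flo > 0))
    stop("no sign change in bracket; inputs: t=", paste(t, collapse = ","),
         " K_I=", model$params$K_I, " k_inact=", k)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    up <- fm > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (max(hi - lo) < 1e-15 * A) break
  }
  x <- (lo + hi) / 2
  # one Newton polish with a central-difference derivative
  h <- pmax(1e-9 * x, 1e-15 * A)
  fp <- (f(x + h) - f(x - h)) / (2 * h)
  ok <- is.finite(fp) & fp > 0
  xn <- x
  xn[ok] <- x[ok] - f(x)[ok] / fp[ok]
  ok2 <- ok & xn > 0 & xn <= A
  x[ok2] <- xn[ok2]
  x
}

#' Second-order covalent efficiency constant
#'
#' `k_inact / K_I` with `K_I` converted from uM to M, giving the
#' conventional M^-1 min^-1 scale of kinetics tables.
#'
#' @param params a [covalent_params] object, or a numeric `K_I` in uM
#'   when `k_inact` is supplied separately.
#' @param k_inact rate in min^-1 (only when `params` is numeric).
#' @return efficiency constant, M^-1 min^-1.
#' @export
kinact_over_KI <- function(params, k_inact = NULL) {
  if (is.numeric(params)) {
    stopifnot(!is.null(k_inact))
    K_I <- params
  } else {
    stopifnot(inherits(params, "covalent_params"))
    K_I <- params$K_I
    k_inact <- params$k_inact
  }
  if (any(K_I == 0)) stop("K_I must be non-zero")
  k_inact / uM_to_M(K_I)
}
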