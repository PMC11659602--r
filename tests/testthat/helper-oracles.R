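# Independent oracles used to cross-check the package implementations.
# These deliberately take different numerical routes from the code they
# verify.

# Fixed-step RK4 integration of the covalent progress-curve ODE system:
#   dE/dt = -kobs E,  dP/dt = v0 * E/E0
# (active-enzyme decay driving product formation).
ode_progress_oracle <- function(I, K_I, k_inact, S, K_M, v0, times,
                                dt = 0.001) {
  A <- K_I * (1 + S / K_M)
  kobs <- k_inact * I / (A + I)
  v0_i <- v0 / (1 + I / A)
  deriv <- function(y) c(-kobs * y[1L], v0_i * y[1L])
  t_end <- max(times)
  n <- ceiling(t_end / dt)
  y <- c(1, 0)  # E/E0, P
  tgrid <- 0
  out_t <- numeric(n + 1L); out_P <- numeric(n + 1L)
  out_t[1L] <- 0; out_P[1L] <- 0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - tgrid)
    k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tgrid <- tgrid + h
    out_t[i + 1L] <- tgrid; out_P[i + 1L] <- y[2L]
  }
  stats::approx(out_t, out_P, xout = times)$y
}

# Damped fixed-point iteration for the implicit IC50(t) relation:
#   x <- (1 - w) x + w * A * g(eta(x) k t)
fixed_point_ic50_oracle <- function(t, K_I, k_inact, S, K_M,
                                    w = 0.15, iters = 20000, tol = 1e-13) {
  A <- K_I * (1 + S / K_M)
  g <- function(u) ifelse(u < 1e-8, 1 - u / 2, (2 - 2 * exp(-u)) / u - 1)
  x <- A / 2
  for (i in seq_len(iters)) {
    xn <- (1 - w) * x + w * A * g(x / (A + x) * k_inact * t)
    if (abs(xn - x) < tol * A) { x <- xn; break }
    x <- xn
  }
  x
}

# Closed-form 1:1 Langmuir response on the intervals of a scheme
# (valid only when k_plus2 = 0): piecewise exponential relaxation.
langmuir_oracle <- function(k_on, k_off, Rmax, scheme, times) {
  iv <- covrapid:::.scheme_intervals(scheme)
  resp <- numeric(length(times))
  R0 <- 0
  for (i in seq_len(nrow(iv))) {
    C <- iv$conc[i]
    a <- k_on * C + k_off
    Req <- if (a > 0) k_on * C * Rmax / a else R0
    sel <- which(times >= iv$start[i] - 1e-12 & times <= iv$stop[i] + 1e-12)
    tau <- times[sel] - iv$start[i]
    resp[sel] <- Req + (R0 - Req) * exp(-a * tau)
    R0 <- Req + (R0 - Req) * exp(-a * (iv$stop[i] - iv$start[i]))
  }
  resp
}

# deSolve integration of the full two-state system over a scheme,
# independent of the package's closed-form segment solver.
lsoda_two_state_oracle <- function(p, scheme, times) {
  iv <- covrapid:::.scheme_intervals(scheme)
  conc_at <- stats::stepfun(iv$stop, c(iv$conc, 0), right = TRUE)
  deriv <- function(t, y, parms) {
    C <- conc_at(t)
    dAB <- p$k_plus1 * C * (p$Rmax - y[1] - y[2]) -
      (p$k_minus1 + p$k_plus2) * y[1] + p$k_minus2 * y[2]
    dABs <- p$k_plus2 * y[1] - p$k_minus2 * y[2]
    list(c(dAB, dABs))
  }
  bounds <- sort(unique(c(iv$start, iv$stop)))
  tt <- sort(unique(c(times, bounds)))
  out <- deSolve::lsoda(c(0, 0), tt, deriv, NULL, rtol = 1e-10, atol = 1e-12)
  idx <- match(times, tt)
  out[idx, 2] + out[idx, 3]
}

# Brute-force connected components of the distance-threshold graph.
components_oracle <- function(peptides, max_dist) {
  n <- length(peptides)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- covrapid:::.pep_dist(peptides[i], peptides[j]) <= max_dist
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# partition equality up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Brute-force grid search for the Krippendorff fit (1% log-spaced
# resolution around a bracketing range), vectorized over the whole grid.
grid_search_krippendorff_oracle <- function(t_j, y_j, S, K_M,
                                            KI_range, k_range) {
  KI_grid <- exp(seq(log(KI_range[1L]), log(KI_range[2L]), by = log(1.01)))
  k_grid <- exp(seq(log(k_range[1L]), log(k_range[2L]), by = log(1.01)))
  gr <- expand.grid(KI = KI_grid, k = k_grid)
  comp <- 1 + S / K_M
  rss <- numeric(nrow(gr))
  for (i in seq_len(nrow(gr))) {
    m <- krippendorff_model(covalent_params(gr$KI[i], gr$k[i]),
                            substrate_context(S, K_M))
    rss[i] <- sum((y_j - krippendorff_ic50(t_j, m))^2)
  }
  best <- which.min(rss)
  list(K_I = gr$KI[best], k_inact = gr$k[best], rss = rss[best])
}
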