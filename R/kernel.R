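#' Build the two-stage IPM iteration matrix
#'
#' Discretizes the size-structured annual projection model on `n_bins`
#' equally spaced bins over the log-size interval `[L, U]` by the midpoint
#' rule, with one extra discrete state for spring seedlings. With
#' `s(z) = logit^-1(surv_int + surv_slope z)`,
#' `g(z'|z) = Normal(z'; grow_int + grow_slope z, grow_sd)`,
#' `p(z) = logit^-1(flow_int + flow_slope z)`,
#' `f(z) = exp(seed_int + seed_slope z)` and
#' `eta(z') = Normal(z'; recruit_mean, recruit_sd)`, the state vector holds
#' the spring-seedling count `M` in entry 1 and per-bin plant counts in
#' entries `2..n_bins+1`, and the matrix is
#'
#' * continuous to continuous: `h * (s(z_j) g(z_i|z_j) +
#'   p(z_j) f(z_j) theta_f B eta(z_i))` — survival-growth plus the
#'   fall-seedling recruitment pathway closed within the year;
#' * seedling to continuous: `h * B * eta(z_i)` — establishment of last
#'   spring's seedlings;
#' * continuous to seedling: `p(z_j) f(z_j) theta_s` — next spring's
#'   seedlings;
#' * seedling to seedling: 0.
#'
#' The establishment probability `B` multiplies both seedling pathways
#' because fall- and spring-germinated recruits cannot be told apart at the
#' April census. With `eviction = "renorm"` (default) each growth column and
#' the recruit-size vector are renormalized to unit mass on `[L, U]`, the
#' standard correction preventing survival leakage past the size limits;
#' `"none"` leaves the raw midpoint masses.
#'
#' @param params A [vital_rate_params()] set.
#' @param L,U Lower/upper log-size integration limits (`L < U`).
#' @param n_bins Number of size bins (default 200).
#' @param eviction `"renorm"` or `"none"`.
#' @return An object of class `ipm_kernel`: list with the
#'   `(n_bins+1) x (n_bins+1)` matrix `A`, mesh midpoints `mesh`, bin width
#'   `h`, limits, and the source `params`.
#' @export
ipm_kernel <- function(params, L, U, n_bins = 200L,
                       eviction = c("renorm", "none")) {
  eviction <- match.arg(eviction)
  p <- as_vital_rate_params(params)
  if (!(L < U)) stopf("need L < U (got L = %g, U = %g)", L, U)
  if (n_bins < 3L) stopf("need n_bins >= 3")
  h <- (U - L) / n_bins
  mesh <- L + h * (seq_len(n_bins) - 0.5)

  s <- inv_logit(p[["surv_int"]] + p[["surv_slope"]] * mesh)
  pf <- inv_logit(p[["flow_int"]] + p[["flow_slope"]] * mesh)
  f <- exp(p[["seed_int"]] + p[["seed_slope"]] * mesh)

  ## growth densities: G[i, j] = g(z_i | z_j)
  G <- outer(mesh, mesh, function(zi, zj) {
    stats::dnorm(zi, p[["grow_int"]] + p[["grow_slope"]] * zj,
                 p[["grow_sd"]])
  })
  eta <- stats::dnorm(mesh, p[["recruit_mean"]], p[["recruit_sd"]])
  if (eviction == "renorm") {
    mass <- h * colSums(G)
    ok <- mass > 0
    G[, ok] <- sweep(G[, ok, drop = FALSE], 2, mass[ok], "/")
    em <- h * sum(eta)
    if (em > 0) eta <- eta / em
  }

  fert <- pf * f  # expected seeds at each midpoint
  A <- matrix(0, n_bins + 1L, n_bins + 1L)
  ## continuous -> continuous (survival-growth + fall recruitment pathway)
  A[-1L, -1L] <- h * (sweep(G, 2, s, "*") +
                        p[["theta_f"]] * p[["estab"]] * outer(eta, fert))
  ## discrete spring-seedling class
  A[-1L, 1L] <- h * p[["estab"]] * eta
  A[1L, -1L] <- fert * p[["theta_s"]]
  A[1L, 1L] <- 0

  if (any(!is.finite(A))) {
    comp <- c("survival", "growth", "reproduction", "seeds", "recruit size")
    stopf("nonfinite kernel entries; check %s parameters",
          paste(comp[c(any(!is.finite(s)), any(!is.finite(G)),
                       any(!is.finite(pf)), any(!is.finite(f)),
                       any(!is.finite(eta)))], collapse = ", "))
  }
  structure(list(A = A, mesh = mesh, h = h, L = L, U = U,
                 n_bins = as.integer(n_bins), eviction = eviction,
                 params = p),
            class = "ipm_kernel")
}

#' @export
print.ipm_kernel <- function(x, ...) {
  cat(sprintf(
    "IPM kernel: %d size bins on [%.3f, %.3f] + 1 seedling class (eviction: %s)\n",
    x$n_bins, x$L, x$U, x$eviction))
  cat(sprintf("lambda = %.6f (log lambda = %.6f)\n", lambda(x),
              log(lambda(x))))
  invisible(x)
}

power_lambda <- function(A, tol = 1e-10, maxit = 10000L) {
  v <- rep(1, ncol(A))
  lam <- 0
  for (i in seq_len(maxit)) {
    w <- A %*% v
    nw <- sum(abs(w))
    if (nw == 0) return(list(lambda = 0, converged = TRUE))
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      return(list(lambda = nw, converged = TRUE, v = w))
    }
    v <- w
    lam <- nw
  }
  list(lambda = lam, converged = FALSE, v = v)
}

#' Asymptotic population growth rate of a kernel
#'
#' The dominant eigenvalue (spectral radius) of the iteration matrix, by
#' dense eigendecomposition, cross-checked against power iteration to a
#' relative 1e-8 (`method = "eigen"`, default). `method = "power"` uses
#' power iteration alone (fast path for resampling loops).
#'
#' @param kernel An `ipm_kernel`, or a nonnegative square matrix.
#' @param method `"eigen"` or `"power"`.
#' @return The dominant eigenvalue `lambda` (a positive number for any
#'   kernel with a reproductive pathway); use `log()` for the log scale the
#'   results are reported on.
#' @export
lambda <- function(kernel, method = c("eigen", "power")) {
  method <- match.arg(method)
  A <- if (inherits(kernel, "ipm_kernel")) kernel$A else as.matrix(kernel)
  if (method == "power") {
    pw <- power_lambda(A)
    if (pw$converged) return(pw$lambda)
    ## reducible matrix or tied moduli: fall back to eigendecomposition
  }
  ev <- eigen(A, only.values = TRUE)$values
  lam <- ev[which.max(Mod(ev))]
  if (abs(Im(lam)) > 1e-8 * (1 + Mod(lam))) {
    warnf("dominant eigenvalue has nonzero imaginary part (%g); real part used",
          Im(lam))
  }
  lam <- Re(lam)
  if (method == "eigen") {
    pw <- power_lambda(A)
    if (pw$converged && lam != 0 &&
        abs(pw$lambda - abs(lam)) / abs(lam) > 1e-8) {
      warnf("power iteration (%.10g) and eigendecomposition (%.10g) disagree",
            pw$lambda, lam)
    }
  }
  lam
}

#' Default integration limits from observed sizes
#'
#' The smallest and largest observed log sizes across all strata of a
#' census (so every treatment's lambda is computed on a common domain),
#' padded by half a growth SD on each side.
#'
#' @param census A `census` object.
#' @param grow_sd Growth residual SD used for the padding.
#' @param pad Padding in units of `grow_sd` (default 0.5).
#' @return Numeric `c(L, U)`.
#' @export
size_limits <- function(census, grow_sd, pad = 0.5) {
  z <- c(census$individuals$z, census$individuals$z1)
  z <- z[is.finite(z)]
  if (!length(z)) stopf("no finite log sizes in census")
  c(min(z) - pad * grow_sd, max(z) + pad * grow_sd)
}
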