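#' Virtual cuvette geometry
#'
#' The slab simulation's rectangular cuvette: light enters normally at the
#' centre of the front face and traverses `path_length` of suspension.
#' Defaults emulate a standard 10 mm path-length cuvette with a 50 x 50 mm
#' face.
#'
#' @param path_length optical path length in m.
#' @param face_width,face_height transverse face dimensions in m.
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(path_length = 0.010, face_width = 0.050,
                          face_height = 0.050) {
  stopifnot(path_length > 0, face_width > 0, face_height > 0)
  structure(list(path_length = path_length, face_width = face_width,
                 face_height = face_height), class = "slab_geometry")
}

#' Per-band medium optics
#'
#' Absorption coefficient, scattering coefficient (both 1/m) and
#' Henyey--Greenstein anisotropy of the virtual suspension at one band.
#'
#' @param sigma_a absorption coefficient, 1/m (>= 0).
#' @param sigma_s scattering coefficient, 1/m (>= 0).
#' @param g anisotropy in (-1, 1); defaults to the calibrated forward value.
#' @return An object of class `medium_optics`.
#' @export
medium_optics <- function(sigma_a, sigma_s, g = hg_default_g()) {
  stopifnot(is.numeric(sigma_a), sigma_a >= 0,
            is.numeric(sigma_s), sigma_s >= 0,
            is.numeric(g), abs(g) < 1)
  structure(list(sigma_a = sigma_a, sigma_s = sigma_s, g = g),
            class = "medium_optics")
}

#' @export
print.medium_optics <- function(x, ...) {
  cat(sprintf("<medium_optics> sigma_a %.4g /m, sigma_s %.4g /m, g %.4f\n",
              x$sigma_a, x$sigma_s, x$g))
  invisible(x)
}

#' Monte Carlo slab simulation
#'
#' Traces `n_photons` through the cuvette: photons enter normally at the
#' front-face centre, free paths are exponential in the extinction
#' coefficient, each collision absorbs with probability
#' `sigma_a / (sigma_a + sigma_s)` and otherwise scatters by
#' Henyey--Greenstein. Photons leaving through the back face are
#' transmitted, through the front face reflected; side exits are counted as
#' absorbed, deliberately replicating the port-loss convention of
#' integrating-sphere measurements (light missing the ports is attributed to
#' absorption). `r_hat + t_hat + a_hat = 1` exactly by construction.
#'
#' @param optics a [medium_optics()].
#' @param slab a [slab_geometry()].
#' @param n_photons photon count (>= 1).
#' @param seed RNG seed (simulation is deterministic given the seed).
#' @return An object of class `slab_result`: `r_hat`, `t_hat`, `a_hat`,
#'   `n_photons`, `seed`.
#' @export
simulate_slab <- function(optics, slab = slab_geometry(), n_photons = 20000L,
                          seed = 1L) {
  stopifnot(inherits(optics, "medium_optics"), inherits(slab, "slab_geometry"),
            n_photons >= 1)
  if (optics$sigma_a == 0 && optics$sigma_s == 0) {
    res <- c(0, 1, 0)   # vacuum: ballistic transmission
  } else {
    res <- cpp_simulate_slab(optics$sigma_a, optics$sigma_s, optics$g,
                             slab$path_length, slab$face_width,
                             slab$face_height, as.integer(n_photons),
                             as.numeric(seed))
  }
  structure(list(r_hat = res[1], t_hat = res[2], a_hat = res[3],
                 n_photons = as.integer(n_photons), seed = seed),
            class = "slab_result")
}

#' @export
print.slab_result <- function(x, ...) {
  cat(sprintf("<slab_result> r_hat %.4f, t_hat %.4f, a_hat %.4f (n = %d)\n",
              x$r_hat, x$t_hat, x$a_hat, x$n_photons))
  invisible(x)
}

#' Invert one band's optical coefficients from a reflectance/transmittance
#' target
#'
#' Finds `sigma_a` and `sigma_s` (with fixed anisotropy `g_fixed`) whose
#' forward slab simulation reproduces the target `(r, t)`, minimizing
#' `|r - r_hat| + |t - t_hat|` by derivative-free nested bisection on the
#' optical depths (the forward map is monotone in both). The photon budget
#' and seed are held fixed across evaluations (common random numbers) so the
#' search is quasi-deterministic. Targets outside the achievable set (e.g. a
#' reflectance above the ceiling reachable at this anisotropy) return the
#' best effort flagged `converged = FALSE`.
#'
#' @param r,t target reflectance and transmittance (fractions, `r + t <= 1`).
#' @param slab a [slab_geometry()].
#' @param g_fixed anisotropy used for every band.
#' @param tol residual tolerance for declaring convergence.
#' @param n_photons photons per forward evaluation.
#' @param seed RNG seed shared by all evaluations.
#' @param start optional starting guess `c(log_tau_a, log_tau_s)` (optical
#'   depths), e.g. from a surrogate prediction.
#' @return A [medium_optics()] with attributes `residual`, `converged`,
#'   `r_hat`, `t_hat`.
#' @export
invert_band <- function(r, t, slab = slab_geometry(), g_fixed = hg_default_g(),
                        tol = 0.02, n_photons = 20000L, seed = 1L,
                        start = NULL) {
  stopifnot(r >= 0, r <= 1, t >= 0, t <= 1)
  if (r + t > 1 + 1e-9) stop("infeasible target: r + t > 1")
  d <- slab$path_length
  if (r < 1e-6 && t > 1 - 1e-6) {   # lossless target
    out <- medium_optics(0, 0, g_fixed)
    attr(out, "residual") <- 0
    attr(out, "converged") <- TRUE
    attr(out, "r_hat") <- 0; attr(out, "t_hat") <- 1
    return(out)
  }
  # The forward map is monotone in both optical depths: t_hat decreases in
  # tau_a (at fixed tau_s) and r_hat increases in tau_s (at the matched
  # tau_a), so the two-unknown inversion is solved by nested bisection, which
  # is robust to the Monte Carlo jitter of the objective (common random
  # numbers keep it quasi-deterministic). When the reflectance target is
  # unobservably small, the scattering depth is driven to zero: the
  # least-scattering medium consistent with the data.
  ta_max <- 30; ts_max <- 50
  n_search <- max(2000L, as.integer(n_photons / 2))
  fwd <- function(tau_a, tau_s, n = n_search)
    cpp_simulate_slab(tau_a / d, tau_s / d, g_fixed, d,
                      slab$face_width, slab$face_height,
                      as.integer(n), as.numeric(seed))
  solve_ta <- function(tau_s) {       # match t at this scattering depth
    lo <- 0; hi <- ta_max
    if (fwd(lo, tau_s)[2] <= t) return(lo)
    if (fwd(hi, tau_s)[2] >= t) return(hi)
    for (k in 1:13) {
      mid <- (lo + hi) / 2
      th <- fwd(mid, tau_s)[2]
      if (abs(th - t) < 0.6 / sqrt(n_search)) return(mid)
      if (th > t) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  if (!is.null(start)) {
    # a surrogate start is accepted directly when it already fits
    s0 <- fwd(exp(start[1]), exp(start[2]), n_photons)
    if (abs(r - s0[1]) + abs(t - s0[2]) <= tol / 2) {
      out <- medium_optics(exp(start[1]) / d, exp(start[2]) / d, g_fixed)
      attr(out, "residual") <- abs(r - s0[1]) + abs(t - s0[2])
      attr(out, "converged") <- TRUE
      attr(out, "r_hat") <- s0[1]; attr(out, "t_hat") <- s0[2]
      return(out)
    }
  }
  if (r < 5 / n_search) {
    # fewer than ~5 expected reflected photons: reflectance is genuinely
    # unobservable at this budget, so take the least-scattering medium
    tau_s <- 0
  } else {
    lo <- 0; hi <- ts_max
    r_hi <- fwd(solve_ta(hi), hi)[1]
    if (r >= r_hi) {
      tau_s <- hi                      # reflectance ceiling: best effort
    } else {
      for (k in 1:13) {
        mid <- (lo + hi) / 2
        rh <- fwd(solve_ta(mid), mid)[1]
        # binomial noise floor of the reflectance estimate at this budget
        if (abs(rh - r) < max(0.6 * sqrt(r / n_search), 2 / n_search)) {
          lo <- hi <- mid; break
        }
        if (rh < r) lo <- mid else hi <- mid
      }
      tau_s <- (lo + hi) / 2
    }
  }
  tau_a <- solve_ta(tau_s)
  s <- fwd(tau_a, tau_s, n_photons)
  resid <- abs(r - s[1]) + abs(t - s[2])
  out <- medium_optics(tau_a / d, tau_s / d, g_fixed)
  attr(out, "residual") <- resid
  attr(out, "converged") <- resid <= tol + 6 / sqrt(n_photons)
  attr(out, "r_hat") <- s[1]
  attr(out, "t_hat") <- s[2]
  out
}
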