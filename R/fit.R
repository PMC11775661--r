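#' Per-band medium spectrum
#'
#' The virtual suspension: absorption and scattering coefficients (1/m) and
#' a shared anisotropy on a band grid, plus the density multiplier that
#' dilutes the suspension at render time (the port-loss convention of the
#' slab measurement overestimates absorption, which is compensated by
#' multiplying the inverted particle densities by a factor, 1/4 by default
#' in the render settings). The multiplier is stored, not yet applied.
#'
#' @param grid a [band_grid()].
#' @param sigma_a,sigma_s per-band coefficients, 1/m.
#' @param g anisotropy shared by all bands.
#' @param density_multiplier dimensionless dilution factor (> 0).
#' @return An object of class `medium_spectrum`.
#' @export
medium_spectrum <- function(grid, sigma_a, sigma_s, g = hg_default_g(),
                            density_multiplier = 1.0) {
  stopifnot(inherits(grid, "band_grid"),
            length(sigma_a) == length(grid$wavelengths),
            length(sigma_s) == length(grid$wavelengths),
            all(sigma_a >= 0), all(sigma_s >= 0), abs(g) < 1,
            density_multiplier > 0)
  structure(list(grid = grid, sigma_a = as.numeric(sigma_a),
                 sigma_s = as.numeric(sigma_s), g = g,
                 density_multiplier = density_multiplier),
            class = "medium_spectrum")
}

#' @export
print.medium_spectrum <- function(x, ...) {
  cat(sprintf("<medium_spectrum> %s, sigma_a [%.3g, %.3g] /m, sigma_s [%.3g, %.3g] /m, g %.4f, multiplier %.3g\n",
              format(x$grid), min(x$sigma_a), max(x$sigma_a),
              min(x$sigma_s), max(x$sigma_s), x$g, x$density_multiplier))
  invisible(x)
}

#' Invert a full target spectrum into a per-band medium
#'
#' Fits the virtual suspension band by band (bands are independent): for
#' every band the slab's absorption and scattering coefficients are found so
#' that the forward Monte Carlo simulation reproduces the measured
#' reflectance/transmittance pair. Either the per-band optimizer or a
#' trained surrogate (optionally refined by the optimizer) does the work.
#' The returned object is a fitted-model object with `print`, `summary`,
#' `coef`, `fitted`, `predict`, `residuals` and `plot` methods.
#'
#' @param target a [target_spectrum()].
#' @param slab a [slab_geometry()].
#' @param method `"optimize"` for per-band search, `"surrogate"` for a pure
#'   function evaluation of a trained surrogate.
#' @param surrogate a [train_surrogate()] result (required for
#'   `method = "surrogate"`; used as the starting guess when supplied with
#'   `method = "optimize"`).
#' @param g_fixed anisotropy used for every band.
#' @param density_multiplier stored in the result's medium (not applied).
#' @param n_photons photons per forward evaluation.
#' @param seed master seed; per-band seeds are derived from it.
#' @param verify_photons photon count for the verification pass that
#'   produces the reported residuals.
#' @return An object of class `slab_fit`.
#' @export
invert_spectrum <- function(target, slab = slab_geometry(),
                            method = c("optimize", "surrogate"),
                            surrogate = NULL, g_fixed = hg_default_g(),
                            density_multiplier = 1.0,
                            n_photons = 20000L, seed = 1L,
                            verify_photons = 4 * n_photons) {
  stopifnot(inherits(target, "target_spectrum"))
  method <- match.arg(method)
  if (method == "surrogate" && is.null(surrogate))
    stop("method = \"surrogate\" requires a trained surrogate")
  if (!is.null(surrogate)) {
    stopifnot(inherits(surrogate, "slab_surrogate"))
    g_fixed <- surrogate$g
  }
  wl <- target$grid$wavelengths
  n <- length(wl)
  d <- slab$path_length
  sigma_a <- sigma_s <- r_hat <- t_hat <- numeric(n)
  converged <- logical(n)
  for (b in seq_len(n)) {
    r <- target$reflectance$values[b]
    t <- target$transmittance$values[b]
    band_seed <- (seed + 7919L * b) %% .Machine$integer.max
    if (method == "surrogate") {
      opt <- predict_params(surrogate, r, t)
      conv <- TRUE
    } else {
      start <- if (!is.null(surrogate)) {
        tau <- surrogate_predict_depths(surrogate[c("model_a", "model_s")],
                                        r, t, surrogate$delta)
        log(pmax(tau, 1e-4))
      } else NULL
      opt <- invert_band(r, t, slab, g_fixed, n_photons = n_photons,
                         seed = band_seed, start = start)
      conv <- attr(opt, "converged")
    }
    chk <- simulate_slab(opt, slab, n_photons = verify_photons,
                         seed = band_seed + 1L)
    sigma_a[b] <- opt$sigma_a; sigma_s[b] <- opt$sigma_s
    r_hat[b] <- chk$r_hat; t_hat[b] <- chk$t_hat
    converged[b] <- conv
  }
  report <- data.frame(band = seq_len(n), wavelength = wl,
                       r = target$reflectance$values,
                       t = target$transmittance$values,
                       r_hat = r_hat, t_hat = t_hat,
                       sigma_a = sigma_a, sigma_s = sigma_s,
                       converged = converged)
  structure(list(medium = medium_spectrum(target$grid, sigma_a, sigma_s,
                                          g_fixed, density_multiplier),
                 report = report,
                 rmse_r = sqrt(mean((r_hat - report$r)^2)),
                 rmse_t = sqrt(mean((t_hat - report$t)^2)),
                 method = method, slab = slab, seed = seed,
                 target = target),
            class = "slab_fit")
}

#' @export
print.slab_fit <- function(x, ...) {
  cat(sprintf("<slab_fit> %s, %d bands (%s)\n", format(x$medium$grid),
              nrow(x$report), x$method))
  cat(sprintf("  RMSE: reflectance %.4f, transmittance %.4f; %d/%d bands converged\n",
              x$rmse_r, x$rmse_t, sum(x$report$converged), nrow(x$report)))
  invisible(x)
}

#' @export
summary.slab_fit <- function(object, ...) {
  cat(sprintf("Slab inversion fit (%s), %d bands\n", object$method,
              nrow(object$report)))
  cat(sprintf("  transmittance RMSE %.4f, reflectance RMSE %.4f\n",
              object$rmse_t, object$rmse_r))
  cat(sprintf("  sigma_a in [%.3g, %.3g] /m, sigma_s in [%.3g, %.3g] /m, g = %.4f\n",
              min(object$medium$sigma_a), max(object$medium$sigma_a),
              min(object$medium$sigma_s), max(object$medium$sigma_s),
              object$medium$g))
  nbad <- sum(!object$report$converged)
  if (nbad > 0)
    cat(sprintf("  %d non-converged band(s): %s nm\n", nbad,
                paste(object$report$wavelength[!object$report$converged],
                      collapse = ", ")))
  invisible(object)
}

#' @export
coef.slab_fit <- function(object, ...) {
  m <- cbind(sigma_a = object$medium$sigma_a, sigma_s = object$medium$sigma_s)
  rownames(m) <- object$report$wavelength
  m
}

#' @export
fitted.slab_fit <- function(object, ...) {
  object$report[, c("wavelength", "r_hat", "t_hat")]
}

#' @export
residuals.slab_fit <- function(object, ...) {
  data.frame(wavelength = object$report$wavelength,
             r = object$report$r - object$report$r_hat,
             t = object$report$t - object$report$t_hat)
}

#' Forward-simulate the fitted medium
#'
#' @param object a `slab_fit`.
#' @param n_photons photons per band.
#' @param seed RNG seed.
#' @param ... unused.
#' @return Data frame with per-band simulated `r_hat`, `t_hat`.
#' @export
predict.slab_fit <- function(object, n_photons = 50000L, seed = 1L, ...) {
  n <- nrow(object$report)
  r_hat <- t_hat <- numeric(n)
  for (b in seq_len(n)) {
    s <- simulate_slab(medium_optics(object$medium$sigma_a[b],
                                     object$medium$sigma_s[b],
                                     object$medium$g),
                       object$slab, n_photons = n_photons,
                       seed = (seed + 31L * b) %% .Machine$integer.max)
    r_hat[b] <- s$r_hat; t_hat[b] <- s$t_hat
  }
  data.frame(wavelength = object$report$wavelength, r_hat = r_hat, t_hat = t_hat)
}

#' @export
plot.slab_fit <- function(x, ...) {
  wl <- x$report$wavelength
  graphics::plot(wl, x$report$t, type = "l", col = "black", ylim = c(0, 1),
                 xlab = "wavelength (nm)", ylab = "fraction", ...)
  graphics::lines(wl, x$report$t_hat, col = "red", lty = 2)
  graphics::lines(wl, x$report$r, col = "grey40")
  graphics::lines(wl, x$report$r_hat, col = "blue", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("t target", "t fitted", "r target", "r fitted"),
                   col = c("black", "red", "grey40", "blue"),
                   lty = c(1, 2, 1, 2))
  invisible(x)
}

#' Write a slab-fit report as CSV
#'
#' Columns: band, wavelength, target r and t, simulated r_hat and t_hat,
#' fitted sigma_a and sigma_s, convergence flag.
#'
#' @param fit a `slab_fit`.
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "slab_fit"))
  utils::write.csv(fit$report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
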