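#' Generate reflectance/transmittance training targets
#'
#' Stratified, jittered quasi-uniform coverage of the feasible target set
#' `{(r, t): r + t <= 1, |r - t| <= rt_band_limit}`. With
#' `rt_band_limit = 0` every point lies on the diagonal `r = t`; with
#' `rt_band_limit = 1` the domain includes the extreme corners `(1, 0)` and
#' `(0, 1)`.
#'
#' @param n_points number of targets.
#' @param rt_band_limit maximum allowed `|r - t|` in \[0, 1\].
#' @param rt_band_min optional lower bound on `|r - t|`, used by the
#'   iterative trainer to concentrate each widening iteration on its newly
#'   admitted annulus instead of re-covering the centre band.
#' @param seed RNG seed (sampling is stratified and reproducible).
#' @return A data frame with columns `r`, `t`.
#' @export
generate_training_points <- function(n_points, rt_band_limit,
                                     rt_band_min = 0, seed = 1L) {
  stopifnot(n_points >= 1, rt_band_limit >= 0, rt_band_limit <= 1,
            rt_band_min >= 0, rt_band_min <= rt_band_limit)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # parameterize by the mean m = (r+t)/2 and the half-difference
  # h = (r-t)/2 with rt_band_min/2 <= |h| <= min(m, rt_band_limit/2);
  # stratify m over its feasible range, jitter h
  i <- seq_len(n_points)
  hmin <- rt_band_min / 2
  m_lo <- hmin
  m <- m_lo + (0.5 - m_lo) * (i - stats::runif(n_points)) / n_points
  hmax <- pmin(m, rt_band_limit / 2)
  mag <- hmin + stats::runif(n_points) * pmax(hmax - hmin, 0)
  h <- ifelse(stats::runif(n_points) < 0.5, -1, 1) * mag
  data.frame(r = m + h, t = m - h)
}

#' Iteratively trained surrogate for the slab inversion
#'
#' Trains a smooth regression surrogate mapping a reflectance/transmittance
#' target `(r, t)` to the slab's optical depths, by the widening iteration
#' scheme: the first iteration inverts targets confined to `|r - t| <= 0.25`
#' starting from the symmetric-guess regime; each subsequent iteration widens
#' the admissible `|r - t|` band (default schedule 0.25, 0.5, 0.75, 1.0),
#' uses the current surrogate prediction as the starting guess, prunes every
#' point whose achieved simulation error in reflectance or transmittance
#' exceeds `error_threshold` (default 2%), and refits the smooth surfaces on
#' the retained points. Points near the extreme corners that the forward
#' model cannot reach are pruned naturally.
#'
#' The smooth model family is a pair of thin-plate regression splines
#' (`mgcv::gam`) for `log(tau_a + delta)` and `log(tau_s + delta)` as
#' functions of `(r, t)`.
#'
#' @param slab a [slab_geometry()].
#' @param g_fixed anisotropy used throughout.
#' @param iterations number of widening iterations (>= 1).
#' @param error_threshold pruning threshold on `max(|r-r_hat|, |t-t_hat|)`.
#' @param schedule `|r - t|` bounds per iteration (last entry should be 1).
#' @param n_points training targets generated per iteration.
#' @param n_photons photons per forward evaluation during inversion.
#' @param seed master seed.
#' @return An object of class `slab_surrogate` with the fitted models, the
#'   retained training set, and a per-iteration log.
#' @export
train_surrogate <- function(slab = slab_geometry(), g_fixed = hg_default_g(),
                            iterations = 4, error_threshold = 0.02,
                            schedule = c(0.25, 0.5, 0.75, 1.0),
                            n_points = 120, n_photons = 10000L, seed = 1L) {
  stopifnot(iterations >= 1, length(schedule) == iterations,
            all(diff(schedule) >= 0))
  d <- slab$path_length
  delta <- 1e-3
  retained <- NULL
  models <- NULL
  log_rows <- list()
  for (it in seq_len(iterations)) {
    # widening iterations concentrate two thirds of their draws on the
    # newly admitted |r - t| annulus and refresh the rest over the full
    # widened domain (the deep-absorption corner lives at small |r - t|
    # and needs continued coverage)
    if (it == 1) {
      pts <- generate_training_points(n_points, schedule[it],
                                      seed = seed + 1000L * it)
    } else {
      n_ann <- ceiling(2 * n_points / 3)
      pts <- rbind(
        generate_training_points(n_ann, schedule[it],
                                 rt_band_min = schedule[it - 1],
                                 seed = seed + 1000L * it),
        generate_training_points(n_points - n_ann, schedule[it],
                                 seed = seed + 1000L * it + 500L))
    }
    rows <- vector("list", nrow(pts))
    for (k in seq_len(nrow(pts))) {
      r <- pts$r[k]; t <- pts$t[k]
      start <- if (!is.null(models)) {
        pr <- surrogate_predict_depths(models, r, t, delta)
        log(pmax(pr, 1e-4))
      } else NULL
      opt <- invert_band(r, t, slab, g_fixed, tol = error_threshold,
                         n_photons = n_photons,
                         seed = seed + 7L * it + 13L * k, start = start)
      rows[[k]] <- data.frame(
        iteration = it, r = r, t = t,
        r_hat = attr(opt, "r_hat"), t_hat = attr(opt, "t_hat"),
        tau_a = opt$sigma_a * d, tau_s = opt$sigma_s * d,
        err_r = abs(r - attr(opt, "r_hat")),
        err_t = abs(t - attr(opt, "t_hat")))
    }
    new_pts <- do.call(rbind, rows)
    ok <- pmax(new_pts$err_r, new_pts$err_t) <= error_threshold
    n_pruned <- sum(!ok)
    retained <- rbind(retained, new_pts[ok, ])
    if (is.null(retained) || nrow(retained) < 10)
      stop("surrogate training failed: nearly all points pruned in iteration ",
           it, " (", n_pruned, " of ", nrow(new_pts), " rejected)")
    models <- surrogate_fit_models(retained, delta)
    log_rows[[it]] <- data.frame(
      iteration = it, rt_band_limit = schedule[it],
      n_generated = nrow(new_pts), n_pruned = n_pruned,
      n_retained_total = nrow(retained),
      max_err_retained = max(pmax(retained$err_r, retained$err_t)))
  }
  # in-sample fit tolerance of the smooth surfaces, on the optical depths
  ret_tr <- transform(retained, lr = log(r + 0.01), lt = log(t + 0.01))
  pred_a <- exp(stats::predict(models$model_a, ret_tr)) - delta
  pred_s <- exp(stats::predict(models$model_s, ret_tr)) - delta
  fit_tol <- max(abs(pred_a - retained$tau_a), abs(pred_s - retained$tau_s))
  structure(list(model_a = models$model_a, model_s = models$model_s,
                 training = retained, log = do.call(rbind, log_rows),
                 g = g_fixed, slab = slab, delta = delta,
                 error_threshold = error_threshold,
                 fit_tolerance = fit_tol,
                 version = "pbrsim-surrogate-1"),
            class = "slab_surrogate")
}

# The smooth surfaces are fitted against log-compressed target coordinates
# (lr, lt) = log(r + 0.01), log(t + 0.01): the absorption depth behaves like
# -log(t), so in these coordinates the surfaces are gently curved and a
# thin-plate spline interpolates them reliably even near the deep-absorption
# corner.
surrogate_fit_models <- function(train, delta) {
  train$lr <- log(train$r + 0.01)
  train$lt <- log(train$t + 0.01)
  k <- max(10, min(100, nrow(train) - 10))
  list(model_a = mgcv::gam(log(tau_a + delta) ~ s(lr, lt, k = k), data = train,
                           method = "REML"),
       model_s = mgcv::gam(log(tau_s + delta) ~ s(lr, lt, k = k), data = train,
                           method = "REML"))
}

surrogate_predict_depths <- function(models, r, t, delta) {
  nd <- data.frame(lr = log(r + 0.01), lt = log(t + 0.01))
  c(tau_a = max(0, exp(as.numeric(stats::predict(models$model_a, nd))) - delta),
    tau_s = max(0, exp(as.numeric(stats::predict(models$model_s, nd))) - delta))
}

#' @export
print.slab_surrogate <- function(x, ...) {
  cat(sprintf("<slab_surrogate> %d retained training points, %d iterations, g = %.4f\n",
              nrow(x$training), nrow(x$log), x$g))
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' Predict medium optics from a trained surrogate
#'
#' A deterministic, smooth function evaluation replacing the per-band
#' optimization. Requests outside the trained domain (`r + t > 1`, values
#' outside \[0, 1\]) are rejected rather than silently extrapolated.
#'
#' @param surrogate a [train_surrogate()] result.
#' @param r,t target reflectance and transmittance.
#' @return A [medium_optics()].
#' @export
predict_params <- function(surrogate, r, t) {
  stopifnot(inherits(surrogate, "slab_surrogate"))
  if (!is.numeric(r) || !is.numeric(t) || r < 0 || r > 1 || t < 0 || t > 1 ||
      r + t > 1 + 1e-9)
    stop("(r, t) outside the trained domain: need r, t in [0,1], r + t <= 1")
  tau <- surrogate_predict_depths(surrogate[c("model_a", "model_s")], r, t,
                                  surrogate$delta)
  d <- surrogate$slab$path_length
  medium_optics(tau[["tau_a"]] / d, tau[["tau_s"]] / d, surrogate$g)
}

#' @rdname predict_params
#' @param object,... `predict` method arguments (`newdata` is a data frame
#'   with columns `r`, `t`).
#' @param newdata data frame of targets.
#' @export
predict.slab_surrogate <- function(object, newdata, ...) {
  out <- lapply(seq_len(nrow(newdata)),
                function(i) predict_params(object, newdata$r[i], newdata$t[i]))
  data.frame(r = newdata$r, t = newdata$t,
             sigma_a = vapply(out, `[[`, 0, "sigma_a"),
             sigma_s = vapply(out, `[[`, 0, "sigma_s"))
}

#' Serialize / restore a trained surrogate
#'
#' Single self-describing file (RDS) carrying the fitted models, the
#' retained training set with per-point simulation errors, the iteration
#' log, and a format version tag.
#'
#' @param surrogate a `slab_surrogate`.
#' @param path file path.
#' @return `read_surrogate` returns the restored `slab_surrogate`.
#' @export
write_surrogate <- function(surrogate, path) {
  stopifnot(inherits(surrogate, "slab_surrogate"))
  saveRDS(surrogate, path)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "slab_surrogate") || !identical(x$version, "pbrsim-surrogate-1"))
    stop("not a pbrsim surrogate file")
  x
}
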