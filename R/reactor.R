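#' Glass photobioreactor dimensions
#'
#' Cylindrical reactor with the aspect ratio locked to `height = 2 * radius`,
#' so `V = 2 * pi * r^3` and the radius follows in closed form,
#' `r = (V / 2 pi)^(1/3)`. The entire lateral wall serves as the light sheet,
#' so the lamp area is `2 pi r h = 4 pi r^2`.
#'
#' @param volume reactor volume in m^3 (> 0).
#' @return An object of class `glass_reactor_dims` with `volume`, `radius`,
#'   `height`, `lamp_area` (SI units).
#' @examples
#' glass_reactor_dims(0.01)    # the 10-litre laboratory unit
#' @export
glass_reactor_dims <- function(volume) {
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0)
    stop("volume must be a single positive number (m^3)")
  r <- (volume / (2 * pi))^(1 / 3)
  structure(list(volume = volume, radius = r, height = 2 * r,
                 lamp_area = 4 * pi * r^2, type = "glass"),
            class = c("glass_reactor_dims", "reactor_dims"))
}

#' Steel photobioreactor dimensions with internal rod lamps
#'
#' The steel reactor is lit by `n_lamps` full-height rod lamps placed inside
#' the vessel. Its outer dimensions are enlarged (keeping `h = 2r`) so that
#' the *working* volume -- vessel volume minus rod volume -- equals the
#' requested suspension volume, while the total rod lateral area equals the
#' prescribed lamp area (typically the matched glass reactor's wall area).
#' Eliminating the rod radius `r_l = A_l / (4 pi n r)` reduces the coupled
#' system to the single equation `2 pi r^3 - A_l^2 / (8 pi n r) = V`, solved
#' by bracketed root finding; the unique positive root is returned.
#'
#' @param working_volume suspension volume in m^3 (> 0).
#' @param n_lamps number of rod lamps (>= 1).
#' @param lamp_area total lamp lateral area in m^2 (> 0).
#' @return An object of class `steel_reactor_dims` with fields
#'   `working_volume`, `radius`, `height`, `n_lamps`, `lamp_radius`,
#'   `lamp_area`.
#' @examples
#' g <- glass_reactor_dims(0.01)
#' steel_reactor_dims(0.01, n_lamps = 6, lamp_area = g$lamp_area)
#' @export
steel_reactor_dims <- function(working_volume, n_lamps, lamp_area) {
  if (!is.numeric(working_volume) || working_volume <= 0)
    stop("working_volume must be positive (m^3)")
  if (!is.numeric(n_lamps) || n_lamps < 1 || n_lamps != round(n_lamps))
    stop("n_lamps must be a positive integer")
  if (!is.numeric(lamp_area) || lamp_area <= 0)
    stop("lamp_area must be positive (m^2)")
  V <- working_volume; n <- n_lamps; A <- lamp_area
  f <- function(r) 2 * pi * r^3 - A^2 / (8 * pi * n * r) - V
  r_lo <- (V / (2 * pi))^(1 / 3)       # zero-lamp limit, f(r_lo) < 0
  r_hi <- r_lo
  for (k in 1:60) {
    r_hi <- r_hi * 2
    if (f(r_hi) > 0) break
  }
  if (f(r_hi) <= 0) stop("no positive root: lamp_area too large for this volume")
  r <- stats::uniroot(f, c(r_lo, r_hi), tol = 1e-14)$root
  rl <- A / (4 * pi * n * r)
  if (rl >= r) stop("lamp rods do not fit: lamp_area too large for this volume")
  out <- structure(list(working_volume = V, radius = r, height = 2 * r,
                        n_lamps = as.integer(n), lamp_radius = rl,
                        lamp_area = A, type = "steel"),
                   class = c("steel_reactor_dims", "reactor_dims"))
  # self-consistency of the reduced system
  v_chk <- pi * r^2 * (2 * r) - n * pi * rl^2 * (2 * r)
  a_chk <- n * 2 * pi * rl * (2 * r)
  stopifnot(abs(v_chk - V) / V < 1e-6, abs(a_chk - A) / A < 1e-6)
  out
}

#' @export
print.reactor_dims <- function(x, ...) {
  cat(sprintf("<%s reactor> volume %.4g l: radius %.2f cm, height %.2f cm",
              x$type,
              1000 * (if (x$type == "glass") x$volume else x$working_volume),
              100 * x$radius, 100 * x$height))
  if (x$type == "steel")
    cat(sprintf(", %d lamps of radius %.2f cm", x$n_lamps, 100 * x$lamp_radius))
  cat(sprintf(", lamp area %.4f m^2\n", x$lamp_area))
  invisible(x)
}

#' Rod-lamp layout inside a steel reactor
#'
#' Places `n_lamps` rod centres inside a reactor of radius `reactor_radius`.
#' A single lamp sits on the axis. Otherwise lamps go on one concentric ring
#' at the equal-area radius `reactor_radius / sqrt(2)` -- the ring that
#' splits the cross-section into equal inner and outer areas, so neither
#' zone is left far from a lamp -- when the pairwise centre spacing permits
#' (at least one lamp diameter); when it does not, they are split across two
#' equal-area rings at radii `sqrt(1/3)` and `sqrt(2/3)` of the reactor
#' radius (inner ring rotated half a step). Rejects layouts where a rod
#' would overlap the wall or a neighbour.
#'
#' @param n_lamps number of rods (>= 1).
#' @param reactor_radius inner reactor radius, m.
#' @param lamp_radius rod radius, m.
#' @return A matrix with columns `x`, `y` of rod centre positions (m).
#' @export
lamp_layout <- function(n_lamps, reactor_radius, lamp_radius) {
  stopifnot(n_lamps >= 1, reactor_radius > 0, lamp_radius > 0,
            lamp_radius < reactor_radius)
  if (n_lamps == 1) {
    pos <- matrix(c(0, 0), ncol = 2)
  } else {
    ring <- function(n, R, phase = 0) {
      a <- phase + 2 * pi * (seq_len(n) - 1) / n
      cbind(R * cos(a), R * sin(a))
    }
    R1 <- reactor_radius / sqrt(2)
    spacing1 <- 2 * R1 * sin(pi / n_lamps)
    if (spacing1 >= 2 * lamp_radius) {
      pos <- ring(n_lamps, R1)
    } else {
      n_out <- ceiling(2 * n_lamps / 3)
      n_in <- n_lamps - n_out
      pos <- rbind(ring(n_out, sqrt(2 / 3) * reactor_radius),
                   if (n_in > 0) ring(n_in, sqrt(1 / 3) * reactor_radius,
                                      phase = pi / n_out))
    }
  }
  colnames(pos) <- c("x", "y")
  # overlap checks
  wall_clear <- reactor_radius - sqrt(rowSums(pos^2)) - lamp_radius
  if (any(wall_clear < 0)) stop("lamp layout overlaps the reactor wall")
  if (nrow(pos) > 1) {
    dmin <- min(stats::dist(pos))
    if (dmin < 2 * lamp_radius) stop("lamp layout: rods overlap each other")
  }
  pos
}
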