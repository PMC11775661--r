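# Independent photon-walk oracle for the slab model, written as plain
# vectorized R with R's own RNG. It shares no code or RNG with the
# package's compiled kernel and is deliberately a straightforward
# transcription of the transport rules: exponential free paths, absorption
# with probability sigma_a / sigma_t at each collision, Henyey--Greenstein
# scattering via inverse-CDF cosines, port-loss side exits counted as
# absorbed.
oracle_slab <- function(sigma_a, sigma_s, g, d = 0.01, w = 0.05, h = 0.05,
                        n = 20000, seed = 1) {
  set.seed(seed)
  st <- sigma_a + sigma_s
  albedo <- if (st > 0) sigma_s / st else 0
  pos <- cbind(x = rep(0, n), y = 0, z = 0)
  dir <- cbind(x = rep(1, n), y = 0, z = 0)
  fate <- rep(NA_integer_, n)   # 0 refl, 1 trans, 2 absorbed/lost
  active <- rep(TRUE, n)
  for (step in 1:10000) {
    idx <- which(active)
    if (!length(idx)) break
    s <- -log(runif(length(idx))) / st
    # distance to each boundary plane along the direction
    p <- pos[idx, , drop = FALSE]; v <- dir[idx, , drop = FALSE]
    tb <- rep(Inf, length(idx)); face <- integer(length(idx))
    cand <- function(tt, f) {
      better <- tt > 0 & tt < tb
      tb[better] <<- tt[better]; face[better] <<- f
    }
    cand(ifelse(v[, 1] > 0, (d - p[, 1]) / v[, 1], Inf), 1L)
    cand(ifelse(v[, 1] < 0, (0 - p[, 1]) / v[, 1], Inf), 0L)
    cand(ifelse(v[, 2] != 0,
                (sign(v[, 2]) * w / 2 - p[, 2]) / v[, 2], Inf), 2L)
    cand(ifelse(v[, 3] != 0,
                (sign(v[, 3]) * h / 2 - p[, 3]) / v[, 3], Inf), 2L)
    escaped <- s >= tb
    fate[idx[escaped]] <- face[escaped]
    active[idx[escaped]] <- FALSE
    stay <- idx[!escaped]
    if (!length(stay)) next
    ss <- s[!escaped]
    pos[stay, ] <- pos[stay, , drop = FALSE] + ss * dir[stay, , drop = FALSE]
    absorbed <- runif(length(stay)) >= albedo
    fate[stay[absorbed]] <- 2L
    active[stay[absorbed]] <- FALSE
    sc <- stay[!absorbed]
    if (!length(sc)) next
    # HG cosine + uniform azimuth, rotated into each photon's frame
    u <- runif(length(sc))
    ct <- if (abs(g) < 1e-12) 2 * u - 1 else {
      tmp <- (1 - g^2) / (1 - g + 2 * g * u)
      (1 + g^2 - tmp^2) / (2 * g)
    }
    stheta <- sqrt(pmax(0, 1 - ct^2))
    phi <- 2 * pi * runif(length(sc))
    for (kk in seq_along(sc)) {
      i <- sc[kk]
      dir[i, ] <- rotate_about(dir[i, ], ct[kk], stheta[kk], phi[kk])
    }
  }
  fate[is.na(fate)] <- 2L
  c(r = mean(fate == 0), t = mean(fate == 1), a = mean(fate == 2))
}

rotate_about <- function(wv, ct, st, phi) {
  a <- if (abs(wv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(wv[2] * a[3] - wv[3] * a[2],
         wv[3] * a[1] - wv[1] * a[3],
         wv[1] * a[2] - wv[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(wv[2] * u[3] - wv[3] * u[2],
         wv[3] * u[1] - wv[1] * u[3],
         wv[1] * u[2] - wv[2] * u[1])
  out <- st * cos(phi) * u + st * sin(phi) * v + ct * wv
  out / sqrt(sum(out^2))
}

# binomial Monte Carlo standard error of a fraction
mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
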