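# Ordinary kriging of an allele-frequency surface on a rectangular grid.
# The exponential variogram is fit to the empirical (binned) variogram by
# weighted least squares with Cressie weights N_j / gamma_model^2; the
# kriging system uses the equivalent covariance form with the nugget kept
# on the lag-zero diagonal AND in the prediction vector at coincident
# points, which makes the predictor an exact interpolator at the sampling
# locations.

fitExponentialVariogram <- function(d, x, nBins = 12) {
  ut <- upper.tri(d)
  h <- d[ut]
  g <- 0.5 * (outer(x, x, "-")[ut])^2
  brk <- seq(0, max(h) * 1.0001, length.out = nBins + 1)
  bin <- findInterval(h, brk, left.open = TRUE)
  bin[bin == 0] <- 1L
  nH <- tabulate(bin, nBins)
  keep <- nH > 0
  gH <- tapply(g, factor(bin, levels = seq_len(nBins)), mean)[keep]
  hH <- tapply(h, factor(bin, levels = seq_len(nBins)), mean)[keep]
  nH <- nH[keep]
  vtot <- stats::var(x)
  obj <- function(par) {
    nug <- par[1]; psill <- exp(par[2]); rng <- exp(par[3])
    mod <- nug + psill * (1 - exp(-hH / rng))
    sum(nH * (gH - mod)^2 / pmax(mod, 1e-12)^2)
  }
  # multi-start over the range axis: trend-like fields want a very large
  # range (the exponential then acts nearly linearly in h), patchy fields a
  # short one, and the WLS surface has local minima between the two
  best <- NULL
  for (rng0 in max(hH) * c(0.1, 1 / 3, 1, 3, 10)) {
    f <- stats::optim(c(0, log(max(vtot, 1e-8)), log(rng0)), obj,
                      method = "L-BFGS-B",
                      lower = c(0, log(1e-10), log(max(hH) * 1e-3)),
                      upper = c(vtot * 2 + 1e-8, log(vtot * 1e4 + 1e-6),
                                log(max(hH) * 1e3)))
    if (is.null(best) || f$value < best$value) best <- f
  }
  fit <- best
  list(nugget = fit$par[1], psill = exp(fit$par[2]), range = exp(fit$par[3]),
       empirical = data.frame(h = as.numeric(hH), gamma = as.numeric(gH),
                              n = nH))
}

#' Ordinary kriging of a frequency surface
#'
#' Interpolates one value per location (typically an allele frequency) onto
#' a rectangular longitude/latitude grid spanning the sampled extent, using
#' ordinary kriging with an exponential variogram fit by weighted least
#' squares to the empirical variogram. The predictor returns the observed
#' value at every sampling location (exact interpolation), so the density
#' of contour lines between locations reflects the steepness of the
#' interpolated cline.
#'
#' @param values numeric vector, one value per location.
#' @inheritParams greatCircleMatrix
#' @param gridSize c(nx, ny) grid resolution (default 200 x 200).
#' @param nBins bins of the empirical variogram.
#' @return list with `lon`, `lat` (grid axes), `surface` (nx x ny matrix of
#'   predictions), `model` (variogram parameters; NULL for a constant
#'   field), `predict` (function(lon, lat) evaluating the kriging predictor
#'   at arbitrary points).
#' @export
krigeFrequencySurface <- function(values, locations, gridSize = c(200, 200),
                                  nBins = 12) {
  m <- coordsOf(locations)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 locations")
  if (length(values) != n) stop("one value per location required")
  lonAxis <- seq(min(m[, 1]), max(m[, 1]), length.out = gridSize[1])
  latAxis <- seq(min(m[, 2]), max(m[, 2]), length.out = gridSize[2])
  if (stats::var(values) == 0) {               # constant field: flat surface
    flat <- matrix(values[1], gridSize[1], gridSize[2])
    return(list(lon = lonAxis, lat = latAxis, surface = flat, model = NULL,
                predict = function(lon, lat) rep(values[1], length(lon))))
  }
  d <- greatCircleMatrix(as.data.frame(m))
  vg <- fitExponentialVariogram(d, values, nBins)
  Cfun <- function(h) vg$psill * exp(-h / vg$range) + vg$nugget * (h == 0)
  Amat <- rbind(cbind(Cfun(d), 1), c(rep(1, n), 0))
  jitter <- 0
  Afac <- tryCatch(solve(Amat), error = function(e) NULL)
  while (is.null(Afac)) {
    jitter <- if (jitter == 0) 1e-10 else jitter * 100
    if (jitter > 1e-2) stop("kriging system is singular")
    message("krigeFrequencySurface: singular system, adding nugget jitter ",
            jitter)
    Amat[cbind(1:n, 1:n)] <- Cfun(0) + jitter
    Afac <- tryCatch(solve(Amat), error = function(e) NULL)
  }
  predictAt <- function(lon, lat) {
    pts <- cbind(lon, lat)
    d0 <- geosphere::distm(pts, m, fun = function(p1, p2)
      geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000)) / 1000
    rhs <- rbind(t(Cfun(d0)), 1)
    w <- Afac %*% rhs
    drop(crossprod(w[seq_len(n), , drop = FALSE], values))
  }
  grid <- expand.grid(lon = lonAxis, lat = latAxis)
  surface <- matrix(predictAt(grid$lon, grid$lat), gridSize[1], gridSize[2])
  list(lon = lonAxis, lat = latAxis, surface = surface, model = vg,
       predict = predictAt)
}
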