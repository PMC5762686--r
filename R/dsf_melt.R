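#' DSF melt curve container
#'
#' @param temperature strictly increasing temperatures, degrees C.
#' @param rfu relative fluorescence units.
#' @param sample sample label (e.g. `"apo"`, a compound id).
#' @return A `melt_curve` data frame.
#' @export
melt_curve <- function(temperature, rfu, sample = NA_character_) {
  if (length(temperature) != length(rfu)) stop("temperature and rfu must match")
  if (any(diff(temperature) <= 0)) stop("temperatures must be strictly increasing")
  out <- data.frame(temperature_C = temperature, rfu = rfu)
  attr(out, "sample") <- sample
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Melting temperature from the derivative maximum of a DSF curve
#'
#' Tm is the temperature that maximises dRFU/dT: the fluorescence of an
#' environment-sensitive dye rises steepest at the unfolding midpoint. The
#' raw curve is smoothed and differentiated in one pass with a
#' Savitzky-Golay filter (degree-2 polynomial, odd window), and the discrete
#' argmax is refined by a quadratic fit through its three surrounding points
#' so Tm resolution is finer than the instrument's temperature step.
#'
#' A curve with no transition (derivative flat up to noise) yields
#' `no_tm = TRUE`; secondary local derivative maxima above half the main
#' peak are reported informationally in `secondary_tm`.
#'
#' @param curve a [melt_curve()] on a (near-)uniform temperature grid.
#' @param smooth_window odd Savitzky-Golay window length in points (>= 5).
#' @return A `melt_result` list: `tm` (degrees C, NA when `no_tm`), `no_tm`,
#'   `derivative` (data frame `temperature_C`, `drfu_dT`), `secondary_tm`,
#'   `sample`.
#' @export
tm_from_derivative <- function(curve, smooth_window = 7) {
  Tg <- curve$temperature_C
  y <- curve$rfu
  n <- length(Tg)
  if (smooth_window %% 2 != 1 || smooth_window < 5) {
    stop("smooth_window must be odd and at least 5")
  }
  if (n < smooth_window) stop("curve shorter than the smoothing window")
  h <- diff(Tg)
  if (max(h) / min(h) > 1 + 1e-3) {
    stop("temperature grid must be (near-)uniform for derivative filtering")
  }
  d <- signal::sgolayfilt(y, p = 2, n = smooth_window, m = 1, ts = mean(h))
  # drop filter edge points: endpoint derivative rows are poorly conditioned
  edge <- (smooth_window - 1) / 2
  core <- (edge + 1):(n - edge)
  dc <- d[core]
  # flat-curve guard: peak must stand out from the derivative's bulk spread
  spread <- stats::mad(dc)
  prom <- max(dc) - stats::median(dc)
  if (prom <= max(4 * spread, 1e-10 * max(abs(y), 1))) {
    return(structure(list(tm = NA_real_, no_tm = TRUE,
                          derivative = data.frame(temperature_C = Tg, drfu_dT = d),
                          secondary_tm = numeric(0),
                          sample = attr(curve, "sample")),
                     class = "melt_result"))
  }
  i <- core[which.max(dc)]
  tm <- Tg[i]
  # refine below grid resolution: least-squares parabola over the peak's
  # contiguous half-maximum region (a 3-point vertex is too noise-sensitive
  # because the curvature signal at typical ramp steps is small)
  lo <- i; while (lo > 1 && d[lo - 1] >= 0.5 * d[i]) lo <- lo - 1
  hi <- i; while (hi < n && d[hi + 1] >= 0.5 * d[i]) hi <- hi + 1
  idx <- lo:hi
  if (length(idx) >= 3) {
    x <- Tg[idx] - Tg[i]
    cf <- stats::coef(stats::lm(d[idx] ~ x + I(x^2)))
    vertex <- unname(-cf[2] / (2 * cf[3]))
    if (is.finite(vertex) && cf[3] < 0 && abs(vertex) <= max(abs(x))) {
      tm <- Tg[i] + vertex
    }
  }
  # informational secondary transitions: interior local maxima >= half peak
  loc <- which(diff(sign(diff(dc))) == -2) + 1
  sec <- setdiff(loc[dc[loc] >= 0.5 * max(dc)], which.max(dc))
  structure(list(tm = tm, no_tm = FALSE,
                 derivative = data.frame(temperature_C = Tg, drfu_dT = d),
                 secondary_tm = Tg[core][sec],
                 sample = attr(curve, "sample")),
            class = "melt_result")
}

#' Ligand-induced thermal shift
#'
#' @param holo,apo `melt_result` objects from [tm_from_derivative()].
#' @return Tm(holo) - Tm(apo), degrees C.
#' @export
delta_tm <- function(holo, apo) {
  if (holo$no_tm || apo$no_tm) stop("both curves must have a defined Tm")
  holo$tm - apo$tm
}
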