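# Fourier difference maps: observed minus model-calculated structure factors
# over a resolution band, synthesized to real space and sigma-scaled. The
# canonical uses are the hydrogen-omit map (revealing hydrogen densities) and
# the charged-vs-neutral map (revealing charge signals at low resolution).

#' Fourier difference map (Fo - Fc)
#'
#' Computes \eqn{\Delta(h) = w(h) (F_o(h) - F_c(h))} for frequencies inside
#' the band and synthesizes it to real space. The returned map data is in
#' sigma units of the difference map itself (`$sigma_raw` holds the absolute
#' scale). Weighting `"none"` uses w = 1; `"shell_variance"` estimates a
#' per-shell signal/(signal+noise) weight from a half-map pair.
#'
#' @param obs observed data: an `sf_set` or a `potential_map`.
#' @param calc_model the model whose structure factors are subtracted (e.g.
#'   the hydrogen-omitted model).
#' @param band a `resolution_band`.
#' @param weighting `"none"` or `"shell_variance"`.
#' @param halves a `halfmap_pair`, required for `"shell_variance"`.
#' @return object of class `difference_map` (inherits `potential_map`):
#'   sigma-scaled `data`, plus `band`, `sigma_raw` and `provenance`.
#' @export
fourier_difference_map <- function(obs, calc_model, band,
                                   weighting = c("none", "shell_variance"),
                                   halves = NULL) {
  weighting <- match.arg(weighting)
  if (inherits(obs, "potential_map")) obs <- sf_from_map(obs)
  if (!inherits(obs, "sf_set")) stop("obs must be an sf_set or potential_map")
  fc <- structure_factors_from_model(calc_model, obs$voxel,
                                     d_min = band$d_high,
                                     dims = obs$dims, origin = obs$origin)
  if (!identical(dim(obs$F), dim(fc$F)))
    stop("grid mismatch: obs ", paste(dim(obs$F), collapse = "x"),
         " vs calc ", paste(dim(fc$F), collapse = "x"))
  delta <- obs$F - fc$F
  w <- NULL
  if (weighting == "shell_variance") {
    if (is.null(halves)) stop("shell_variance weighting requires a halfmap_pair")
    w <- shell_variance_weights(halves, obs$d_star)
    delta <- delta * w
  }
  sfd <- obs
  sfd$F <- delta
  sfd$d_min <- band$d_high
  m <- synthesize_map(sfd, band)
  as_difference_map(m, band,
                    provenance = list(weighting = weighting,
                                      n_calc_atoms = nrow(calc_model$atoms)))
}

as_difference_map <- function(m, band, provenance = list()) {
  sr <- map_sigma(m)
  if (sr == 0) sr <- 1  # identically zero map: leave data unscaled
  m$data <- m$data / sr
  m$sigma_raw <- sr
  m$band <- band
  m$provenance <- provenance
  class(m) <- c("difference_map", "potential_map")
  m
}

#' Absolute-scale data of a difference map
#' @param dmap a `difference_map` (data in its own sigma units).
#' @return 3D array on the absolute (pre-scaling) scale.
#' @export
difference_map_absolute <- function(dmap) dmap$data * dmap$sigma_raw

# Per-shell w = var_signal / (var_signal + var_noise) estimated from half
# maps: the noise variance of the averaged map is var(F1 - F2)/4 per shell.
shell_variance_weights <- function(halves, d_star) {
  f1 <- sf_from_map(halves$half1)$F
  f2 <- sf_from_map(halves$half2)$F
  dims <- dim(f1)
  shell_w <- 1 / (max(dims) * halves$half1$voxel)
  shell <- pmin(floor(d_star / shell_w), ceiling(max(d_star) / shell_w))
  fmean <- (f1 + f2) / 2
  vn <- tapply(abs(f1 - f2)^2 / 4, shell, mean)
  vo <- tapply(abs(fmean)^2, shell, mean)
  vs <- pmax(vo - vn, 0)
  wshell <- ifelse(vs + vn > 0, vs / (vs + vn), 0)
  array(wshell[as.character(shell)], dim = dims)
}

#' Difference maps over a series of resolution bands
#'
#' One sigma-scaled `difference_map` per band (each map's `sigma_raw` allows
#' recovery of a shared absolute scale via [difference_map_absolute()]).
#'
#' @param obs observed `sf_set` or `potential_map`.
#' @param calc_model model to subtract.
#' @param bands list of `resolution_band`s, e.g. 100-2.5, 20-2.5, ... 2.5-1.19.
#' @param ... passed to [fourier_difference_map()].
#' @return named list of `difference_map`s.
#' @export
resolution_series_maps <- function(obs, calc_model, bands, ...) {
  if (inherits(obs, "potential_map")) obs <- sf_from_map(obs)
  out <- lapply(bands, function(b) fourier_difference_map(obs, calc_model, b, ...))
  names(out) <- vapply(bands, format, "")
  out
}

#' Standard resolution-band series for charge analysis
#'
#' The progression used when attributing negative densities: a fixed
#' high-resolution limit with the low-resolution limit tightened stepwise,
#' plus the complementary high-resolution-only band.
#'
#' @param d_lows low-resolution limits in Angstrom.
#' @param d_high high-resolution limit of the series.
#' @param d_min map resolution for the final complementary band (NULL skips it).
#' @return list of `resolution_band`s.
#' @export
charge_band_series <- function(d_lows = c(100, 20, 10, 5, 3.3), d_high = 2.5,
                               d_min = 1.19) {
  bands <- lapply(d_lows, resolution_band, d_high = d_high)
  if (!is.null(d_min)) bands <- c(bands, list(resolution_band(d_high, d_min)))
  bands
}
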