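# Coulomb potential maps on a node-centered voxel grid. Grid node (i, j, k)
# (0-based) sits at origin + (i, j, k) * voxel; the box is periodic, matching
# the discrete Fourier conventions used throughout.

#' Potential map
#'
#' @param data 3D numeric array of map values.
#' @param voxel_size isotropic voxel size in Angstrom.
#' @param origin box-corner offset in Angstrom (length 3).
#' @return object of class `potential_map`.
#' @export
potential_map <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, voxel_size > 0, length(origin) == 3)
  structure(list(data = data, voxel = voxel_size, origin = as.numeric(origin)),
            class = "potential_map")
}

#' @export
print.potential_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s: %d x %d x %d voxels at %.4f A, sigma = %.4g\n",
              class(x)[1], d[1], d[2], d[3], x$voxel, map_sigma(x)))
  invisible(x)
}

#' Map sigma (RMS deviation from the mean)
#'
#' The contouring unit for density levels: the root-mean-square deviation of
#' the map about its mean, taken over all voxels of the box with no mask.
#'
#' @param map a `potential_map` or a 3D array.
#' @return sigma in map units.
#' @export
map_sigma <- function(map) {
  v <- if (is.list(map)) map$data else map
  sqrt(mean((v - mean(v))^2))
}

#' Resolution band
#'
#' A spatial-frequency band given as a resolution range, low to high. The
#' band is half-open in frequency: coefficients with
#' \eqn{1/d_{low} \le |h| < 1/d_{high}} are included. A `d_low` of 100 or
#' more is treated as "all low frequencies except the F(0) term", which is
#' always excluded so that band-limited maps have zero mean.
#'
#' @param d_low low-resolution (large d) limit in Angstrom.
#' @param d_high high-resolution (small d) limit in Angstrom.
#' @return object of class `resolution_band`.
#' @export
resolution_band <- function(d_low, d_high) {
  stopifnot(d_low > d_high, d_high > 0)
  structure(list(d_low = d_low, d_high = d_high), class = "resolution_band")
}

#' @export
format.resolution_band <- function(x, ...)
  sprintf("%g-%g A", x$d_low, x$d_high)

# Integer FFT frequencies for axis length n: 0, 1, ..., then negative.
fft_freq_int <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k)
}

# Smallest size >= n whose prime factors are all in {2, 3, 5}.
good_fft_size <- function(n) {
  ok <- function(m) {
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!ok(n)) n <- n + 1
  n
}

# |h| in 1/Angstrom on the reciprocal grid (3D array).
d_star_grid <- function(dims, voxel) {
  q1 <- fft_freq_int(dims[1]) / (dims[1] * voxel)
  q2 <- fft_freq_int(dims[2]) / (dims[2] * voxel)
  q3 <- fft_freq_int(dims[3]) / (dims[3] * voxel)
  sqrt(outer(outer(q1^2, q2^2, "+"), q3^2, "+"))
}

# Logical array: TRUE on Nyquist planes (even axis length only), where the
# discrete transform cannot represent a conjugate-symmetric pair.
nyquist_mask <- function(dims) {
  ny <- function(n) {
    k <- 0:(n - 1)
    if (n %% 2 == 0) k == n / 2 else rep(FALSE, n)
  }
  outer(outer(ny(dims[1]), ny(dims[2]), "|"), ny(dims[3]), "|")
}

band_selection <- function(d_star, band) {
  lo <- if (band$d_low >= 100) 0 else 1 / band$d_low
  hi <- 1 / band$d_high
  d_star >= lo & d_star < hi & d_star > 0
}

#' Synthesize a band-limited real-space map from structure factors
#'
#' Coefficients outside the band (and the F(0) term) are zeroed, then the
#' grid is inverse Fourier transformed. The result is real up to numerical
#' tolerance; its sigma is computed over all voxels.
#'
#' @param sf a `sf_set` from [structure_factors_from_model()] or
#'   [sf_from_map()].
#' @param band a `resolution_band`.
#' @return a `potential_map` with the band recorded in `$band`.
#' @export
synthesize_map <- function(sf, band) {
  sel <- band_selection(sf$d_star, band)
  if (!any(sel)) stop("empty band ", format(band), ": no coefficients survive")
  Fb <- array(0 + 0i, dim = sf$dims)
  Fb[sel] <- sf$F[sel]
  m <- stats::fft(Fb) / length(Fb)
  im <- max(abs(Im(m)))
  re <- max(abs(Re(m)))
  if (im > 1e-6 * max(re, .Machine$double.eps))
    warning("non-negligible imaginary component after synthesis: ",
            format(im / re))
  out <- potential_map(Re(m), sf$voxel, sf$origin)
  out$band <- band
  out
}

#' Simulate a band-limited Coulomb potential map from a model
#'
#' Composition of [structure_factors_from_model()] and [synthesize_map()];
#' deterministic for fixed inputs.
#'
#' @param model an `atomic_model`.
#' @param voxel_size voxel size in Angstrom (default `band$d_high / 4` for
#'   sub-voxel peak interpolation accuracy).
#' @param band a `resolution_band`; its `d_high` sets the resolution cutoff.
#' @return a `potential_map`.
#' @export
simulate_coulomb_map <- function(model, voxel_size = NULL, band) {
  if (is.null(voxel_size)) voxel_size <- band$d_high / 4
  sf <- structure_factors_from_model(model, voxel_size, d_min = band$d_high)
  synthesize_map(sf, band)
}

#' Interpolated map value at arbitrary positions
#'
#' Trilinear interpolation on the periodic grid.
#'
#' @param map a `potential_map`.
#' @param pos n x 3 matrix (or length-3 vector) of positions in Angstrom.
#' @return numeric vector of interpolated values.
#' @export
map_value_at <- function(map, pos) {
  pos <- matrix(pos, ncol = 3)
  dims <- dim(map$data)
  u <- sweep(pos, 2, map$origin) / map$voxel
  i0 <- floor(u)
  fr <- u - i0
  val <- numeric(nrow(pos))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ii <- cbind((i0[, 1] + dx) %% dims[1] + 1,
                (i0[, 2] + dy) %% dims[2] + 1,
                (i0[, 3] + dz) %% dims[3] + 1)
    val <- val + w * map$data[ii]
  }
  val
}
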