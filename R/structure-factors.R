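# Structure factors from an atomic model on the reciprocal grid of a chosen
# voxel sampling:
#
#   F(h) = sum_j occ_j f_j(s_h) exp(-B_j d*^2 / 4) exp(2 pi i h . u_j)
#
# with f_j the electron scattering factor of atom j's species (element plus
# fractional charge), d* = |h| in 1/Angstrom, s = d*/2, and u_j the
# fractional position in the periodic grid box. Both the Debye-Waller factor
# and the phase factorize along the three axes, so the sum is evaluated with
# per-axis vectors rather than a full triple loop.

#' Structure factors from an atomic model
#'
#' @param model an `atomic_model`.
#' @param voxel_size target voxel size in Angstrom; must satisfy the Nyquist
#'   bound `voxel_size <= d_min / 2`.
#' @param d_min resolution cutoff in Angstrom; coefficients beyond `1/d_min`
#'   are zero.
#' @param dims optional grid dimensions; derived from the model cell when
#'   NULL (rounded up to FFT-friendly sizes, so the grid box may slightly
#'   exceed the model cell).
#' @param origin grid box corner (defaults to the model origin).
#' @return object of class `sf_set`: complex coefficient array `F`, `dims`,
#'   `voxel`, `origin`, `d_min` and the `d_star` grid.
#' @export
structure_factors_from_model <- function(model, voxel_size, d_min,
                                         dims = NULL, origin = NULL) {
  if (nrow(model$atoms) == 0) stop("model has no atoms")
  if (voxel_size > d_min / 2 + 1e-12)
    stop("voxel_size ", voxel_size, " too coarse for d_min ", d_min,
         ": Nyquist requires voxel_size <= d_min/2 = ", d_min / 2)
  if (is.null(origin)) origin <- model$origin
  if (is.null(dims))
    dims <- vapply(ceiling(model$cell / voxel_size), good_fft_size, 1)
  dims <- as.integer(dims)

  a <- model$atoms
  xyz <- coords(model)
  u <- sweep(xyz, 2, origin)
  box <- dims * voxel_size

  ds <- d_star_grid(dims, voxel_size)
  keep <- ds <= 1 / d_min & !nyquist_mask(dims)
  idx <- which(keep)
  sub <- arrayInd(idx, dims)
  s <- ds[idx] / 2

  # scattering factor per unique species on the masked frequency subset;
  # charged species have no finite f at s = 0, but F(0) is never used in
  # synthesis, so the s = 0 term of a charged atom is set to zero
  key <- paste(a$element, a$charge)
  ftab <- lapply(split(seq_len(nrow(a)), key), function(rows) {
    el <- a$element[rows[1]]; q <- a$charge[rows[1]]
    f <- numeric(length(s))
    pos <- s > 0
    f[pos] <- electron_ff(el, s[pos], q)
    f[!pos] <- if (q == 0) electron_ff(el, 0, 0) else 0
    f
  })

  h1 <- fft_freq_int(dims[1]); h2 <- fft_freq_int(dims[2]); h3 <- fft_freq_int(dims[3])
  q1sq <- (h1 / box[1])^2; q2sq <- (h2 / box[2])^2; q3sq <- (h3 / box[3])^2

  Fv <- complex(length(idx))
  for (j in seq_len(nrow(a))) {
    c1 <- exp(complex(real = -a$b[j] * q1sq / 4,
                      imaginary = 2 * pi * h1 * u[j, 1] / box[1]))
    c2 <- exp(complex(real = -a$b[j] * q2sq / 4,
                      imaginary = 2 * pi * h2 * u[j, 2] / box[2]))
    c3 <- exp(complex(real = -a$b[j] * q3sq / 4,
                      imaginary = 2 * pi * h3 * u[j, 3] / box[3]))
    Fv <- Fv + (a$occ[j] * ftab[[key[j]]]) *
      (c1[sub[, 1]] * c2[sub[, 2]] * c3[sub[, 3]])
  }
  Farr <- array(0 + 0i, dim = dims)
  Farr[idx] <- Fv
  structure(list(F = Farr, dims = dims, voxel = voxel_size,
                 origin = as.numeric(origin), d_min = d_min, d_star = ds),
            class = "sf_set")
}

#' @export
print.sf_set <- function(x, ...) {
  cat(sprintf("structure factor set: %d x %d x %d grid, voxel %.4f A, d_min %s A\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel,
              ifelse(is.na(x$d_min), "none", format(x$d_min))))
  invisible(x)
}

#' Structure factors of an existing map
#'
#' Forward transform of a real-space map, inverse to [synthesize_map()]:
#' synthesizing the full band of the returned set reproduces the map.
#'
#' @param map a `potential_map`.
#' @return an `sf_set` (d_min is NA: the full grid transform).
#' @export
sf_from_map <- function(map) {
  dims <- dim(map$data)
  Farr <- stats::fft(map$data, inverse = TRUE)
  structure(list(F = Farr, dims = dims, voxel = map$voxel,
                 origin = map$origin, d_min = NA_real_,
                 d_star = d_star_grid(dims, map$voxel)),
            class = "sf_set")
}
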