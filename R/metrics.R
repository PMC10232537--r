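# Model-precision and bookkeeping metrics: coordinate RMSD between models,
# a deterministic local refit of a model into a map (the desk-scale stand-in
# for independent restrained refinement against each half map), the
# half-map model-precision metric derived from it, Fourier shell
# correlation, and dose / pixel-rescaling arithmetic.

#' RMSD between two models
#'
#' Root-mean-square coordinate deviation over matched atoms. Atoms are
#' matched by (residue number, atom name); no superposition is applied, as
#' both models are assumed to share the map coordinate frame.
#'
#' @param a,b `atomic_model`s.
#' @param selection `"heavy"` (non-hydrogen, default), `"all"`, or a
#'   predicate `function(atoms) -> logical` applied to `a`.
#' @return RMSD in Angstrom.
#' @export
rmsd_between_models <- function(a, b, selection = "heavy") {
  sel <- function(atoms) {
    if (is.function(selection)) selection(atoms)
    else if (identical(selection, "all")) rep(TRUE, nrow(atoms))
    else atoms$element != "H"
  }
  aa <- a$atoms[sel(a$atoms), , drop = FALSE]
  ba <- b$atoms[sel(b$atoms), , drop = FALSE]
  ka <- paste(aa$resno, aa$atom)
  kb <- paste(ba$resno, ba$atom)
  m <- match(ka, kb)
  if (anyNA(m))
    stop("atoms unmatched in second model: ",
         paste(utils::head(ka[is.na(m)], 10), collapse = ", "))
  if (any(!(kb %in% ka)))
    stop("atoms unmatched in first model: ",
         paste(utils::head(kb[!(kb %in% ka)], 10), collapse = ", "))
  d2 <- rowSums((as.matrix(aa[, c("x", "y", "z")]) -
                 as.matrix(ba[m, c("x", "y", "z")]))^2)
  sqrt(mean(d2))
}

# Trigonometric (Fourier) interpolant of a map with analytic gradient and
# Hessian: the natural continuous extension of a band-limited grid.
fourier_interpolant <- function(map) {
  dims <- dim(map$data)
  Fmat <- matrix(stats::fft(map$data, inverse = TRUE), dims[1],
                 dims[2] * dims[3])
  box <- dims * map$voxel
  h1 <- fft_freq_int(dims[1]); h2 <- fft_freq_int(dims[2]); h3 <- fft_freq_int(dims[3])
  k1 <- -2i * pi * h1 / box[1]; k2 <- -2i * pi * h2 / box[2]
  k3 <- -2i * pi * h3 / box[3]
  N <- prod(dims)
  function(r) {
    u <- (r - map$origin) / box
    e1 <- exp(-2i * pi * h1 * u[1])
    e2 <- exp(-2i * pi * h2 * u[2])
    e3 <- exp(-2i * pi * h3 * u[3])
    A0 <- matrix(e1 %*% Fmat, dims[2], dims[3])
    A1 <- matrix((e1 * k1) %*% Fmat, dims[2], dims[3])
    A2 <- matrix((e1 * k1^2) %*% Fmat, dims[2], dims[3])
    b00 <- drop(e2 %*% A0); b01 <- drop((e2 * k2) %*% A0)
    b02 <- drop((e2 * k2^2) %*% A0); b10 <- drop(e2 %*% A1)
    b11 <- drop((e2 * k2) %*% A1); b20 <- drop(e2 %*% A2)
    re <- function(z) Re(z) / N
    val <- re(sum(b00 * e3))
    g <- c(re(sum(b10 * e3)), re(sum(b01 * e3)), re(sum(b00 * (e3 * k3))))
    H <- matrix(c(re(sum(b20 * e3)), re(sum(b11 * e3)), re(sum(b10 * (e3 * k3))),
                  re(sum(b11 * e3)), re(sum(b02 * e3)), re(sum(b01 * (e3 * k3))),
                  re(sum(b10 * (e3 * k3))), re(sum(b01 * (e3 * k3))),
                  re(sum(b00 * (e3 * k3^2)))), 3, 3)
    list(value = val, grad = g, hess = H)
  }
}

#' Local density-maximum refit of a model into a map
#'
#' Moves each non-hydrogen site to the local maximum of the Fourier
#' interpolated density within `max_shift` of its starting position, by
#' damped Newton ascent with step capping. Deterministic for fixed inputs.
#' This is a desk-scale surrogate for independent restrained refinement
#' against a half map: it preserves the logic of fitting the same model
#' independently to independent noise realizations. Sites in locally flat
#' density are left unmoved and flagged.
#'
#' @param model an `atomic_model`.
#' @param half a `potential_map`.
#' @param max_shift maximum displacement per site in Angstrom.
#' @return the refitted `atomic_model`, with a data.frame of per-site shifts
#'   and flags in attribute `"refit"`.
#' @export
halfmap_local_refit <- function(model, half, max_shift = 0.5) {
  stopifnot(max_shift >= 0)
  out <- model
  if (max_shift == 0) {
    attr(out, "refit") <- data.frame(site = integer(0))
    return(out)
  }
  interp <- fourier_interpolant(half)
  sigma <- map_sigma(half)
  a <- model$atoms
  heavy <- which(a$element != "H")
  info <- data.frame(site = heavy, shift = 0, flat = FALSE, iterations = 0L)
  step_cap <- half$voxel / 2
  gscale <- max(sigma, .Machine$double.xmin) / half$voxel
  gtol <- 1e-6 * gscale
  for (r in seq_along(heavy)) {
    j <- heavy[r]
    r0 <- as.numeric(a[j, c("x", "y", "z")])
    pos <- r0
    fe <- interp(pos)
    if (sqrt(sum(fe$grad^2)) <= 1e-8 * gscale &&
        max(abs(fe$hess)) <= 1e-8 * gscale / half$voxel) {
      info$flat[r] <- TRUE
      next
    }
    it <- 0
    repeat {
      it <- it + 1
      gn <- sqrt(sum(fe$grad^2))
      if (gn <= gtol || it > 50) break
      ev <- eigen(fe$hess, symmetric = TRUE, only.values = TRUE)$values
      step <- if (all(ev < 0)) solve(fe$hess, -fe$grad) else fe$grad / gn * step_cap
      sn <- sqrt(sum(step^2))
      if (sn > step_cap) step <- step * step_cap / sn
      # backtracking: accept only value increases within the max_shift ball
      t <- 1
      repeat {
        cand <- pos + t * step
        excess <- sqrt(sum((cand - r0)^2))
        if (excess > max_shift) cand <- r0 + (cand - r0) * max_shift / excess
        fc <- interp(cand)
        if (fc$value > fe$value || t < 1e-3) break
        t <- t / 2
      }
      moved <- sqrt(sum((cand - pos)^2))
      if (fc$value <= fe$value) break  # pinned at the shift bound or stuck
      pos <- cand
      fe <- fc
      if (moved < 1e-6) break
    }
    info$shift[r] <- sqrt(sum((pos - r0)^2))
    info$iterations[r] <- it
    out$atoms[j, c("x", "y", "z")] <- pos
  }
  attr(out, "refit") <- info
  out
}

#' Half-map model precision (RMSD between half-map refits)
#'
#' Refits the model independently into each half map and reports the RMSD
#' between the two refitted models: an estimate of the coordinate
#' uncertainty contributed by reconstruction noise. Zero for identical
#' halves; grows with half-map noise.
#'
#' @param model an `atomic_model`.
#' @param halves a `halfmap_pair`.
#' @param max_shift per-site refit bound in Angstrom.
#' @param selection passed to [rmsd_between_models()] (default non-hydrogen).
#' @return list with `rmsd` (Angstrom), the two refitted models, and a
#'   per-element breakdown data.frame.
#' @export
rmsd_half <- function(model, halves, max_shift = 0.5, selection = "heavy") {
  m1 <- halfmap_local_refit(model, halves$half1, max_shift)
  m2 <- halfmap_local_refit(model, halves$half2, max_shift)
  overall <- rmsd_between_models(m1, m2, selection)
  a1 <- m1$atoms[m1$atoms$element != "H", ]
  a2 <- m2$atoms[m2$atoms$element != "H", ]
  d2 <- rowSums((as.matrix(a1[, c("x", "y", "z")]) -
                 as.matrix(a2[, c("x", "y", "z")]))^2)
  per <- do.call(rbind, lapply(split(d2, a1$element), function(v)
    data.frame(rmsd = sqrt(mean(v)), n = length(v))))
  per$element <- rownames(per); rownames(per) <- NULL
  list(rmsd = overall, model1 = m1, model2 = m2,
       per_element = per[, c("element", "rmsd", "n")])
}

#' Fourier shell correlation between half maps
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of the
#' two halves (the F(0) term excluded).
#'
#' @param halves a `halfmap_pair`.
#' @param shell_width shell width in 1/Angstrom (default: one reciprocal
#'   voxel of the longest axis).
#' @return data.frame with `d_star` (shell center, 1/Angstrom), `d`
#'   (Angstrom), `fsc`, `n` (coefficients per shell).
#' @export
fsc_curve <- function(halves, shell_width = NULL) {
  f1 <- sf_from_map(halves$half1)
  f2 <- sf_from_map(halves$half2)
  dims <- dim(f1$F)
  if (is.null(shell_width)) shell_width <- 1 / (max(dims) * halves$half1$voxel)
  ds <- f1$d_star
  dmax <- 1 / (2 * halves$half1$voxel)  # Nyquist of the sampling
  sel <- ds > 0 & ds <= dmax & !nyquist_mask(dims)
  shell <- floor(ds[sel] / shell_width)
  x <- f1$F[sel]; y <- f2$F[sel]
  num <- tapply(Re(x * Conj(y)), shell, sum)
  dx <- tapply(abs(x)^2, shell, sum)
  dy <- tapply(abs(y)^2, shell, sum)
  n <- tapply(shell, shell, length)
  ok <- dx > 0 & dy > 0  # shells with no power carry no correlation
  if (sum(ok) < 3) stop("too few shells for an FSC curve")
  sh <- as.numeric(names(num))[ok]
  data.frame(d_star = (sh + 0.5) * shell_width,
             d = 1 / ((sh + 0.5) * shell_width),
             fsc = as.numeric((num / sqrt(dx * dy))[ok]), n = as.numeric(n[ok]))
}

#' Resolution at an FSC threshold
#'
#' First crossing of the FSC curve below the threshold, located by linear
#' interpolation between shell centers. The gold-standard half-map threshold
#' is 0.143.
#'
#' @param fsc data.frame from [fsc_curve()].
#' @param threshold FSC threshold.
#' @return resolution d in Angstrom (NA with a warning if the curve never
#'   falls below the threshold).
#' @export
resolution_at <- function(fsc, threshold = 0.143) {
  below <- which(fsc$fsc < threshold)
  if (!length(below)) {
    warning("FSC never falls below ", threshold, " within the sampled shells")
    return(NA_real_)
  }
  i <- below[1]
  if (i == 1) return(fsc$d[1])
  x0 <- fsc$d_star[i - 1]; x1 <- fsc$d_star[i]
  y0 <- fsc$fsc[i - 1]; y1 <- fsc$fsc[i]
  xc <- x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
  1 / xc
}

#' Dose specification
#'
#' @param dose_rate electrons per second per physical pixel.
#' @param frame_time seconds per movie frame.
#' @param n_frames number of summed frames (>= 0).
#' @param pixel_size physical pixel size in Angstrom.
#' @return object of class `dose_spec`.
#' @export
dose_spec <- function(dose_rate, frame_time, n_frames, pixel_size) {
  if (dose_rate <= 0 || frame_time <= 0 || pixel_size <= 0 || n_frames < 0)
    stop("dose_rate, frame_time, pixel_size must be positive; n_frames >= 0")
  structure(list(dose_rate = dose_rate, frame_time = frame_time,
                 n_frames = n_frames, pixel_size = pixel_size),
            class = "dose_spec")
}

#' Total electron dose
#'
#' dose_rate x frame_time x n_frames / pixel_size^2, in electrons per
#' square Angstrom.
#'
#' @param spec a `dose_spec`.
#' @return dose in e-/A^2.
#' @export
electron_dose <- function(spec) {
  spec$dose_rate * spec$frame_time * spec$n_frames / spec$pixel_size^2
}

#' Pixel size after box rescaling
#'
#' Re-extracting particles in a different box while keeping the same
#' physical extent rescales the pixel: box_in x pixel_in / box_out.
#'
#' @param box_in input box size in pixels.
#' @param pixel_in input pixel size in Angstrom.
#' @param box_out output box size in pixels.
#' @return output pixel size in Angstrom.
#' @export
rescaled_pixel_size <- function(box_in, pixel_in, box_out) {
  if (box_in <= 0 || box_out <= 0 || pixel_in <= 0)
    stop("box sizes and pixel size must be positive")
  box_in * pixel_in / box_out
}
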