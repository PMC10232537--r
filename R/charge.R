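# Quantification of charge-related negative densities around selected atoms
# across resolution bands and dose series, and the partial-charge
# difference-map simulation.

#' Negative-density metrics around atoms
#'
#' For each atom: the minimum map value within `radius`, the integral of
#' values at or below `-level` within `radius` (sigma times voxel volume
#' units), and the interpolated map value at the atom position.
#'
#' @param map a `difference_map` (sigma units) or `potential_map` (scaled by
#'   its own sigma).
#' @param model an `atomic_model`.
#' @param atoms integer indices of atoms in `model`.
#' @param radius sphere radius in Angstrom (default 1.0).
#' @param level sigma level defining "negative density" (default 4).
#' @return data.frame with one row per atom: `atom`, `residue`, `resno`,
#'   `min_density`, `integrated_negative`, `value_at_atom`.
#' @export
negative_density_metric <- function(map, model, atoms, radius = 1.0, level = 4) {
  stopifnot(radius > 0, level > 0)
  v <- map$data
  if (!inherits(map, "difference_map")) v <- v / map_sigma(map)
  dims <- dim(v)
  vox <- map$voxel
  a <- model$atoms
  box <- dims * vox
  out <- list()
  smap <- map; smap$data <- v
  for (ai in atoms) {
    pos <- as.numeric(a[ai, c("x", "y", "z")])
    rel <- pos - map$origin
    if (any(rel < 0) || any(rel > box))
      stop("atom ", a$atom[ai], " ", a$resno[ai], " lies outside the map box")
    ctr <- rel / vox
    rng <- lapply(1:3, function(k) {
      lo <- floor(ctr[k] - radius / vox); hi <- ceiling(ctr[k] + radius / vox)
      (lo:hi) %% dims[k]  # periodic, 0-based
    })
    g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
    # distances with periodic wrap relative to atom position
    dd <- function(idx0, c0, n) {
      d <- (idx0 - c0) %% n
      pmin(d, n - d) * vox
    }
    r2 <- dd(g$i, ctr[1], dims[1])^2 + dd(g$j, ctr[2], dims[2])^2 +
          dd(g$k, ctr[3], dims[3])^2
    inside <- r2 <= radius^2
    vals <- v[cbind(g$i + 1L, g$j + 1L, g$k + 1L)][inside]
    va <- map_value_at(smap, pos)
    out[[length(out) + 1]] <- data.frame(
      atom = a$atom[ai], residue = a$residue[ai], resno = a$resno[ai],
      min_density = if (length(vals)) min(vals) else va,
      integrated_negative = sum(vals[vals <= -level]) * vox^3,
      value_at_atom = va)
  }
  do.call(rbind, out)
}

#' Simulated partial-charge difference maps
#'
#' Builds the charged and all-neutral variants of a model, subtracts the
#' neutral structure factors from the charged ones and synthesizes the
#' difference per band. By linearity the difference involves only the
#' charged atoms, so only their scattering contributions are computed. The
#' returned maps are sigma-scaled `difference_map`s (absolute scale via
#' [difference_map_absolute()]).
#'
#' @param model an `atomic_model`.
#' @param charged_atom_ids indices of atoms to charge.
#' @param q fractional charge in \[-1, 1\].
#' @param bands list of `resolution_band`s.
#' @param voxel_size voxel size in Angstrom (default: finest band d_high / 4).
#' @return named list of `difference_map`s.
#' @export
simulate_partial_charge_difference <- function(model, charged_atom_ids, q,
                                               bands, voxel_size = NULL) {
  if (abs(q) > 1) stop("|q| must be <= 1")
  d_min <- min(vapply(bands, function(b) b$d_high, 1))
  if (is.null(voxel_size)) voxel_size <- d_min / 4
  sub <- model
  sub$atoms <- model$atoms[charged_atom_ids, , drop = FALSE]
  sub$bonds <- matrix(integer(0), ncol = 2)
  # grid must match the full model's default grid
  dims <- vapply(ceiling(model$cell / voxel_size), good_fft_size, 1)
  f_neu <- structure_factors_from_model(sub, voxel_size, d_min, dims = dims,
                                        origin = model$origin)
  sub$atoms$charge <- q
  f_chg <- structure_factors_from_model(sub, voxel_size, d_min, dims = dims,
                                        origin = model$origin)
  sfd <- f_chg
  sfd$F <- f_chg$F - f_neu$F
  out <- lapply(bands, function(b)
    as_difference_map(synthesize_map(sfd, b), b,
                      provenance = list(q = q, atoms = charged_atom_ids)))
  names(out) <- vapply(bands, format, "")
  out
}

#' Charge-signal trends across a map series
#'
#' Applies [negative_density_metric()] to each map of a resolution or dose
#' series and summarizes, per atom, whether the magnitude of the minimum
#' density is monotone non-increasing along the series.
#'
#' @param maps list of `difference_map`s on the same grid.
#' @param model an `atomic_model`.
#' @param atoms atom indices.
#' @param radius,level as in [negative_density_metric()].
#' @param absolute use the shared absolute scale instead of per-map sigma
#'   units (recommended when comparing across bands).
#' @return list with `signals` (data.frame, one row per map x atom) and
#'   `monotone` (data.frame per atom).
#' @export
map_series_analysis <- function(maps, model, atoms, radius = 1.0, level = 4,
                                absolute = FALSE) {
  dims <- dim(maps[[1]]$data)
  ids <- names(maps)
  if (is.null(ids)) ids <- as.character(seq_along(maps))
  rows <- list()
  for (m in seq_along(maps)) {
    mp <- maps[[m]]
    if (!identical(dim(mp$data), dims))
      stop("grid mismatch within map series: ",
           paste(dim(mp$data), collapse = "x"), " vs ",
           paste(dims, collapse = "x"))
    if (absolute) {
      mp$data <- difference_map_absolute(mp)
      class(mp) <- class(maps[[m]])  # keep sigma-unit semantics off
    }
    sig <- negative_density_metric(mp, model, atoms, radius, level)
    sig$map <- ids[m]
    rows[[m]] <- sig
  }
  signals <- do.call(rbind, rows)
  mono <- do.call(rbind, lapply(split(signals, list(signals$atom, signals$resno),
                                      drop = TRUE), function(g) {
    g <- g[match(ids, g$map), ]
    data.frame(atom = g$atom[1], resno = g$resno[1],
               monotone_nonincreasing = all(diff(abs(g$min_density)) <= 1e-9))
  }))
  rownames(mono) <- NULL
  list(signals = signals, monotone = mono)
}
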