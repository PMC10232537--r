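# Density peak detection with sub-voxel interpolation, assignment of peaks
# to riding-hydrogen sites, and per-bond-type distance statistics.

# Least-squares design for the full 3D quadratic on the 3x3x3 neighborhood:
# value ~ 1 + x + y + z + x^2 + y^2 + z^2 + xy + xz + yz.
quad27_pinv <- local({
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  X <- with(g, cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z))
  P <- solve(t(X) %*% X) %*% t(X)
  list(P = P)
})

# Sub-voxel offset and interpolated height from a 27-vector of neighborhood
# values (grid order: x fastest). Newton step on the fitted quadratic,
# clamped to half a voxel per axis.
quad27_refine <- function(v27) {
  beta <- drop(quad27_pinv$P %*% v27)
  g <- beta[2:4]
  H <- matrix(c(2 * beta[5], beta[8], beta[9],
                beta[8], 2 * beta[6], beta[10],
                beta[9], beta[10], 2 * beta[7]), 3, 3)
  off <- tryCatch(solve(H, -g), error = function(e) c(0, 0, 0))
  off <- pmax(pmin(off, 0.5), -0.5)
  h <- beta[1] + sum(g * off) + 0.5 * sum(off * (H %*% off))
  list(offset = off, height = h)
}

#' Find density peaks
#'
#' Local maxima over the 26-neighborhood with value at or above the
#' threshold, refined to sub-voxel positions by 3D quadratic interpolation of
#' the 3x3x3 neighborhood. For a `difference_map` the data (and threshold)
#' are already in sigma units; a plain `potential_map` is thresholded in
#' units of its own sigma. Border voxels are not considered.
#'
#' @param map a `potential_map` or `difference_map`.
#' @param threshold detection level in sigma units (> 0).
#' @return data.frame of peaks sorted by height (sigma units), with columns
#'   `x`, `y`, `z` (Angstrom), `height`, and grid indices `i`, `j`, `k`.
#' @export
find_peaks <- function(map, threshold) {
  stopifnot(threshold > 0)
  v <- map$data
  if (!inherits(map, "difference_map")) v <- v / map_sigma(map)
  d <- dim(v)
  if (any(d < 3)) stop("map too small for peak detection")
  core <- v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  ismax <- core >= threshold
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- v[2:(d[1] - 1) + dx, 2:(d[2] - 1) + dy, 2:(d[3] - 1) + dz]
    ismax <- ismax & (core > nb | (core == nb & (dx > 0 | (dx == 0 & (dy > 0 | (dy == 0 & dz > 0))))))
    if (!any(ismax)) break
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      height = numeric(0), i = integer(0), j = integer(0),
                      k = integer(0)))
  idx <- idx + 1L  # back to full-array indices
  res <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    v27 <- as.vector(v[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])
    q <- quad27_refine(v27)
    c(i + q$offset[1], j + q$offset[2], k + q$offset[3], q$height)
  })
  res <- do.call(rbind, res)
  out <- data.frame(
    x = map$origin[1] + (res[, 1] - 1) * map$voxel,
    y = map$origin[2] + (res[, 2] - 1) * map$voxel,
    z = map$origin[3] + (res[, 3] - 1) * map$voxel,
    height = res[, 4], i = idx[, 1], j = idx[, 2], k = idx[, 3])
  out <- out[out$height >= threshold, , drop = FALSE]
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign difference-map peaks to riding-hydrogen sites
#'
#' Each peak is matched to the nearest ideal riding-hydrogen position within
#' `max_offset`, greedily in order of decreasing peak height, one peak per
#' hydrogen site. This deterministic rule replaces manual selection of peaks
#' by riding position. The recorded distance is from the refined peak
#' position to the parent heavy atom.
#'
#' @param peaks data.frame from [find_peaks()].
#' @param model an `atomic_model` whose hydrogens are at ideal riding
#'   positions (see [add_riding_hydrogens()]).
#' @param max_offset maximum peak-to-riding-site distance in Angstrom.
#' @return list with `assignments` (data.frame: peak position and height,
#'   hydrogen atom/residue labels, bond class, `excluded` flag, peak-to-site
#'   `offset` and peak-to-parent `distance`, parent B-factor) and
#'   `unassigned` (peaks with no site within `max_offset`).
#' @export
assign_hydrogen_peaks <- function(peaks, model, max_offset = 0.5) {
  a <- model$atoms
  hidx <- which(a$element == "H")
  if (!length(hidx)) stop("model has no hydrogens; add riding hydrogens first")
  hpos <- as.matrix(a[hidx, c("x", "y", "z")])
  used <- rep(FALSE, length(hidx))
  rows <- list()
  unassigned <- integer(0)
  for (r in seq_len(nrow(peaks))) {
    p <- as.numeric(peaks[r, c("x", "y", "z")])
    d2 <- colSums((t(hpos) - p)^2)
    d2[used] <- Inf
    jm <- which.min(d2)
    if (!length(jm) || sqrt(d2[jm]) > max_offset) {
      unassigned <- c(unassigned, r)
      next
    }
    used[jm] <- TRUE
    hj <- hidx[jm]
    par <- a$parent[hj]
    ppos <- as.numeric(a[par, c("x", "y", "z")])
    rows[[length(rows) + 1]] <- data.frame(
      x = p[1], y = p[2], z = p[3], height = peaks$height[r],
      h_atom = a$atom[hj], residue = a$residue[hj], resno = a$resno[hj],
      parent_atom = a$atom[par], bond_type = a$h_class[hj],
      excluded = a$excluded[hj],
      offset = sqrt(d2[jm]), distance = sqrt(sum((p - ppos)^2)),
      parent_b = a$b[par])
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               height = numeric(0), h_atom = character(0),
               residue = character(0), resno = integer(0),
               parent_atom = character(0), bond_type = character(0),
               excluded = logical(0), offset = numeric(0),
               distance = numeric(0), parent_b = numeric(0))
  list(assignments = assignments,
       unassigned = peaks[unassigned, , drop = FALSE])
}

#' Per-bond-type hydrogen distance statistics
#'
#' Mean and sample standard deviation of the peak-to-parent distance per
#' bond type at each detection threshold, in the style of a
#' distances-by-bond-type summary table. The aggregate class `C-H` is the
#' union of `Calk-H` and `Caro-H`. Assignments flagged `excluded` (lysine
#' side-chain amines, water) are left out. The sd is reported only for
#' n >= 2.
#'
#' @param assignments data.frame from [assign_hydrogen_peaks()].
#' @param thresholds sigma levels (peak height cutoffs), default c(2, 4).
#' @return data.frame with columns `bond_type`, `threshold`, `mean`, `sd`, `n`.
#' @export
bond_length_statistics <- function(assignments, thresholds = c(2, 4)) {
  asn <- assignments[!assignments$excluded, , drop = FALSE]
  out <- list()
  for (thr in thresholds) {
    sel <- asn[asn$height >= thr, , drop = FALSE]
    for (cls in bond_type_classes()) {
      d <- if (cls == "C-H")
        sel$distance[sel$bond_type %in% c("Calk-H", "Caro-H")]
      else sel$distance[sel$bond_type == cls]
      n <- length(d)
      out[[length(out) + 1]] <- data.frame(
        bond_type = cls, threshold = thr,
        mean = if (n) mean(d) else NA_real_,
        sd = if (n >= 2) stats::sd(d) else NA_real_, n = n)
    }
  }
  do.call(rbind, out)
}

#' Peak-position trend table
#'
#' Flat export of (bond type, peak-to-parent distance, peak height, parent
#' B-factor) per assignment, for plotting distance-vs-height and
#' distance-vs-B trends, together with the Spearman rank correlation of
#' distance with peak height per bond type (NA when either variable is
#' constant).
#'
#' @param assignments data.frame from [assign_hydrogen_peaks()].
#' @return list with `table` (data.frame) and `correlations` (data.frame:
#'   `bond_type`, `spearman_distance_height`, `n`).
#' @export
peak_trend_table <- function(assignments) {
  tab <- assignments[!assignments$excluded,
                     c("bond_type", "distance", "height", "parent_b")]
  rownames(tab) <- NULL
  cors <- lapply(split(tab, tab$bond_type), function(g) {
    r <- if (nrow(g) >= 3 && stats::sd(g$distance) > 0 && stats::sd(g$height) > 0)
      stats::cor(g$distance, g$height, method = "spearman") else NA_real_
    data.frame(bond_type = g$bond_type[1], spearman_distance_height = r,
               n = nrow(g))
  })
  list(table = tab, correlations = do.call(rbind, unname(cors)))
}
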