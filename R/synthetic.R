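# Synthetic-data generator: polypeptide toy models with riding hydrogens,
# optional partial charges, band-limited maps and half-map pairs with
# independent noise. These stand in for a deposited high-resolution
# apoferritin reconstruction at desk scale.

DEFAULT_RESIDUE_MIX <- c("ALA", "GLY", "SER", "ASP", "GLU",
                         "ASN", "GLN", "PHE", "TYR", "LYS")

#' Synthetic data specification
#'
#' Collects the generator's study conditions: chain composition, the
#' per-atom isotropic B-factor range (default 10-35 Angstrom^2, the range
#' observed for well-ordered side chains in sub-1.2 Angstrom maps), target
#' resolution (default 1.19 Angstrom), half-map noise level and seed.
#'
#' @param n_residues chain length (default 20).
#' @param residue_mix residue types cycled to build the sequence.
#' @param sequence explicit sequence (overrides `n_residues`/`residue_mix`).
#' @param b_range isotropic B-factor range in Angstrom^2.
#' @param d_min map resolution in Angstrom.
#' @param noise_sigma half-map noise standard deviation as a fraction of the
#'   signal map sigma (0 = noiseless).
#' @param seed integer seed; identical spec + seed gives identical outputs.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 20, residue_mix = DEFAULT_RESIDUE_MIX,
                           sequence = NULL, b_range = c(10, 35),
                           d_min = 1.19, noise_sigma = 0, seed = 1L) {
  if (is.null(sequence))
    sequence <- rep(residue_mix, length.out = n_residues)
  unknown <- setdiff(sequence, supported_residues())
  if (length(unknown)) stop("unknown residues: ", paste(unknown, collapse = ", "))
  stopifnot(length(b_range) == 2, b_range[1] <= b_range[2], b_range[1] >= 0,
            d_min > 0, noise_sigma >= 0)
  structure(list(sequence = sequence, b_range = b_range, d_min = d_min,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Backbone torsions of an extended beta strand; extended conformation keeps
# side chains of consecutive residues on alternating sides of the chain.
BACKBONE <- list(phi = -139, psi = 135, omega = 180,
                 b_nca = 1.458, b_cac = 1.525, b_cn = 1.329, b_co = 1.231,
                 a_ncac = 111.0, a_cacn = 116.2, a_cnca = 121.7, a_caco = 120.8)

#' Build a toy polypeptide model
#'
#' Builds an extended chain with idealized backbone geometry; side chains
#' (and the carbonyl O) are grafted from idealized residue templates by
#' superposing each template's N/CA/C onto the built backbone. Heavy-atom
#' B-factors are drawn uniformly from `spec$b_range` under `spec$seed`.
#' Hydrogens are not included; see [add_riding_hydrogens()].
#'
#' @param spec a `synthetic_spec`.
#' @param pad box padding around the model in Angstrom.
#' @return an `atomic_model` (heavy atoms only).
#' @export
build_toy_model <- function(spec, pad = 6) {
  tpl <- residue_templates()
  seqv <- spec$sequence
  bb <- BACKBONE
  n_res <- length(seqv)

  rows <- list()
  bonds <- list()
  prev <- NULL  # list(N=, CA=, C=) positions of previous residue
  offset <- 0L
  prev_c_index <- NA_integer_
  for (i in seq_len(n_res)) {
    res <- seqv[i]
    t <- tpl[[res]]
    hnames <- vapply(t$heavy, function(a) a$name, "")
    hxyz <- t(vapply(t$heavy, function(a) unlist(a$xyz), numeric(3)))
    helem <- vapply(t$heavy, function(a) a$element, "")

    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(bb$b_nca, 0, 0)
      C <- place_atom(c(0, 1, 0), N, CA, bb$b_cac, bb$a_ncac, 33)
    } else {
      N <- place_atom(prev$N, prev$CA, prev$C, bb$b_cn, bb$a_cacn, bb$psi)
      CA <- place_atom(prev$CA, prev$C, N, bb$b_nca, bb$a_cnca, bb$omega)
      C <- place_atom(prev$C, N, CA, bb$b_cac, bb$a_ncac, bb$phi)
    }
    O <- place_atom(N, CA, C, bb$b_co, bb$a_caco, bb$psi + 180)

    tr <- rigid_transform(hxyz[match(c("N", "CA", "C"), hnames), ],
                          rbind(N, CA, C))
    pos <- tr(hxyz)
    pos[match(c("N", "CA", "C"), hnames), ] <- rbind(N, CA, C)
    pos[match("O", hnames), ] <- O

    rows[[i]] <- data.frame(atom = hnames, residue = res, resno = i,
                            element = helem, x = pos[, 1], y = pos[, 2],
                            z = pos[, 3], b = NA_real_, occ = 1, charge = 0)
    bl <- do.call(rbind, lapply(t$bonds, function(p)
      offset + c(match(p[[1]], hnames), match(p[[2]], hnames))))
    if (!is.na(prev_c_index))
      bl <- rbind(bl, c(prev_c_index, offset + match("N", hnames)))
    bonds[[i]] <- bl
    prev_c_index <- offset + match("C", hnames)
    offset <- offset + length(hnames)
    prev <- list(N = N, CA = CA, C = C)
  }
  atoms <- do.call(rbind, rows)
  atoms$b <- with_seed(spec$seed,
                       stats::runif(nrow(atoms), spec$b_range[1], spec$b_range[2]))

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min)
  shift <- pad - lo
  atoms[, c("x", "y", "z")] <- sweep(xyz, 2, shift, "+")
  cell <- apply(sweep(xyz, 2, shift, "+"), 2, max) + pad
  atomic_model(atoms, do.call(rbind, bonds), cell = cell)
}

#' Add riding hydrogens at idealized positions
#'
#' Hydrogens are generated from the heavy-atom coordinates: side-chain and
#' alpha hydrogens by grafting the idealized template geometry, the backbone
#' amide hydrogen on the external bisector of C(i-1)-N-CA in the peptide
#' plane. Every hydrogen is then set to its class distance from the parent
#' along the ideal direction, using either internuclear ("nuclear",
#' neutron-derived) or electron-cloud centroid ("electron", X-ray-derived)
#' reference distances. Hydrogen B-factors and occupancies ride on the
#' parent atom.
#'
#' @param model an `atomic_model` of template residues (no hydrogens yet).
#' @param distance_set `"nuclear"` or `"electron"`.
#' @return an `atomic_model` with hydrogens appended after the heavy atoms.
#' @export
add_riding_hydrogens <- function(model, distance_set = c("nuclear", "electron")) {
  distance_set <- match.arg(distance_set)
  dist_tab <- RIDING_DISTANCES[[distance_set]]
  tpl <- residue_templates()
  a <- model$atoms
  if (any(a$element == "H")) stop("model already contains hydrogens")

  hrows <- list()
  hbonds <- list()
  resnos <- unique(a$resno)
  for (i in resnos) {
    ridx <- which(a$resno == i)
    res <- a$residue[ridx[1]]
    t <- tpl[[res]]
    hnames <- vapply(t$heavy, function(x) x$name, "")
    hxyz <- t(vapply(t$heavy, function(x) unlist(x$xyz), numeric(3)))
    mpos <- as.matrix(a[ridx, c("x", "y", "z")])
    mnames <- a$atom[ridx]
    tr <- rigid_transform(hxyz[match(c("N", "CA", "C"), hnames), ],
                          mpos[match(c("N", "CA", "C"), mnames), ])
    cnt <- template_h_count(res)
    for (h in t$hydrogens) {
      par_local <- match(h$parent, mnames)
      par_global <- ridx[par_local]
      ppos <- mpos[par_local, ]
      raw <- drop(tr(unlist(h$xyz)))
      cls <- classify_bond_type(res, h$parent, as.integer(cnt[[h$parent]]))
      d <- dist_tab[[cls$class]]
      pos <- ppos + vunit(raw - ppos) * d
      hrows[[length(hrows) + 1]] <- data.frame(
        atom = h$name, residue = res, resno = i, element = "H",
        x = pos[1], y = pos[2], z = pos[3], b = a$b[par_global],
        occ = a$occ[par_global], charge = 0, parent = par_global,
        h_class = cls$class, excluded = cls$excluded)
    }
    # backbone amide hydrogen (not for the N-terminal residue)
    if (i > min(resnos)) {
      Ni <- ridx[match("N", mnames)]
      CAi <- ridx[match("CA", mnames)]
      prev_idx <- which(a$resno == i - 1)
      Cprev <- prev_idx[match("C", a$atom[prev_idx])]
      npos <- as.numeric(a[Ni, c("x", "y", "z")])
      dir <- -(vunit(as.numeric(a[Cprev, c("x", "y", "z")]) - npos) +
               vunit(as.numeric(a[CAi, c("x", "y", "z")]) - npos))
      cls <- classify_bond_type(res, "N", 1L)
      pos <- npos + vunit(dir) * dist_tab[["N-H"]]
      hrows[[length(hrows) + 1]] <- data.frame(
        atom = "H", residue = res, resno = i, element = "H",
        x = pos[1], y = pos[2], z = pos[3], b = a$b[Ni], occ = a$occ[Ni],
        charge = 0, parent = Ni, h_class = cls$class, excluded = cls$excluded)
    }
  }
  hdf <- do.call(rbind, hrows)
  a$parent <- NA_integer_; a$h_class <- NA_character_; a$excluded <- FALSE
  atoms <- rbind(a, hdf)
  bonds <- rbind(model$bonds,
                 cbind(hdf$parent, nrow(a) + seq_len(nrow(hdf))))
  out <- atomic_model(atoms, bonds, cell = model$cell, origin = model$origin)
  out
}

#' Half-map pair
#'
#' Two maps of the same signal with independent noise realizations, the
#' synthetic analogue of unfiltered half maps from disjoint particle halves.
#'
#' @param half1,half2 `potential_map`s on identical grids.
#' @return object of class `halfmap_pair`.
#' @export
halfmap_pair <- function(half1, half2) {
  stopifnot(identical(dim(half1$data), dim(half2$data)),
            isTRUE(all.equal(half1$voxel, half2$voxel)))
  structure(list(half1 = half1, half2 = half2), class = "halfmap_pair")
}

#' Generate a synthetic half-map pair
#'
#' Synthesizes the noiseless signal map from the model at `spec$d_min`, then
#' adds independent white Gaussian noise of standard deviation
#' `spec$noise_sigma * sigma(signal)` to each half.
#'
#' @param model an `atomic_model`.
#' @param spec a `synthetic_spec`.
#' @param voxel_size voxel size (default `spec$d_min / 4`).
#' @return a `halfmap_pair`; the noiseless signal map is attached as
#'   `$signal`.
#' @export
make_half_maps <- function(model, spec, voxel_size = NULL) {
  band <- resolution_band(100, spec$d_min)
  signal <- simulate_coulomb_map(model, voxel_size, band)
  sdn <- spec$noise_sigma * map_sigma(signal)
  halves <- lapply(1:2, function(k) {
    m <- signal
    if (sdn > 0)
      m$data <- m$data + with_seed(spec$seed * 10L + k,
        array(stats::rnorm(length(m$data), sd = sdn), dim = dim(m$data)))
    m
  })
  out <- halfmap_pair(halves[[1]], halves[[2]])
  out$signal <- signal
  out$noise_sd <- sdn
  out
}

#' Generate a dose (frame) series of half-map pairs
#'
#' Emulates reconstructions from the first n frames of a movie series: the
#' signal is fixed while the noise variance scales as 1/n_frames (noise
#' standard deviation `spec$noise_sigma * sigma(signal) / sqrt(n)`).
#' Optionally the model B-factors grow linearly with accumulated frames to
#' emulate radiation damage.
#'
#' @param model an `atomic_model`.
#' @param spec a `synthetic_spec`; `noise_sigma` is the per-frame noise level.
#' @param frame_counts increasing integer vector of cumulative frame counts.
#' @param damage_b_per_frame B-factor increase per accumulated frame
#'   (Angstrom^2); 0 disables damage.
#' @param voxel_size voxel size (default `spec$d_min / 4`).
#' @return named list of `halfmap_pair`s ("frame2", "frame3", ...).
#' @export
make_dose_series <- function(model, spec, frame_counts = c(2, 3, 20, 40),
                             damage_b_per_frame = 0, voxel_size = NULL) {
  stopifnot(all(diff(frame_counts) > 0))
  band <- resolution_band(100, spec$d_min)
  base_signal <- simulate_coulomb_map(model, voxel_size, band)
  sig0 <- map_sigma(base_signal)
  out <- list()
  for (k in seq_along(frame_counts)) {
    n <- frame_counts[k]
    signal <- if (damage_b_per_frame > 0) {
      m <- model
      m$atoms$b <- m$atoms$b + damage_b_per_frame * n
      simulate_coulomb_map(m, voxel_size, band)
    } else base_signal
    sdn <- spec$noise_sigma * sig0 / sqrt(n)
    halves <- lapply(1:2, function(j) {
      mm <- signal
      if (sdn > 0)
        mm$data <- mm$data + with_seed(spec$seed * 100L + 2L * n + j,
          array(stats::rnorm(length(mm$data), sd = sdn), dim = dim(mm$data)))
      mm
    })
    pr <- halfmap_pair(halves[[1]], halves[[2]])
    pr$signal <- signal
    pr$noise_sd <- sdn
    out[[paste0("frame", n)]] <- pr
  }
  out
}
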