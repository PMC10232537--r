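# Shared fixtures, memoized so expensive maps are built once per test run.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# Nuclear riding distances used when placing hydrogens (per bond class).
NUCLEAR <- c("C-H" = 1.09, "Calk-H" = 1.09, "Caro-H" = 1.08,
             "C-H2" = 1.09, "C-H3" = 1.09, "N-H" = 1.02, "O-H" = 0.98)

# Small mixed peptide with hydrogens, structure factors and H-omit
# difference map (B restricted to the well-ordered range).
small_peptide <- function() fixture("small_peptide", function() {
  spec <- synthetic_spec(n_residues = 6,
                         sequence = c("ALA", "GLY", "ASP", "PHE", "ASN", "LYS"),
                         b_range = c(10, 20), seed = 7)
  model <- add_riding_hydrogens(build_toy_model(spec), "nuclear")
  obs <- structure_factors_from_model(model, 1.19 / 4, 1.19)
  dm <- fourier_difference_map(obs, omit_atoms(model), resolution_band(100, 1.19))
  list(spec = spec, model = model, obs = obs, diffmap = dm)
})

# Full-size recovery fixture: 20 residues (>= 60 C/N/O-H bonds), hydrogens
# at nuclear reference distances, B in the range of the well-ordered core
# (hydrogens in the source statistics ride parents with B <= 20 A^2).
recovery_fixture <- function() fixture("recovery", function() {
  spec <- synthetic_spec(n_residues = 20, b_range = c(10, 20), seed = 11)
  model <- add_riding_hydrogens(build_toy_model(spec), "nuclear")
  obs <- structure_factors_from_model(model, 1.19 / 4, 1.19)
  dm <- fourier_difference_map(obs, omit_atoms(model), resolution_band(100, 1.19))
  peaks <- find_peaks(dm, 2)
  asg <- assign_hydrogen_peaks(peaks, model, 0.5)
  list(spec = spec, model = model, obs = obs, diffmap = dm,
       peaks = peaks, assignments = asg$assignments,
       unassigned = asg$unassigned)
})

# Charged-carboxylate model for charge-signature tests.
charged_fixture <- function() fixture("charged", function() {
  spec <- synthetic_spec(n_residues = 4, sequence = c("ALA", "ASP", "GLY", "GLU"),
                         b_range = c(10, 20), seed = 3)
  model <- build_toy_model(spec)
  list(spec = spec, model = model, oxygens = carboxylate_oxygens(model))
})

# Widely separated single atoms: the clean fixture for local-refit
# properties (no peak overlap between bonded atoms).
sparse_atoms <- function() fixture("sparse", function() {
  set.seed(2)
  g <- expand.grid(x = c(5, 11), y = c(5, 11), z = c(5, 11))
  g <- g + matrix(stats::runif(24, -0.8, 0.8), ncol = 3)
  model <- atomic_model(data.frame(
    atom = "C", residue = "UNK", resno = 1:8, element = "C",
    x = g$x, y = g$y, z = g$z, b = 15, occ = 1, charge = 0),
    cell = c(16, 16, 16))
  map <- simulate_coulomb_map(model, band = resolution_band(100, 1.19))
  list(model = model, map = map)
})

# Direct (non-FFT) evaluation of a band-limited map at arbitrary points:
# plain sum over the nonzero Fourier coefficients. Independent of the
# package's interpolation code paths.
direct_map_value <- function(sf, pts) {
  nz <- which(sf$F != 0)
  Fv <- sf$F[nz]
  ijk <- arrayInd(nz, sf$dims) - 1L
  h1 <- ifelse(ijk[, 1] > sf$dims[1] / 2, ijk[, 1] - sf$dims[1], ijk[, 1])
  h2 <- ifelse(ijk[, 2] > sf$dims[2] / 2, ijk[, 2] - sf$dims[2], ijk[, 2])
  h3 <- ifelse(ijk[, 3] > sf$dims[3] / 2, ijk[, 3] - sf$dims[3], ijk[, 3])
  box <- sf$dims * sf$voxel
  N <- prod(sf$dims)
  apply(matrix(pts, ncol = 3), 1, function(p) {
    u <- (p - sf$origin) / box
    Re(sum(Fv * exp(-2i * pi * (h1 * u[1] + h2 * u[2] + h3 * u[3])))) / N
  })
}
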