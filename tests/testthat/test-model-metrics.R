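# Model RMSD, half-map refit, RMSD between half-map refits, FSC and the
# dose / rescaling arithmetic.

rand_model <- function(n, seed, sd = 0) {
  set.seed(seed)
  atomic_model(data.frame(atom = paste0("C", seq_len(n)), residue = "UNK",
                          resno = seq_len(n), element = "C",
                          x = stats::runif(n, 2, 10) + stats::rnorm(n, sd = sd),
                          y = stats::runif(n, 2, 10), z = stats::runif(n, 2, 10),
                          b = 15, occ = 1, charge = 0), cell = c(12, 12, 12))
}

perturb <- function(m, sd, seed) {
  set.seed(seed)
  m$atoms[, c("x", "y", "z")] <- m$atoms[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(m$atoms), sd = sd), ncol = 3)
  m
}

test_that("rmsd closed forms: identity, translation, Gaussian perturbation", {
  m <- rand_model(50, 1)
  expect_equal(rmsd_between_models(m, m), 0)
  mt <- m
  mt$atoms[, c("x", "y", "z")] <- mt$atoms[, c("x", "y", "z")] +
    rep(c(0.3, -0.4, 1.2), each = 50)
  expect_equal(rmsd_between_models(m, mt), sqrt(0.3^2 + 0.4^2 + 1.2^2),
               tolerance = 1e-12)
  # both models perturbed by iid Gaussian of scale sc per coordinate:
  # E[rmsd] ~ sc * sqrt(6) over many sites
  big <- rand_model(4000, 2)
  sc <- 0.05
  r <- rmsd_between_models(perturb(big, sc, 3), perturb(big, sc, 4))
  expect_equal(r, sc * sqrt(6), tolerance = 0.05)
})

test_that("rmsd is a metric on random triples and rejects unmatched atoms", {
  m <- rand_model(30, 5)
  a <- perturb(m, 0.1, 6); b <- perturb(m, 0.1, 7); c <- perturb(m, 0.1, 8)
  dab <- rmsd_between_models(a, b)
  dba <- rmsd_between_models(b, a)
  dac <- rmsd_between_models(a, c)
  dbc <- rmsd_between_models(b, c)
  expect_equal(dab, dba)
  expect_gt(dab, 0)
  expect_lte(dac, dab + dbc + 1e-12)
  b2 <- b
  b2$atoms$atom[1] <- "XX"
  expect_error(rmsd_between_models(a, b2), "unmatched")
})

test_that("local refit is a fixed point on the generating map and recovers displacements", {
  sp <- sparse_atoms()
  r1 <- halfmap_local_refit(sp$model, sp$map, 0.5)
  expect_lt(max(attr(r1, "refit")$shift), 0.01)
  md <- perturb(sp$model, 0.2 / sqrt(3), 9)
  r2 <- halfmap_local_refit(md, sp$map, 0.5)
  expect_lt(rmsd_between_models(r2, sp$model), 0.03)
  # max_shift = 0 is the identity
  r0 <- halfmap_local_refit(md, sp$map, 0)
  expect_identical(coords(r0), coords(md))
  # flat density: site flagged and unmoved
  flat <- potential_map(array(1, c(16, 16, 16)), 1)
  rf <- halfmap_local_refit(sp$model, flat, 0.5)
  expect_true(all(attr(rf, "refit")$flat))
  expect_identical(coords(rf), coords(sp$model))
})

test_that("rmsd_half is zero for identical halves and monotone in noise", {
  sp <- sparse_atoms()
  ident <- halfmap_pair(sp$map, sp$map)
  expect_equal(rmsd_half(sp$model, ident)$rmsd, 0)
  vals <- vapply(c(0.1, 0.4, 1.2), function(ns) {
    h <- lapply(1:2, function(k) {
      m <- sp$map
      set.seed(100 + k + round(1000 * ns))
      m$data <- m$data + array(stats::rnorm(length(m$data),
                                            sd = ns * map_sigma(sp$map)),
                               dim = dim(m$data))
      m
    })
    rmsd_half(sp$model, halfmap_pair(h[[1]], h[[2]]))$rmsd
  }, 1)
  expect_gt(vals[1], 0)
  expect_true(all(diff(vals) > 0))
})

test_that("FSC is 1 for identical maps and noise-level for independent noise", {
  sp <- sparse_atoms()
  fc <- fsc_curve(halfmap_pair(sp$map, sp$map))
  expect_true(all(abs(fc$fsc - 1) < 1e-9))
  expect_true(all(fc$fsc >= -1 - 1e-9 & fc$fsc <= 1 + 1e-9))
  set.seed(31)
  mk <- function() potential_map(array(stats::rnorm(32^3), c(32, 32, 32)), 0.5)
  fn <- fsc_curve(halfmap_pair(mk(), mk()))
  expect_lt(max(abs(fn$fsc) * sqrt(fn$n)), 4.5)
  expect_error(fsc_curve(halfmap_pair(mk(), mk()), shell_width = 10),
               "too few shells")
})

test_that("FSC of signal plus noise follows gamma/(1+gamma)", {
  spec <- synthetic_spec(n_residues = 2, sequence = c("ALA", "SER"),
                         noise_sigma = 0.5, seed = 5)
  model <- add_riding_hydrogens(build_toy_model(spec), "nuclear")
  hm <- make_half_maps(model, spec)
  fc <- fsc_curve(hm)
  sfs <- sf_from_map(hm$signal)
  dims <- dim(sfs$F)
  w <- 1 / (max(dims) * hm$half1$voxel)
  sel <- sfs$d_star > 0 & sfs$d_star <= 1 / (2 * hm$half1$voxel) &
    !empot:::nyquist_mask(dims)
  sh <- floor(sfs$d_star[sel] / w)
  gam <- tapply(abs(sfs$F[sel])^2, sh, mean) /
    (length(sfs$F) * hm$noise_sd^2)
  theory <- gam / (1 + gam)
  dev <- abs(fc$fsc - theory[as.character(floor(fc$d_star / w))])
  big <- fc$n >= 100
  expect_lt(max(dev[big]), 0.06)
  expect_lt(sqrt(mean(dev[big]^2)), 0.02)
})

test_that("resolution_at interpolates the threshold crossing", {
  fake <- data.frame(d_star = c(0.1, 0.2, 0.3, 0.4),
                     d = 1 / c(0.1, 0.2, 0.3, 0.4),
                     fsc = c(0.9, 0.5, 0.1, 0.02), n = 100)
  # linear crossing of 0.143 between 0.2 and 0.3
  xc <- 0.2 + (0.143 - 0.5) / (0.1 - 0.5) * 0.1
  expect_equal(resolution_at(fake, 0.143), 1 / xc)
  flat <- fake; flat$fsc <- rep(0.9, 4)
  expect_warning(r <- resolution_at(flat), "never falls")
  expect_true(is.na(r))
})

test_that("dose and pixel-rescaling arithmetic reproduce the acquisition numbers", {
  expect_equal(electron_dose(dose_spec(3.819, 0.0585, 3, 0.495)), 2.735372,
               tolerance = 1e-6)
  expect_equal(electron_dose(dose_spec(3.819, 0.0585, 2, 0.495)), 1.823581,
               tolerance = 1e-6)
  expect_equal(electron_dose(dose_spec(3.819, 0.0585, 0, 0.495)), 0)
  expect_error(dose_spec(3.819, 0.0585, 3, 0), "positive")
  expect_equal(rescaled_pixel_size(480, 0.495, 600), 0.396)
  expect_equal(rescaled_pixel_size(480, 0.495, 480), 0.495)
  expect_equal(rescaled_pixel_size(600, rescaled_pixel_size(480, 0.495, 600),
                                   480), 0.495)
  expect_error(rescaled_pixel_size(0, 0.495, 600), "positive")
})
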