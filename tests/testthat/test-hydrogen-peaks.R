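# Peak detection, riding-hydrogen assignment, bond classification and
# distance statistics.

test_that("sub-voxel peak position matches a dense-grid oracle within 0.02 A", {
  pos <- c(4.13, 3.87, 4.31)
  m <- atomic_model(data.frame(atom = "O", residue = "HOH", resno = 1,
                               element = "O", x = pos[1], y = pos[2],
                               z = pos[3], b = 18, occ = 1, charge = 0),
                    cell = c(8, 8, 8))
  sf <- structure_factors_from_model(m, 1.19 / 4, 1.19)
  pm <- synthesize_map(sf, resolution_band(100, 1.19))
  pk <- find_peaks(pm, 4)
  expect_equal(nrow(pk), 1)
  # oracle: argmax over a dense sub-voxel grid of direct Fourier evaluations
  fine <- pm$voxel / 20
  g <- as.matrix(expand.grid(x = seq(pos[1] - 0.2, pos[1] + 0.2, by = fine),
                             y = seq(pos[2] - 0.2, pos[2] + 0.2, by = fine),
                             z = seq(pos[3] - 0.2, pos[3] + 0.2, by = fine)))
  vals <- direct_map_value(sf, g)
  dense <- g[which.max(vals), ]
  expect_lt(sqrt(sum((as.numeric(pk[1, 1:3]) - dense)^2)), 0.02)
})

test_that("separated blobs give separate peaks; high threshold gives none", {
  m <- atomic_model(data.frame(atom = c("O", "O"), residue = "HOH",
                               resno = 1:2, element = "O",
                               x = c(3, 7), y = c(4, 4), z = c(4, 4),
                               b = 15, occ = 1, charge = 0),
                    cell = c(10, 8, 8))
  pm <- simulate_coulomb_map(m, 0.3, resolution_band(100, 1.19))
  pk <- find_peaks(pm, 4)
  expect_equal(nrow(pk), 2)
  expect_equal(nrow(find_peaks(pm, max(pm$data) / map_sigma(pm) * 1.01)), 0)
})

test_that("bond types classify by element, ring membership and hydrogen count", {
  expect_equal(classify_bond_type("PHE", "CD1")$class, "Caro-H")
  expect_equal(classify_bond_type("ALA", "CB")$class, "C-H3")
  expect_equal(classify_bond_type("ALA", "CA")$class, "Calk-H")
  expect_equal(classify_bond_type("GLY", "CA")$class, "C-H2")
  expect_equal(classify_bond_type("SER", "OG")$class, "O-H")
  expect_equal(classify_bond_type("ASN", "ND2")$class, "N-H")
  # lysine side-chain amine is excluded from the statistics
  lys <- classify_bond_type("LYS", "NZ")
  expect_equal(lys$class, "N-H")
  expect_true(lys$excluded)
  expect_false(classify_bond_type("LYS", "N")$excluded)
  expect_error(classify_bond_type("ALA", "C"), "no riding hydrogens")
})

test_that("peaks at riding positions assign with zero offset; distant peaks do not", {
  rec <- recovery_fixture()
  m <- rec$model
  h1 <- which(m$atoms$element == "H")[1]
  fake <- data.frame(x = m$atoms$x[h1], y = m$atoms$y[h1], z = m$atoms$z[h1],
                     height = 10, i = 1, j = 1, k = 1)
  asg <- assign_hydrogen_peaks(fake, m, 0.5)
  expect_equal(nrow(asg$assignments), 1)
  expect_equal(asg$assignments$offset, 0)
  expect_equal(asg$assignments$distance,
               NUCLEAR[[asg$assignments$bond_type]], tolerance = 1e-9)
  far <- data.frame(x = 1, y = 1, z = 1, height = 10, i = 1, j = 1, k = 1)
  asg2 <- assign_hydrogen_peaks(far, m, 0.5)
  expect_equal(nrow(asg2$assignments), 0)
  expect_equal(nrow(asg2$unassigned), 1)
})

test_that("noiseless omit map recovers every hydrogen site exactly once", {
  rec <- recovery_fixture()
  n_h <- sum(rec$model$atoms$element == "H")
  expect_equal(nrow(rec$peaks), n_h)
  expect_equal(nrow(rec$assignments), nrow(rec$peaks))
  expect_equal(nrow(rec$unassigned), 0)
  expect_false(any(duplicated(paste(rec$assignments$resno,
                                    rec$assignments$h_atom))))
})

test_that("recovered class means sit at the placed nuclear distances", {
  rec <- recovery_fixture()
  st <- bond_length_statistics(rec$assignments, thresholds = 4)
  st$err <- st$mean - NUCLEAR[st$bond_type]
  # isolated hydrogens recover within interpolation accuracy
  solo <- st[st$bond_type %in% c("C-H", "Calk-H", "Caro-H", "N-H", "O-H"), ]
  expect_true(all(abs(solo$err) <= 0.02))
  # hydrogens sharing a parent coalesce slightly (band-limited peak overlap
  # pulls paired peaks together); the bias stays small for core-like B
  paired <- st[st$bond_type %in% c("C-H2", "C-H3"), ]
  expect_true(all(paired$err < 0))
  expect_true(all(abs(paired$err) <= 0.035))
})

test_that("statistics table conventions: counts, sd and threshold nesting", {
  rec <- recovery_fixture()
  st <- bond_length_statistics(rec$assignments, thresholds = c(2, 4))
  for (thr in c(2, 4)) {
    s <- st[st$threshold == thr, ]
    expect_equal(s$n[s$bond_type == "C-H"],
                 s$n[s$bond_type == "Calk-H"] + s$n[s$bond_type == "Caro-H"])
  }
  # the >=4 sigma assignment set is a subset of the >=2 sigma set
  n2 <- st$n[st$threshold == 2]
  n4 <- st$n[st$threshold == 4]
  expect_true(all(n4 <= n2))
  # excluded hydrogens (Lys NZ) never enter
  expect_gt(sum(rec$assignments$excluded), 0)
  expect_equal(sum(st$n[st$threshold == 2 & st$bond_type != "C-H"]),
               sum(!rec$assignments$excluded))
  # single observation: mean reported, sd omitted
  one <- bond_length_statistics(rec$assignments[1, , drop = FALSE], 2)
  row <- one[one$n == 1, ]
  expect_equal(nrow(row), if (row$bond_type[1] == "C-H") 2 else 1)
  expect_false(any(is.na(row$mean)))
  expect_true(all(is.na(row$sd)))
})

test_that("trend table exports cleanly and flags undefined correlations", {
  rec <- recovery_fixture()
  tt <- peak_trend_table(rec$assignments)
  expect_named(tt$table, c("bond_type", "distance", "height", "parent_b"))
  # CSV round trip of a small deterministic slice
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tt$table[1:3, ], f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back, tt$table[1:3, ], ignore_attr = TRUE)
  # constant heights: correlation undefined
  const <- rec$assignments[1:4, ]
  const$height <- 5
  cc <- peak_trend_table(const)$correlations
  expect_true(all(is.na(cc$spearman_distance_height)))
})

test_that("noisy maps show longer distances for lower peaks (negative trend)", {
  # the apparent-lengthening mechanism: broader (higher-B) hydrogens give
  # lower peaks whose noisy positions jitter more, and |true + jitter|
  # inflates the measured distance. Visible on hydrogens without a
  # same-parent partner (paired hydrogens are dominated by mutual overlap
  # instead); pooled over noise realizations as the trend is weak.
  spec <- synthetic_spec(n_residues = 20, b_range = c(10, 35), seed = 11)
  model <- add_riding_hydrogens(build_toy_model(spec), "nuclear")
  obs <- structure_factors_from_model(model, 1.19 / 4, 1.19)
  dm <- fourier_difference_map(obs, omit_atoms(model),
                               resolution_band(100, 1.19))
  pooled <- list()
  for (seed in 21:28) {
    set.seed(seed)
    noisy <- dm
    noisy$data <- noisy$data + array(stats::rnorm(length(noisy$data), sd = 0.8),
                                     dim = dim(noisy$data))
    s <- sqrt(mean((noisy$data - mean(noisy$data))^2))
    noisy$data <- noisy$data / s
    asg <- assign_hydrogen_peaks(find_peaks(noisy, 2), model, 0.5)$assignments
    pooled[[length(pooled) + 1]] <-
      asg[asg$bond_type %in% c("Calk-H", "Caro-H", "N-H", "O-H"), ]
  }
  pooled <- do.call(rbind, pooled)
  expect_gt(nrow(pooled), 300)
  resid <- pooled$distance - NUCLEAR[pooled$bond_type]
  expect_lt(stats::cor(resid, pooled$height, method = "spearman"), 0)
  # equivalently: low peaks sit further out on average than high peaks
  lo <- resid[pooled$height < stats::median(pooled$height)]
  hi <- resid[pooled$height >= stats::median(pooled$height)]
  expect_gt(mean(lo), mean(hi))
})
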