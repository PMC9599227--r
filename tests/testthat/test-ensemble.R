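ring_coords <- function(res) {
  as.matrix(res[match(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), res$name),
                c("x", "y", "z")])
}

test_that("superposing the reference ring onto itself is the identity", {
  ref <- reference_hexagon()
  out <- superpose_onto_reference_ring(list(list(ring = ref,
                                                 donor = rbind(c(0, 0, 3)))))
  expect_equal(out[[1]]$rmsd, 0, tolerance = 1e-9)
  expect_equal(out[[1]]$R, diag(3), tolerance = 1e-9)
  expect_equal(out[[1]]$donor, rbind(c(0, 0, 3)), tolerance = 1e-9)
})

test_that("a known rigid transform is inverted by the superposition", {
  set.seed(23)
  for (k in 1:5) {
    R <- nhpi:::random_rotation()
    t <- runif(3, -15, 15)
    ref <- reference_hexagon()
    moved <- sweep(ref %*% t(R), 2, t, `+`)
    donor <- sweep(rbind(c(0.5, 0.2, 3.1)) %*% t(R), 2, t, `+`)
    out <- superpose_onto_reference_ring(
      list(list(ring = moved, donor = donor)))[[1]]
    expect_equal(out$rmsd, 0, tolerance = 1e-9)
    expect_equal(out$donor, rbind(c(0.5, 0.2, 3.1)), tolerance = 1e-9)
    # rmsd is invariant to any further rigid pre-transform
    R2 <- nhpi:::random_rotation()
    moved2 <- sweep(moved %*% t(R2), 2, c(3, -2, 7), `+`)
    out2 <- superpose_onto_reference_ring(
      list(list(ring = moved2, donor = NULL)))[[1]]
    expect_equal(out2$rmsd, out$rmsd, tolerance = 1e-9)
  }
})

test_that("opposite planted elevations land on opposite reference sides", {
  up <- plant_pair_fragment(3.4, 15, 150, tau = 50)
  # reflect the 'up' pair through the ring plane to elevate at -50
  dn_donor <- up$donor
  dn_donor$z <- -dn_donor$z
  pairs <- list(
    list(ring = ring_coords(up$ring),
         donor = as.matrix(up$donor[, c("x", "y", "z")])),
    list(ring = ring_coords(up$ring),
         donor = as.matrix(dn_donor[, c("x", "y", "z")])))
  out <- superpose_onto_reference_ring(pairs)
  z_up <- out[[1]]$donor[up$donor$name == "CG", 3]
  z_dn <- out[[2]]$donor[up$donor$name == "CG", 3]
  expect_gt(z_up, 0)
  expect_lt(z_up * z_dn, 0)
  expect_error(superpose_onto_reference_ring(
    list(list(ring = matrix(rep(1:6, 3), 6, 3), donor = NULL))),
    "degenerate")
})

test_that("density maps normalise, track the colour channel, and find the mode", {
  one <- data.frame(d_nm = 3.3, theta = 12, omega = 150)
  dm <- compute_density_map(one)
  expect_equal(nrow(dm$bins), 1)
  expect_equal(dm$bins$fraction, 1)
  expect_equal(dm$bins$color_mean, 150)
  # two equal clusters: fractions 0.5 each
  two <- data.frame(d_nm = c(rep(3.05, 10), rep(4.05, 10)),
                    theta = c(rep(7, 10), rep(42, 10)),
                    omega = c(rep(160, 10), rep(100, 10)))
  dm2 <- compute_density_map(two)
  expect_equal(nrow(dm2$bins), 2)
  expect_equal(dm2$bins$fraction, c(0.5, 0.5))
  expect_equal(sum(dm2$bins$fraction), 1, tolerance = 1e-9)
  # ties break toward smaller first-axis midpoint
  expect_equal(dm2$modal$a_mid, 3.05)
  expect_error(compute_density_map(two[0, ]), "empty")
})

test_that("a planted Gaussian cloud puts the mode where it was planted", {
  set.seed(31)
  n <- 400
  series <- data.frame(d_nm = rnorm(n, 3.3, 0.05),
                       theta = rnorm(n, 15, 1.5),
                       omega = rnorm(n, 150, 4))
  dm <- compute_density_map(series)
  expect_lt(abs(dm$modal$a_mid - 3.3), 0.1)
  expect_lt(abs(dm$modal$b_mid - 15), 5)
  expect_equal(sum(dm$bins$fraction), 1, tolerance = 1e-9)
})

test_that("cutoff occupancy is the mean per-frame pass indicator", {
  all_in <- data.frame(d_nm = rep(3.3, 5), theta = rep(8, 5),
                       omega = rep(160, 5))
  expect_equal(cutoff_occupancy(all_in), 1.0)
  all_out <- transform(all_in, d_nm = 7.4)
  expect_equal(cutoff_occupancy(all_out), 0.0)
  mixed <- rbind(all_in, all_out)
  expect_equal(cutoff_occupancy(mixed), 0.5)
})

test_that("trajectory occupancy recovers the planted pass fraction", {
  tr <- generate_trajectory(500, 0.22, noise_sd = 0.02, seed = 11)
  ser <- trajectory_geometry_series(tr, "A", 1, "B", 1)
  expect_equal(nrow(ser), 500)
  occ <- cutoff_occupancy(ser)
  expect_equal(occ, floor(0.22 * 500) / 500, tolerance = 0.02)
  # determinism: same seed, same occupancy
  tr2 <- generate_trajectory(100, 0.4, seed = 5)
  tr3 <- generate_trajectory(100, 0.4, seed = 5)
  s2 <- trajectory_geometry_series(tr2, "A", 1, "B", 1)
  s3 <- trajectory_geometry_series(tr3, "A", 1, "B", 1)
  expect_identical(cutoff_occupancy(s2), cutoff_occupancy(s3))
})

test_that("noise-free melting curves return the planted Tm", {
  mc <- generate_melt_curve(40, noise_sd = 0)
  fit <- melting_temperature(mc$temperature, mc$ellipticity)
  expect_equal(fit$tm, 40, tolerance = 0.05)
  expect_true(all(fit$F > -0.2 & fit$F < 1.2))
})

test_that("flat curves raise a no-transition error", {
  mc <- generate_melt_curve(40, amplitude = 0, noise_sd = 0)
  expect_error(melting_temperature(mc$temperature, mc$ellipticity),
               "no transition")
})

test_that("the normalisation is agnostic to the sign of the transition", {
  mc <- generate_melt_curve(40, noise_sd = 0)
  up <- melting_temperature(mc$temperature, mc$ellipticity)
  flipped <- melting_temperature(mc$temperature, -mc$ellipticity)
  expect_equal(flipped$tm, up$tm, tolerance = 1e-6)
})

test_that("explicit baseline windows are honoured", {
  mc <- generate_melt_curve(45, noise_sd = 0)
  fit <- melting_temperature(mc$temperature, mc$ellipticity,
                             folded_window = c(4, 20),
                             unfolded_window = c(70, 80))
  expect_equal(fit$tm, 45, tolerance = 0.05)
  expect_error(melting_temperature(mc$temperature, mc$ellipticity,
                                   folded_window = c(4, 4.5)),
               "fewer than 2")
})
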