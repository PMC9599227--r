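test_that("ring frame centroid/normal follow the traversal convention", {
  r <- make_ideal_ring("phe")
  rf <- build_ring_frame(r)
  expect_equal(rf$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(rf$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_true(rf$planar_ok)
  expect_equal(vnorm <- sqrt(sum(rf$normal^2)), 1, tolerance = 1e-9)
  expect_lt(abs(sum(rf$normal * rf$xhat)), 1e-9)
  expect_lt(abs(sum(rf$normal * rf$yhat)), 1e-9)
  # reversed traversal (swap the D1/D2 and E1/E2 labels) flips the normal
  rev_ring <- r
  rev_ring$name <- c("CB", "CG", "CD2", "CE2", "CZ", "CE1", "CD1")
  rf2 <- build_ring_frame(rev_ring)
  expect_equal(rf2$normal, c(0, 0, -1), tolerance = 1e-12)
})

test_that("out-of-plane ring distortion is measured and flagged", {
  r <- make_ideal_ring("phe")
  r$z[r$name == "CD1"] <- r$z[r$name == "CD1"] + 0.3
  rf <- build_ring_frame(r)
  expect_equal(rf$center[3], 0.05, tolerance = 1e-9)  # 0.3 / 6
  # independent least-squares check: smallest singular value / sqrt(6)
  P <- as.matrix(r[r$name %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                   c("x", "y", "z")])
  rms_ls <- svd(sweep(P, 2, colMeans(P)))$d[3] / sqrt(6)
  expect_equal(rf$planarity_rms, rms_ls, tolerance = 1e-12)
  expect_true(rf$planar_ok)   # 0.086 A is still within the 0.1 A bound
  r$z[r$name == "CD1"] <- 0.5
  expect_false(build_ring_frame(r)$planar_ok)
})

test_that("missing ring atoms are reported by name", {
  r <- make_ideal_ring("phe")
  expect_error(build_ring_frame(r[r$name != "CZ", ]), "CZ")
})

test_that("theoretical amide hydrogens are planar, trigonal, at 1.0 A", {
  res <- data.frame(record = "ATOM", serial = 1:4,
                    name = c("CG", "CD", "OE1", "NE2"), altloc = "",
                    resname = "GLN", chain = "A", resno = 1L, icode = "",
                    x = c(-1.0, 0, -0.6, 1.33), y = c(-1.2, 0, 1.2, 0),
                    z = 0, occupancy = 1, bfactor = 0,
                    element = c("C", "C", "O", "N"), is_hetero = FALSE)
  d <- build_amide_donor(res)
  expect_equal(d$H[, 3], c(0, 0), tolerance = 1e-9)       # in-plane
  expect_equal(sqrt(rowSums((d$H - rep(d$N, each = 2))^2)), c(1, 1),
               tolerance = 1e-9)
  for (i in 1:2)
    expect_equal(nhpi:::vec_angle(d$H[i, ] - d$N, d$Cdelta - d$N), 120,
                 tolerance = 1e-6)
  # the two H sit on opposite sides of the N-Cdelta axis
  expect_lt(d$H[1, 2] * d$H[2, 2], 0)
  expect_error(build_amide_donor(res[res$name != "OE1", ]), "OE1")
})

test_that("donor built after rotation equals the rotated donor", {
  res <- plant_pair_fragment(3.5, 20, 150)$donor
  set.seed(5)
  for (k in 1:5) {
    R <- nhpi:::random_rotation()
    t <- runif(3, -10, 10)
    res2 <- res
    res2[, c("x", "y", "z")] <-
      sweep(as.matrix(res[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
    d1 <- build_amide_donor(res)
    d2 <- build_amide_donor(res2)
    expect_equal(d2$H, sweep(d1$H %*% t(R), 2, t, `+`), tolerance = 1e-9)
  }
})

test_that("pair geometry reproduces analytic limiting cases", {
  ring <- build_ring_frame(make_ideal_ring("phe"))
  # collinear: N on the normal axis, H pointing straight at M
  p <- plant_pair_fragment(3.0, 0, 180)
  g <- p$geometry
  expect_equal(g$d_nm, 3.0, tolerance = 1e-9)
  expect_equal(g$theta, 0, tolerance = 1e-6)
  expect_equal(g$omega, 180, tolerance = 1e-6)
  # in-plane donor: theta = 90
  res <- plant_pair_fragment(4.0, 90, 150)
  expect_equal(res$geometry$theta, 90, tolerance = 1e-6)
})

test_that("both d_cg_pi conventions are available", {
  p <- plant_pair_fragment(3.4, 15, 150, tau = 50)
  don <- build_amide_donor(p$donor)
  rg <- build_ring_frame(p$ring)
  g_cen <- compute_pair_geometry(don, rg, geometry_config("centroid"))
  g_pl <- compute_pair_geometry(don, rg, geometry_config("plane"))
  expect_equal(g_pl$d_cg_pi,
               g_cen$d_cg_pi * sin(g_cen$tau * pi / 180),
               tolerance = 1e-9)
  expect_lt(g_pl$d_cg_pi, g_cen$d_cg_pi)
})

test_that("six parameters match the brute-force oracle on random placements", {
  set.seed(101)
  for (k in 1:300) {
    pl <- random_pair_placement()
    g <- compute_pair_geometry(build_amide_donor(pl$donor),
                               build_ring_frame(pl$ring))
    o <- oracle_pair_geometry(pl$donor, pl$ring)
    expect_equal(c(g$d_nm, g$theta, g$omega, g$d_cg_pi, g$tau, g$chi),
                 unname(o), tolerance = 1e-9)
  }
})

test_that("parameters are invariant under rigid motion of both fragments", {
  p <- plant_pair_fragment(3.3, 8.4, 159.2)
  g0 <- p$geometry
  set.seed(17)
  for (k in 1:10) {
    R <- nhpi:::random_rotation()
    t <- runif(3, -20, 20)
    xf <- function(df) {
      df[, c("x", "y", "z")] <-
        sweep(as.matrix(df[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
      df
    }
    g <- compute_pair_geometry(build_amide_donor(xf(p$donor)),
                               build_ring_frame(xf(p$ring)))
    expect_equal(c(g$d_nm, g$theta, g$omega, g$d_cg_pi, g$tau, g$chi),
                 c(g0$d_nm, g0$theta, g0$omega, g0$d_cg_pi, g0$tau,
                   g0$chi), tolerance = 1e-6)
  }
})

test_that("reflection through the ring plane flips tau only", {
  p <- plant_pair_fragment(3.4, 25, 140, tau = 55)
  g0 <- p$geometry
  don <- p$donor
  don$z <- -don$z   # ring is in z = 0: reflect the donor
  g1 <- compute_pair_geometry(build_amide_donor(don),
                              build_ring_frame(p$ring))
  expect_equal(g1$tau, -g0$tau, tolerance = 1e-6)
  expect_equal(g1$d_nm, g0$d_nm, tolerance = 1e-9)
  expect_equal(g1$theta, g0$theta, tolerance = 1e-6)
  expect_equal(g1$d_cg_pi, g0$d_cg_pi, tolerance = 1e-9)
})

test_that("theta is folded to the acute angle for either normal sign", {
  p <- plant_pair_fragment(3.2, 30, 150)
  rg <- build_ring_frame(p$ring)
  rg_flipped <- rg
  rg_flipped$normal <- -rg$normal
  don <- build_amide_donor(p$donor)
  expect_equal(compute_pair_geometry(don, rg_flipped)$theta,
               compute_pair_geometry(don, rg)$theta, tolerance = 1e-9)
})

test_that("degenerate chi (donor axis along the normal) is NA", {
  # CG on the normal axis below N: the CG-to-N vector has no in-plane
  # projection
  p <- plant_pair_fragment(3.5, 0, tau = 90)
  expect_true(is.na(p$geometry$chi))
})
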