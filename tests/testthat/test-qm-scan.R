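test_that("the toluene frame puts C1 at the origin and CM on -x", {
  tol <- make_ideal_toluene()
  fr <- build_toluene_frame(tol)
  P <- to_toluene_frame(fr, as.matrix(tol[, c("x", "y", "z")]))
  expect_equal(P[tol$name == "C1", ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(P[tol$name == "CM", ], c(-1.51, 0, 0), tolerance = 1e-6)
  # ring carbons planar in the frame
  expect_true(all(abs(P[tol$name != "CM", 3]) < 0.05))
  # missing methyl carbon is an error
  expect_error(build_toluene_frame(tol[tol$name != "CM", ]),
               "not identifiable")
})

test_that("the toluene frame is invariant to rigid pre-transforms", {
  tol <- make_ideal_toluene()
  set.seed(41)
  for (k in 1:5) {
    R <- nhpi:::random_rotation()
    t <- runif(3, -10, 10)
    tol2 <- tol
    tol2[, c("x", "y", "z")] <-
      sweep(as.matrix(tol[, c("x", "y", "z")]) %*% t(R), 2, t, `+`)
    fr <- build_toluene_frame(tol2)
    P <- to_toluene_frame(fr, as.matrix(tol2[, c("x", "y", "z")]))
    P0 <- to_toluene_frame(build_toluene_frame(tol),
                           as.matrix(tol[, c("x", "y", "z")]))
    expect_equal(P, P0, tolerance = 1e-9)
  }
})

test_that("lattice sizes follow from the ranges and steps", {
  expect_equal(grid_spec()$n_points, 2704)           # 13 x 13 x 16
  expect_equal(grid_spec(x_range = c(0, 0), y_range = c(0, 0),
                         z_range = c(2, 2))$n_points, 1)
  expect_equal(grid_spec(z_step = 0.5)$n_points, 13 * 13 * 7)
  expect_error(grid_spec(x_step = -1))
  expect_error(grid_spec(z_range = c(-1, 2)), "positive")
})

test_that("every grid point lies in the scan quadrant with unique indices", {
  gr <- generate_scan_grid()
  expect_equal(nrow(gr$points), 2704)
  expect_false(anyDuplicated(gr$points$index) > 0)
  expect_true(all(gr$points$x >= 0 & gr$points$y >= 0 & gr$points$z > 0))
})

test_that("vectorised grid geometry matches the reference pair pipeline", {
  gr <- generate_scan_grid()
  set.seed(47)
  for (i in sample(gr$points$index, 25)) {
    cc <- scan_point_coordinates(gr, i)
    ac <- cc[grepl("^ac_", cc$name), ]
    don <- data.frame(
      record = "ATOM", serial = 1:4,
      name = sub("ac_", "", ac$name), altloc = "", resname = "ACM",
      chain = "A", resno = 1L, icode = "", x = ac$x, y = ac$y, z = ac$z,
      occupancy = 1, bfactor = 0, element = ac$element,
      is_hetero = FALSE, stringsAsFactors = FALSE)
    g1 <- compute_pair_geometry(build_amide_donor(don),
                                build_ring_frame(gr$toluene))
    g2 <- gr$geometry[gr$geometry$index == i, ]
    expect_equal(
      c(g2$d_nm, g2$theta, g2$omega, g2$d_cg_pi, g2$tau, g2$chi),
      c(g1$d_nm, g1$theta, g1$omega, g1$d_cg_pi, g1$tau, g1$chi),
      tolerance = 1e-9)
  }
})

test_that("XYZ emission writes one file per point plus a manifest", {
  dir <- withr::local_tempdir()
  gr <- generate_scan_grid(grid_spec(x_range = c(0, 0.4), x_step = 0.4,
                                     y_range = c(0, 0), y_step = 0.4,
                                     z_range = c(3, 3.2), z_step = 0.2))
  man <- write_scan_geometries(gr, dir)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  xyz <- readLines(file.path(dir, man$file[1]))
  expect_equal(as.integer(xyz[1]), 11)   # 7 toluene + 4 acetamide atoms
  # round-trip of the constrained N position through the file
  n_line <- strsplit(trimws(xyz[grep("^N ", xyz)]), " +")[[1]]
  expect_equal(as.numeric(n_line[2:4]), unlist(man[1, c("n_x", "n_y", "n_z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a planted quadratic energy field is minimised at the right site", {
  gr <- generate_scan_grid()
  energies <- data.frame(index = gr$geometry$index,
                         energy = (gr$geometry$d_nm - 3.2)^2 - 5.81)
  surf <- attach_energies_and_project(gr, energies)
  best <- gr$geometry$index[which.min(abs(gr$geometry$d_nm - 3.2))]
  expect_equal(surf$minimum$index, best)
  expect_equal(surf$minimum$energy, min(energies$energy))
  expect_lt(surf$minimum$energy, -5.7)
  # envelope rows match a brute-force filter and bin count
  sel <- gr$geometry$theta > 0 & gr$geometry$theta < 20
  expect_equal(sum(surf$envelope_d_nm$n), sum(sel))
  expect_true(all(diff(surf$envelope_d_nm$d_nm_mid) > 0))
})

test_that("constant fields tie-break to the first index and points can be missing", {
  gr <- generate_scan_grid()
  energies <- data.frame(index = gr$geometry$index, energy = 1.0)
  surf <- attach_energies_and_project(gr, energies)
  expect_equal(surf$minimum$index, 1L)
  # drop half the energies: excluded with a message, counted
  expect_message(
    surf2 <- attach_energies_and_project(gr, energies[1:1352, ]),
    "1352")
  expect_equal(surf2$n_missing, 1352)
  expect_equal(nrow(surf2$points), 1352)
})

test_that("projections are stable under point-order permutation", {
  gr <- generate_scan_grid()
  set.seed(53)
  energies <- data.frame(index = gr$geometry$index,
                         energy = rnorm(2704))
  s1 <- attach_energies_and_project(gr, energies)
  s2 <- attach_energies_and_project(gr, energies[sample(2704), ])
  expect_equal(s1$minimum$index, s2$minimum$index)
  expect_equal(s1$envelope_d_nm, s2$envelope_d_nm)
  expect_equal(s1$projection_tau, s2$projection_tau)
  # both angular filter conventions are supported and labelled
  s_tau <- attach_energies_and_project(gr, energies, angle_filter = "tau")
  expect_equal(s_tau$angle_filter, "tau")
  sel <- gr$geometry$tau > 40 & gr$geometry$tau < 50
  expect_equal(nrow(s_tau$projection_tau), sum(sel))
})
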