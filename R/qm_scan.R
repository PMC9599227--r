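#' @title Acetamide-toluene scan-grid generation
#' @description Builds the toluene-anchored coordinate frame, generates
#'   the quadrant scan lattice on which the amide nitrogen is constrained,
#'   emits per-point complex geometries for external quantum-chemistry
#'   engines, and ingests externally computed energies to locate the
#'   global minimum and produce envelope projections.  No energies are
#'   ever computed here.
#' @name qm_scan
NULL

#' Build the toluene-anchored frame
#'
#' Origin at C1 (the ring carbon bearing the methyl group), x-axis along
#' methyl-carbon-to-C1, z-axis along the ring normal (sign fixed by the
#' canonical C1..C6 traversal), y completing a right-handed frame.  The
#' frame is invariant to any rigid transform of the input toluene.
#'
#' @param residue atom data frame with ring carbons C1..C6 and a methyl
#'   carbon named CM, CH3 or C7.
#' @return list of class `toluene_frame`: `origin`, `xhat`, `yhat`,
#'   `zhat`, `ring` (the [build_ring_frame()] result), `CM`.
#' @export
build_toluene_frame <- function(residue) {
  ring <- build_ring_frame(residue)
  cm_name <- intersect(c("CM", "CH3", "C7"), residue$name)
  c1 <- atom_xyz(residue, "C1")
  if (!length(cm_name) || is.null(c1))
    stop("toluene methyl carbon (CM/CH3/C7) or ring C1 not identifiable")
  cm <- atom_xyz(residue, cm_name[1])
  zhat <- ring$normal
  x0 <- c1 - cm
  xhat <- unitv(x0 - dot3(x0, zhat) * zhat)
  yhat <- cross3(zhat, xhat)
  base::structure(list(origin = c1, xhat = xhat, yhat = yhat, zhat = zhat,
                       ring = ring, CM = cm),
                  class = "toluene_frame")
}

#' Map lab coordinates into a toluene frame
#' @param frame a [build_toluene_frame()] result.
#' @param coords n x 3 matrix of lab coordinates.
#' @return n x 3 matrix of frame coordinates.
#' @export
to_toluene_frame <- function(frame, coords) {
  B <- cbind(frame$xhat, frame$yhat, frame$zhat)
  sweep(coords, 2, frame$origin) %*% B
}

#' Scan-lattice specification
#'
#' Defaults give the standard quadrant scan: x and y from 0 to 4.8
#' Angstrom every 0.4, z from 2.0 to 5.0 every 0.2, i.e.
#' 13 x 13 x 16 = 2704 points (both endpoints included on every axis).
#'
#' @param x_range,y_range,z_range inclusive `c(lo, hi)` ranges (Angstrom).
#' @param x_step,y_step,z_step lattice steps (Angstrom).
#' @return list of class `grid_spec` with an `n_points` field.
#' @export
grid_spec <- function(x_range = c(0, 4.8), x_step = 0.4,
                      y_range = c(0, 4.8), y_step = 0.4,
                      z_range = c(2.0, 5.0), z_step = 0.2) {
  ax <- function(rng, step, name) {
    stopifnot(step > 0, rng[2] >= rng[1])
    s <- seq(rng[1], rng[2], by = step)
    if (!length(s)) stop("empty ", name, " range")
    s
  }
  xs <- ax(x_range, x_step, "x")
  ys <- ax(y_range, y_step, "y")
  zs <- ax(z_range, z_step, "z")
  if (any(zs <= 0)) stop("z range must be strictly positive")
  base::structure(list(x = xs, y = ys, z = zs,
                       n_points = length(xs) * length(ys) * length(zs)),
                  class = "grid_spec")
}

# canonical acetamide atom offsets relative to the constrained N, in the
# toluene frame: N-C along +z (so the N-H bisector points to -z, toward
# the ring), amide plane = the xz-plane through N
acetamide_template <- function() {
  ez <- c(0, 0, 1); ex <- c(1, 0, 0)
  C <- AMIDE_N_CD * ez
  CM <- C + AMIDE_CD_CG * (cos(rad(AMIDE_CG_CD_N)) * (-ez) +
                             sin(rad(AMIDE_CG_CD_N)) * ex)
  O <- C + AMIDE_CD_O * (cos(rad(AMIDE_O_CD_N)) * (-ez) -
                           sin(rad(AMIDE_O_CD_N)) * ex)
  rbind(N = c(0, 0, 0), C = C, O = O, CM = CM)
}

#' Generate the acetamide-toluene scan grid
#'
#' One point per lattice site of `spec`; at each site the acetamide is
#' placed rigidly in a canonical initial orientation (N at the site, N-H
#' bisector toward -z so both hydrogens face the ring, amide plane
#' containing the z-axis) and the six-parameter pair geometry is derived
#' for the acetamide-toluene complex.
#'
#' @param spec a [grid_spec()].
#' @param derive_geometry compute the derived pair geometry per point
#'   (default `TRUE`).
#' @return list of class `scan_grid`: `spec`, `points` (data frame
#'   `index`, `x`, `y`, `z`), `geometry` (per-point six parameters, when
#'   derived), `toluene` (idealised toluene atom table in the frame),
#'   `template` (acetamide offsets relative to N).
#' @export
generate_scan_grid <- function(spec = grid_spec(), derive_geometry = TRUE) {
  pts <- expand.grid(x = spec$x, y = spec$y, z = spec$z,
                     KEEP.OUT.ATTRS = FALSE)
  pts <- data.frame(index = seq_len(nrow(pts)), pts)
  tol <- make_ideal_toluene()
  tmpl <- acetamide_template()
  geom <- NULL
  if (derive_geometry) {
    frame <- build_toluene_frame(tol)
    M <- to_toluene_frame(frame, rbind(frame$ring$center))[1, ]
    P <- as.matrix(pts[, c("x", "y", "z")])
    geom <- derive_grid_geometry(P, M, tmpl)
    geom <- data.frame(index = pts$index, geom)
  }
  base::structure(list(spec = spec, points = pts, geometry = geom,
                       toluene = tol, template = tmpl),
                  class = "scan_grid")
}

# vectorised six-parameter geometry for the rigid canonical acetamide at
# every lattice site; ring normal is +z and substituent (CM->C1) is +x in
# the toluene frame
derive_grid_geometry <- function(P, M, tmpl) {
  n <- nrow(P)
  V <- sweep(P, 2, M)              # M -> N
  d_nm <- sqrt(rowSums(V^2))
  theta <- deg(acos(clamp1(abs(V[, 3]) / d_nm)))
  h_off <- rbind(c(-sqrt(3) / 2, 0, -0.5), c(sqrt(3) / 2, 0, -0.5))
  om <- matrix(0, n, 2)
  for (k in 1:2) {
    H <- sweep(P, 2, h_off[k, ], `+`)
    A <- -matrix(h_off[k, ], n, 3, byrow = TRUE)   # H -> N
    B <- sweep(-H, 2, M, `+`)                      # H -> M
    cr <- cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
                A[, 3] * B[, 1] - A[, 1] * B[, 3],
                A[, 1] * B[, 2] - A[, 2] * B[, 1])
    om[, k] <- deg(atan2(sqrt(rowSums(cr^2)), rowSums(A * B)))
  }
  h_used <- max.col(om)
  omega <- om[cbind(seq_len(n), h_used)]
  CG <- sweep(P, 2, tmpl["CM", ], `+`)
  G <- sweep(CG, 2, M)
  d_cg <- sqrt(rowSums(G^2))
  tau <- deg(asin(clamp1(G[, 3] / d_cg)))
  a <- -tmpl["CM", ]               # Cgamma -> N, constant offset
  a_p <- c(a[1], a[2])
  chi <- rep(deg(atan2(abs(a_p[2]), a_p[1])), n)  # vs substituent +x
  if (sqrt(sum(a_p^2)) < 1e-9) chi <- rep(NA_real_, n)
  data.frame(d_nm = d_nm, theta = theta, omega = omega, d_cg_pi = d_cg,
             tau = tau, chi = chi, h_used = h_used)
}

#' Full complex coordinates at one scan point
#'
#' @param grid a [generate_scan_grid()] result.
#' @param index lattice point index.
#' @return data frame `element`, `name`, `x`, `y`, `z` of the toluene +
#'   acetamide complex in the toluene frame.
#' @export
scan_point_coordinates <- function(grid, index) {
  p <- grid$points[grid$points$index == index, ]
  if (!nrow(p)) stop("no grid point with index ", index)
  site <- c(p$x, p$y, p$z)
  ac <- sweep(grid$template, 2, site, `+`)
  tol <- grid$toluene
  data.frame(
    element = c(rep("C", nrow(tol)), c("N", "C", "O", "C")),
    name = c(tol$name, paste0("ac_", rownames(grid$template))),
    x = c(tol$x, ac[, 1]), y = c(tol$y, ac[, 2]), z = c(tol$z, ac[, 3]),
    stringsAsFactors = FALSE)
}

#' Write one XYZ coordinate file
#'
#' @param elements character vector of element symbols.
#' @param coords n x 3 matrix.
#' @param file output path.
#' @param comment second header line.
#' @export
write_xyz <- function(elements, coords, file, comment = "") {
  lines <- c(as.character(length(elements)), comment,
             sprintf("%-2s %12.6f %12.6f %12.6f", elements,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, file)
  invisible(lines)
}

#' Emit per-point XYZ geometries and a manifest
#'
#' Writes one XYZ file per lattice point plus `manifest.tsv` mapping
#' index, filename and the constrained N position, so any external engine
#' can evaluate the energies.
#'
#' @param grid a [generate_scan_grid()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
write_scan_geometries <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("point_%04d.xyz", grid$points$index)
  for (i in seq_len(nrow(grid$points))) {
    cc <- scan_point_coordinates(grid, grid$points$index[i])
    write_xyz(cc$element, as.matrix(cc[, c("x", "y", "z")]),
              file.path(dir, files[i]),
              comment = sprintf("index %d N at %.3f %.3f %.3f",
                                grid$points$index[i], grid$points$x[i],
                                grid$points$y[i], grid$points$z[i]))
  }
  manifest <- data.frame(index = grid$points$index, file = files,
                         n_x = grid$points$x, n_y = grid$points$y,
                         n_z = grid$points$z)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Attach external energies to a scan grid and project
#'
#' Joins an energy table onto the grid, locates the global minimum (ties
#' broken by first index), and builds two projection tables: (i) the
#' minimum-energy envelope versus `d_nm` over points with
#' `0 < theta < theta_max`, and (ii) energy versus `tau` (with `d_cg_pi`)
#' over points whose `angle_filter` parameter lies in `angle_range`.
#' Points without an energy are excluded and counted.
#'
#' @param grid a [generate_scan_grid()] with derived geometry.
#' @param energies data frame with columns `index` and `energy`
#'   (kcal/mol).
#' @param theta_max upper theta bound for the distance envelope
#'   (default 20 degrees).
#' @param angle_filter `"chi"` or `"tau"` - which parameter the second
#'   projection filters on (both conventions are in circulation; the
#'   output names the one used).
#' @param angle_range `c(lo, hi)` for the filter (default 40-50 degrees).
#' @param d_nm_bin envelope bin width (default 0.1 Angstrom).
#' @return list of class `energy_surface`: `points` (geometry + energy),
#'   `minimum` (row of the global minimum), `envelope_d_nm`,
#'   `projection_tau`, `angle_filter`, `n_missing`.
#' @export
attach_energies_and_project <- function(grid, energies, theta_max = 20,
                                        angle_filter = c("chi", "tau"),
                                        angle_range = c(40, 50),
                                        d_nm_bin = 0.1) {
  angle_filter <- match.arg(angle_filter)
  stopifnot(inherits(grid, "scan_grid"), !is.null(grid$geometry),
            all(c("index", "energy") %in% names(energies)))
  pts <- merge(grid$geometry, energies[, c("index", "energy")],
               by = "index", all.x = TRUE)
  pts <- pts[order(pts$index), ]
  n_missing <- sum(is.na(pts$energy))
  if (n_missing)
    message(n_missing, " grid point(s) without energies excluded")
  pts <- pts[!is.na(pts$energy), , drop = FALSE]
  if (!nrow(pts)) stop("no grid points with energies")
  imin <- which(pts$energy == min(pts$energy))[1]
  minimum <- pts[imin, ]
  env_sel <- pts$theta > 0 & pts$theta < theta_max
  env <- pts[env_sel, , drop = FALSE]
  envelope <- NULL
  if (nrow(env)) {
    bin <- floor(env$d_nm / d_nm_bin)
    emin <- tapply(env$energy, bin, min)
    envelope <- data.frame(
      d_nm_mid = (as.numeric(names(emin)) + 0.5) * d_nm_bin,
      energy_min = as.numeric(emin),
      n = as.integer(tapply(env$energy, bin, length)))
    envelope <- envelope[order(envelope$d_nm_mid), ]
    rownames(envelope) <- NULL
  }
  av <- pts[[angle_filter]]
  proj_sel <- !is.na(av) & av > angle_range[1] & av < angle_range[2]
  projection <- pts[proj_sel, c("index", "tau", "d_cg_pi", "energy")]
  projection <- projection[order(projection$tau), ]
  rownames(projection) <- NULL
  base::structure(list(points = pts, minimum = minimum,
                       envelope_d_nm = envelope,
                       projection_tau = projection,
                       angle_filter = angle_filter,
                       angle_range = angle_range,
                       n_missing = n_missing),
                  class = "energy_surface")
}
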