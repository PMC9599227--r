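#' @title Ensemble and trajectory analysis
#' @description Ring superposition for population views, 2-D density maps
#'   over geometric parameters, cutoff occupancy along a trajectory, and
#'   melting-temperature extraction from CD thermal-denaturation curves.
#' @name ensemble_analysis
NULL

#' Ideal reference hexagon (6 x 3 matrix)
#'
#' Regular hexagon of circumradius equal to the aromatic C-C bond
#' (1.39 Angstrom) in the z = 0 plane, first vertex on +x, traversed
#' counter-clockwise viewed from +z.
#' @param bond C-C bond length (default 1.39).
#' @return 6 x 3 coordinate matrix.
#' @export
reference_hexagon <- function(bond = 1.39) {
  ang <- rad(seq(0, 300, by = 60))
  cbind(bond * cos(ang), bond * sin(ang), 0)
}

# Kabsch / orthogonal Procrustes: rotation + translation taking P onto Q
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

#' Superpose donor-ring pairs onto a reference ring
#'
#' Each pair's six ring carbons (in canonical traversal order) are
#' superposed onto the ideal reference hexagon by least-squares rigid
#' fitting (orthogonal Procrustes); the same transform carries the donor
#' atoms into the reference frame.
#'
#' @param pairs list of pairs; each element is a list with `ring`
#'   (6 x 3 matrix, canonical atom order) and `donor` (m x 3 matrix).
#' @param reference reference ring coordinates (default
#'   [reference_hexagon()]).
#' @return list, one element per pair: `donor` (transformed donor
#'   coordinates), `ring` (transformed ring), `rmsd`, `R`, `t`.
#' @export
superpose_onto_reference_ring <- function(pairs,
                                          reference = reference_hexagon()) {
  lapply(pairs, function(p) {
    stopifnot(is.matrix(p$ring), nrow(p$ring) == 6)
    C <- sweep(p$ring, 2, colMeans(p$ring))
    if (svd(C)$d[2] < 1e-9)
      stop("degenerate (collinear) ring input")
    tr <- kabsch(p$ring, reference)
    xf <- function(X) sweep(X %*% t(tr$R), 2, tr$t, `+`)
    ring_t <- xf(p$ring)
    rmsd <- sqrt(mean(rowSums((ring_t - reference)^2)))
    donor_t <- if (!is.null(p$donor)) xf(p$donor) else NULL
    list(donor = donor_t, ring = ring_t, rmsd = rmsd, R = tr$R, t = tr$t)
  })
}

#' Two-dimensional density map over geometric parameters
#'
#' Histograms a geometry series on `(param_a, param_b)`, reports the
#' occurrence fraction per occupied bin, the per-bin mean of a third
#' parameter (colour channel), and the modal bin (ties broken toward
#' smaller `param_a`).
#'
#' @param series data frame of per-frame geometry.
#' @param axes character vector of two column names (default
#'   `c("d_nm", "theta")`).
#' @param color column name averaged per bin (default `"omega"`).
#' @param bin_widths widths for the two axes; default 0.1 Angstrom for
#'   distance-like and 5 degrees for angle-like columns.
#' @return list of class `density_map`: `bins` (data frame with bin
#'   midpoints `a_mid`, `b_mid`, `count`, `fraction`, `color_mean`),
#'   `modal` (the modal row), `axes`, `color`, `bin_widths`.
#' @export
compute_density_map <- function(series, axes = c("d_nm", "theta"),
                                color = "omega", bin_widths = NULL) {
  if (!nrow(series)) stop("empty geometry series")
  stopifnot(length(axes) == 2, all(axes %in% names(series)),
            color %in% names(series))
  default_width <- function(col)
    if (grepl("^d_", col)) 0.1 else 5
  if (is.null(bin_widths))
    bin_widths <- vapply(axes, default_width, numeric(1))
  a <- series[[axes[1]]]; b <- series[[axes[2]]]
  wa <- bin_widths[1]; wb <- bin_widths[2]
  ia <- floor(a / wa); ib <- floor(b / wb)
  key <- paste(ia, ib, sep = ":")
  cnt <- tapply(rep(1L, length(key)), key, sum)
  cmean <- tapply(series[[color]], key, mean)
  ks <- names(cnt)
  parts <- do.call(rbind, strsplit(ks, ":", fixed = TRUE))
  bins <- data.frame(
    a_mid = (as.numeric(parts[, 1]) + 0.5) * wa,
    b_mid = (as.numeric(parts[, 2]) + 0.5) * wb,
    count = as.integer(cnt),
    fraction = as.numeric(cnt) / length(key),
    color_mean = as.numeric(cmean))
  bins <- bins[order(bins$a_mid, bins$b_mid), , drop = FALSE]
  rownames(bins) <- NULL
  top <- bins[bins$count == max(bins$count), , drop = FALSE]
  modal <- top[order(top$a_mid, top$b_mid), , drop = FALSE][1, ]
  base::structure(list(bins = bins, modal = modal, axes = axes,
                       color = color, bin_widths = c(wa, wb)),
                  class = "density_map")
}

#' Per-frame geometry of one donor-ring pair along a trajectory
#'
#' @param structure a multi-model `nhpi_structure`.
#' @param donor_chain,donor_resno,ring_chain,ring_resno pair addresses.
#' @param donor_icode,ring_icode insertion codes.
#' @param geometry a [geometry_config()].
#' @return data frame with `frame` plus the six parameters per model.
#' @export
trajectory_geometry_series <- function(structure, donor_chain, donor_resno,
                                       ring_chain, ring_resno,
                                       donor_icode = "", ring_icode = "",
                                       geometry = geometry_config()) {
  rows <- lapply(seq_along(structure$models), function(k) {
    m <- structure$models[[k]]
    dn <- build_amide_donor(
      residue_atoms(m, donor_chain, donor_resno, donor_icode), geometry)
    rg <- build_ring_frame(
      residue_atoms(m, ring_chain, ring_resno, ring_icode))
    g <- compute_pair_geometry(dn, rg, geometry)
    cbind(frame = k, g[, c("d_nm", "theta", "omega", "d_cg_pi", "tau",
                           "chi", "h_used")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of frames satisfying the NH-pi cutoffs
#'
#' @param series geometry series (columns `d_nm`, `theta`, `omega`).
#' @param config a [screen_config()].
#' @return fraction in `[0, 1]`.
#' @export
cutoff_occupancy <- function(series, config = screen_config()) {
  if (!nrow(series)) stop("empty geometry series")
  mean(series$d_nm < config$cutoff_d_nm &
         series$theta < config$cutoff_theta &
         series$omega > config$cutoff_omega)
}

#' Melting temperature from a CD thermal-denaturation curve
#'
#' Fits linear folded and unfolded baselines on the stated temperature
#' windows (defaults: the lowest and highest quarters of the temperature
#' range), forms the folded fraction
#' `F(T) = (theta(T) - theta_U(T)) / (theta_F(T) - theta_U(T))`, and
#' reports the melting temperature as the temperature where `F` crosses
#' 0.5 (linear interpolation between bracketing points).  A curve whose
#' `F` never crosses 0.5 is an error (`"no transition"`); a non-monotone
#' curve yields the first crossing with a warning.
#'
#' @param temperature ascending temperatures (degrees C).
#' @param ellipticity observed ellipticities.
#' @param folded_window,unfolded_window optional `c(lo, hi)` temperature
#'   windows for the baseline fits.
#' @return list of class `melt_curve`: `tm`, `F` (folded-fraction
#'   series), `folded_fit`, `unfolded_fit` (intercept/slope),
#'   `temperature`, `ellipticity`.
#' @export
melting_temperature <- function(temperature, ellipticity,
                                folded_window = NULL,
                                unfolded_window = NULL) {
  stopifnot(length(temperature) == length(ellipticity),
            length(temperature) >= 10)
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  rng <- range(temperature)
  span <- diff(rng)
  if (is.null(folded_window))
    folded_window <- c(rng[1], rng[1] + 0.25 * span)
  if (is.null(unfolded_window))
    unfolded_window <- c(rng[2] - 0.25 * span, rng[2])
  fit_window <- function(w) {
    sel <- temperature >= w[1] & temperature <= w[2]
    if (sum(sel) < 2) stop("baseline window contains fewer than 2 points")
    stats::coef(stats::lm(ellipticity[sel] ~ temperature[sel]))
  }
  fb <- fit_window(folded_window)
  ub <- fit_window(unfolded_window)
  thF <- fb[1] + fb[2] * temperature
  thU <- ub[1] + ub[2] * temperature
  denom <- thF - thU
  if (all(abs(denom) < 1e-8 * max(abs(ellipticity), 1)))
    stop("no transition: folded and unfolded baselines coincide")
  Fv <- (ellipticity - thU) / denom
  if (any(Fv < -0.2 | Fv > 1.2))
    warning("folded fraction outside [-0.2, 1.2] after baseline fit")
  s <- Fv - 0.5
  n <- length(s)
  cross <- which(s[-n] * s[-1] < 0 | s[-n] == 0)
  if (s[n] == 0) cross <- c(cross, n)
  if (!length(cross)) stop("no transition: F(T) never crosses 0.5")
  if (length(cross) > 1)
    warning("F(T) crosses 0.5 more than once; reporting first crossing")
  i <- cross[1]
  tm <- if (s[i] == 0) temperature[i]
        else temperature[i] + (0.5 - Fv[i]) *
          (temperature[i + 1] - temperature[i]) / (Fv[i + 1] - Fv[i])
  base::structure(list(tm = unname(tm), F = Fv,
                       folded_fit = unname(fb), unfolded_fit = unname(ub),
                       folded_window = folded_window,
                       unfolded_window = unfolded_window,
                       temperature = temperature,
                       ellipticity = ellipticity),
                  class = "melt_curve")
}
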