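#' @title Synthetic fixtures
#' @description Generates everything the pipeline can be tested on
#'   without downloads: ideal rings, donor-ring fragments planted at
#'   prescribed six-parameter geometry (the constructive inverse of the
#'   measurement), decoy structures with known pass/fail counts,
#'   multi-model trajectories with a planted cutoff occupancy, and
#'   two-state melting curves.  Every generator is deterministic given
#'   its seed.
#' @name synthetic_data
NULL

RING_CC <- 1.39   # aromatic C-C bond length
CB_CG <- 1.51     # substituent bond length

make_atom_df <- function(names, coords, resname, chain, resno,
                         elements = NULL, serial_start = 1L) {
  coords <- rbind(coords)
  if (is.null(elements))
    elements <- substr(gsub("[0-9]", "", names), 1, 1)
  data.frame(record = "ATOM",
             serial = seq(serial_start, length.out = length(names)),
             name = names, altloc = "", resname = resname, chain = chain,
             resno = as.integer(resno), icode = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occupancy = 1, bfactor = 0, element = elements,
             is_hetero = FALSE, stringsAsFactors = FALSE)
}

hexagon_coords <- function(center, start_angle = 0) {
  ang <- rad(start_angle + seq(0, 300, by = 60))
  sweep(cbind(RING_CC * cos(ang), RING_CC * sin(ang), 0), 2, center, `+`)
}

#' Ideal aromatic ring fragment
#'
#' A regular planar hexagon (C-C 1.39 Angstrom) centred at the origin in
#' the z = 0 plane, canonical traversal counter-clockwise viewed from +z
#' (so [build_ring_frame()] reports normal +z).  The `"phe"` kind adds a
#' C-beta 1.51 Angstrom from C-gamma, in-plane, pointing outward.
#'
#' @param kind `"benzene"` (atoms C1..C6) or `"phe"` (Phe naming,
#'   CG..CD2 plus CB).
#' @param R,t rigid pose: coordinates become `coords %*% t(R) + t`.
#' @param chain,resno residue addressing.
#' @return atom data frame.
#' @export
make_ideal_ring <- function(kind = c("phe", "benzene"), R = diag(3),
                            t = c(0, 0, 0), chain = "B", resno = 1L) {
  kind <- match.arg(kind)
  P <- hexagon_coords(c(0, 0, 0))
  if (kind == "phe") {
    cb <- P[1, ] * (RING_CC + CB_CG) / RING_CC
    P <- rbind(cb, P)
    nm <- c("CB", PHE_RING)
    resname <- "PHE"
  } else {
    nm <- TOL_RING
    resname <- "BEN"
  }
  P <- sweep(P %*% t(R), 2, t, `+`)
  make_atom_df(nm, P, resname, chain, resno)
}

#' Ideal toluene fragment in its own frame
#'
#' Ring carbon C1 at the origin, methyl carbon CM at (-1.51, 0, 0), ring
#' centroid at (+1.39, 0, 0), ring in the z = 0 plane with canonical
#' normal +z - i.e. already expressed in the toluene-anchored frame of
#' [build_toluene_frame()].
#'
#' @param chain,resno residue addressing.
#' @return atom data frame.
#' @export
make_ideal_toluene <- function(chain = "X", resno = 1L) {
  M <- c(RING_CC, 0, 0)
  P <- hexagon_coords(M, start_angle = 180)
  P <- rbind(P, c(-CB_CG, 0, 0))
  make_atom_df(c(TOL_RING, "CM"), P, "TOL", chain, resno)
}

# --- planting solver ------------------------------------------------------

# rigid amide derived constants
r_NG <- function() {
  sqrt(AMIDE_N_CD^2 + AMIDE_CD_CG^2 -
         2 * AMIDE_N_CD * AMIDE_CD_CG * cos(rad(AMIDE_CG_CD_N)))
}

perp_basis <- function(a) {
  b1 <- cross3(a, c(0, 0, 1))
  if (vnorm(b1) < 1e-6) b1 <- cross3(a, c(1, 0, 0))
  b1 <- unitv(b1)
  list(b1 = b1, b2 = cross3(a, b1))
}

rows_angle <- function(A, B) {
  cr <- cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
              A[, 3] * B[, 1] - A[, 1] * B[, 3],
              A[, 1] * B[, 2] - A[, 2] * B[, 1])
  deg(atan2(sqrt(rowSums(cr^2)), rowSums(A * B)))
}

# max-over-hydrogens omega for amides built on N->Cdelta direction u and
# in-plane perpendicular p; H directions are at 120 deg from u
omega_rows <- function(N, M, U, P) {
  ca <- -0.5; sa <- sqrt(3) / 2
  vM <- matrix(M - N, nrow(U), 3, byrow = TRUE)
  o <- matrix(0, nrow(U), 2)
  for (k in 1:2) {
    D <- ca * U + (if (k == 1) sa else -sa) * P
    o[, k] <- rows_angle(-D, vM - D)
  }
  apply(o, 1, max)
}

# find parameter value where f (vectorised profile) hits zero; returns NA
# when the target is unreachable
solve_profile <- function(profile, target, lo = 0, hi = 2 * pi,
                          n_grid = 721) {
  g <- seq(lo, hi, length.out = n_grid)
  f <- profile(g) - target
  sc <- which(f[-length(f)] * f[-1] < 0)
  if (length(sc)) {
    r <- stats::uniroot(function(x) profile(x) - target,
                        lower = g[sc[1]], upper = g[sc[1] + 1],
                        tol = 1e-14)
    return(r$root)
  }
  # tangential solution (e.g. omega = 180 at the profile maximum)
  i0 <- which.min(abs(f))
  lo2 <- g[max(1, i0 - 1)]; hi2 <- g[min(n_grid, i0 + 1)]
  op <- stats::optimize(function(x) abs(profile(x) - target),
                        lower = lo2, upper = hi2, tol = 1e-12)
  if (op$objective < 1e-7) return(op$minimum)
  NA_real_
}

plant_error <- function(msg) {
  stop(base::structure(class = c("nhpi_plant_error", "error", "condition"),
                       list(message = msg, call = sys.call(-1))))
}

#' Plant a donor-ring fragment at prescribed geometry
#'
#' Constructive inverse of [compute_pair_geometry()]: builds an ideal Phe
#' ring (centroid at the origin, normal +z) and a rigid Gln-like amide
#' whose measured parameters reproduce every requested value within 1e-6
#' (verified internally).  The amide N is placed on the cone fixed by
#' `d_nm` and `theta` (at the given `azimuth`); `tau`/`chi` then place
#' the reference carbon on the rigid amide skeleton, and the remaining
#' spin degree of freedom is solved so the hydrogen-side angle `omega`
#' (maximised over the two amide hydrogens) matches.  Requests that the
#' rigid amide geometry cannot satisfy are rejected with an error of
#' class `nhpi_plant_error` naming the violated constraint.
#'
#' @param d_nm,theta target bond-conformation parameters (Angstrom,
#'   degrees).
#' @param omega optional target N-H...M angle (degrees).
#' @param tau optional target signed elevation of the reference carbon
#'   (degrees, -90..90).
#' @param chi optional target in-plane azimuth (degrees, 0..180;
#'   requires `tau`).
#' @param azimuth free parameter: azimuth of N about the ring normal
#'   (degrees, default 0).
#' @param jitter Gaussian coordinate noise sigma in Angstrom applied to
#'   all atoms after construction (default 0; uses the current RNG
#'   stream).
#' @return list of class `planted_pair`: `donor` and `ring` atom data
#'   frames, `geometry` (the measured [compute_pair_geometry()] row) and
#'   `requested`.
#' @export
plant_pair_fragment <- function(d_nm, theta, omega = NULL, tau = NULL,
                                chi = NULL, azimuth = 0, jitter = 0) {
  stopifnot(d_nm > 0, theta >= 0, theta <= 90)
  if (!is.null(omega)) stopifnot(omega > 0, omega <= 180)
  if (!is.null(tau)) stopifnot(tau >= -90, tau <= 90)
  if (!is.null(chi)) {
    stopifnot(chi >= 0, chi <= 180)
    if (is.null(tau)) stop("a chi target requires a tau target")
  }
  ring <- make_ideal_ring("phe", chain = "B", resno = 1L)
  M <- c(0, 0, 0)
  subst <- c(-1, 0, 0)   # CB->CG direction of the ideal ring
  az <- rad(azimuth)
  th <- rad(theta)
  N <- d_nm * c(sin(th) * cos(az), sin(th) * sin(az), cos(th))

  if (!is.null(tau)) {
    heavy <- plant_with_tau(N, M, subst, tau, chi, omega, azimuth)
  } else {
    heavy <- plant_free_sidechain(N, M, omega)
  }
  donor <- make_atom_df(c("CG", "CD", "OE1", "NE2"),
                        rbind(heavy$CG, heavy$CD, heavy$O, N),
                        "GLN", "A", 1L,
                        elements = c("C", "C", "O", "N"))
  if (jitter > 0) {
    donor[, c("x", "y", "z")] <- donor[, c("x", "y", "z")] +
      stats::rnorm(3 * nrow(donor), sd = jitter)
    ring[, c("x", "y", "z")] <- ring[, c("x", "y", "z")] +
      stats::rnorm(3 * nrow(ring), sd = jitter)
  }
  g <- compute_pair_geometry(build_amide_donor(donor),
                             build_ring_frame(ring))
  requested <- list(d_nm = d_nm, theta = theta, omega = omega, tau = tau,
                    chi = chi)
  if (jitter == 0) {
    achieved <- c(d_nm = g$d_nm, theta = g$theta, omega = g$omega,
                  tau = g$tau, chi = g$chi)
    for (nm in names(requested)) {
      want <- requested[[nm]]
      if (is.null(want)) next
      if (abs(achieved[[nm]] - want) > 1e-6)
        plant_error(sprintf(
          "constructed fragment misses target %s (wanted %.6f, got %.6f)",
          nm, want, achieved[[nm]]))
    }
  }
  base::structure(list(donor = donor, ring = ring, geometry = g,
                       requested = requested),
                  class = "planted_pair")
}

# free side chain: whole amide in the plane spanned by v = unit(M - N)
# and a deterministic perpendicular w; spin angle beta solved for omega
plant_free_sidechain <- function(N, M, omega) {
  v <- unitv(M - N)
  w <- perp_basis(v)$b1
  uP <- function(beta) {
    U <- outer(cos(beta), v) + outer(sin(beta), w)
    P <- outer(-sin(beta), v) + outer(cos(beta), w)
    list(U = U, P = P)
  }
  if (is.null(omega)) {
    beta <- pi
  } else {
    prof <- function(beta) {
      b <- uP(beta)
      omega_rows(N, M, b$U, b$P)
    }
    beta <- solve_profile(prof, omega)
    if (is.na(beta))
      plant_error(sprintf(
        "omega target %.3f unreachable: the trigonal amide hydrogens cannot realise it at this d_nm/theta", omega))
  }
  b <- uP(beta)
  u <- b$U[1, ]; p <- b$P[1, ]
  amide_from_up(N, u, p)
}

amide_from_up <- function(N, u, p) {
  CD <- N + AMIDE_N_CD * u
  CG <- CD + AMIDE_CD_CG * (cos(rad(AMIDE_CG_CD_N)) * (-u) +
                              sin(rad(AMIDE_CG_CD_N)) * p)
  O <- CD + AMIDE_CD_O * (cos(rad(AMIDE_O_CD_N)) * (-u) -
                            sin(rad(AMIDE_O_CD_N)) * p)
  list(CD = CD, CG = CG, O = O)
}

# tau (and optionally chi) fix the reference carbon; the amide spin about
# the N-CG axis is then solved for omega
plant_with_tau <- function(N, M, subst, tau, chi, omega, azimuth) {
  r_ng <- r_NG()
  dir_of <- function(phi)
    c(cos(rad(tau)) * cos(phi), cos(rad(tau)) * sin(phi), sin(rad(tau)))
  # the reference carbon lies on the ray from M at elevation tau and on
  # the sphere |CG - N| = r_ng: up to two root branches (extended /
  # compact); branch 1 is the larger (extended) distance
  cg_of <- function(phi, branch) {
    dir <- dir_of(phi)
    bh <- dot3(dir, N)
    disc <- bh^2 - (sum(N * N) - r_ng^2)
    if (disc < 0) return(NULL)
    tt <- c(bh + sqrt(disc), bh - sqrt(disc))
    t1 <- tt[branch]
    if (is.na(t1) || t1 <= 1e-9) return(NULL)
    M + t1 * dir
  }
  chi_of_cg <- function(CG) {
    a <- N - CG
    a_p <- c(a[1], a[2], 0)
    if (vnorm(a_p) < 1e-9) return(NA_real_)
    vec_angle(a_p, subst)
  }
  cg_candidates <- list()
  if (!is.null(chi)) {
    g <- seq(0, 2 * pi, length.out = 721)
    for (branch in 1:2) {
      prof <- function(phi)
        vapply(phi, function(ph) {
          cg <- cg_of(ph, branch)
          if (is.null(cg)) return(NA_real_)
          chi_of_cg(cg)
        }, numeric(1))
      f <- prof(g) - chi
      ok <- !is.na(f)
      sc <- which(ok[-length(f)] & ok[-1] & f[-length(f)] * f[-1] < 0)
      for (s in sc) {
        phi <- stats::uniroot(function(x) prof(x) - chi,
                              lower = g[s], upper = g[s + 1],
                              tol = 1e-14)$root
        cg <- cg_of(phi, branch)
        if (!is.null(cg)) cg_candidates[[length(cg_candidates) + 1L]] <- cg
      }
      if (!length(sc) && any(ok)) {
        i0 <- which.min(abs(f))
        obj <- function(x) {
          y <- abs(prof(x) - chi)
          if (is.na(y)) 1e6 else y
        }
        op <- stats::optimize(obj, lower = g[max(1, i0 - 1)],
                              upper = g[min(length(g), i0 + 1)],
                              tol = 1e-12)
        if (op$objective < 1e-7) {
          cg <- cg_of(op$minimum, branch)
          if (!is.null(cg))
            cg_candidates[[length(cg_candidates) + 1L]] <- cg
        }
      }
    }
    if (!length(cg_candidates))
      plant_error(sprintf(
        "chi target %.3f unreachable at the requested tau/d_nm/theta", chi))
  } else {
    # chi free: any azimuth of the reference carbon is acceptable; try a
    # small set of placements (both root branches) until omega is soluble
    phis <- rad(azimuth) + seq(0, 2 * pi, length.out = 9)[-9]
    for (branch in 1:2)
      for (ph in phis) {
        cg <- cg_of(ph, branch)
        if (!is.null(cg))
          cg_candidates[[length(cg_candidates) + 1L]] <- cg
      }
    if (!length(cg_candidates))
      plant_error("tau target incompatible with d_nm/theta: no reference-carbon placement on the rigid amide")
  }
  # spin the amide about the N-CG axis; try every chi-consistent CG
  cosA <- (AMIDE_N_CD^2 + r_ng^2 - AMIDE_CD_CG^2) / (2 * AMIDE_N_CD * r_ng)
  sinA <- sqrt(1 - cosA^2)
  for (CG in cg_candidates) {
    a <- unitv(CG - N)
    pb <- perp_basis(a)
    heavy_of <- function(psi) {
      e <- cos(psi) * pb$b1 + sin(psi) * pb$b2
      CD <- N + AMIDE_N_CD * (cosA * a + sinA * e)
      u <- unitv(CD - N)
      wd <- CG - CD
      p <- unitv(wd - dot3(wd, u) * u)
      O <- CD + AMIDE_CD_O * (cos(rad(AMIDE_O_CD_N)) * (-u) -
                                sin(rad(AMIDE_O_CD_N)) * p)
      list(CD = CD, CG = CG, O = O, u = u, p = p)
    }
    if (is.null(omega)) return(heavy_of(0))
    prof <- function(psi)
      vapply(psi, function(ps) {
        h <- heavy_of(ps)
        omega_rows(N, M, rbind(h$u), rbind(h$p))
      }, numeric(1))
    psi <- solve_profile(prof, omega)
    if (!is.na(psi)) return(heavy_of(psi))
  }
  plant_error(sprintf(
    "omega target %.3f unreachable: the trigonal amide hydrogens cannot realise it at the requested tau/chi", omega))
}

#' Pack planted pairs into a structure model
#'
#' @param pairs list of `planted_pair` objects.
#' @param poses optional list of `list(R, t)` rigid poses, one per pair.
#' @return a single-model atom data frame; residues are renumbered
#'   (donor `2i - 1`, ring `2i`) on chain A with sequential serials.
#' @export
pack_pairs_model <- function(pairs, poses = NULL) {
  rows <- list()
  serial <- 1L
  for (i in seq_along(pairs)) {
    d <- pairs[[i]]$donor; r <- pairs[[i]]$ring
    if (!is.null(poses)) {
      xf <- function(df) {
        P <- as.matrix(df[, c("x", "y", "z")])
        P <- sweep(P %*% t(poses[[i]]$R), 2, poses[[i]]$t, `+`)
        df[, c("x", "y", "z")] <- P
        df
      }
      d <- xf(d); r <- xf(r)
    }
    d$chain <- "A"; d$resno <- 2L * i - 1L
    r$chain <- "A"; r$resno <- 2L * i
    d$serial <- seq(serial, length.out = nrow(d)); serial <- serial + nrow(d)
    r$serial <- seq(serial, length.out = nrow(r)); serial <- serial + nrow(r)
    rows[[length(rows) + 1L]] <- rbind(d, r)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sample_plant <- function(kind) {
  spec <- switch(kind,
    pass = list(d = stats::runif(1, 2.9, 4.0),
                th = stats::runif(1, 2, 19),
                om = stats::runif(1, 126, 172)),
    far = list(d = stats::runif(1, 6.5, 9.0),
               th = stats::runif(1, 2, 19),
               om = stats::runif(1, 126, 172)),
    theta_fail = list(d = stats::runif(1, 2.9, 4.0),
                      th = stats::runif(1, 32, 58),
                      om = stats::runif(1, 126, 172)),
    omega_fail = list(d = stats::runif(1, 2.9, 4.0),
                      th = stats::runif(1, 2, 19),
                      om = stats::runif(1, 95, 115)))
  spec
}

plant_sampled <- function(kind, max_tries = 50) {
  for (k in seq_len(max_tries)) {
    s <- sample_plant(kind)
    p <- tryCatch(plant_pair_fragment(s$d, s$th, s$om),
                  nhpi_plant_error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  stop("could not sample a feasible '", kind, "' plant")
}

#' Generate a decoy structure with known pass/fail counts
#'
#' Embeds `n_pass` donor-ring pairs sampled at least 0.2 Angstrom / 5
#' degrees inside every cutoff and `n_fail` pairs at least that far
#' outside (failing by distance, theta or omega), all pairs mutually
#' separated by more than 12 Angstrom and posed with seeded random rigid
#' transforms.  Deterministic per seed.
#'
#' @param n_pass,n_fail pair counts.
#' @param seed RNG seed.
#' @return an `nhpi_structure` (single model).
#' @export
generate_decoy_structure <- function(n_pass, n_fail, seed = 1) {
  stopifnot(n_pass >= 0, n_fail >= 0)
  set.seed(seed)
  n <- n_pass + n_fail
  kinds <- c(rep("pass", n_pass),
             rep(c("far", "theta_fail", "omega_fail"),
                 length.out = n_fail))
  pairs <- lapply(kinds, plant_sampled)
  poses <- lapply(seq_len(max(n, 1)), function(i)
    list(R = random_rotation(), t = c(18 * (i - 1), 0, 0)))
  if (n == 0) stop("at least one pair required")
  model <- pack_pairs_model(pairs, poses)
  new_structure(list(model), id = sprintf("decoy-%d", seed))
}

#' Generate a multi-model trajectory with a planted cutoff occupancy
#'
#' `n_frames` models of a single donor-ring pair; a seeded random subset
#' of `floor(pass_fraction * n_frames)` frames is planted inside the
#' cutoffs (with 0.2 Angstrom / 5 degree margins) and the rest outside
#' (theta pushed past the cutoff).  Gaussian coordinate jitter `noise_sd`
#' is applied to every atom.
#'
#' @param n_frames number of models.
#' @param pass_fraction target fraction of passing frames in `[0, 1]`.
#' @param noise_sd coordinate jitter sigma (Angstrom, default 0.02).
#' @param seed RNG seed.
#' @return an `nhpi_structure` with `n_frames` models; donor at A:GLN1,
#'   ring at B:PHE1 in every model.
#' @export
generate_trajectory <- function(n_frames, pass_fraction, noise_sd = 0.02,
                                seed = 1) {
  stopifnot(n_frames >= 1, pass_fraction >= 0, pass_fraction <= 1)
  set.seed(seed)
  n_pass <- floor(pass_fraction * n_frames)
  pass_idx <- sample.int(n_frames, n_pass)
  is_pass <- seq_len(n_frames) %in% pass_idx
  models <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    p <- plant_sampled(if (is_pass[i]) "pass" else "theta_fail")
    model <- rbind(p$donor, p$ring)
    if (noise_sd > 0)
      model[, c("x", "y", "z")] <- model[, c("x", "y", "z")] +
        stats::rnorm(3 * nrow(model), sd = noise_sd)
    model$serial <- seq_len(nrow(model))
    models[[i]] <- model
  }
  new_structure(models, id = sprintf("traj-%d", seed))
}

#' Generate a two-state melting curve with linear baselines
#'
#' Folded fraction `F(T) = 1 / (1 + exp((T - tm) / width))`; observed
#' signal `theta_U(T) + (theta_F(T) - theta_U(T)) * F(T)` plus Gaussian
#' noise.  An `amplitude` of 0 makes the curve baseline-only ("no
#' transition" downstream).
#'
#' @param tm melting temperature (degrees C), inside the temperature
#'   range.
#' @param temperatures measurement temperatures (default 4-80 C every
#'   1 C).
#' @param amplitude folded-minus-unfolded signal difference at the low
#'   end of the range; 0 gives a baseline-only (transition-free) curve.
#' @param folded_tilt additional slope of the folded baseline relative to
#'   the unfolded one (signal units per degree C); only applied when
#'   `amplitude` is nonzero.
#' @param unfolded_slope,unfolded_intercept unfolded baseline parameters.
#' @param width transition width parameter (degrees C, default 2).
#' @param noise_sd Gaussian noise sigma in signal units.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return data frame `temperature`, `ellipticity`; the true parameters
#'   are attached as attributes.
#' @export
generate_melt_curve <- function(tm, temperatures = seq(4, 80, by = 1),
                                amplitude = 3000, folded_tilt = -6,
                                unfolded_slope = -2,
                                unfolded_intercept = 300, width = 2,
                                noise_sd = 0, seed = 1) {
  stopifnot(tm > min(temperatures), tm < max(temperatures), width > 0)
  thU <- unfolded_intercept + unfolded_slope * temperatures
  tilt <- if (amplitude == 0) 0 else folded_tilt
  thF <- thU + amplitude + tilt * (temperatures - min(temperatures))
  Fv <- 1 / (1 + exp((temperatures - tm) / width))
  y <- thU + (thF - thU) * Fv
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  out <- data.frame(temperature = temperatures, ellipticity = y)
  attr(out, "true") <- list(tm = tm, amplitude = amplitude, width = width)
  out
}
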