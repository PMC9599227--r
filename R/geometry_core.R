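#' @title Donor-ring pair geometry
#' @description Builds an oriented frame on a phenyl ring, places
#'   theoretical amide hydrogens, and measures the six parameters that
#'   describe an NH-pi contact: three bond-conformation parameters
#'   (`d_nm`, `theta`, `omega`) and three side-chain-position parameters
#'   (`d_cg_pi`, `tau`, `chi`).
#' @name geometry_core
NULL

PHE_RING <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
TOL_RING <- c("C1", "C2", "C3", "C4", "C5", "C6")

# ideal side-chain amide internal geometry (Angstrom / degrees); used both
# for theoretical construction and by the synthetic planting solver
AMIDE_N_CD   <- 1.33   # N-C(=O) bond
AMIDE_CD_CG  <- 1.52   # C(=O)-C bond
AMIDE_CD_O   <- 1.23   # C=O bond
AMIDE_CG_CD_N <- 116.7 # C-C(=O)-N angle
AMIDE_O_CD_N  <- 121.9 # O=C-N angle
AMIDE_H_N_CD  <- 120   # H-N-C(=O) angle, trigonal sp2

#' Geometry configuration
#'
#' @param d_cg_pi_mode how the reference-carbon/ring distance is measured:
#'   `"centroid"` (default) is the distance from the reference carbon
#'   (Gln C-gamma or the acetamide methyl carbon) to the ring centroid;
#'   `"plane"` is the perpendicular distance to the ring plane.
#' @param hydrogen_bond_length N-H bond length in Angstrom for theoretical
#'   hydrogen placement (default 1.0).
#' @return a list of class `geometry_config`.
#' @export
geometry_config <- function(d_cg_pi_mode = c("centroid", "plane"),
                            hydrogen_bond_length = 1.0) {
  d_cg_pi_mode <- match.arg(d_cg_pi_mode)
  stopifnot(hydrogen_bond_length > 0)
  structure(list(d_cg_pi_mode = d_cg_pi_mode,
                 hydrogen_bond_length = hydrogen_bond_length),
            class = "geometry_config")
}

atom_xyz <- function(res, name) {
  i <- which(res$name == name)
  if (!length(i)) return(NULL)
  c(res$x[i[1]], res$y[i[1]], res$z[i[1]])
}

res_address <- function(res) {
  if (!nrow(res)) return("")
  sprintf("%s:%s%d%s", res$chain[1], res$resname[1], res$resno[1],
          res$icode[1])
}

#' Build an oriented frame on a six-membered aromatic ring
#'
#' The centroid is the arithmetic mean of the six ring carbons and the
#' normal is the least-squares plane normal.  The normal sign is fixed by
#' the right-hand rule on the canonical atom traversal
#' (CG-CD1-CE1-CZ-CE2-CD2 for Phe, C1..C6 for toluene/benzene), so signed
#' elevations (`tau`) are reproducible.  Rings whose planarity RMS exceeds
#' 0.1 Angstrom are flagged (`planar_ok = FALSE`) but still returned.
#'
#' @param residue atom data frame of a Phe residue (ring atoms
#'   CG,CD1,CE1,CZ,CE2,CD2, optionally CB) or a benzene/toluene fragment
#'   (C1..C6, optionally methyl CM/CH3/C7).
#' @return an object of class `ring_frame` with fields `center` (centroid
#'   M), `normal`, `xhat`, `yhat` (in-plane right-handed axes),
#'   `substituent` (unit C-beta to C-gamma direction, or `NULL`),
#'   `atoms_used`, `planarity_rms`, `planar_ok`, `address`.
#' @export
build_ring_frame <- function(residue) {
  stopifnot(is.data.frame(residue), nrow(residue) > 0)
  if (all(PHE_RING %in% residue$name)) {
    ring_names <- PHE_RING
    sub_from <- "CB"; sub_to <- "CG"
  } else if (all(TOL_RING %in% residue$name)) {
    ring_names <- TOL_RING
    sub_from <- intersect(c("CM", "CH3", "C7"), residue$name)[1]
    sub_to <- "C1"
  } else {
    have <- intersect(c(PHE_RING, TOL_RING), residue$name)
    miss_phe <- setdiff(PHE_RING, residue$name)
    miss_tol <- setdiff(TOL_RING, residue$name)
    miss <- if (length(miss_phe) <= length(miss_tol)) miss_phe else miss_tol
    stop("ring atoms missing from residue ", res_address(residue), ": ",
         paste(miss, collapse = ", "))
  }
  P <- t(vapply(ring_names, function(nm) atom_xyz(residue, nm),
                numeric(3)))
  M <- colMeans(P)
  C <- sweep(P, 2, M)
  sv <- svd(C)
  normal <- sv$v[, 3]
  resid_z <- C %*% normal
  planarity_rms <- sqrt(mean(resid_z^2))
  # orient by the polygon traversal (right-hand rule)
  area <- c(0, 0, 0)
  for (i in seq_len(6)) {
    j <- if (i == 6) 1 else i + 1
    area <- area + cross3(C[i, ], C[j, ])
  }
  if (dot3(normal, area) < 0) normal <- -normal
  normal <- unitv(normal)
  xhat <- unitv(C[1, ] - dot3(C[1, ], normal) * normal)
  yhat <- cross3(normal, xhat)
  substituent <- NULL
  if (!is.na(sub_from) && !is.null(atom_xyz(residue, sub_from))) {
    substituent <- unitv(atom_xyz(residue, sub_to) -
                           atom_xyz(residue, sub_from))
  }
  structure(list(center = M, normal = normal, xhat = xhat, yhat = yhat,
                 substituent = substituent, atoms_used = ring_names,
                 planarity_rms = planarity_rms,
                 planar_ok = planarity_rms <= 0.1,
                 address = res_address(residue)),
            class = "ring_frame")
}

# shared hydrogen construction: two sp2 H at bond length from N, in the
# amide plane defined by (Cdelta, Oe1, N), each at 120 deg from N->Cdelta
amide_hydrogens <- function(N, CD, O, bond = 1.0) {
  u <- N - CD
  w <- O - CD
  nrm <- cross3(u, w)
  if (vnorm(nrm) < 1e-6 * vnorm(u) * vnorm(w))
    stop("amide plane undefined (near-linear C-N/C-O geometry)")
  plane_n <- unitv(nrm)
  u <- unitv(u)              # Cdelta -> N
  p <- cross3(plane_n, u)    # in-plane, perpendicular to N-Cdelta axis
  ca <- cos(rad(AMIDE_H_N_CD))
  sa <- sin(rad(AMIDE_H_N_CD))
  # H-N-Cdelta = 120 deg: H direction makes 120 deg with N->Cdelta (= -u
  # viewed from N... N->Cdelta is -u from N; careful: u points Cdelta->N)
  d1 <- ca * (-u) + sa * p
  d2 <- ca * (-u) - sa * p
  rbind(N + bond * d1, N + bond * d2)
}

#' Build an amide donor with theoretical hydrogens
#'
#' Hydrogens present in the input are ignored; two hydrogens are placed at
#' `hydrogen_bond_length` (default 1.0 Angstrom) from the amide nitrogen,
#' in the amide plane, trigonal sp2 (each H-N-C angle 120 degrees, on
#' opposite sides of the N-C axis).
#'
#' @param residue atom data frame: GLN (CG, CD, OE1, NE2), ASN (CB, CG,
#'   OD1, ND2), or an acetamide fragment (methyl CM/CH3/C1 plus C, O, N).
#' @param config a [geometry_config()].
#' @return an object of class `amide_donor` with `N`, `H` (2 x 3 matrix),
#'   `Cgamma` (reference carbon: Gln CG / Asn CB / acetamide methyl C),
#'   `Cdelta` (carbonyl carbon), `address`.
#' @export
build_amide_donor <- function(residue, config = geometry_config()) {
  stopifnot(is.data.frame(residue), nrow(residue) > 0)
  schemes <- list(
    GLN = c(cg = "CG", cd = "CD", o = "OE1", n = "NE2"),
    ASN = c(cg = "CB", cd = "CG", o = "OD1", n = "ND2"))
  rn <- residue$resname[1]
  if (!is.null(schemes[[rn]])) {
    sc <- schemes[[rn]]
  } else {
    meth <- intersect(c("CM", "CH3", "C1"), residue$name)
    if (length(meth) && all(c("C", "O", "N") %in% residue$name)) {
      sc <- c(cg = meth[1], cd = "C", o = "O", n = "N")
    } else {
      stop("residue ", res_address(residue),
           " is not a recognised amide donor (GLN/ASN/acetamide)")
    }
  }
  pos <- lapply(sc, function(nm) atom_xyz(residue, nm))
  absent <- sc[vapply(pos, is.null, logical(1))]
  if (length(absent))
    stop("amide donor atoms missing from residue ", res_address(residue),
         ": ", paste(absent, collapse = ", "))
  H <- amide_hydrogens(pos$n, pos$cd, pos$o,
                       bond = config$hydrogen_bond_length)
  structure(list(N = pos$n, H = H, Cgamma = pos$cg, Cdelta = pos$cd,
                 address = res_address(residue)),
            class = "amide_donor")
}

#' Compute the six geometric parameters of a donor-ring pair
#'
#' * `d_nm`: distance from the amide N to the ring centroid M.
#' * `theta`: acute angle (0-90 deg) between the M-to-N vector and the
#'   ring normal (either sign of the normal gives the same value).
#' * `omega`: N-H...M angle at the hydrogen, maximised over the two amide
#'   hydrogens; `h_used` records which hydrogen won.
#' * `d_cg_pi`: reference-carbon/ring distance per the configured mode.
#' * `tau`: signed elevation (degrees, -90..90) of the centroid-to-Cgamma
#'   direction above the ring plane; positive on the +normal side.
#' * `chi`: unsigned angle (0-180 deg) between the in-plane projections of
#'   the Cgamma-to-N vector and the ring substituent (C-beta to C-gamma)
#'   direction; `NA` when either projection is degenerate or the ring has
#'   no substituent.
#'
#' @param donor an [build_amide_donor()] result.
#' @param ring a [build_ring_frame()] result.
#' @param config a [geometry_config()].
#' @return a one-row data frame of class `pair_geometry`.
#' @export
compute_pair_geometry <- function(donor, ring, config = geometry_config()) {
  stopifnot(inherits(donor, "amide_donor"), inherits(ring, "ring_frame"))
  M <- ring$center
  n <- ring$normal
  v <- donor$N - M
  d_nm <- vnorm(v)
  if (d_nm < 1e-9) stop("amide N coincides with the ring centroid")
  theta <- deg(acos(clamp1(abs(dot3(v / d_nm, n)))))
  om <- vapply(1:2, function(i) {
    H <- donor$H[i, ]
    vec_angle(donor$N - H, M - H)
  }, numeric(1))
  h_used <- which.max(om)
  omega <- om[h_used]
  g <- donor$Cgamma - M
  d_cg_pi <- switch(config$d_cg_pi_mode,
                    centroid = vnorm(g),
                    plane = abs(dot3(g, n)))
  tau <- deg(asin(clamp1(dot3(unitv(g), n))))
  chi <- NA_real_
  if (!is.null(ring$substituent)) {
    a <- donor$N - donor$Cgamma
    a_p <- a - dot3(a, n) * n
    s_p <- ring$substituent - dot3(ring$substituent, n) * n
    if (vnorm(a_p) > 1e-9 && vnorm(s_p) > 1e-9)
      chi <- vec_angle(a_p, s_p)
  }
  out <- data.frame(d_nm = d_nm, theta = theta, omega = omega,
                    d_cg_pi = d_cg_pi, tau = tau, chi = chi,
                    h_used = h_used,
                    donor_address = donor$address,
                    ring_address = ring$address,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_geometry", class(out))
  out
}
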