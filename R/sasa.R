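#' @title Solvent-accessible surface area (Shrake-Rupley)
#' @description Numerical SASA with a deterministic Fibonacci sphere
#'   quadrature and a probe sphere, plus the burial classification of
#'   donor-ring pairs by their summed residue ASA.
#' @name surface_burial
NULL

#' Default van der Waals radius set (Angstrom)
#'
#' Heavy-atom radii in the Chothia/NACCESS tradition; hydrogens are
#' excluded from SASA by default (heavy-atom convention).
#' @return named numeric vector, element symbol to radius.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# deterministic, near-uniform unit-sphere quadrature
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

guess_element <- function(name, element) {
  el <- toupper(element)
  miss <- !nzchar(el)
  if (any(miss)) {
    nm <- toupper(gsub("[0-9']", "", name[miss]))
    el[miss] <- ifelse(substr(nm, 1, 2) %in% c("CL", "BR", "SE"),
                       substr(nm, 1, 2), substr(nm, 1, 1))
  }
  el
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, `n_points` quadrature points are placed on a sphere of
#' radius `r_atom + probe`; a point is accessible when it lies outside
#' every neighbouring atom's probe-expanded sphere, and
#' `ASA = 4 * pi * (r + probe)^2 * accessible / n_points`.  Neighbours are
#' those within `r_i + r_j + 2 * probe`.  Hydrogens and (by default)
#' waters are excluded.
#'
#' @param structure an `nhpi_structure` or a bare atom data frame.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param radii named radius set (see [default_vdw_radii()]).
#' @param model model index when a structure is given.
#' @param include_waters keep water residues in the calculation?
#' @param fallback_radius radius for unknown elements; `NA` (default)
#'   makes unknown elements an error.
#' @return list of class `sasa_result`: `atoms` (atom table with `radius`
#'   and `asa` columns), `residues` (per-residue ASA), `probe`,
#'   `n_points`.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960,
                               radii = default_vdw_radii(), model = 1,
                               include_waters = FALSE,
                               fallback_radius = NA_real_) {
  m <- if (inherits(structure, "nhpi_structure"))
    structure$models[[model]] else structure
  el <- guess_element(m$name, m$element)
  keep <- el != "H"
  if (!include_waters) keep <- keep & !(m$resname %in% c("HOH", "WAT"))
  m <- m[keep, , drop = FALSE]
  el <- el[keep]
  r <- unname(radii[el])
  if (anyNA(r)) {
    if (is.na(fallback_radius))
      stop("no radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- fallback_radius
  }
  P <- as.matrix(m[, c("x", "y", "z")])
  n_atoms <- nrow(P)
  S <- fibonacci_sphere(n_points)
  asa <- numeric(n_atoms)
  re <- r + probe
  for (i in seq_len(n_atoms)) {
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2 +
      (P[, 3] - P[i, 3])^2
    nb <- which(d2 < (re[i] + r + probe)^2 & seq_len(n_atoms) != i)
    pts <- sweep(S * re[i], 2, P[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - P[j, 1])^2 + (pts[acc, 2] - P[j, 2])^2 +
        (pts[acc, 3] - P[j, 3])^2
      # points exactly on a shared boundary are owned by the lower-index
      # atom, so degenerate overlaps still partition the surface
      thr <- re[j]^2
      eps <- 1e-9 * thr
      acc[acc] <- if (j < i) dj2 >= thr + eps else dj2 >= thr - eps
    }
    asa[i] <- 4 * pi * re[i]^2 * sum(acc) / n_points
  }
  m$radius <- r
  m$asa <- asa
  key <- paste(m$chain, m$resno, m$icode, sep = "\r")
  resid <- unique(data.frame(chain = m$chain, resno = m$resno,
                             icode = m$icode, resname = m$resname,
                             stringsAsFactors = FALSE))
  resid$asa <- vapply(
    paste(resid$chain, resid$resno, resid$icode, sep = "\r"),
    function(k) sum(asa[key == k]), numeric(1), USE.NAMES = FALSE)
  base::structure(list(atoms = m, residues = resid, probe = probe,
                       n_points = n_points), class = "sasa_result")
}

#' Summed solvent accessibility of a donor-ring pair
#'
#' @param sasa a [shrake_rupley_sasa()] result.
#' @param donor_chain,donor_resno,ring_chain,ring_resno pair addresses.
#' @param donor_icode,ring_icode insertion codes.
#' @return whole-residue ASA of donor residue + ring residue (Angstrom^2).
#' @export
pair_sasa <- function(sasa, donor_chain, donor_resno, ring_chain,
                      ring_resno, donor_icode = "", ring_icode = "") {
  r <- sasa$residues
  pick <- function(ch, no, ic) {
    i <- which(r$chain == ch & r$resno == no & r$icode == ic)
    if (!length(i)) stop("residue ", ch, no, " absent from SASA result")
    r$asa[i[1]]
  }
  pick(donor_chain, donor_resno, donor_icode) +
    pick(ring_chain, ring_resno, ring_icode)
}

#' Classify the burial of a donor-ring pair from its summed ASA
#'
#' Classes: `buried` (< 30 A^2), `intermediate` (30-60 A^2, a gap bin
#' between the published bounds), `partially_exposed` (60-120 A^2,
#' exclusive) and `fully_exposed` (>= 120 A^2).
#'
#' @param pair_asa summed pair ASA in Angstrom^2 (vectorised).
#' @return character vector of class labels.
#' @export
classify_pair_burial <- function(pair_asa) {
  if (any(pair_asa < 0)) stop("negative ASA")
  ifelse(pair_asa < 30, "buried",
         ifelse(pair_asa <= 60, "intermediate",
                ifelse(pair_asa < 120, "partially_exposed",
                       "fully_exposed")))
}
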