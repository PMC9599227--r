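# Independent brute-force vector-algebra implementation of the six pair
# parameters, coded directly from their definitions with different
# primitives than the package (Newell polygon normal instead of SVD,
# acos instead of atan2 angles, Rodrigues rotations for the hydrogens).
# Used only as an oracle; never called by package code.

oracle_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

oracle_angle <- function(a, b) {
  cang <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  acos(min(1, max(-1, cang))) * 180 / pi
}

oracle_rodrigues <- function(v, axis, ang_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- ang_deg * pi / 180
  v * cos(th) + oracle_cross(k, v) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
}

# Newell's method over the ring polygon; orientation follows traversal
oracle_ring_normal <- function(P) {
  n <- c(0, 0, 0)
  for (i in seq_len(nrow(P))) {
    j <- if (i == nrow(P)) 1 else i + 1
    n <- n + c((P[i, 2] - P[j, 2]) * (P[i, 3] + P[j, 3]),
               (P[i, 3] - P[j, 3]) * (P[i, 1] + P[j, 1]),
               (P[i, 1] - P[j, 1]) * (P[i, 2] + P[j, 2]))
  }
  n / sqrt(sum(n^2))
}

# donor_res / ring_res: atom data frames (GLN and PHE naming)
oracle_pair_geometry <- function(donor_res, ring_res, bond = 1.0,
                                 mode = "centroid") {
  get <- function(res, nm) {
    i <- which(res$name == nm)
    c(res$x[i], res$y[i], res$z[i])
  }
  ringP <- t(sapply(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                    function(nm) get(ring_res, nm)))
  M <- colMeans(ringP)
  nrm <- oracle_ring_normal(ringP)
  N <- get(donor_res, "NE2"); CD <- get(donor_res, "CD")
  OE1 <- get(donor_res, "OE1"); CG <- get(donor_res, "CG")

  d_nm <- sqrt(sum((N - M)^2))
  th <- oracle_angle(N - M, nrm)
  theta <- min(th, 180 - th)

  # hydrogens: rotate the N->CD direction by +/-120 deg about the amide
  # plane normal
  plane_axis <- oracle_cross(OE1 - CD, N - CD)
  u_ncd <- (CD - N) / sqrt(sum((CD - N)^2))
  H <- rbind(N + bond * oracle_rodrigues(u_ncd, plane_axis, 120),
             N + bond * oracle_rodrigues(u_ncd, plane_axis, -120))
  omega <- max(oracle_angle(N - H[1, ], M - H[1, ]),
               oracle_angle(N - H[2, ], M - H[2, ]))

  g <- CG - M
  d_cg_pi <- if (mode == "centroid") sqrt(sum(g^2)) else abs(sum(g * nrm))
  tau <- 90 - oracle_angle(g, nrm)

  cb <- get(ring_res, "CB")
  chi <- NA_real_
  if (length(cb) == 3) {
    s <- get(ring_res, "CG") - cb
    a <- N - CG
    proj <- function(v) v - sum(v * nrm) * nrm
    ap <- proj(a); sp <- proj(s)
    if (sqrt(sum(ap^2)) > 1e-9 && sqrt(sum(sp^2)) > 1e-9)
      chi <- oracle_angle(ap, sp)
  }
  c(d_nm = d_nm, theta = theta, omega = omega, d_cg_pi = d_cg_pi,
    tau = tau, chi = chi)
}

# random rigid placement of an ideal Gln-like amide near an ideal ring;
# returns donor and ring residue tables
random_pair_placement <- function() {
  ring <- make_ideal_ring("phe")
  # ideal amide heavy-atom skeleton at the origin
  ncd <- 1.33; cdcg <- 1.52; cdo <- 1.23
  a1 <- 116.7 * pi / 180; a2 <- 121.9 * pi / 180
  N <- c(0, 0, 0); CD <- c(ncd, 0, 0)
  CG <- CD + cdcg * c(-cos(a1), sin(a1), 0)
  OE1 <- CD + cdo * c(-cos(a2), -sin(a2), 0)
  P <- rbind(CG, CD, OE1, N)
  R <- nhpi:::random_rotation()
  d <- runif(1, 2.0, 8.0)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  P <- P %*% t(R)
  P <- sweep(P, 2, d * dir - P[4, ], `+`)   # N lands at d * dir
  donor <- data.frame(record = "ATOM", serial = 1:4,
                      name = c("CG", "CD", "OE1", "NE2"), altloc = "",
                      resname = "GLN", chain = "A", resno = 1L, icode = "",
                      x = P[, 1], y = P[, 2], z = P[, 3], occupancy = 1,
                      bfactor = 0, element = c("C", "C", "O", "N"),
                      is_hetero = FALSE, stringsAsFactors = FALSE)
  list(donor = donor, ring = ring)
}
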