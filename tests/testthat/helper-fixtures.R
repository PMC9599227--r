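# Programmatic fixtures: a raw fixed-column PDB text (17 atoms over two
# residues) and small builders shared across test files.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          altloc = "", occ = 1, bf = 10, element = NULL,
                          record = "ATOM") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) <= 3) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno, x, y, z,
          occ, bf, element)
}

# GLN (9 heavy atoms) + ILE (8 heavy atoms): 17 ATOM records, 1 model
fixture_pdb_text <- function() {
  gln <- list(c("N", -1.2, 0.5, 0.0), c("CA", 0.0, 1.2, 0.2),
              c("C", 1.2, 0.4, 0.6), c("O", 1.3, -0.8, 0.5),
              c("CB", 0.1, 2.4, 1.2), c("CG", 1.3, 3.3, 1.1),
              c("CD", 1.2, 4.4, 2.1), c("OE1", 0.2, 4.6, 2.8),
              c("NE2", 2.3, 5.2, 2.2))
  ile <- list(c("N", 2.3, 1.0, 1.1), c("CA", 3.5, 0.4, 1.6),
              c("C", 4.7, 1.3, 1.4), c("O", 4.7, 2.5, 1.6),
              c("CB", 3.8, -0.9, 0.8), c("CG1", 5.0, -1.7, 1.3),
              c("CG2", 2.6, -1.8, 0.8), c("CD1", 5.4, -2.8, 0.4))
  lines <- character(0)
  serial <- 1
  for (a in gln) {
    lines <- c(lines, pdb_atom_line(serial, a[1], "GLN", "A", 1,
                                    as.numeric(a[2]), as.numeric(a[3]),
                                    as.numeric(a[4])))
    serial <- serial + 1
  }
  for (a in ile) {
    lines <- c(lines, pdb_atom_line(serial, a[1], "ILE", "A", 2,
                                    as.numeric(a[2]), as.numeric(a[3]),
                                    as.numeric(a[4])))
    serial <- serial + 1
  }
  c(lines, "END")
}

# single-model structure holding one planted pair
pair_structure <- function(p) {
  m <- rbind(p$donor, p$ring)
  m$serial <- seq_len(nrow(m))
  new_structure(list(m))
}

# bare atom table row(s) for SASA tests
simple_atoms <- function(coords, element = "C", resno = NULL) {
  coords <- rbind(coords)
  n <- nrow(coords)
  if (is.null(resno)) resno <- rep(1L, n)
  data.frame(record = "ATOM", serial = seq_len(n), name = element,
             altloc = "", resname = "LIG", chain = "A",
             resno = as.integer(resno), icode = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occupancy = 1, bfactor = 0, element = element,
             is_hetero = FALSE, stringsAsFactors = FALSE)
}

# regular icosahedron directions (12 unit vectors)
icosahedron_dirs <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
             c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

# crude staggered collagen-like triple helix: three chains of Gly-Pro-Hyp
# C-alpha traces along z (rise per residue ~2.86 A), leading chain offset
# furthest along the axis
collagen_ca_model <- function(n_res = 24, order = c("A", "B", "C")) {
  rise <- 2.86
  offs <- c(2 * rise / 3, rise / 3, 0)
  rows <- list()
  serial <- 1L
  resnames <- rep(c("GLY", "PRO", "HYP"), length.out = n_res)
  for (k in seq_along(order)) {
    ang <- 2 * pi * (k - 1) / 3
    for (i in seq_len(n_res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        record = "ATOM", serial = serial, name = "CA", altloc = "",
        resname = resnames[i], chain = order[k], resno = i, icode = "",
        x = 2.5 * cos(ang + 0.3 * i), y = 2.5 * sin(ang + 0.3 * i),
        z = rise * i + offs[k], occupancy = 1, bfactor = 0,
        element = "C", is_hetero = FALSE, stringsAsFactors = FALSE)
      serial <- serial + 1L
    }
  }
  do.call(rbind, rows)
}
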