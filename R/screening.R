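#' @title Screening of candidate NH-pi pairs
#' @description Enumerates donor-ring pairs in a structure, applies the
#'   empirical NH-pi cutoffs (d_NM < 4.3 A, theta < 25 deg,
#'   omega > 120 deg, strict inequalities), classifies collagen register,
#'   and filters dataset entries on resolution / R-factor / chain length.
#' @name screening
NULL

#' Screening configuration
#'
#' @param enumeration_dmax maximum donor-N to ring-centroid distance for a
#'   pair to be enumerated at all (default 4.5 Angstrom).
#' @param cutoff_d_nm,cutoff_theta,cutoff_omega the NH-pi screening
#'   cutoffs; a pair passes iff `d_nm < cutoff_d_nm`,
#'   `theta < cutoff_theta` and `omega > cutoff_omega` (all strict).
#' @param donor_resnames,ring_resnames residue names considered as amide
#'   donors / aromatic rings.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(enumeration_dmax = 4.5, cutoff_d_nm = 4.3,
                          cutoff_theta = 25, cutoff_omega = 120,
                          donor_resnames = "GLN", ring_resnames = "PHE") {
  stopifnot(enumeration_dmax >= cutoff_d_nm, cutoff_d_nm > 0,
            cutoff_theta > 0, cutoff_omega > 0)
  structure(list(enumeration_dmax = enumeration_dmax,
                 cutoff_d_nm = cutoff_d_nm, cutoff_theta = cutoff_theta,
                 cutoff_omega = cutoff_omega,
                 donor_resnames = donor_resnames,
                 ring_resnames = ring_resnames),
            class = "screen_config")
}

split_residue_keys <- function(model) {
  unique(model[, c("chain", "resno", "icode", "resname")])
}

#' Enumerate candidate donor-ring pairs in one model
#'
#' Every (donor residue, ring residue) combination whose N-to-centroid
#' distance is at most `enumeration_dmax` yields one record with the full
#' six-parameter geometry.  Intra-residue pairs are excluded; a residue
#' may appear in many records.  A structure with no donors or no rings
#' yields an empty record table.
#'
#' @param structure an `nhpi_structure`.
#' @param config a [screen_config()].
#' @param model model index (default 1).
#' @param geometry a [geometry_config()].
#' @return data frame with one row per candidate pair: addressing columns
#'   (`donor_chain`, `donor_resno`, `ring_chain`, `ring_resno`, ...) plus
#'   the six geometric parameters and `h_used`.
#' @export
enumerate_candidate_pairs <- function(structure, config = screen_config(),
                                      model = 1,
                                      geometry = geometry_config()) {
  stopifnot(inherits(structure, "nhpi_structure"))
  m <- structure$models[[model]]
  keys <- split_residue_keys(m)
  donors <- keys[keys$resname %in% config$donor_resnames, , drop = FALSE]
  rings <- keys[keys$resname %in% config$ring_resnames, , drop = FALSE]
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_icode = character(0),
                      donor_resname = character(0),
                      ring_chain = character(0), ring_resno = integer(0),
                      ring_icode = character(0), ring_resname = character(0),
                      d_nm = numeric(0), theta = numeric(0),
                      omega = numeric(0), d_cg_pi = numeric(0),
                      tau = numeric(0), chi = numeric(0),
                      h_used = integer(0), stringsAsFactors = FALSE)
  if (!nrow(donors) || !nrow(rings)) return(empty)
  donor_objs <- lapply(seq_len(nrow(donors)), function(i) {
    res <- residue_atoms(m, donors$chain[i], donors$resno[i],
                         donors$icode[i])
    tryCatch(build_amide_donor(res, geometry), error = function(e) NULL)
  })
  ring_objs <- lapply(seq_len(nrow(rings)), function(i) {
    res <- residue_atoms(m, rings$chain[i], rings$resno[i], rings$icode[i])
    tryCatch(build_ring_frame(res), error = function(e) NULL)
  })
  rows <- list()
  for (i in seq_len(nrow(donors))) {
    dn <- donor_objs[[i]]
    if (is.null(dn)) next
    for (j in seq_len(nrow(rings))) {
      rg <- ring_objs[[j]]
      if (is.null(rg)) next
      if (donors$chain[i] == rings$chain[j] &&
          donors$resno[i] == rings$resno[j] &&
          donors$icode[i] == rings$icode[j]) next
      if (vnorm(dn$N - rg$center) > config$enumeration_dmax) next
      g <- compute_pair_geometry(dn, rg, geometry)
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = donors$chain[i], donor_resno = donors$resno[i],
        donor_icode = donors$icode[i], donor_resname = donors$resname[i],
        ring_chain = rings$chain[j], ring_resno = rings$resno[j],
        ring_icode = rings$icode[j], ring_resname = rings$resname[j],
        d_nm = g$d_nm, theta = g$theta, omega = g$omega,
        d_cg_pi = g$d_cg_pi, tau = g$tau, chi = g$chi, h_used = g$h_used,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the NH-pi cutoffs to candidate records
#'
#' @param records data frame from [enumerate_candidate_pairs()] (or any
#'   table with `d_nm`, `theta`, `omega` columns).
#' @param config a [screen_config()].
#' @return `records` with a logical `pass` column; the summary attributes
#'   `n_records`, `n_pass` and `pass_fraction` are attached.
#' @export
screen_pairs <- function(records, config = screen_config()) {
  stopifnot(all(c("d_nm", "theta", "omega") %in% names(records)))
  records$pass <- records$d_nm < config$cutoff_d_nm &
    records$theta < config$cutoff_theta &
    records$omega > config$cutoff_omega
  attr(records, "n_records") <- nrow(records)
  attr(records, "n_pass") <- sum(records$pass)
  attr(records, "pass_fraction") <-
    if (nrow(records)) sum(records$pass) / nrow(records) else NA_real_
  records
}

triplet_position <- function(resno, gly_phase) {
  # gly_phase: a residue number at which Gly sits; position 0 = Gly,
  # 1 = X, 2 = Y within the Gly-X-Y repeat
  ((resno - gly_phase) %% 3)
}

infer_gly_phase <- function(model, chain) {
  res <- unique(model[model$chain == chain, c("resno", "resname")])
  gly <- res$resno[res$resname == "GLY"]
  if (length(gly) < 2) return(NA_integer_)
  ph <- gly %% 3
  if (length(unique(ph)) != 1) return(NA_integer_)
  gly[1]
}

#' Infer leading/middle/trailing chain order of a collagen triple helix
#'
#' The three strands of a triple helix are staggered by about one residue
#' along the helix axis.  For each chain a line `axial = s * resno + b` is
#' fitted to the C-alpha positions projected on the common principal axis
#' (sign fixed so `s > 0`); at equal residue number the leading chain sits
#' furthest along the axis, so chains are ordered by decreasing intercept.
#'
#' @param model atom data frame with C-alpha atoms (`name == "CA"`) for
#'   three chains.
#' @return character vector of the three chain ids in leading, middle,
#'   trailing order, or `NULL` when inference is impossible.
#' @export
infer_chain_order <- function(model) {
  ca <- model[model$name == "CA" & !model$is_hetero, , drop = FALSE]
  chains <- unique(ca$chain)
  if (length(chains) != 3) return(NULL)
  P <- as.matrix(ca[, c("x", "y", "z")])
  Pc <- sweep(P, 2, colMeans(P))
  axis <- svd(Pc)$v[, 1]
  proj <- as.numeric(Pc %*% axis)
  slopes <- b <- numeric(3)
  for (k in seq_along(chains)) {
    sel <- ca$chain == chains[k]
    if (sum(sel) < 2) return(NULL)
    fit <- stats::lm.fit(cbind(1, ca$resno[sel]), proj[sel])
    b[k] <- fit$coefficients[1]
    slopes[k] <- fit$coefficients[2]
  }
  if (any(!is.finite(slopes)) || any(abs(slopes) < 1e-6)) return(NULL)
  if (mean(slopes) < 0) b <- -b
  chains[order(-b)]
}

#' Classify the collagen register of screened pairs
#'
#' In a Gly-X-Y triple helix a donor at the Y position of one chain can
#' contact a ring at the X position of the *next* triplet on the next
#' chain (leading-to-middle-to-trailing sense): an *axial* pair; or the X
#' position of its *own* triplet: a *lateral* pair.  Everything else is
#' `"none"`; non-collagen input yields `"n/a"`.
#'
#' @param records candidate/screened pair table.
#' @param structure the source `nhpi_structure`.
#' @param chain_order optional chain ids in leading, middle, trailing
#'   order; inferred with [infer_chain_order()] when `NULL`.
#' @param gly_phase optional named integer vector (per chain) giving a
#'   residue number occupied by Gly, fixing the Gly-X-Y frame; inferred
#'   from Gly positions when `NULL`.
#' @param model model index.
#' @return `records` with a `register` character column.
#' @export
classify_collagen_register <- function(records, structure,
                                       chain_order = NULL,
                                       gly_phase = NULL, model = 1) {
  m <- structure$models[[model]]
  if (is.null(chain_order)) chain_order <- infer_chain_order(m)
  ok <- !is.null(chain_order) && length(chain_order) == 3
  if (ok && is.null(gly_phase)) {
    gly_phase <- vapply(chain_order, function(ch) infer_gly_phase(m, ch),
                        integer(1))
    names(gly_phase) <- chain_order
    if (anyNA(gly_phase)) ok <- FALSE
  }
  if (!ok) {
    warning("collagen chain order/register frame could not be inferred; ",
            "labelling all pairs 'n/a'")
    records$register <- rep("n/a", nrow(records))
    return(records)
  }
  nxt <- stats::setNames(chain_order[c(2, 3, 1)], chain_order)
  lab <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    dch <- records$donor_chain[i]; rch <- records$ring_chain[i]
    if (!(dch %in% chain_order) || !(rch %in% chain_order)) {
      lab[i] <- "n/a"; next
    }
    dpos <- triplet_position(records$donor_resno[i], gly_phase[[dch]])
    rpos <- triplet_position(records$ring_resno[i], gly_phase[[rch]])
    if (dpos != 2 || rpos != 1 || nxt[[dch]] != rch) {
      lab[i] <- "none"; next
    }
    dtrip <- (records$donor_resno[i] - gly_phase[[dch]] - 2) %/% 3
    rtrip <- (records$ring_resno[i] - gly_phase[[rch]] - 1) %/% 3
    lab[i] <- if (rtrip == dtrip + 1) "axial"
              else if (rtrip == dtrip) "lateral"
              else "none"
  }
  records$register <- lab
  records
}

#' Filter dataset entries on the standard crystallographic criteria
#'
#' Keeps entries with resolution <= 2.0 Angstrom, R-factor <= 0.25
#' (inclusive bounds) and minimum chain length >= 40 residues; entries
#' must be experimental with full coordinates.  Homology/redundancy
#' filtering is not performed; supply a pre-culled list.
#'
#' @param entries data frame with columns `id`, `resolution`, `r_factor`,
#'   `min_chain_length`, and optionally logical `experimental` and
#'   `full_coordinates` (assumed `TRUE` when absent).
#' @param max_resolution,max_r_factor,min_chain_length the thresholds.
#' @return `entries` with logical `accepted` and character `reason`
#'   columns (`reason` is `""` for accepted entries).
#' @export
filter_dataset_entries <- function(entries, max_resolution = 2.0,
                                   max_r_factor = 0.25,
                                   min_chain_length = 40) {
  need <- c("resolution", "r_factor", "min_chain_length")
  stopifnot(all(need %in% names(entries)))
  if (is.null(entries$experimental))
    entries$experimental <- TRUE
  if (is.null(entries$full_coordinates))
    entries$full_coordinates <- TRUE
  reason <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    reason[i] <-
      if (anyNA(e[need])) "missing metadata"
      else if (!isTRUE(e$experimental)) "not experimental"
      else if (!isTRUE(e$full_coordinates)) "incomplete coordinates"
      else if (e$resolution > max_resolution) "resolution"
      else if (e$r_factor > max_r_factor) "r_factor"
      else if (e$min_chain_length < min_chain_length) "chain length"
      else ""
  }
  entries$accepted <- reason == ""
  entries$reason <- reason
  entries
}
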