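#' @title PDB structure input/output
#' @description A minimal fixed-column PDB reader/writer.  A structure is a
#'   list of models; each model is a data frame with one row per atom.
#'   This flat-table representation (rather than nested residue objects)
#'   is the idiomatic R form: residues are addressed by
#'   `(chain, resno, icode)` and extracted with [residue_atoms()].
#' @name structure_io
NULL

ATOM_COLS <- c("record", "serial", "name", "altloc", "resname", "chain",
               "resno", "icode", "x", "y", "z", "occupancy", "bfactor",
               "element", "is_hetero")

#' Construct a structure object
#'
#' @param models list of atom data frames (one per model), all sharing the
#'   same chain identifiers.
#' @param id entry identifier (default `""`).
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @param r_factor crystallographic R-factor (fraction), or `NA`.
#' @return an object of class `nhpi_structure`.
#' @export
new_structure <- function(models, id = "", resolution = NA_real_,
                          r_factor = NA_real_) {
  stopifnot(is.list(models), length(models) >= 1)
  models <- lapply(models, function(m) {
    stopifnot(is.data.frame(m))
    missing <- setdiff(ATOM_COLS, names(m))
    if (length(missing))
      stop("atom table lacks columns: ", paste(missing, collapse = ", "))
    m
  })
  structure(list(models = models, id = id,
                 resolution = resolution, r_factor = r_factor),
            class = "nhpi_structure")
}

#' @export
print.nhpi_structure <- function(x, ...) {
  cat(sprintf("<nhpi_structure '%s': %d model(s), %d atoms in model 1",
              x$id, length(x$models), nrow(x$models[[1]])))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A", x$resolution))
  if (!is.na(x$r_factor)) cat(sprintf(", R %.3f", x$r_factor))
  cat(">\n")
  invisible(x)
}

#' Number of models in a structure
#' @param structure an `nhpi_structure`.
#' @return integer model count.
#' @export
n_models <- function(structure) length(structure$models)

#' Extract the atoms of one residue
#'
#' @param model an atom data frame (one model of a structure).
#' @param chain chain identifier.
#' @param resno residue sequence number.
#' @param icode insertion code (default `""`).
#' @return the matching rows of `model`.
#' @export
residue_atoms <- function(model, chain, resno, icode = "") {
  model[model$chain == chain & model$resno == resno & model$icode == icode, ,
        drop = FALSE]
}

#' Count water molecules in a model
#'
#' Waters are identified by residue name `HOH` or `WAT`; the count is the
#' number of such residues, not atoms.
#' @param model an atom data frame.
#' @return integer number of water residues.
#' @export
count_waters <- function(model) {
  w <- model[model$resname %in% c("HOH", "WAT"), , drop = FALSE]
  if (!nrow(w)) return(0L)
  nrow(unique(w[, c("chain", "resno", "icode")]))
}

parse_num <- function(s, line_no, what) {
  s <- trimws(s)
  if (!nzchar(s)) return(NA_real_)
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x))
    stop(sprintf("malformed %s field on line %d: '%s'", what, line_no, s))
  x
}

#' Parse a PDB-format structure
#'
#' Reads fixed-column `ATOM`/`HETATM` records, honouring `MODEL`/`ENDMDL`
#' blocks.  Resolution is taken from `REMARK   2` and the working-set
#' R-factor from `REMARK   3` when present.  Hydrogen atoms are retained in
#' the table but all downstream amide geometry uses theoretical hydrogen
#' placement, never file hydrogens.
#'
#' @param source path to a PDB file, or a character vector of PDB lines
#'   (a single string containing newlines is also accepted).
#' @param altloc alternate-location policy: `"highest"` keeps, per atom
#'   name within a residue, the conformer with the highest occupancy
#'   (ties broken by lexicographic altloc), `"first"` keeps the first
#'   encountered, `"all"` keeps every conformer.
#' @param models `"first"` (static analysis) or `"all"` (trajectory mode).
#' @param id entry identifier stored on the structure.
#' @return an `nhpi_structure`.
#' @export
parse_structure <- function(source, altloc = c("highest", "first", "all"),
                            models = c("first", "all"), id = "") {
  altloc <- match.arg(altloc)
  models <- match.arg(models)
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (id == "") id <- sub("\\.(pdb|ent)$", "", basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records in input")

  resolution <- NA_real_
  r_factor <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rem2)) {
    m <- regmatches(rem2[1], regexpr("[0-9]+\\.[0-9]+", rem2[1]))
    if (length(m)) resolution <- as.numeric(m)
  }
  rem3 <- grep("^REMARK   3   R VALUE", lines, value = TRUE)
  rem3 <- grep("WORKING SET", rem3, value = TRUE)
  if (length(rem3)) {
    m <- regmatches(rem3[1], regexpr("[0-9]*\\.[0-9]+", rem3[1]))
    if (length(m)) r_factor <- as.numeric(m)
  }

  model_list <- list()
  cur <- list()
  in_model <- FALSE
  flush_model <- function(cur) {
    if (!length(cur)) return(NULL)
    do.call(rbind, cur)
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      in_model <- TRUE
      cur <- list()
    } else if (r == "ENDMDL") {
      m <- flush_model(cur)
      if (!is.null(m)) model_list[[length(model_list) + 1L]] <- m
      cur <- list()
      in_model <- FALSE
      if (models == "first" && length(model_list) >= 1) break
    } else if (is_atom[i]) {
      ln <- lines[i]
      if (nchar(ln) < 54)
        stop(sprintf("truncated ATOM/HETATM record on line %d", i))
      ln <- formatC(ln, width = 80, flag = "-")
      cur[[length(cur) + 1L]] <- data.frame(
        record = trimws(substr(ln, 1, 6)),
        serial = as.integer(parse_num(substr(ln, 7, 11), i, "serial")),
        name = trimws(substr(ln, 13, 16)),
        altloc = trimws(substr(ln, 17, 17)),
        resname = trimws(substr(ln, 18, 20)),
        chain = trimws(substr(ln, 22, 22)),
        resno = as.integer(parse_num(substr(ln, 23, 26), i, "resSeq")),
        icode = trimws(substr(ln, 27, 27)),
        x = parse_num(substr(ln, 31, 38), i, "x"),
        y = parse_num(substr(ln, 39, 46), i, "y"),
        z = parse_num(substr(ln, 47, 54), i, "z"),
        occupancy = parse_num(substr(ln, 55, 60), i, "occupancy"),
        bfactor = parse_num(substr(ln, 61, 66), i, "bfactor"),
        element = trimws(substr(ln, 77, 78)),
        is_hetero = substr(ln, 1, 6) == "HETATM",
        stringsAsFactors = FALSE)
    }
  }
  if (!in_model && length(cur)) {
    m <- flush_model(cur)
    if (!is.null(m)) {
      if (length(model_list)) {
        # stray atoms after ENDMDL (e.g. shared waters): append to model 1
        model_list[[1]] <- rbind(model_list[[1]], m)
      } else {
        model_list[[1]] <- m
      }
    }
  }
  if (!length(model_list)) stop("no ATOM or HETATM records in input")
  if (models == "first") model_list <- model_list[1]

  model_list <- lapply(model_list, function(m) {
    m$occupancy[is.na(m$occupancy)] <- 1
    m$bfactor[is.na(m$bfactor)] <- 0
    if (any(!is.finite(m$x) | !is.finite(m$y) | !is.finite(m$z)))
      stop("non-finite coordinates in input")
    m$name[!nzchar(m$name)] <- NA_character_
    if (anyNA(m$name)) stop("empty atom name in input")
    rownames(m) <- NULL
    collapse_altloc(m, altloc)
  })
  new_structure(model_list, id = id, resolution = resolution,
                r_factor = r_factor)
}

collapse_altloc <- function(m, policy) {
  if (policy == "all" || all(m$altloc == "")) return(m)
  key <- paste(m$chain, m$resno, m$icode, m$resname, m$name, sep = "\r")
  keep <- rep(TRUE, nrow(m))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    if (policy == "first") {
      win <- idx[1]
    } else {
      sub <- m[idx, ]
      ord <- order(-sub$occupancy, sub$altloc)
      win <- idx[ord[1]]
    }
    keep[setdiff(idx, win)] <- FALSE
  }
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

fmt_coord <- function(v) {
  bad <- v >= 9999.9985 | v <= -999.9985
  if (any(bad))
    stop("coordinate not representable in 8.3 PDB columns: ",
         v[which(bad)[1]])
  sprintf("%8.3f", v)
}

#' Write a structure in PDB format
#'
#' Multi-model structures are written as `MODEL`/`ENDMDL` blocks.  The
#' round trip `parse_structure(write_structure(s))` reproduces coordinates
#' to 0.001 Angstrom and all addressing fields.
#'
#' @param structure an `nhpi_structure`.
#' @param file optional path; when `NULL` the text is returned only.
#' @return character vector of PDB lines, invisibly when `file` is given.
#' @export
write_structure <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "nhpi_structure"))
  multi <- length(structure$models) > 1
  out <- character(0)
  if (!is.na(structure$resolution))
    out <- c(out, sprintf(
      "REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", structure$resolution))
  if (!is.na(structure$r_factor))
    out <- c(out, sprintf(
      "REMARK   3   R VALUE            (WORKING SET) : %.3f",
      structure$r_factor))
  for (mi in seq_along(structure$models)) {
    m <- structure$models[[mi]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", mi))
    nm <- ifelse(nchar(m$name) <= 3 & nchar(m$element) == 1,
                 sprintf(" %-3s", m$name), sprintf("%-4s", m$name))
    lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %s%s%s%6.2f%6.2f          %2s",
                     ifelse(m$is_hetero, "HETATM", "ATOM"),
                     m$serial, nm, m$altloc, m$resname, m$chain,
                     m$resno, m$icode,
                     fmt_coord(m$x), fmt_coord(m$y), fmt_coord(m$z),
                     m$occupancy, m$bfactor, m$element)
    out <- c(out, lines)
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
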