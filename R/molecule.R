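#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Standard atomic weights (IUPAC 2021, abridged), Da.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904
)

#' Construct a small molecule
#'
#' A molecule is the substrate of the shape-screening stage: named atoms with
#' 3D coordinates in Angstrom, formal charges, and a bond list. The molecular
#' weight is computed from standard atomic masses.
#'
#' @param name Identifier.
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (formal charge, integer, default 0).
#' @param bonds Data frame with columns `a1`, `a2` (1-based atom indices) and
#'   optionally `order` (default 1). May have zero rows (e.g. XYZ input).
#' @return An object of class `lf_molecule`: a list with elements `name`,
#'   `atoms` (tibble), `bonds` (tibble) and `mw` (Da).
#' @examples
#' m <- molecule("methane",
#'   atoms = data.frame(element = c("C", "H", "H", "H", "H"),
#'                      x = c(0, .63, -.63, -.63, .63),
#'                      y = c(0, .63, -.63, .63, -.63),
#'                      z = c(0, .63, .63, -.63, -.63)),
#'   bonds = data.frame(a1 = 1, a2 = 2:5))
#' m$mw
#' @export
molecule <- function(name, atoms, bonds = NULL) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) < 1) abort("a molecule needs at least one atom")
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    abort("`atoms` must have columns element, x, y, z")
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  atoms$element <- normalize_element(atoms$element)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) abort("all atom coordinates must be finite")
  if (is.null(bonds)) bonds <- tibble(a1 = integer(), a2 = integer(),
                                      order = integer())
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0) {
    if (!all(c("a1", "a2") %in% names(bonds)))
      abort("`bonds` must have columns a1, a2")
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    idx <- c(bonds$a1, bonds$a2)
    if (any(idx < 1 | idx > nrow(atoms)))
      abort("bond indices out of range")
  } else {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  unknown <- setdiff(unique(atoms$element), names(.ATOMIC_MASS))
  if (length(unknown) > 0)
    abort(paste0("unknown element(s): ", paste(unknown, collapse = ", ")))
  mw <- sum(.ATOMIC_MASS[atoms$element])
  structure(list(name = name, atoms = atoms, bonds = bonds, mw = mw),
            class = "lf_molecule")
}

#' @export
print.lf_molecule <- function(x, ...) {
  cat(sprintf("<lf_molecule> %s: %d atoms, %d bonds, MW %.2f Da\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$mw))
  invisible(x)
}

# "CL"/"cl" -> "Cl" etc.
normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Heavy-atom coordinate matrix of a molecule
#'
#' @param mol An `lf_molecule`.
#' @param heavy Drop hydrogens (default `TRUE`); shape scoring works on heavy
#'   atoms only.
#' @return Numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(mol, heavy = TRUE) {
  a <- mol$atoms
  if (heavy) a <- a[a$element != "H", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Filter molecules by molecular weight
#'
#' Retains molecules with molecular weight strictly below `max_mw`
#' (drug-likeness style cut used when selecting screening candidates, e.g.
#' MW < 400 Da). Order is preserved.
#'
#' @param mols List of `lf_molecule`.
#' @param max_mw Cutoff in Da; must be positive.
#' @return Sub-list of `mols` with `mw < max_mw`.
#' @export
mw_filter <- function(mols, max_mw) {
  stopifnot(is.numeric(max_mw), length(max_mw) == 1)
  if (max_mw <= 0) abort("`max_mw` must be positive")
  mols[vapply(mols, function(m) m$mw < max_mw, logical(1))]
}

#' Read small-molecule structures
#'
#' Reads SDF/MOL (V2000, via ChemmineR) or XYZ files into a list of
#' molecules. Coordinates are preserved exactly as printed; element symbols
#' are normalized. Formal charges are taken from `M  CHG` property lines
#' (and the legacy atom-block charge column), which ChemmineR drops, so the
#' reader re-scans each record for them. XYZ carries no connectivity: those
#' molecules get an empty bond list and cannot be feature-typed.
#'
#' @param path File path.
#' @param format One of `"sdf"`, `"mol"`, `"xyz"`; default guessed from the
#'   file extension.
#' @return List of `lf_molecule`.
#' @export
read_structures <- function(path, format = c("auto", "sdf", "mol", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", mol = "mol", xyz = "xyz",
                     abort("cannot guess format; pass `format`"))
  }
  if (format == "xyz") read_xyz(path) else read_sdf(path)
}

read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split into records on $$$$; a bare MOL file is a single record
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, utils::head(ends, -1) + 1)
  records <- purrr::map2(starts, ends, function(s, e) lines[s:e])
  records <- purrr::keep(records, function(r) any(nzchar(trimws(r))))
  purrr::imap(records, function(rec, i) {
    tryCatch(parse_v2000_record(rec),
             error = function(e) {
               abort(sprintf("unparseable SDF record %d: %s", i,
                             conditionMessage(e)))
             })
  })
}

parse_v2000_record <- function(rec) {
  name <- trimws(rec[1])
  counts <- rec[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds) || n_atoms < 1)
    stop("bad counts line")
  atom_lines <- rec[5:(4 + n_atoms)]
  if (length(atom_lines) != n_atoms || anyNA(atom_lines))
    stop("truncated atom block")
  x <- as.numeric(substr(atom_lines, 1, 10))
  y <- as.numeric(substr(atom_lines, 11, 20))
  z <- as.numeric(substr(atom_lines, 21, 30))
  el <- trimws(substr(atom_lines, 32, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z) || any(!nzchar(el)))
    stop("bad atom line")
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  chg_code[is.na(chg_code)] <- 0L
  # legacy column: 1..7 map to +3..-3 (4 = doublet radical, treated as 0)
  legacy <- c(`1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L, `5` = -1L,
              `6` = -2L, `7` = -3L)
  charge <- ifelse(chg_code %in% 1:7, legacy[as.character(chg_code)], 0L)
  bonds <- tibble(a1 = integer(), a2 = integer(), order = integer())
  if (n_bonds > 0) {
    bond_lines <- rec[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    if (length(bond_lines) != n_bonds || anyNA(bond_lines))
      stop("truncated bond block")
    bonds <- tibble(
      a1 = as.integer(substr(bond_lines, 1, 3)),
      a2 = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9))
    )
    if (anyNA(bonds$a1) || anyNA(bonds$a2)) stop("bad bond line")
  }
  # M  CHG lines override the legacy column entirely (per the V2000 spec)
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines) > 0) {
    charge <- rep(0L, n_atoms)
    for (cl in chg_lines) {
      flds <- as.integer(strsplit(trimws(substring(cl, 7)), "\\s+")[[1]])
      n <- flds[1]
      for (k in seq_len(n)) {
        charge[flds[2 * k]] <- flds[2 * k + 1]
      }
    }
  }
  molecule(name = if (nzchar(name)) name else "unnamed",
           atoms = tibble(element = el, x = x, y = y, z = z,
                          charge = as.integer(charge)),
           bonds = bonds)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mols <- list()
  i <- 1
  rec <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    rec <- rec + 1
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      abort(sprintf("unparseable XYZ record %d: bad atom count", rec))
    name <- trimws(lines[i + 1])
    body <- lines[(i + 2):(i + 1 + n)]
    if (length(body) != n || anyNA(body))
      abort(sprintf("unparseable XYZ record %d: truncated", rec))
    flds <- strsplit(trimws(body), "\\s+")
    el <- vapply(flds, `[`, character(1), 1)
    xyz <- t(vapply(flds, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(xyz))
      abort(sprintf("unparseable XYZ record %d: bad coordinates", rec))
    mols[[rec]] <- molecule(
      name = if (nzchar(name)) name else sprintf("xyz_%d", rec),
      atoms = tibble(element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
    i <- i + 2 + n
  }
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols A single `lf_molecule` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "lf_molecule")) mols <- list(mols)
  txt <- unlist(lapply(mols, format_v2000_record))
  writeLines(txt, path)
  invisible(path)
}

format_v2000_record <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  header <- c(mol$name, "  ligandflow", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        a$x, a$y, a$z, a$element)
  bond_lines <- if (nrow(b) > 0)
    sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order) else character()
  chg <- which(a$charge != 0)
  chg_lines <- if (length(chg) > 0) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, a$charge[ix]), collapse = ""))
    }, character(1))
  } else character()
  c(header, counts, atom_lines, bond_lines, chg_lines, "M  END", "$$$$")
}
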