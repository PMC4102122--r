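# Structure reading (PDB via bio3d, GRO hand-parsed), vdW assignment and
# atom selections.

#' Default van der Waals radii by element
#'
#' Element-based radii in Angstrom used for pore radius profiling. Not tied
#' to a particular force field; override via the `vdw_table` argument of
#' [read_structure()].
#'
#' @return named numeric vector of radii (Angstrom).
#' @export
default_vdw_table <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80, K = 2.75)
}

# fallback radius for elements absent from the table
.vdw_fallback <- 1.70

assign_vdw <- function(elements, vdw_table = default_vdw_table()) {
  r <- unname(vdw_table[elements])
  unknown <- is.na(r)
  if (any(unknown)) {
    warn("unknown element(s) %s assigned default vdW radius %.2f A",
         paste(unique(elements[unknown]), collapse = ", "), .vdw_fallback)
    r[unknown] <- .vdw_fallback
  }
  r
}

#' Construct a structure object
#'
#' @param atoms data.frame with columns `name`, `resname`, `resno`, `chain`,
#'   `element`, `vdw` (Angstrom), one row per atom, in file order.
#' @param coords optional n x 3 matrix of reference coordinates (Angstrom).
#' @param box optional length-3 vector of orthogonal box lengths (Angstrom).
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms, coords = NULL, box = NULL) {
  req <- c("name", "resname", "resno", "chain", "element", "vdw")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    abort("atoms is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) abort("structure has zero atoms")
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0)) {
    abort("every atom must have a positive finite vdW radius")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L) {
      abort("coords must be a %d x 3 matrix", nrow(atoms))
    }
    dimnames(coords) <- NULL
  }
  structure(list(atoms = atoms, coords = coords, box = box),
            class = "md_structure")
}

#' Number of atoms in a structure
#' @param x an `md_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues, chains: %s\n",
              n_atoms(x),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

# Derive an element symbol from a PDB/GRO atom name, e.g. "OW" -> "O",
# "CA" -> "C", "1H" -> "H". Two-letter elements must be supplied by the
# file's element column; name-based guessing takes the first alphabetic char.
element_from_name <- function(name) {
  first <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
  toupper(first)
}

#' Read a structure from a PDB or GRO file
#'
#' Format is detected from the file extension. vdW radii are assigned per
#' element from `vdw_table`; unknown elements receive 1.70 Angstrom with a
#' warning. GRO coordinates (nm) are converted to Angstrom.
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @param vdw_table named vector of per-element radii (Angstrom).
#' @return an [md_structure()].
#' @export
read_structure <- function(path, vdw_table = default_vdw_table()) {
  if (!file.exists(path)) abort("structure file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    read_structure_pdb(path, vdw_table)
  } else if (ext == "gro") {
    read_structure_gro(path, vdw_table)
  } else {
    abort("unsupported structure format '.%s' (expected .pdb or .gro)", ext)
  }
}

read_structure_pdb <- function(path, vdw_table) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort("failed to parse PDB %s: %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0L) abort("structure %s contains zero atoms", path)
  element <- at$elesy
  no_ele <- is.na(element) | element == ""
  element[no_ele] <- element_from_name(at$elety[no_ele])
  atoms <- data.frame(
    name = at$elety, resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "", at$chain),
    element = toupper(element),
    vdw = NA_real_, stringsAsFactors = FALSE
  )
  atoms$vdw <- assign_vdw(atoms$element, vdw_table)
  md_structure(atoms, coords = cbind(at$x, at$y, at$z))
}

# GRO fixed-column format: resno(5) resname(5) name(5) atomno(5) x y z (%8.3f, nm)
read_structure_gro <- function(path, vdw_table) {
  lines <- readLines(path)
  if (length(lines) < 3L) abort("truncated GRO file %s (%d lines)", path, length(lines))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0L) abort("GRO %s: bad atom count on line 2", path)
  if (length(lines) < 2L + n + 1L) {
    abort("GRO %s: expected %d atom lines, found %d", path, n, length(lines) - 3L)
  }
  rows <- lines[3:(2 + n)]
  parse_field <- function(x, from, to) substr(x, from, to)
  resno <- suppressWarnings(as.integer(trimws(parse_field(rows, 1, 5))))
  resname <- trimws(parse_field(rows, 6, 10))
  name <- trimws(parse_field(rows, 11, 15))
  x <- suppressWarnings(as.numeric(parse_field(rows, 21, 28)))
  y <- suppressWarnings(as.numeric(parse_field(rows, 29, 36)))
  z <- suppressWarnings(as.numeric(parse_field(rows, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) abort("GRO %s: unparseable atom record at line %d", path, 2L + bad[1])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  box <- if (length(boxv) >= 3 && all(is.finite(boxv[1:3]))) boxv[1:3] * 10 else NULL
  atoms <- data.frame(
    name = name, resname = resname, resno = resno,
    chain = "", element = element_from_name(name),
    vdw = NA_real_, stringsAsFactors = FALSE
  )
  atoms$vdw <- assign_vdw(atoms$element, vdw_table)
  md_structure(atoms, coords = cbind(x, y, z) * 10, box = box)
}

#' Write a structure (with its reference coordinates) to a PDB file
#'
#' @param struct an [md_structure()] with coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  if (is.null(struct$coords)) abort("structure has no coordinates to write")
  a <- struct$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(struct$coords)),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
    elesy = a$element
  )
  invisible(path)
}

# residue names recognised as water by the convenience preset
.water_resnames <- c("HOH", "SOL", "TIP3", "WAT")

#' Select atoms by attribute
#'
#' Values within one argument combine with OR; different arguments combine
#' with AND (e.g. `resno = c(117, 225)` selects both residues on all chains).
#' The preset `"water_oxygens"` matches residue names HOH/SOL/TIP3/WAT with
#' atom names starting with "O".
#'
#' @param struct an [md_structure()].
#' @param resname,name,resno,chain,element attribute filters (vectors, OR
#'   within each).
#' @param preset `"water_oxygens"` or `NULL`.
#' @param allow_empty if `FALSE` (default) an empty selection is an error.
#' @param label free-text label stored on the selection.
#' @return an `atom_selection`: list with `indices` (1-based, file order)
#'   and `label`.
#' @export
select_atoms <- function(struct, resname = NULL, name = NULL, resno = NULL,
                         chain = NULL, element = NULL, preset = NULL,
                         allow_empty = FALSE, label = NULL) {
  a <- struct$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(preset)) {
    preset <- match.arg(preset, "water_oxygens")
    keep <- keep & a$resname %in% .water_resnames & startsWith(a$name, "O")
    if (is.null(label)) label <- preset
  }
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(element)) keep <- keep & a$element %in% element
  idx <- which(keep)
  if (length(idx) == 0L && !allow_empty) {
    abort("selection matched no atoms (pass allow_empty = TRUE to permit)")
  }
  structure(list(indices = idx, label = if (is.null(label)) "" else label),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}
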