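# Core domain containers: atom tables, periodic structures, selections.

POLYMER_CLASSES <- c("cellulose", "xylan", "lignin", "water", "ion", "unknown")

# residue_type -> polymer_class and per-residue formula mass (Da).
# Masses are residue (linked) formula masses including implicit hydrogens:
# builders emit heavy atoms only, so mass bookkeeping is residue-wise.
# Lignin monomer masses use the monolignol formula; the ~2 Da loss per
# radical coupling is neglected (<1% of lignin mass).
RESIDUE_INFO <- data.frame(
  residue_type  = c("GLC", "XYL", "GLCA", "ACE", "SYR", "GUA", "WAT", "NA"),
  polymer_class = c("cellulose", "xylan", "xylan", "xylan", "lignin",
                    "lignin", "water", "ion"),
  mass = c(162.141, 132.115, 176.124, 42.037, 210.229, 180.200,
           18.015, 22.990),
  stringsAsFactors = FALSE
)

#' Create an atom table
#'
#' Builds the ordered atom table used inside [scw_structure()]. Atom ids are
#' dense and 0-based; residue indices are 1-based within a chain, numbered
#' from the reducing end for glycans.
#'
#' @param element chemical element symbols ("C", "O", "NA", ...).
#' @param atom_label role labels, unique within a residue ("C1".."C6",
#'   "O2", "AcMe", "S3", "OMe3", ...).
#' @param residue_index integer residue number within the chain.
#' @param residue_type monomer code: GLC, XYL, GLCA, ACE, SYR, GUA, WAT, NA.
#' @param chain_id integer chain identifier.
#' @param x,y,z coordinates, Angstrom.
#' @param polymer_class optional; derived from `residue_type` when missing.
#' @return a `data.frame` with one row per atom.
#' @export
atom_table <- function(element, atom_label, residue_index, residue_type,
                       chain_id, x, y, z, polymer_class = NULL) {
  n <- length(element)
  if (is.null(polymer_class)) {
    polymer_class <- RESIDUE_INFO$polymer_class[
      match(residue_type, RESIDUE_INFO$residue_type)]
    polymer_class[is.na(polymer_class)] <- "unknown"
  }
  data.frame(
    atom_id = seq_len(n) - 1L,
    element = as.character(element),
    atom_label = as.character(atom_label),
    residue_index = as.integer(residue_index),
    residue_type = as.character(residue_type),
    chain_id = as.integer(chain_id),
    polymer_class = as.character(polymer_class),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
}

#' Periodic structure container
#'
#' A structure is an ordered atom table plus an optional orthorhombic box.
#' Analysis routines use heavy atoms only; builders never emit hydrogens.
#'
#' @param atoms an atom table (see [atom_table()]); may have 0 rows.
#' @param box numeric length-3 box edges in Angstrom, or NULL.
#' @param periodic logical; defaults to TRUE when a box is given.
#' @return an object of class `scw_structure`.
#' @export
scw_structure <- function(atoms = atom_table(character(), character(),
                                             integer(), character(),
                                             integer(), numeric(), numeric(),
                                             numeric()),
                          box = NULL, periodic = !is.null(box)) {
  if (nrow(atoms) > 0) atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  s <- structure(list(atoms = atoms, box = box, periodic = isTRUE(periodic)),
                 class = "scw_structure")
  validate_structure(s)
  s
}

#' Validate a structure's invariants
#'
#' Checks finite coordinates, dense unique atom ids, positive box when
#' periodic, and residue_type/polymer_class consistency.
#'
#' @param s an `scw_structure`.
#' @return `s`, invisibly; errors on violation.
#' @export
validate_structure <- function(s) {
  stopifnot(inherits(s, "scw_structure"))
  a <- s$atoms
  if (nrow(a) > 0) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      stop("non-finite coordinates")
    if (!identical(a$atom_id, seq_len(nrow(a)) - 1L))
      stop("atom ids must be dense, unique and 0-based")
    known <- a$residue_type %in% RESIDUE_INFO$residue_type
    expect <- RESIDUE_INFO$polymer_class[
      match(a$residue_type[known], RESIDUE_INFO$residue_type)]
    if (any(a$polymer_class[known] != expect))
      stop("polymer_class inconsistent with residue_type")
    if (!all(a$polymer_class %in% POLYMER_CLASSES))
      stop("unknown polymer_class")
  }
  if (s$periodic) {
    if (is.null(s$box) || length(s$box) != 3 || any(!is.finite(s$box)) ||
        any(s$box <= 0))
      stop("periodic structure requires 3 positive box lengths")
  }
  invisible(s)
}

#' @export
print.scw_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<scw_structure> %d atoms, %d chains", nrow(a),
              length(unique(a$chain_id))))
  if (x$periodic)
    cat(sprintf(", box %.2f x %.2f x %.2f A", x$box[1], x$box[2], x$box[3]))
  cat("\n")
  if (nrow(a) > 0) {
    tab <- table(a$polymer_class)
    cat("  atoms by class:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

coords_matrix <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z"), drop = FALSE])
}

set_coords <- function(s, m) {
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

#' Total mass of a structure (Da)
#'
#' Residue-wise formula masses (implicit hydrogens included) summed over all
#' residues; used for density and moisture bookkeeping.
#'
#' @param s an `scw_structure`.
#' @return mass in Dalton.
#' @export
structure_mass <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) return(0)
  key <- paste(a$chain_id, a$residue_index, a$residue_type)
  first <- !duplicated(key)
  m <- RESIDUE_INFO$mass[match(a$residue_type[first],
                               RESIDUE_INFO$residue_type)]
  if (anyNA(m)) stop("unknown residue_type in mass table")
  sum(m)
}

#' Mass density of a periodic structure (g/cm^3)
#'
#' @param s a periodic `scw_structure`.
#' @return density in g/cm^3 from [structure_mass()] and box volume.
#' @export
structure_density <- function(s) {
  if (!s$periodic) stop("density requires a periodic structure")
  # Da -> g (x 1.66054e-24), A^3 -> cm^3 (x 1e-24)
  structure_mass(s) * 1.66054 / prod(s$box)
}

#' Atom selection predicate
#'
#' A reproducible predicate over atom sites: polymer class, a label set and
#' an optional chain set. Resolution returns the matching atom ids in table
#' order.
#'
#' @param polymer_class one of cellulose/xylan/lignin/water/ion, or NULL.
#' @param labels character vector of atom labels, or NULL for any.
#' @param chains integer chain ids, or NULL for any.
#' @param elements element symbols, or NULL for any.
#' @return an object of class `scw_selection`.
#' @export
scw_selection <- function(polymer_class = NULL, labels = NULL, chains = NULL,
                          elements = NULL) {
  structure(list(polymer_class = polymer_class, labels = labels,
                 chains = chains, elements = elements),
            class = "scw_selection")
}

#' Resolve a selection to atom ids
#'
#' @param s an `scw_structure`.
#' @param sel an `scw_selection`.
#' @return ordered integer vector of 0-based atom ids (possibly empty).
#' @export
resolve_selection <- function(s, sel) {
  stopifnot(inherits(sel, "scw_selection"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$polymer_class)) keep <- keep & a$polymer_class %in% sel$polymer_class
  if (!is.null(sel$labels)) keep <- keep & a$atom_label %in% sel$labels
  if (!is.null(sel$chains)) keep <- keep & a$chain_id %in% sel$chains
  if (!is.null(sel$elements)) keep <- keep & a$element %in% sel$elements
  a$atom_id[keep]
}

#' Concatenate structures
#'
#' Chain ids are offset so they stay unique; atom ids are renumbered dense.
#' Box/periodicity are taken from `box`/`periodic` if given, else from the
#' first periodic input.
#'
#' @param ... `scw_structure` objects.
#' @param box optional box for the result.
#' @param periodic optional periodicity flag.
#' @return combined `scw_structure`.
#' @export
combine_structures <- function(..., box = NULL, periodic = NULL) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "scw_structure"))
    xs <- xs[[1]]
  tabs <- list(); offset <- 0L
  for (s in xs) {
    a <- s$atoms
    if (nrow(a) > 0) {
      old <- sort(unique(a$chain_id))
      a$chain_id <- offset + match(a$chain_id, old)
      offset <- offset + length(old)
      tabs[[length(tabs) + 1L]] <- a
    }
    if (is.null(box) && s$periodic) { box <- s$box }
  }
  atoms <- if (length(tabs)) do.call(rbind, tabs) else scw_structure()$atoms
  if (is.null(periodic)) periodic <- !is.null(box)
  scw_structure(atoms, box = box, periodic = periodic)
}

translate_structure <- function(s, v) {
  s$atoms$x <- s$atoms$x + v[1]
  s$atoms$y <- s$atoms$y + v[2]
  s$atoms$z <- s$atoms$z + v[3]
  s
}

# Rotation about z by angle (degrees), about the centroid unless origin given.
rotate_structure_z <- function(s, angle_deg, origin = c(0, 0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  m <- coords_matrix(s)
  m <- sweep(m, 2, origin) %*% t(R)
  set_coords(s, sweep(m, 2, origin, "+"))
}

rotate_structure <- function(s, R, origin = c(0, 0, 0)) {
  m <- sweep(coords_matrix(s), 2, origin) %*% t(R)
  set_coords(s, sweep(m, 2, origin, "+"))
}

#' Wrap coordinates into the primary box image
#'
#' @param s a periodic `scw_structure`.
#' @return structure with coordinates wrapped into [0, box).
#' @export
wrap_structure <- function(s) {
  if (!s$periodic) return(s)
  m <- coords_matrix(s)
  for (k in 1:3) m[, k] <- m[, k] - s$box[k] * floor(m[, k] / s$box[k])
  set_coords(s, m)
}
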