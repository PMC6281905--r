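# Molecular structure container, XYZ/PDB readers and writers, covalent-radius
# bond perception, and reaction-center identification.
#
# Atom indices are 1-based throughout the package (R convention); PDB serials
# are stored as read and preserved on write.

#' Construct a molecular geometry
#'
#' The basic structure container: an ordered set of atoms with Cartesian
#' coordinates in angstrom, optional per-atom naming/residue metadata, a net
#' charge and a role tag.
#'
#' @param elements Character vector of element symbols; every element must
#'   have a tabulated covalent radius and mass (see [covalent_radius()]).
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (angstrom); all entries must be finite.
#' @param serial Integer atom serials, unique and positive; defaults to
#'   `1:n`.
#' @param name Optional per-atom labels (e.g. `"O3'"`, `"P"`).
#' @param residue_name,residue_number,chain_id Optional strand metadata
#'   (recycled if scalar).
#' @param charge Net integer charge; -1 for monoanionic, -2 for dianionic
#'   esters.
#' @param label Free-text label for the species.
#' @param role One of `"reactant"`, `"transition_state"`, `"fragment"`,
#'   `"reference"`, or `NA`.
#' @return An object of class `"geometry"`.
#' @examples
#' w <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'               label = "water")
#' n_atoms(w)
#' @export
geometry <- function(elements, coords, serial = seq_along(elements),
                     name = NA_character_, residue_name = NA_character_,
                     residue_number = NA_integer_, chain_id = NA_character_,
                     charge = 0L, label = "", role = NA_character_) {
  elements <- .normalize_element(as.character(elements))
  n <- length(elements)
  if (n == 0L) stop("geometry must contain at least one atom")
  if (!all(.known_element(elements))) {
    stop("unrecognized element symbol(s): ",
         paste(unique(elements[!.known_element(elements)]), collapse = ", "))
  }
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || nrow(coords) != n || ncol(coords) != 3) {
    stop("coords must be an n x 3 matrix matching length(elements)")
  }
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  serial <- as.integer(serial)
  if (length(serial) != n || anyNA(serial) || any(serial <= 0L) ||
      anyDuplicated(serial)) {
    stop("serial must be unique positive integers, one per atom")
  }
  if (!is.na(role) &&
      !role %in% c("reactant", "transition_state", "fragment", "reference")) {
    stop("role must be one of reactant, transition_state, fragment, reference")
  }
  rec <- function(x, mode) {
    x <- rep_len(x, n)
    storage.mode(x) <- mode
    x
  }
  structure(list(
    elements = elements, coords = coords, serial = serial,
    name = rec(name, "character"),
    residue_name = rec(residue_name, "character"),
    residue_number = rec(residue_number, "integer"),
    chain_id = rec(chain_id, "character"),
    charge = as.integer(charge), label = as.character(label),
    role = as.character(role)
  ), class = "geometry")
}

#' Number of atoms in a geometry
#' @param x A `geometry`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "geometry"))
  length(x$elements)
}

#' @export
print.geometry <- function(x, ...) {
  comp <- table(x$elements)
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat("<geometry>", if (nzchar(x$label)) x$label else "(unlabelled)", "\n")
  cat("  atoms:", n_atoms(x), paste0("(", formula, ")"),
      " charge:", x$charge,
      if (!is.na(x$role)) paste0(" role: ", x$role) else "", "\n")
  invisible(x)
}

.read_lines_or_text <- function(file, text) {
  if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
}

#' Read a geometry from XYZ format
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` record per atom (coordinates in angstrom). Serials are
#' assigned 1..n in file order.
#'
#' @param file Path to an XYZ file.
#' @param text Alternatively, the file content as a single string.
#' @param label,charge,role Passed to [geometry()]; `label` defaults to the
#'   XYZ comment line.
#' @return A `geometry`.
#' @examples
#' read_xyz(text = "1\nlone phosphorus\nP 0 0 0")
#' @export
read_xyz <- function(file = NULL, text = NULL, label = NULL, charge = 0L,
                     role = NA_character_) {
  lines <- .read_lines_or_text(file, text)
  if (length(lines) < 1L) stop("XYZ parse error at line 1: empty input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n <= 0L) {
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'")
  }
  if (length(lines) < n + 2L) {
    stop("XYZ parse error: header claims ", n, " atoms but only ",
         max(length(lines) - 2L, 0L), " atom records present")
  }
  comment <- if (length(lines) >= 2L) lines[2] else ""
  el <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L) {
      stop("XYZ parse error at line ", ln, ": expected 'element x y z'")
    }
    if (!.known_element(tok[1])) {
      stop("XYZ parse error at line ", ln, ": unknown element '", tok[1], "'")
    }
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate")
    }
    el[i] <- tok[1]
    xyz[i, ] <- v
  }
  geometry(el, xyz, charge = charge,
           label = if (is.null(label)) trimws(comment) else label,
           role = role)
}

#' Write a geometry in XYZ format
#'
#' @param geom A `geometry`.
#' @param file Output path; if `NULL` the XYZ text is returned invisibly.
#' @param digits Coordinate decimals (default 6).
#' @return The XYZ text, invisibly.
#' @export
write_xyz <- function(geom, file = NULL, digits = 6) {
  stopifnot(inherits(geom, "geometry"))
  body <- sprintf(paste0("%-2s %", digits + 6, ".", digits, "f %",
                         digits + 6, ".", digits, "f %",
                         digits + 6, ".", digits, "f"),
                  geom$elements, geom$coords[, 1], geom$coords[, 2],
                  geom$coords[, 3])
  txt <- paste(c(as.character(n_atoms(geom)), geom$label, body),
               collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

# Element from a PDB atom-name field (columns 13-16), used when the element
# column is blank: letters of columns 13-14, preferring a 2-letter match.
.element_from_pdb_name <- function(name4) {
  two <- gsub("[^A-Za-z]", "", substr(name4, 1, 2))
  if (nchar(two) == 2 && .known_element(two)) return(.normalize_element(two))
  one <- gsub("[^A-Za-z]", "", name4)
  if (!nzchar(one)) return(NA_character_)
  first <- substr(one, 1, 1)
  if (.known_element(first)) .normalize_element(first) else NA_character_
}

#' Read ATOM/HETATM records from a PDB file
#'
#' Fixed-width parsing per PDB v3.3. The element is taken from the element
#' column (77-78) when present, otherwise inferred from the atom-name
#' convention. All non-ATOM/HETATM records are ignored.
#'
#' @param file Path to a PDB file.
#' @param text Alternatively, the content as a single string.
#' @param charge,label,role Passed to [geometry()].
#' @return A `geometry` with residue metadata and original serials.
#' @export
read_pdb_subset <- function(file = NULL, text = NULL, charge = 0L,
                            label = "", role = NA_character_) {
  lines <- .read_lines_or_text(file, text)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM") |
                  substr(lines, 1, 4) == "ATOM" & nchar(lines) >= 54)
  keep <- keep[grepl("^(ATOM|HETATM)", lines[keep])]
  if (length(keep) == 0L) {
    stop("empty structure: no ATOM/HETATM records found")
  }
  f <- function(ln, a, b) substr(ln, a, b)
  el <- character(length(keep)); nm <- character(length(keep))
  rn <- character(length(keep)); ch <- character(length(keep))
  ri <- integer(length(keep)); sr <- integer(length(keep))
  xyz <- matrix(NA_real_, length(keep), 3)
  for (k in seq_along(keep)) {
    ln <- lines[keep[k]]
    if (nchar(ln) < 54) {
      stop("PDB parse error at line ", keep[k], ": record too short")
    }
    sr[k] <- suppressWarnings(as.integer(trimws(f(ln, 7, 11))))
    nm[k] <- trimws(f(ln, 13, 16))
    rn[k] <- trimws(f(ln, 18, 20))
    ch[k] <- trimws(f(ln, 22, 22))
    ri[k] <- suppressWarnings(as.integer(trimws(f(ln, 23, 26))))
    v <- suppressWarnings(as.numeric(c(f(ln, 31, 38), f(ln, 39, 46),
                                       f(ln, 47, 54))))
    if (anyNA(v)) {
      stop("PDB parse error at line ", keep[k], ": non-numeric coordinate")
    }
    xyz[k, ] <- v
    e <- trimws(f(ln, 77, 78))
    if (nzchar(e) && .known_element(e)) {
      el[k] <- .normalize_element(e)
    } else {
      el[k] <- .element_from_pdb_name(f(ln, 13, 16))
    }
    if (is.na(el[k]) || !nzchar(el[k])) {
      stop("PDB parse error at line ", keep[k],
           ": cannot infer element from name '", nm[k], "'")
    }
  }
  if (anyNA(sr) || anyDuplicated(sr)) sr <- seq_along(keep)
  ch[!nzchar(ch)] <- NA_character_
  geometry(el, xyz, serial = sr, name = nm, residue_name = rn,
           residue_number = ri, chain_id = ch, charge = charge,
           label = label, role = role)
}

#' Write a geometry as PDB ATOM records
#'
#' Serials, names and residue metadata are preserved. An optional per-atom
#' numeric vector is written into the B-factor column; the ONIOM writer uses
#' this to tag layers (1 = QM, 0 = MM).
#'
#' @param geom A `geometry`.
#' @param file Output path; if `NULL` the text is returned invisibly.
#' @param bfactor Optional numeric vector (length `n_atoms(geom)`).
#' @return The PDB text, invisibly.
#' @export
write_pdb <- function(geom, file = NULL, bfactor = NULL) {
  stopifnot(inherits(geom, "geometry"))
  n <- n_atoms(geom)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  stopifnot(length(bfactor) == n)
  nm <- ifelse(is.na(geom$name), geom$elements, geom$name)
  # names of up to 3 chars conventionally start in column 14
  nm4 <- ifelse(nchar(nm) <= 3, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  rn <- ifelse(is.na(geom$residue_name), "UNK", geom$residue_name)
  ch <- ifelse(is.na(geom$chain_id), "A", geom$chain_id)
  ri <- ifelse(is.na(geom$residue_number), 1L, geom$residue_number)
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    geom$serial, nm4, rn, ch, ri,
    geom$coords[, 1], geom$coords[, 2], geom$coords[, 3],
    1.00, bfactor, toupper(geom$elements))
  txt <- paste(c(lines, "END"), collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Perceive bonds from covalent radii
#'
#' Atoms i and j are bonded iff their distance does not exceed
#' `scale * (r_cov(i) + r_cov(j))`. All bonds are treated as single bonds;
#' bond orders are not modelled.
#'
#' @param geom A `geometry`.
#' @param scale Positive scale factor on the covalent-radius sum
#'   (default 1.15).
#' @return An object of class `"bond_graph"`: a list with `adjacency` (list
#'   of sorted integer neighbour vectors, one per atom) and `n`.
#' @export
perceive_bonds <- function(geom, scale = 1.15) {
  stopifnot(inherits(geom, "geometry"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a positive number")
  }
  r <- covalent_radius(geom$elements)   # errors on missing radius
  n <- n_atoms(geom)
  d <- as.matrix(stats::dist(geom$coords))
  cutoff <- scale * outer(r, r, "+")
  adj <- vector("list", n)
  bonded <- d <= cutoff
  diag(bonded) <- FALSE
  for (i in seq_len(n)) adj[[i]] <- unname(which(bonded[i, ]))
  structure(list(adjacency = adj, n = n), class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("<bond_graph>", x$n, "atoms,", sum(lengths(x$adjacency)) / 2,
      "bonds\n")
  invisible(x)
}

.bond_degree <- function(bonds) lengths(bonds$adjacency)

#' Identify the reaction center of an ester
#'
#' The reaction center is the As or P atom bonded to the greatest number of
#' oxygen atoms (the site attacked by the water nucleophile). Ties are
#' broken by lowest serial and flagged via the `"ambiguous"` attribute.
#'
#' @param geom A `geometry` containing at least one As or P atom.
#' @param bonds Its `bond_graph` (default: perceived with standard scale).
#' @return Integer atom index with attribute `ambiguous` (logical).
#' @export
identify_reaction_center <- function(geom, bonds = perceive_bonds(geom)) {
  stopifnot(inherits(geom, "geometry"), inherits(bonds, "bond_graph"))
  cand <- which(geom$elements %in% c("As", "P"))
  if (length(cand) == 0L) {
    stop("not an ester: geometry contains no As or P atom")
  }
  n_ox <- vapply(cand, function(i) {
    sum(geom$elements[bonds$adjacency[[i]]] == "O")
  }, integer(1))
  best <- cand[n_ox == max(n_ox)]
  winner <- best[which.min(geom$serial[best])]
  structure(winner, ambiguous = length(best) > 1L)
}
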