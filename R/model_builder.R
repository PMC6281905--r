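# Model-building operations: ester classification, As-for-P backbone
# substitution, two-layer QM/MM (ONIOM-style) partitioning with hydrogen
# link atoms, and strand extraction from PDB-derived structures.

# breadth-first graph distances (in bonds) from a start atom; Inf when
# unreachable
.graph_distances <- function(bonds, start) {
  d <- rep(Inf, bonds$n)
  d[start] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in bonds$adjacency[[v]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# connected component containing `start` in the bond graph with the given
# edges removed (edges: 2-column matrix)
.component_of <- function(bonds, start, drop_edges = NULL) {
  blocked <- function(a, b) FALSE
  if (!is.null(drop_edges) && nrow(drop_edges)) {
    key <- c(paste(drop_edges[, 1], drop_edges[, 2]),
             paste(drop_edges[, 2], drop_edges[, 1]))
    blocked <- function(a, b) paste(a, b) %in% key
  }
  seen <- rep(FALSE, bonds$n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in bonds$adjacency[[v]]) {
        if (!seen[w] && !blocked(v, w)) {
          seen[w] <- TRUE
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  which(seen)
}

#' Classify a biological ester
#'
#' Walks outward from the central As/P atom and counts ester linkages:
#' oxygens bridging from the center to a non-hydrogen heavy atom. One
#' bridge makes a monoester, two a diester. A phosphorus beyond the bridge
#' gives the `O-P-R` leaving-group pattern (class 1A, e.g. pyrophosphate /
#' pyroarsenate); a carbon gives `O-C-R` (class 1B for monoesters, e.g.
#' ribose-1-arsenate; class 2 for diesters, e.g. the DNA backbone). The
#' anionic state is read from the geometry's charge (-1 mono, -2 di).
#'
#' @param geom A `geometry`.
#' @param bonds Its `bond_graph` (default: perceived).
#' @return Object of class `"ester_classification"`: `ester_class` (`"1A"`,
#'   `"1B"` or `"2"`), `ester_type`, `leaving_group_pattern`,
#'   `central_atom`, `anionic_state`, `center` (atom index), `ambiguous`.
#' @export
classify_ester <- function(geom, bonds = perceive_bonds(geom)) {
  stopifnot(inherits(geom, "geometry"), inherits(bonds, "bond_graph"))
  center <- identify_reaction_center(geom, bonds)
  ox <- bonds$adjacency[[center]]
  ox <- ox[geom$elements[ox] == "O"]
  bridged <- character(0)
  for (o in ox) {
    heavy <- setdiff(bonds$adjacency[[o]], center)
    heavy <- heavy[geom$elements[heavy] != "H"]
    if (length(heavy)) bridged <- c(bridged, geom$elements[heavy[1]])
  }
  nb <- length(bridged)
  if (nb == 0L || nb > 2L) {
    stop("unsupported ester: found ", nb, " ester linkage(s) at the ",
         "reaction center (expected 1 or 2)")
  }
  if (nb == 1L) {
    ester_type <- "monoester"
    if (bridged == "P") {
      cls <- "1A"; pat <- "O-P-R"
    } else if (bridged == "C") {
      cls <- "1B"; pat <- "O-C-R"
    } else {
      stop("unsupported ester: bridged atom is ", bridged,
           " (expected P or C)")
    }
  } else {
    ester_type <- "diester"
    if (!all(bridged == "C")) {
      stop("unsupported ester: diester bridges must both be to carbon, got ",
           paste(bridged, collapse = ", "))
    }
    cls <- "2"; pat <- "O-C-R"
  }
  anionic <- if (geom$charge == -1L) "mono" else if (geom$charge == -2L) "di"
  else {
    warning("charge ", geom$charge,
            " does not correspond to a mono- or dianionic ester")
    NA_character_
  }
  structure(list(ester_class = cls, ester_type = ester_type,
                 leaving_group_pattern = pat,
                 central_atom = geom$elements[center],
                 anionic_state = anionic, center = as.integer(center),
                 ambiguous = isTRUE(attr(center, "ambiguous"))),
            class = "ester_classification")
}

#' @export
print.ester_classification <- function(x, ...) {
  cat(sprintf("<ester_classification> class %s %s (%s), central %s, %sanionic\n",
              x$ester_class, x$ester_type, x$leaving_group_pattern,
              x$central_atom,
              if (is.na(x$anionic_state)) "?-" else
                paste0(x$anionic_state, "-")))
  invisible(x)
}

#' Replace backbone phosphorus atoms with arsenic
#'
#' Turns selected P atoms into As in place. By default coordinates are
#' untouched (every non-target coordinate is preserved bit-exactly). With
#' `adjust_bonds = TRUE`, each As-O bond of a substituted center is
#' lengthened along its axis by the covalent-radius difference
#' As - P (= 0.12 angstrom), moving only the oxygen atoms of that ester
#' group. An oxygen bridging two substituted centers receives both
#' displacements, which only approximates the two target bond lengths.
#'
#' @param geom A `geometry`.
#' @param positions Atom indices; every one must currently be a P atom. An
#'   empty selection returns the geometry unchanged.
#' @param adjust_bonds Lengthen the new As-O bonds (default `FALSE`).
#' @param scale Bond-perception scale used when `adjust_bonds = TRUE`.
#' @return The substituted `geometry`.
#' @export
substitute_central_atoms <- function(geom, positions, adjust_bonds = FALSE,
                                     scale = 1.15) {
  stopifnot(inherits(geom, "geometry"))
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(geom)
  if (any(positions < 1L | positions > n_atoms(geom))) {
    stop("substitution error: position out of range")
  }
  if (!all(geom$elements[positions] == "P")) {
    bad <- positions[geom$elements[positions] != "P"]
    stop("substitution error: atom(s) ", paste(bad, collapse = ", "),
         " are not phosphorus")
  }
  out <- geom
  if (adjust_bonds) {
    bonds <- perceive_bonds(geom, scale = scale)
    dr <- covalent_radius("As") - covalent_radius("P")
    for (p in positions) {
      for (o in bonds$adjacency[[p]]) {
        if (geom$elements[o] != "O") next
        axis <- out$coords[o, ] - geom$coords[p, ]
        axis <- axis / sqrt(sum(axis^2))
        out$coords[o, ] <- out$coords[o, ] + dr * axis
      }
    }
  }
  out$elements[positions] <- "As"
  if (!all(is.na(out$name))) {
    out$name[positions] <- sub("^P", "AS", out$name[positions])
  }
  out
}

#' Two-layer QM/MM partition
#'
#' Splits a structure into a QM (model) layer around the reaction center
#' and an MM (low) layer, cutting only non-polar bonds between two
#' sp3-hybridized carbons (topological criterion: carbon with exactly four
#' neighbours) whose endpoints are both more than `min_graph_distance`
#' bonds away from the center. Among all admissible cut sets the QM region
#' is made as small as possible while staying connected and containing the
#' center. A hydrogen link atom is placed on each cut-bond axis at
#' `link_distance` from the QM-side carbon.
#'
#' If no eligible cut bond exists the whole system is returned as QM with a
#' warning (not an error).
#'
#' @param geom A `geometry`.
#' @param bonds Its `bond_graph`; must be connected.
#' @param center Reaction-center atom index (default:
#'   [identify_reaction_center()]).
#' @param min_graph_distance Bond-count threshold from the center; both cut
#'   bond endpoints must lie strictly beyond it (default 4).
#' @param link_distance Link-atom C-H distance in angstrom (default 1.09,
#'   unscaled).
#' @param frozen_mm Flag recorded in the partition (default `TRUE`, the MM
#'   layer is kept frozen to preserve backbone constraints).
#' @return Object of class `"oniom_partition"`: `qm_atoms`, `mm_atoms`
#'   (disjoint, exhaustive), `cut_bonds` (matrix, QM side first),
#'   `link_atoms` (data frame: host QM index, replaced MM index, element,
#'   x, y, z), `center`, `frozen_mm`, `warning`.
#' @export
partition_oniom <- function(geom, bonds = perceive_bonds(geom),
                            center = NULL, min_graph_distance = 4,
                            link_distance = 1.09, frozen_mm = TRUE) {
  stopifnot(inherits(geom, "geometry"), inherits(bonds, "bond_graph"))
  if (is.null(center)) center <- as.integer(identify_reaction_center(geom, bonds))
  center <- .check_indices(geom, center)
  dist_c <- .graph_distances(bonds, center)
  if (any(is.infinite(dist_c))) {
    stop("bond graph is not connected; partitioning requires a connected ",
         "structure")
  }
  deg <- .bond_degree(bonds)
  sp3_c <- geom$elements == "C" & deg == 4L
  # candidate cut bonds: sp3 C - sp3 C, both ends > threshold from center
  cand <- NULL
  for (i in which(sp3_c)) {
    for (j in bonds$adjacency[[i]]) {
      if (j > i && sp3_c[j] &&
          dist_c[i] > min_graph_distance && dist_c[j] > min_graph_distance) {
        cand <- rbind(cand, c(i, j))
      }
    }
  }
  warn <- NULL
  if (is.null(cand)) {
    warn <- "no eligible sp3 C-C cut bond; whole system assigned to QM"
    warning(warn)
    qm <- seq_len(bonds$n)
    cut <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("qm", "mm")))
  } else {
    # removing every candidate at once yields the smallest admissible QM
    # region (any admissible region is a union of components of that graph)
    qm <- .component_of(bonds, center, drop_edges = cand)
    on_boundary <- xor(cand[, 1] %in% qm, cand[, 2] %in% qm)
    cut <- cand[on_boundary, , drop = FALSE]
    flip <- !(cut[, 1] %in% qm)
    cut[flip, ] <- cut[flip, 2:1]
    dimnames(cut) <- list(NULL, c("qm", "mm"))
  }
  mm <- setdiff(seq_len(bonds$n), qm)
  link <- data.frame(host = integer(0), replaced = integer(0),
                     element = character(0), x = numeric(0), y = numeric(0),
                     z = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cut)) {
    pos <- t(apply(cut, 1, function(b) {
      axis <- geom$coords[b[2], ] - geom$coords[b[1], ]
      geom$coords[b[1], ] + link_distance * axis / sqrt(sum(axis^2))
    }))
    link <- data.frame(host = cut[, 1], replaced = cut[, 2],
                       element = "H", x = pos[, 1], y = pos[, 2],
                       z = pos[, 3], stringsAsFactors = FALSE)
  }
  structure(list(qm_atoms = sort(qm), mm_atoms = sort(mm),
                 cut_bonds = cut, link_atoms = link,
                 center = as.integer(center),
                 min_graph_distance = min_graph_distance,
                 frozen_mm = isTRUE(frozen_mm), warning = warn),
            class = "oniom_partition")
}

#' @export
print.oniom_partition <- function(x, ...) {
  cat("<oniom_partition>", length(x$qm_atoms), "QM atoms,",
      length(x$mm_atoms), "MM atoms,", nrow(x$cut_bonds),
      "cut bond(s) /", nrow(x$link_atoms), "link atom(s)\n")
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Write a layered structure and partition manifest
#'
#' Serializes the partition as (a) a PDB file with the layer encoded in the
#' B-factor column (1.00 = QM, 0.00 = MM) and (b) a JSON manifest listing
#' both atom sets, cut bonds and link atoms.
#'
#' @param geom The partitioned `geometry`.
#' @param part An `oniom_partition` of `geom`.
#' @param pdb_file,json_file Output paths; `NULL` skips writing and the
#'   texts are returned invisibly.
#' @return List with `pdb` and `json` texts, invisibly.
#' @export
write_oniom_partition <- function(geom, part, pdb_file = NULL,
                                  json_file = NULL) {
  stopifnot(inherits(geom, "geometry"), inherits(part, "oniom_partition"))
  layer <- as.numeric(seq_len(n_atoms(geom)) %in% part$qm_atoms)
  pdb <- write_pdb(geom, file = pdb_file, bfactor = layer)
  js <- as.character(jsonlite::toJSON(list(
    center = part$center, qm_atoms = part$qm_atoms,
    mm_atoms = part$mm_atoms, cut_bonds = part$cut_bonds,
    link_atoms = part$link_atoms, frozen_mm = part$frozen_mm,
    min_graph_distance = part$min_graph_distance),
    digits = NA, auto_unbox = TRUE, dataframe = "rows"))
  if (!is.null(json_file)) writeLines(js, json_file)
  invisible(list(pdb = pdb, json = js))
}

#' Extract residues of one chain from a structure
#'
#' @param geom A `geometry` with residue metadata (e.g. from
#'   [read_pdb_subset()]).
#' @param chain Chain identifier.
#' @param residues Integer vector of residue numbers (e.g. `1:4`); every
#'   requested residue must exist in the chain, otherwise the selection
#'   crosses a gap/chain break and an error is raised.
#' @param cap Cap severed bonds at selected oxygens with hydrogens at
#'   0.96 angstrom along the severed bond axis (default `FALSE`: the
#'   selection is left unmodified).
#' @param scale Bond-perception scale used when `cap = TRUE`.
#' @return The extracted `geometry` with original metadata preserved.
#' @export
extract_strand <- function(geom, chain, residues, cap = FALSE,
                           scale = 1.15) {
  stopifnot(inherits(geom, "geometry"))
  residues <- as.integer(residues)
  in_chain <- !is.na(geom$chain_id) & geom$chain_id == chain
  present <- unique(geom$residue_number[in_chain])
  missing <- setdiff(residues, present)
  if (length(missing)) {
    stop("selection crosses a chain break: residue(s) ",
         paste(missing, collapse = ", "), " not present in chain '",
         chain, "'")
  }
  sel <- which(in_chain & geom$residue_number %in% residues)
  if (length(sel) == 0L) stop("empty selection")
  sub <- function(x) x[sel]
  out <- geometry(geom$elements[sel], geom$coords[sel, , drop = FALSE],
                  serial = geom$serial[sel], name = sub(geom$name),
                  residue_name = sub(geom$residue_name),
                  residue_number = sub(geom$residue_number),
                  chain_id = sub(geom$chain_id), charge = geom$charge,
                  label = geom$label, role = geom$role)
  if (cap) {
    bonds <- perceive_bonds(geom, scale = scale)
    add <- NULL
    for (k in seq_along(sel)) {
      a <- sel[k]
      if (geom$elements[a] != "O") next
      for (b in setdiff(bonds$adjacency[[a]], sel)) {
        axis <- geom$coords[b, ] - geom$coords[a, ]
        axis <- axis / sqrt(sum(axis^2))
        add <- rbind(add, c(k, geom$coords[a, ] + 0.96 * axis))
      }
    }
    if (!is.null(add)) {
      nh <- nrow(add)
      out <- geometry(
        c(out$elements, rep("H", nh)),
        rbind(out$coords, add[, 2:4, drop = FALSE]),
        serial = c(out$serial, max(out$serial) + seq_len(nh)),
        name = c(out$name, rep("HCAP", nh)),
        residue_name = c(out$residue_name,
                         out$residue_name[add[, 1]]),
        residue_number = c(out$residue_number,
                           out$residue_number[add[, 1]]),
        chain_id = c(out$chain_id, out$chain_id[add[, 1]]),
        charge = out$charge, label = out$label, role = out$role)
    }
  }
  out
}
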