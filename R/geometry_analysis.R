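# Internal-coordinate measurements (distances, angles, dihedrals),
# reactant-vs-TS parameter tables, and Kabsch least-squares superposition.

.check_indices <- function(geom, idx) {
  idx <- as.integer(idx)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_atoms(geom))) {
    stop("atom index out of range (geometry has ", n_atoms(geom), " atoms)")
  }
  if (anyDuplicated(idx)) stop("atom indices must be distinct")
  idx
}

#' Interatomic distance
#'
#' @param geom A `geometry`.
#' @param i,j Distinct 1-based atom indices.
#' @return Euclidean distance in angstrom.
#' @export
atom_distance <- function(geom, i, j) {
  idx <- .check_indices(geom, c(i, j))
  sqrt(sum((geom$coords[idx[1], ] - geom$coords[idx[2], ])^2))
}

#' Bond angle
#'
#' Angle at vertex `j` subtended by atoms `i` and `k`.
#'
#' @param geom A `geometry`.
#' @param i,j,k Distinct atom indices; `j` is the vertex.
#' @return Angle in degrees, in \[0, 180\].
#' @export
atom_angle <- function(geom, i, j, k) {
  idx <- .check_indices(geom, c(i, j, k))
  u <- geom$coords[idx[1], ] - geom$coords[idx[2], ]
  w <- geom$coords[idx[3], ] - geom$coords[idx[2], ]
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0) stop("undefined angle: zero-length arm")
  cosang <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Dihedral (torsion) angle
#'
#' Signed torsion about the `j`-`k` axis, using the atan2 convention.
#'
#' @param geom A `geometry`.
#' @param i,j,k,l Distinct atom indices.
#' @return Signed angle in degrees, in (-180, 180].
#' @export
atom_dihedral <- function(geom, i, j, k, l) {
  idx <- .check_indices(geom, c(i, j, k, l))
  p <- geom$coords[idx, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) == 0 || sum(n2^2) == 0) {
    stop("undefined dihedral: collinear or coincident atoms on the axis")
  }
  x <- sum(n1 * n2)
  y <- sum(b1 * n2) * nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Define a geometric parameter for a reactant/TS comparison table
#'
#' @param kind `"distance"`, `"angle"`, or `"dihedral"`.
#' @param roles Character role labels (2, 3 or 4 to match `kind`), e.g.
#'   `c("E", "O_p")`; used to render the parameter name.
#' @param reactant,ts Integer atom indices of those roles in the reactant
#'   and transition-state geometries respectively.
#' @return An object of class `"param_spec"`.
#' @export
param_spec <- function(kind = c("distance", "angle", "dihedral"), roles,
                       reactant, ts = reactant) {
  kind <- match.arg(kind)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  roles <- as.character(roles)
  if (length(roles) != need) {
    stop(kind, " parameter needs ", need, " roles, got ", length(roles))
  }
  if (length(reactant) != need || length(ts) != need) {
    stop(kind, " parameter needs ", need, " atom indices per geometry")
  }
  if (anyDuplicated(reactant) || anyDuplicated(ts)) {
    stop("mapped atom indices must be distinct")
  }
  lab <- switch(kind,
    distance = sprintf("d(%s)", paste(roles, collapse = "-")),
    angle = sprintf("angle(%s)", paste(roles, collapse = "-")),
    dihedral = sprintf("dihedral(%s)", paste(roles, collapse = "-")))
  structure(list(kind = kind, roles = roles, label = lab,
                 reactant = as.integer(reactant), ts = as.integer(ts)),
            class = "param_spec")
}

.measure_spec <- function(geom, spec, which) {
  idx <- spec[[which]]
  switch(spec$kind,
    distance = atom_distance(geom, idx[1], idx[2]),
    angle = atom_angle(geom, idx[1], idx[2], idx[3]),
    dihedral = atom_dihedral(geom, idx[1], idx[2], idx[3], idx[4]))
}

#' Reactant-versus-transition-state parameter table
#'
#' Measures each parameter in both geometries and tabulates the change on
#' going from reactant to TS (`delta = ts - reactant`).
#'
#' @param reactant,ts `geometry` objects.
#' @param specs A list of [param_spec()] objects (a single spec is
#'   accepted).
#' @return A data frame of class `"geometry_table"` with columns
#'   `parameter`, `kind`, `unit`, `reactant`, `ts`, `delta`. Values are kept
#'   at full precision; printing rounds to 2 decimals.
#' @export
parameter_table <- function(reactant, ts, specs) {
  stopifnot(inherits(reactant, "geometry"), inherits(ts, "geometry"))
  if (inherits(specs, "param_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("at least one param_spec is required")
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "param_spec"))
    vr <- tryCatch(.measure_spec(reactant, sp, "reactant"), error = function(e)
      stop("parameter '", sp$label, "' (reactant): ", conditionMessage(e),
           call. = FALSE))
    vt <- tryCatch(.measure_spec(ts, sp, "ts"), error = function(e)
      stop("parameter '", sp$label, "' (ts): ", conditionMessage(e),
           call. = FALSE))
    data.frame(parameter = sp$label, kind = sp$kind,
               unit = if (sp$kind == "distance") "angstrom" else "degrees",
               reactant = vr, ts = vt, delta = vt - vr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("geometry_table", "data.frame")
  out
}

#' @export
print.geometry_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$reactant <- sprintf("%.2f", y$reactant)
  y$ts <- sprintf("%.2f", y$ts)
  y$delta <- sprintf("%+.2f", y$delta)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Export a geometry table as TSV or JSON
#'
#' @param x A `geometry_table`.
#' @param file Output path; if `NULL` the text is returned invisibly.
#' @param format `"tsv"` or `"json"`.
#' @return The serialized text, invisibly.
#' @export
write_geometry_table <- function(x, file = NULL,
                                 format = c("tsv", "json")) {
  stopifnot(inherits(x, "geometry_table"))
  format <- match.arg(format)
  txt <- if (format == "tsv") {
    hdr <- paste(names(x), collapse = "\t")
    body <- apply(as.data.frame(x), 1, function(r)
      paste(trimws(unname(r)), collapse = "\t"))
    paste(c(hdr, body), collapse = "\n")
  } else {
    as.character(jsonlite::toJSON(as.data.frame(x), digits = NA,
                                  dataframe = "rows"))
  }
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

.coords_of <- function(x) {
  if (inherits(x, "geometry")) x$coords else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

#' Pair atoms of two structures by residue number and atom name
#'
#' Helper building the 1:1 correspondence for [kabsch_superpose()]; pairs
#' atoms sharing `(residue_number, name)`, optionally restricted to heavy
#' atoms.
#'
#' @param ref,mobile `geometry` objects with residue metadata.
#' @param heavy_only Drop hydrogens (default `TRUE`).
#' @return Two-column integer matrix of (ref index, mobile index) pairs.
#' @export
pair_atoms <- function(ref, mobile, heavy_only = TRUE) {
  stopifnot(inherits(ref, "geometry"), inherits(mobile, "geometry"))
  key <- function(g) paste(g$residue_number, g$name, sep = "/")
  kr <- key(ref); km <- key(mobile)
  ok_r <- !is.na(ref$residue_number) & !is.na(ref$name)
  ok_m <- !is.na(mobile$residue_number) & !is.na(mobile$name)
  if (heavy_only) {
    ok_r <- ok_r & ref$elements != "H"
    ok_m <- ok_m & mobile$elements != "H"
  }
  m <- match(kr, ifelse(ok_m, km, NA_character_))
  i <- which(ok_r & !is.na(m))
  cbind(ref = i, mobile = m[i])
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid alignment of paired coordinate sets via the
#' Kabsch algorithm (SVD with determinant correction, so the result is a
#' proper rotation). The transform maps mobile coordinates onto the
#' reference frame: `x' = R x + t`.
#'
#' @param ref,mobile `geometry` objects or n x 3 coordinate matrices.
#' @param pairs Two-column matrix of (ref, mobile) atom indices. If `NULL`
#'   and both inputs are geometries with residue metadata, [pair_atoms()]
#'   is used; if `NULL` and the coordinate counts match, atoms are paired
#'   by position.
#' @param heavy_only Passed to [pair_atoms()] when pairing automatically.
#' @return An object of class `"superposition"`: list with `rotation`
#'   (3 x 3, proper orthogonal), `translation` (length 3, angstrom), `rmsd`
#'   (angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(ref, mobile, pairs = NULL, heavy_only = TRUE) {
  P <- .coords_of(ref); Q <- .coords_of(mobile)
  if (is.null(pairs)) {
    if (inherits(ref, "geometry") && inherits(mobile, "geometry") &&
        any(!is.na(ref$residue_number))) {
      pairs <- pair_atoms(ref, mobile, heavy_only = heavy_only)
    } else if (nrow(P) == nrow(Q)) {
      pairs <- cbind(seq_len(nrow(P)), seq_len(nrow(P)))
    } else {
      stop("pairs must be supplied when structures cannot be auto-paired")
    }
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must be a two-column index matrix")
  if (nrow(pairs) < 3L) {
    stop("degenerate superposition: at least 3 matched pairs required")
  }
  A <- P[pairs[, 1], , drop = FALSE]   # reference
  B <- Q[pairs[, 2], , drop = FALSE]   # mobile
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv_check <- svd(A0)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1e-300)) {
    stop("degenerate superposition: matched reference atoms are collinear")
  }
  H <- crossprod(B0, A0)               # 3x3 covariance, mobile -> ref
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(ca - R %*% cb)
  fit <- sweep(B %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_pairs = nrow(pairs)), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition>", x$n_pairs, "pairs, rmsd",
      sprintf("%.4f", x$rmsd), "angstrom\n")
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition`.
#' @param x A `geometry` or coordinate matrix.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_superposition <- function(sp, x) {
  stopifnot(inherits(sp, "superposition"))
  co <- .coords_of(x)
  out <- sweep(co %*% t(sp$rotation), 2, sp$translation, "+")
  if (inherits(x, "geometry")) {
    x$coords <- out
    dimnames(x$coords) <- list(NULL, c("x", "y", "z"))
    x
  } else out
}

#' Serialize a superposition as JSON
#'
#' @param sp A `superposition`.
#' @param file Output path; if `NULL` the JSON text is returned invisibly.
#' @return JSON text, invisibly.
#' @export
write_superposition <- function(sp, file = NULL) {
  stopifnot(inherits(sp, "superposition"))
  txt <- as.character(jsonlite::toJSON(list(
    rotation = sp$rotation, translation = sp$translation,
    rmsd = sp$rmsd, n_pairs = sp$n_pairs), digits = NA, auto_unbox = TRUE))
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
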