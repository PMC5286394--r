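# Atomic models: a flat atom table plus chain -> subunit / copy maps.
# Author residue numbering is preserved verbatim throughout; crosslink
# tables reference author numbering.

#' Construct an atomic model
#'
#' An atomic model is a flat table of atoms together with two chain-level
#' maps: which subunit each chain belongs to and which copy index (1 or 2
#' for duplicated subunits) it represents.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `elety` (atom name), `x`, `y`, `z` (Angstrom).
#' @param subunits named character vector mapping chain id to subunit
#'   name. Defaults to one subunit per chain, named after the chain.
#' @param copies named integer vector mapping chain id to copy index.
#'   Defaults to 1 for every chain.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, subunits = NULL, copies = NULL) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  chains <- unique(as.character(atoms$chain))
  if (is.null(subunits)) subunits <- setNames(chains, chains)
  if (is.null(copies)) copies <- setNames(rep(1L, length(chains)), chains)
  if (!all(chains %in% names(subunits)))
    stop("every chain must map to a subunit")
  if (!all(chains %in% names(copies)))
    stop("every chain must map to a copy index")
  # residue numbers unique within a chain (per atom name)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) && anyDuplicated(ca[, c("chain", "resno")]))
    stop("duplicate residue numbers within a chain")
  structure(list(atoms = atoms,
                 subunit_of_chain = subunits[chains],
                 copy_of_chain = copies[chains]),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  nres <- nrow(unique(x$atoms[x$atoms$elety == "CA", c("chain", "resno")]))
  cat(sprintf("atomic_model: %d atoms, %d chains, %d CA residues\n",
              nrow(x$atoms), length(x$subunit_of_chain), nres))
  invisible(x)
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Reads all atoms of the first model, preserving author residue
#' numbering. Parsing is delegated to \pkg{bio3d}.
#'
#' @param path file path.
#' @param format `"pdb"` or `"cif"`; guessed from the extension when
#'   `NULL`.
#' @param subunits,copies optional chain maps, see [atomic_model()].
#' @return An `atomic_model`.
#' @export
read_structure <- function(path, format = NULL, subunits = NULL,
                           copies = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "cif"))
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no atoms in ", path)
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(chain = chain, resno = at$resno, resname = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atomic_model(atoms, subunits = subunits, copies = copies)
}

#' Write an atomic model as PDB
#'
#' @param model an `atomic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resname, chain = at$chain,
                   elety = at$elety)
  invisible(path)
}

#' Extract Calpha coordinates
#'
#' @param model an `atomic_model`.
#' @param chains optional chain subset.
#' @return data.frame with `chain`, `resno` and `x`,`y`,`z`, ordered by
#'   chain then residue number.
#' @export
calpha <- function(model, chains = NULL) {
  at <- model$atoms
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!is.null(chains)) ca <- ca[ca$chain %in% chains, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms")
  ca <- ca[order(ca$chain, ca$resno), c("chain", "resno", "x", "y", "z")]
  rownames(ca) <- NULL
  ca
}

# internal: coordinates matrix from a calpha table
ca_xyz <- function(ca) as.matrix(ca[, c("x", "y", "z")])

#' Subset a model to one rigid body
#'
#' @param model an `atomic_model`.
#' @param body a `rigid_body` (see [segment_rigid_bodies()]).
#' @return An `atomic_model` restricted to the body's residues.
#' @export
body_model <- function(model, body) {
  at <- model$atoms
  keep <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(body$ranges))) {
    r <- body$ranges[i, ]
    keep <- keep | (at$chain == r$chain & at$resno >= r$start &
                      at$resno <= r$end)
  }
  if (!any(keep)) stop("body ", body$name, " selects no atoms")
  atomic_model(at[keep, , drop = FALSE],
               subunits = model$subunit_of_chain,
               copies = model$copy_of_chain)
}

#' Apply rigid-body poses to a model
#'
#' Each body's atoms are rotated about the body's Calpha centroid and
#' translated: `x' = R (x - c0) + c0 + t`. Atoms outside every body are
#' left in place.
#'
#' @param model an `atomic_model`.
#' @param bodies list of `rigid_body`.
#' @param poses named list (by body name) of `list(q = quaternion,
#'   t = translation)`.
#' @return The transformed `atomic_model`.
#' @export
apply_poses <- function(model, bodies, poses) {
  at <- model$atoms
  for (b in bodies) {
    p <- poses[[b$name]]
    if (is.null(p)) next
    keep <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(b$ranges))) {
      r <- b$ranges[i, ]
      keep <- keep | (at$chain == r$chain & at$resno >= r$start &
                        at$resno <= r$end)
    }
    if (!any(keep)) next
    ca <- at[keep & at$elety == "CA", c("x", "y", "z"), drop = FALSE]
    c0 <- if (nrow(ca)) colMeans(ca) else
      colMeans(at[keep, c("x", "y", "z")])
    R <- quat_to_matrix(p$q)
    xyz <- as.matrix(at[keep, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, c0) %*% t(R)
    xyz <- sweep(xyz, 2, c0 + p$t, "+")
    at[keep, c("x", "y", "z")] <- xyz
  }
  out <- model
  out$atoms <- at
  out
}

#' Quaternion to rotation matrix
#'
#' @param q numeric(4), `(w, x, y, z)`, unit norm.
#' @return 3x3 proper rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Rotation matrix about an axis
#'
#' @param axis numeric(3) rotation axis (need not be normalized).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle); C <- 1 - c1
  matrix(c(c1 + u[1]^2 * C, u[1] * u[2] * C - u[3] * s1, u[1] * u[3] * C + u[2] * s1,
           u[2] * u[1] * C + u[3] * s1, c1 + u[2]^2 * C, u[2] * u[3] * C - u[1] * s1,
           u[3] * u[1] * C - u[2] * s1, u[3] * u[2] * C + u[1] * s1, c1 + u[3]^2 * C),
         nrow = 3, byrow = TRUE)
}

# internal: rotation matrix -> quaternion (w,x,y,z)
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}
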