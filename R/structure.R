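#' Coordinate model for a single protein structure
#'
#' A `barrel_structure` holds the protein ATOM records of one model as a flat
#' atom table ordered by (chain, residue number). It is the common currency of
#' every measurement in the package: hydrogen-bond detection, strand
#' segmentation and all barrel metrology operate on this object.
#'
#' @param atoms data.frame with columns `chain` (character), `resno` (integer,
#'   author numbering), `resid` (3-letter residue code), `elety` (atom name,
#'   e.g. "CA"), `elem` (element symbol), `x`, `y`, `z` (Angstrom) and `b`
#'   (B-factor / per-residue confidence).
#' @param id identifier for the structure.
#' @param source one of `"experimental"`, `"prediction"`, `"synthetic"`.
#'
#' @return An object of class `barrel_structure`.
#' @export
barrel_structure <- function(atoms, id = "structure",
                             source = c("experimental", "prediction", "synthetic")) {
  source <- match.arg(source)
  need <- c("chain", "resno", "resid", "elety", "elem", "x", "y", "z", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no protein atoms")
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates in ", sum(bad), " atom(s)")
  if (any(!nzchar(atoms$elety))) stop("empty atom names present")
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, source = source, atoms = atoms),
            class = "barrel_structure")
}

#' @export
print.barrel_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<barrel_structure> %s (%s)\n", x$id, x$source))
  cat(sprintf("  %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nrow(rt),
              paste(unique(rt$chain), collapse = ", ")))
  invisible(x)
}

# One row per residue; `complete` is TRUE iff backbone N, CA, C, O all present.
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   resid = a$resid[first], stringsAsFactors = FALSE)
  have <- function(name) {
    hit <- unique(key[a$elety == name])
    paste(rt$chain, rt$resno, sep = "\r") %in% hit
  }
  rt$complete <- have("N") & have("CA") & have("C") & have("O")
  rt[order(rt$chain, rt$resno), , drop = FALSE]
}

# Matrix of coordinates for one named backbone atom per residue, aligned to
# residue_table() rows; NA rows where the atom is missing.
atom_coords <- function(s, elety) {
  rt <- residue_table(s)
  a <- s$atoms[s$atoms$elety == elety, , drop = FALSE]
  m <- matrix(NA_real_, nrow(rt), 3L)
  idx <- match(paste(rt$chain, rt$resno), paste(a$chain, a$resno))
  ok <- !is.na(idx)
  m[ok, ] <- as.matrix(a[idx[ok], c("x", "y", "z")])
  m
}

element_from_name <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  e <- substr(e, 1L, 1L)
  ifelse(e %in% c("C", "N", "O", "S", "H", "P"), e, "C")
}

#' Read a protein structure from a PDB or mmCIF file
#'
#' Keeps the ATOM records of the first model only (matching single-conformer
#' measurements on NMR ensembles), drops HETATM/water records, and resolves
#' alternate locations to the highest-occupancy copy. Files using insertion
#' codes are rejected: all residue ranges in this package are author-numbered
#' inclusive ranges without insertion codes.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param source provenance tag stored on the structure; prediction files carry
#'   per-residue confidence in the B-factor column.
#' @param model model number to keep for multi-model files (default 1).
#' @return A [barrel_structure()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "cif"),
                           source = c("experimental", "prediction", "synthetic"),
                           model = 1L) {
  dialect <- match.arg(dialect)
  source <- match.arg(source)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- if (dialect == "cif") {
    suppressWarnings(bio3d::read.cif(path, multi = TRUE))
  } else {
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE)
  }
  sel <- pdb$atom$type == "ATOM"
  at <- pdb$atom[sel, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no protein ATOM records in '", path, "'")
  # first (or requested) model only; bio3d stores model coordinates row-wise
  # in pdb$xyz aligned with pdb$atom row order
  nmod <- nrow(pdb$xyz)
  if (nmod > 1L) {
    if (model < 1L || model > nmod) stop("model ", model, " not present (file has ", nmod, ")")
    xyzm <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at[, c("x", "y", "z")] <- xyzm[which(sel), , drop = FALSE]
  }
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(ins))) {
    stop("insertion codes present (residues ",
         paste(unique(at$resno[!is.na(ins) & nzchar(ins)]), collapse = ","),
         "); renumber the file first")
  }
  # alternate locations: keep highest occupancy per (chain, resno, elety),
  # preserving the file's atom order
  occ <- at$o
  occ[is.na(occ)] <- 1
  at$row0 <- seq_len(nrow(at))
  ord <- order(at$chain, at$resno, at$elety, -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(at$row0), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | !nzchar(elem))) elem <- element_from_name(at$elety)
  elem[is.na(elem) | !nzchar(elem)] <- element_from_name(at$elety[is.na(elem) | !nzchar(elem)])
  atoms <- data.frame(chain = as.character(at$chain), resno = as.integer(at$resno),
                      resid = as.character(at$resid), elety = as.character(at$elety),
                      elem = trimws(as.character(elem)),
                      x = at$x, y = at$y, z = at$z,
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  id <- sub("\\.(pdb|ent|cif)$", "", basename(path), ignore.case = TRUE)
  barrel_structure(atoms, id = id, source = source)
}

#' Write a structure as a standard PDB file
#'
#' Emits fixed-column ATOM records; the output round-trips through
#' [read_structure()] with coordinates preserved to 1e-3 Angstrom.
#'
#' @param s a [barrel_structure()].
#' @param path output file path.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "barrel_structure"))
  a <- s$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write '", path, "': directory does not exist")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety, elesy = a$elem,
                   o = rep(1, nrow(a)), b = a$b)
  invisible(path)
}

#' Mean per-residue model confidence
#'
#' Folding-engine predictions carry per-residue confidence (pLDDT-style) in
#' the B-factor column of the CA atoms. Values stored on a 0-100 scale are
#' auto-detected (any value > 1.5) and rescaled to the unit interval.
#'
#' @param s a [barrel_structure()] with `source = "prediction"` (or any
#'   structure whose B-factors hold confidences).
#' @return Mean CA confidence in `[0, 1]`.
#' @export
mean_confidence <- function(s) {
  stopifnot(inherits(s, "barrel_structure"))
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  rt <- residue_table(s)
  missing_ca <- !(paste(rt$chain, rt$resno) %in% paste(ca$chain, ca$resno))
  if (any(missing_ca)) {
    stop("residues without CA atoms: ",
         paste(paste0(rt$chain[missing_ca], rt$resno[missing_ca]), collapse = ", "))
  }
  v <- ca$b
  if (any(v > 1.5)) v <- v / 100
  mean(v)
}

#' Apply a rigid-body transformation to a structure
#'
#' Used by the invariance checks: every reported metric must be unchanged
#' under rotation + translation of the coordinates.
#'
#' @param s a [barrel_structure()].
#' @param rot 3x3 rotation matrix.
#' @param trans length-3 translation vector (Angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(s, rot = diag(3), trans = c(0, 0, 0)) {
  stopifnot(inherits(s, "barrel_structure"))
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1L] + trans[1L]
  s$atoms$y <- xyz[, 2L] + trans[2L]
  s$atoms$z <- xyz[, 3L] + trans[3L]
  s
}

# Uniformly rescale all coordinates about the origin (test helper for the
# linear-scaling property of distances).
scale_structure <- function(s, factor) {
  s$atoms$x <- s$atoms$x * factor
  s$atoms$y <- s$atoms$y * factor
  s$atoms$z <- s$atoms$z * factor
  s
}
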