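#' Construct a structure model
#'
#' Lightweight container for a set of atoms (one conformer). Used throughout
#' for distance queries, solvent accessibility and restraint validation.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param model_id label for the model.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = "model") {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[need]
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("all atomic positions must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom) triples: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(list(model_id = model_id, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s': %d atoms, %d residues, chains %s>\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Read a structure model from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d. Alternate locations are resolved to
#' the conformation with the highest occupancy (ties: first in file).
#' Residue numbering and chain identifiers are taken verbatim from the file.
#'
#' @param path PDB file.
#' @param model_index 1-based index of the MODEL to extract.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_models <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (model_index < 1 || model_index > n_models)
    stop("model index ", model_index, " not found (file has ",
         n_models, " model(s))")
  at <- pdb$atom
  coords <- if (is.matrix(xyz)) xyz[model_index, ] else as.numeric(xyz)
  at$x <- coords[seq(1, length(coords), by = 3)]
  at$y <- coords[seq(2, length(coords), by = 3)]
  at$z <- coords[seq(3, length(coords), by = 3)]
  # resolve altlocs: keep highest occupancy per (chain, resno, atom name)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
    i[which.max(occ[i])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  element <- at$elesy
  guess <- toupper(substr(gsub("[0-9]", "", at$elety), 1, 1))
  element <- ifelse(is.na(element) | element == "", guess, element)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno, resname = at$resid,
                      atom = at$elety, element = element,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure_model(atoms, model_id = sprintf("%s#%d", basename(path), model_index))
}

#' Write one or more structure models as a PDB file
#'
#' Minimal fixed-width ATOM writer; a list of models is written as a
#' multi-model file (MODEL/ENDMDL blocks) suitable for ensemble inputs.
#'
#' @param model a [structure_model()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  models <- if (inherits(model, "structure_model")) list(model) else model
  fmt <- function(m) {
    a <- m$atoms
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(a)),
            ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
            a$resname, a$chain, a$resno, a$x, a$y, a$z, 1, 0, a$element)
  }
  lines <- if (length(models) == 1L) {
    c(fmt(models[[1]]), "END")
  } else {
    c(unlist(lapply(seq_along(models), function(i) {
      c(sprintf("MODEL     %4d", i), fmt(models[[i]]), "ENDMDL")
    })), "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Atom selector
#'
#' @param chain chain identifier (NULL matches any).
#' @param resno residue number(s) (NULL matches any).
#' @param atom atom name(s) (NULL matches any).
#' @return selector object used by distance and restraint functions.
#' @export
atom_sel <- function(chain = NULL, resno = NULL, atom = NULL) {
  structure(list(chain = chain, resno = resno, atom = atom),
            class = "atom_sel")
}

#' Indices of atoms matched by a selector
#' @param model a [structure_model()].
#' @param sel an [atom_sel()] or integer indices (returned unchanged).
#' @return integer vector of row indices into `model$atoms`.
#' @export
match_atoms <- function(model, sel) {
  if (is.numeric(sel)) return(as.integer(sel))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  if (!is.null(sel$atom))  keep <- keep & a$atom %in% sel$atom
  which(keep)
}

.coords <- function(model, idx) {
  as.matrix(model$atoms[idx, c("x", "y", "z"), drop = FALSE])
}

#' Euclidean distance between two uniquely selected atoms
#'
#' @param model a [structure_model()].
#' @param atom_a,atom_b selectors ([atom_sel()]) each matching exactly one atom.
#' @return distance in Angstrom.
#' @export
interatomic_distance <- function(model, atom_a, atom_b) {
  ia <- match_atoms(model, atom_a)
  ib <- match_atoms(model, atom_b)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("selectors must each match exactly one atom (matched ",
         length(ia), " and ", length(ib), ")")
  sqrt(sum((.coords(model, ia) - .coords(model, ib))^2))
}

#' r^-6-weighted effective distance between two atom groups
#'
#' The ambiguous-restraint effective distance
#' \eqn{(\sum_{i,j} d_{ij}^{-6})^{-1/6}} over all cross pairs; it is always
#' less than or equal to the minimum pairwise distance and is dominated by
#' the closest contacts.
#'
#' @param model a [structure_model()].
#' @param group_a,group_b non-empty atom selectors or index vectors.
#' @return effective distance in Angstrom.
#' @export
effective_distance <- function(model, group_a, group_b) {
  ia <- match_atoms(model, group_a)
  ib <- match_atoms(model, group_b)
  if (!length(ia) || !length(ib)) stop("both atom groups must be non-empty")
  ca <- .coords(model, ia); cb <- .coords(model, ib)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  d2[d2 < 0] <- 0
  sum(d2^(-3))^(-1 / 6)
}

# Near-uniform deterministic points on the unit sphere (golden-spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point sampling of the solvent-accessible surface: each atom is
#' expanded by the probe radius and sampled with a deterministic
#' near-uniform point set; points falling inside any neighbouring expanded
#' sphere are buried. Hydrogens are ignored by default.
#'
#' @param model a [structure_model()].
#' @param probe_radius solvent probe radius, Angstrom (water: 1.4).
#' @param n_points sampling points per atom (>= 92).
#' @param include_hydrogens include H atoms as area-bearing and occluding.
#' @param radii named per-element radius table (Angstrom).
#' @return data.frame: one row per (non-hydrogen) atom with column `sasa`
#'   (Angstrom^2); total SASA as attribute `total`.
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                               include_hydrogens = FALSE,
                               radii = vdw_radii()) {
  stopifnot(probe_radius > 0, n_points >= 92)
  a <- model$atoms
  if (!include_hydrogens) a <- a[a$element != "H", , drop = FALSE]
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop("no van der Waals radius defined for element(s): ",
         paste(unknown, collapse = ", "))
  n <- nrow(a)
  xyz <- as.matrix(a[c("x", "y", "z")])
  rad <- radii[a$element] + probe_radius
  pts <- .sphere_points(n_points)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- pts * rad[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- colSums((t(sp[acc, , drop = FALSE]) - xyz[j, ])^2)
      acc[acc] <- dj2 > rad[j]^2
    }
    sasa[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  out <- data.frame(chain = a$chain, resno = a$resno, resname = a$resname,
                    atom = a$atom, element = a$element, sasa = sasa,
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(sasa)
  out
}

#' Per-residue solvent accessibility with relative values
#'
#' Aggregates [shrake_rupley_sasa()] per residue and divides by the
#' Gly-X-Gly theoretical maximum for the residue type.
#'
#' @param model a [structure_model()].
#' @param reference named vector of per-residue-type maximum SASA
#'   (default [max_sasa_reference()]).
#' @param ... passed to [shrake_rupley_sasa()].
#' @return data.frame: chain, resno, resname, sasa, rel_sasa.
#' @export
residue_accessibility <- function(model, reference = max_sasa_reference(),
                                  ...) {
  per_atom <- shrake_rupley_sasa(model, ...)
  key <- paste(per_atom$chain, per_atom$resno, sep = "\r")
  agg <- stats::aggregate(per_atom$sasa, by = list(key = key), FUN = sum)
  first <- per_atom[!duplicated(key), c("chain", "resno", "resname")]
  first <- first[match(agg$key, unique(key)), ]
  out <- data.frame(first, sasa = agg$x, stringsAsFactors = FALSE)
  out$rel_sasa <- mapply(relative_accessibility, out$sasa, out$resname,
                         MoreArgs = list(reference = reference))
  out[order(out$chain, out$resno), ]
}

#' Relative accessibility of one residue
#'
#' @param sasa residue solvent-accessible area, Angstrom^2.
#' @param resname three-letter residue type.
#' @param reference named vector of per-type maxima.
#' @return fraction (may marginally exceed 1 for extended conformations).
#' @export
relative_accessibility <- function(sasa, resname,
                                   reference = max_sasa_reference()) {
  if (!resname %in% names(reference))
    stop("no reference maximum SASA for residue type: ", resname)
  stopifnot(sasa >= 0)
  unname(sasa / reference[resname])
}
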