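#' Combined chemical shift perturbation
#'
#' Weighted combination of amide 1H and 15N shift differences between free
#' and bound spectra:
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2}}
#' with the conventional nitrogen weight w = 0.15.
#'
#' @param delta_h,delta_n 1H and 15N shift differences, ppm (vectorized).
#' @param weight nitrogen scaling weight.
#' @return CSP in ppm.
#' @export
csp <- function(delta_h, delta_n, weight = 0.15) {
  stopifnot(weight > 0)
  sqrt(delta_h^2 + (weight * delta_n)^2)
}

#' Classify interface residues as active or passive
#'
#' Statistical interface mapping: over all scored residues (finite CSP,
#' prolines excluded) the mean and standard deviation (n-1) of the CSP are
#' computed. Residues are:
#' \itemize{
#'   \item \strong{active} if CSP >= mean + `sd_active`*SD and relative
#'     solvent accessibility exceeds `sasa_threshold`;
#'   \item \strong{passive} if CSP >= mean + `sd_passive`*SD (and not
#'     active), or if their resonance lost intensity on binding and they lie
#'     within `contiguity_radius` of an active residue.
#' }
#' Active residues with no other classified residue within
#' `contiguity_radius` (no continuous surface) are demoted to passive.
#' With zero CSP dispersion the thresholds are unreachable and nothing is
#' classified.
#'
#' @param records data.frame with columns `chain`, `resno`, and either
#'   `csp` or both `delta_h`/`delta_n`; optional `resname`, `rel_sasa`
#'   (required for the accessibility gate), `intensity_loss` (logical).
#' @param sasa_threshold relative-accessibility gate for active residues
#'   (default 0.15).
#' @param sd_active,sd_passive SD multipliers (defaults 1.5 and 1.0).
#' @param contiguity_radius Angstrom; used for the intensity-loss rule and
#'   the continuous-surface demotion (requires `model`).
#' @param model optional [structure_model()] for distance checks; when NULL
#'   the contiguity rules are skipped.
#' @param weight nitrogen weight for [csp()] when computed from deltas.
#' @return `records` with columns `csp` and `classification`
#'   (`"active"`/`"passive"`/`"none"`).
#' @export
classify_residues <- function(records, sasa_threshold = 0.15,
                              sd_active = 1.5, sd_passive = 1.0,
                              contiguity_radius = 8, model = NULL,
                              weight = 0.15) {
  r <- as.data.frame(records)
  if (is.null(r$csp)) {
    stopifnot(!is.null(r$delta_h), !is.null(r$delta_n))
    r$csp <- csp(r$delta_h, r$delta_n, weight)
  }
  if (is.null(r$intensity_loss)) r$intensity_loss <- FALSE
  scored <- is.finite(r$csp)
  if (!is.null(r$resname)) scored <- scored & r$resname != "PRO"
  if (sum(scored) < 5)
    stop("need at least 5 scored residues to classify (have ", sum(scored), ")")
  m <- mean(r$csp[scored])
  s <- stats::sd(r$csp[scored])
  rel <- if (is.null(r$rel_sasa)) rep(NA_real_, nrow(r)) else r$rel_sasa
  active <- scored & s > 0 & r$csp >= m + sd_active * s &
    !is.na(rel) & rel > sasa_threshold
  passive <- scored & s > 0 & r$csp >= m + sd_passive * s & !active

  res_dist <- function(i, j) {
    # minimum interatomic distance between residues i and j of `r`
    ai <- match_atoms(model, atom_sel(r$chain[i], r$resno[i]))
    aj <- match_atoms(model, atom_sel(r$chain[j], r$resno[j]))
    if (!length(ai) || !length(aj)) return(Inf)
    ca <- .coords(model, ai); cb <- .coords(model, aj)
    sqrt(min(outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)))
  }
  if (!is.null(model)) {
    # intensity-loss residues near an active residue become passive
    act_idx <- which(active)
    for (i in which(r$intensity_loss & !active & !passive)) {
      near <- any(vapply(act_idx, function(j) res_dist(i, j) <= contiguity_radius,
                         logical(1)))
      if (near) passive[i] <- TRUE
    }
    # continuous-surface rule: isolated actives demoted to passive
    classified <- which(active | passive)
    for (i in which(active)) {
      others <- setdiff(classified, i)
      near <- length(others) > 0 &&
        any(vapply(others, function(j) res_dist(i, j) <= contiguity_radius,
                   logical(1)))
      if (!near) { active[i] <- FALSE; passive[i] <- TRUE }
    }
  }
  r$classification <- ifelse(active, "active",
                             ifelse(passive, "passive", "none"))
  r$classification[!scored] <- "none"
  r
}

#' Build ambiguous interaction restraints from active/passive sets
#'
#' One AIR per active residue: any atom of an active residue of one
#' molecule to any atom of the active-plus-passive set of the partner,
#' enforced as an r^-6 effective distance with an upper bound (default
#' 2.0 A). The restraint count equals the total number of active residues.
#'
#' @param active_a,passive_a,active_b,passive_b data.frames with columns
#'   `chain`, `resno` (passive sets may be empty).
#' @param max_dist effective-distance upper bound, Angstrom.
#' @return list of `air_restraint` objects, each with fields
#'   `active_residue`, `target_residues`, `max_effective_distance`.
#' @export
build_airs <- function(active_a, passive_a, active_b, passive_b,
                       max_dist = 2.0) {
  stopifnot(max_dist > 0)
  nr <- function(x) if (is.null(x)) 0L else nrow(x)
  if (nr(active_a) == 0 || nr(active_b) == 0)
    stop("at least one active residue is required on each molecule")
  one_side <- function(active, t_active, t_passive) {
    targets <- rbind(t_active[c("chain", "resno")],
                     if (nr(t_passive)) t_passive[c("chain", "resno")])
    lapply(seq_len(nrow(active)), function(i) {
      structure(list(active_residue = active[i, c("chain", "resno")],
                     target_residues = targets,
                     max_effective_distance = max_dist),
                class = "air_restraint")
    })
  }
  c(one_side(active_a, active_b, passive_b),
    one_side(active_b, active_a, passive_a))
}

#' Violation of an ambiguous interaction restraint in a model
#'
#' Effective distance from all atoms of the active residue to all atoms of
#' the target residues, minus the upper bound (floored at zero).
#'
#' @param restraint an `air_restraint` from [build_airs()].
#' @param model a [structure_model()].
#' @return violation in Angstrom (0 when satisfied).
#' @export
air_violation <- function(restraint, model) {
  act <- restraint$active_residue
  ia <- match_atoms(model, atom_sel(act$chain, act$resno))
  tg <- restraint$target_residues
  ib <- unlist(lapply(seq_len(nrow(tg)), function(k)
    match_atoms(model, atom_sel(tg$chain[k], tg$resno[k]))))
  if (!length(ia) || !length(ib))
    stop("restraint residues not present in the model")
  max(0, effective_distance(model, ia, ib) - restraint$max_effective_distance)
}

#' Write AIRs in the docking `.tbl` assign dialect
#'
#' Each restraint becomes one `assign` statement with an ambiguous OR list
#' over the target residues, distance `d = max_effective_distance`, lower
#' offset `d` (lower bound 0) and upper offset 0.
#'
#' @param airs list of `air_restraint` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airs_tbl <- function(airs, path) {
  lines <- unlist(lapply(airs, function(a) {
    tg <- a$target_residues
    ors <- paste(sprintf("(segid %s and resid %d)", tg$chain, tg$resno),
                 collapse = " or ")
    d <- a$max_effective_distance
    sprintf("assign (segid %s and resid %d) (%s) %.1f %.1f 0.0",
            a$active_residue$chain, a$active_residue$resno, ors, d, d)
  }))
  writeLines(c("! ambiguous interaction restraints (effective r^-6 distance)",
               lines), path)
  invisible(path)
}
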