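# Distance restraints live in a plain data.frame (class "restraint_set"):
# one row per atom-pair restraint with explicit provenance columns.

.restraint_cols <- c("chain_a", "resno_a", "atom_a",
                     "chain_b", "resno_b", "atom_b",
                     "lower", "upper", "derived_distance", "padding",
                     "source", "tag_site", "status")

#' Construct a restraint set from a data.frame
#'
#' Normalizes a data.frame of atom-pair distance restraints to the
#' `restraint_set` layout. Required columns: `chain_a`, `resno_a`,
#' `atom_a`, `chain_b`, `resno_b`, `atom_b`, `lower`, `upper`; provenance
#' columns (`derived_distance`, `padding`, `source`, `tag_site`, `status`)
#' are filled with NA when absent.
#'
#' @param df data.frame of restraints.
#' @return `restraint_set` data.frame.
#' @export
restraint_set <- function(df) {
  need <- c("chain_a", "resno_a", "atom_a", "chain_b", "resno_b", "atom_b",
            "lower", "upper")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("restraints lack column(s): ",
                         paste(miss, collapse = ", "))
  .as_restraint_set(as.data.frame(df))
}

.as_restraint_set <- function(df) {
  for (nm in setdiff(.restraint_cols, names(df)))
    df[[nm]] <- if (nm %in% c("lower", "upper", "derived_distance", "padding"))
      NA_real_ else NA_character_
  df <- df[.restraint_cols]
  stopifnot(all(df$lower <= df$upper))
  class(df) <- c("restraint_set", "data.frame")
  df
}

#' Build distance restraints from quantified PREs
#'
#' Converts each quantified PRE into an upper-bound-only distance restraint
#' between proxy atoms: the probe atom (amide nitrogen for backbone PREs,
#' methyl carbon for methyl PREs) and the Cbeta of the spin-label site.
#' Only intensity ratios below `ratio_cutoff` (default 0.8) are converted;
#' the rest are marked `filtered_ratio`. The electron-nucleus distance from
#' [distance_from_gamma2()] plus an empirical `padding` (default 6 A,
#' covering tag length and quantification error) becomes the upper bound;
#' the lower bound is 0 because incomplete saturation makes the apparent
#' PRE distance an overestimate of the true distance in the complex.
#' Bleached probes are excluded (count in attribute `n_bleached`).
#'
#' @param measurements data.frame with columns `tag_site`, `chain`,
#'   `resnum`, `probe` (atom name), `ratio`, `gamma2`, `status` (as
#'   produced by [extract_pre()]).
#' @param params an [sbmf_parameters()].
#' @param tag_map data.frame mapping `tag_site` labels to the tagged
#'   residue: columns `tag_site`, `chain`, `resno` (proxy atom is CB).
#' @param ratio_cutoff intensity-ratio gate.
#' @param padding empirical error bound added to the distance, Angstrom.
#' @param kappa prefactor, Angstrom^6 s^-2.
#' @return `restraint_set` data.frame (rows with status `retained` or
#'   `filtered_ratio`); attributes `n_bleached`, `n_no_pre`.
#' @export
build_pre_restraints <- function(measurements, params, tag_map,
                                 ratio_cutoff = 0.8, padding = 6,
                                 kappa = kappa_h()) {
  m <- as.data.frame(measurements)
  need <- c("tag_site", "chain", "resnum", "probe", "ratio", "gamma2", "status")
  stopifnot(all(need %in% names(m)))
  miss <- setdiff(unique(m$tag_site), tag_map$tag_site)
  if (length(miss))
    stop("tag site(s) not resolvable in tag_map: ", paste(miss, collapse = ", "))
  n_bleached <- sum(m$status == "bleached")
  n_no_pre <- sum(m$status == "no_pre")
  m <- m[m$status == "quantified", , drop = FALSE]
  ti <- match(m$tag_site, tag_map$tag_site)
  keep <- m$ratio < ratio_cutoff & m$gamma2 > 0
  r <- rep(NA_real_, nrow(m))
  r[keep] <- distance_from_gamma2(m$gamma2[keep], params, kappa)
  out <- data.frame(chain_a = m$chain, resno_a = m$resnum, atom_a = m$probe,
                    chain_b = tag_map$chain[ti], resno_b = tag_map$resno[ti],
                    atom_b = "CB",
                    lower = 0, upper = r + padding,
                    derived_distance = r, padding = padding,
                    source = "pre", tag_site = m$tag_site,
                    status = ifelse(keep, "retained", "filtered_ratio"),
                    stringsAsFactors = FALSE)
  out$upper[!keep] <- Inf
  out <- .as_restraint_set(out)
  attr(out, "n_bleached") <- n_bleached
  attr(out, "n_no_pre") <- n_no_pre
  out
}

#' Eliminate restraints satisfiable in an encounter-complex ensemble
#'
#' A PRE observed on a transiently interacting system can stem from the
#' encounter complex rather than the final complex. To avoid such
#' contamination, any restraint whose atom-pair distance is within its
#' upper bound in \emph{any} member of the supplied encounter ensemble is
#' eliminated (`status = "eliminated_encounter"`); the remainder are
#' retained. Rows not in `retained` status on entry pass through unchanged.
#'
#' @param restraints a `restraint_set`.
#' @param encounter_ensemble list of [structure_model()]s.
#' @return the `restraint_set` with updated statuses; attributes
#'   `n_eliminated`, `n_retained`.
#' @export
filter_encounter_satisfiable <- function(restraints, encounter_ensemble) {
  stopifnot(length(encounter_ensemble) >= 1)
  rs <- restraints
  for (i in seq_len(nrow(rs))) {
    if (rs$status[i] != "retained") next
    d <- vapply(encounter_ensemble, function(mod) {
      interatomic_distance(mod,
                           atom_sel(rs$chain_a[i], rs$resno_a[i], rs$atom_a[i]),
                           atom_sel(rs$chain_b[i], rs$resno_b[i], rs$atom_b[i]))
    }, numeric(1))
    if (any(d <= rs$upper[i])) rs$status[i] <- "eliminated_encounter"
  }
  attr(rs, "n_eliminated") <- sum(rs$status == "eliminated_encounter")
  attr(rs, "n_retained") <- sum(rs$status == "retained")
  rs
}

#' Connectivity restraints: linker, ppant unfurling and active-site reach
#'
#' Emits the three geometric restraints used alongside the PRE set:
#' \itemize{
#'   \item an inter-domain linker restraint (Calpha of the first domain's
#'     C-terminal residue to Calpha of the second domain's N-terminal
#'     residue), upper bound 59.5 A;
#'   \item a phosphopantetheine-arm unfurling restraint (thiol S to
#'     phosphate P), bounds 14.0-16.5 A;
#'   \item an active-site reach restraint (thiol S to the catalytic
#'     histidine Cepsilon1), upper bound 8.0 A.
#' }
#'
#' @param linker_a,linker_b lists `(chain, resno, atom)` for the two linker
#'   Calpha atoms.
#' @param ppant_s,ppant_p,his_ce1 atom triples for the ppant thiol sulfur,
#'   ppant phosphate phosphorus and catalytic histidine CE1.
#' @param linker_max,ppant_bounds,active_site_max the bounds (Angstrom).
#' @param model optional [structure_model()]; when given, every named atom
#'   must resolve in it.
#' @return `restraint_set` with three rows (sources `linker`,
#'   `ppant_unfurl`, `ppant_active_site`).
#' @export
add_connectivity_restraints <- function(linker_a, linker_b,
                                        ppant_s, ppant_p, his_ce1,
                                        linker_max = 59.5,
                                        ppant_bounds = c(14.0, 16.5),
                                        active_site_max = 8.0,
                                        model = NULL) {
  trip <- function(x) {
    stopifnot(length(x) >= 3)
    list(chain = x[[1]], resno = as.integer(x[[2]]), atom = x[[3]])
  }
  a <- lapply(list(linker_a, linker_b, ppant_s, ppant_p, his_ce1), trip)
  if (!is.null(model)) {
    for (s in a) {
      if (length(match_atoms(model, atom_sel(s$chain, s$resno, s$atom))) != 1)
        stop("named atom not found in model: ",
             paste(s$chain, s$resno, s$atom))
    }
  }
  out <- data.frame(
    chain_a = c(a[[1]]$chain, a[[3]]$chain, a[[3]]$chain),
    resno_a = c(a[[1]]$resno, a[[3]]$resno, a[[3]]$resno),
    atom_a = c(a[[1]]$atom, a[[3]]$atom, a[[3]]$atom),
    chain_b = c(a[[2]]$chain, a[[4]]$chain, a[[5]]$chain),
    resno_b = c(a[[2]]$resno, a[[4]]$resno, a[[5]]$resno),
    atom_b = c(a[[2]]$atom, a[[4]]$atom, a[[5]]$atom),
    lower = c(0, ppant_bounds[1], 0),
    upper = c(linker_max, ppant_bounds[2], active_site_max),
    derived_distance = NA_real_, padding = NA_real_,
    source = c("linker", "ppant_unfurl", "ppant_active_site"),
    tag_site = NA_character_, status = "retained",
    stringsAsFactors = FALSE)
  .as_restraint_set(out)
}

#' Check restraint violations against a structure model
#'
#' @param restraints a `restraint_set`.
#' @param model a [structure_model()].
#' @return the restraints with `model_distance` and `violation` columns
#'   (`violation = max(0, d - upper, lower - d)`); unresolvable atom pairs
#'   get NA with a warning. Summary in attributes `n_violated`,
#'   `max_violation`.
#' @export
check_violations <- function(restraints, model) {
  rs <- as.data.frame(restraints)
  d <- rep(NA_real_, nrow(rs))
  for (i in seq_len(nrow(rs))) {
    ia <- match_atoms(model, atom_sel(rs$chain_a[i], rs$resno_a[i], rs$atom_a[i]))
    ib <- match_atoms(model, atom_sel(rs$chain_b[i], rs$resno_b[i], rs$atom_b[i]))
    if (length(ia) != 1 || length(ib) != 1) {
      warning("skipping restraint ", i, ": atoms not resolvable in model")
      next
    }
    d[i] <- sqrt(sum((.coords(model, ia) - .coords(model, ib))^2))
  }
  rs$model_distance <- d
  rs$violation <- pmax(0, d - rs$upper, rs$lower - d)
  attr(rs, "n_violated") <- sum(rs$violation > 0, na.rm = TRUE)
  attr(rs, "max_violation") <- if (all(is.na(rs$violation))) NA_real_ else
    max(rs$violation, na.rm = TRUE)
  rs
}

#' Write a restraint set
#'
#' The `cns_tbl` dialect writes one assign statement per restraint,
#' `assign (sel_a) (sel_b) d dminus dplus`, using the upper-bound-only
#' encoding d = upper, dminus = upper - lower, dplus = 0 (bit-exact and
#' reversible; documented in the file header). The `json` dialect keeps the
#' full provenance columns.
#'
#' @param restraints a `restraint_set`.
#' @param path output file.
#' @param dialect `"cns_tbl"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path,
                             dialect = c("cns_tbl", "json")) {
  dialect <- match.arg(dialect)
  rs <- as.data.frame(restraints)
  if (dialect == "json") {
    jsonlite::write_json(rs, path, digits = NA, na = "null")
    return(invisible(path))
  }
  keep <- is.finite(rs$upper)
  rs <- rs[keep, , drop = FALSE]
  lines <- sprintf(paste0("assign (segid %s and resid %d and name %s) ",
                          "(segid %s and resid %d and name %s) %.10g %.10g 0"),
                   rs$chain_a, rs$resno_a, rs$atom_a,
                   rs$chain_b, rs$resno_b, rs$atom_b,
                   rs$upper, rs$upper - rs$lower)
  writeLines(c("! distance restraints; encoding: d = upper bound,",
               "! dminus = upper - lower (so lower = d - dminus), dplus = 0",
               lines), path)
  invisible(path)
}

#' Read a `cns_tbl` restraint file written by [write_restraints()]
#'
#' @param path file in the assign-statement dialect.
#' @return `restraint_set` with bounds recovered exactly.
#' @export
read_restraints <- function(path) {
  lines <- grep("^assign", readLines(path), value = TRUE)
  pat <- paste0("^assign \\(segid (\\S+) and resid (-?\\d+) and name (\\S+)\\) ",
                "\\(segid (\\S+) and resid (-?\\d+) and name (\\S+)\\) ",
                "(\\S+) (\\S+) (\\S+)$")
  m <- regmatches(lines, regexec(pat, lines))
  if (any(lengths(m) != 10)) stop("unparseable assign statement in ", path)
  f <- function(i) vapply(m, `[`, character(1), i + 1)
  upper <- as.numeric(f(7))
  .as_restraint_set(data.frame(
    chain_a = f(1), resno_a = as.integer(f(2)), atom_a = f(3),
    chain_b = f(4), resno_b = as.integer(f(5)), atom_b = f(6),
    lower = upper - as.numeric(f(8)), upper = upper,
    source = "file", status = "retained", stringsAsFactors = FALSE))
}
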