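#' Effective non-uniform-sampling sparsity
#'
#' When the indirect spectral widths are oversampled relative to the
#' chemical-shift dispersion, the Nyquist grid grows by
#' `oversampling^n_dims` hypercomplex points, so the nominal NUS sparsity
#' understates the effectively sampled fraction of the equivalent
#' non-oversampled grid: effective = nominal x oversampling^n_dims, and the
#' per-dimension sampled fraction is effective^(1/n_dims).
#'
#' @param nominal nominal sparsity, fraction in (0, 1].
#' @param n_dims number of indirect dimensions (>= 1).
#' @param oversampling per-dimension oversampling factor (integer >= 1).
#' @return list of class `nus_plan`: raw fractions plus reported
#'   percentages (`effective_pct` to 2 significant figures,
#'   `per_dimension_pct` to the nearest percent).
#' @export
#' @examples
#' effective_nus_sparsity(0.0055, 3, 2)  # 4.4% effective, 35% per dimension
effective_nus_sparsity <- function(nominal, n_dims = 3, oversampling = 2) {
  stopifnot(nominal > 0, nominal <= 1, n_dims >= 1, oversampling >= 1)
  effective <- nominal * oversampling^n_dims
  if (effective > 1)
    stop("effective sparsity exceeds 1 (", signif(effective, 3),
         "); check the oversampling factor")
  per_dim <- effective^(1 / n_dims)
  structure(list(nominal_sparsity = nominal, n_indirect_dims = n_dims,
                 oversampling_factor = oversampling,
                 effective_sparsity = effective,
                 per_dimension_fraction = per_dim,
                 effective_pct = signif(100 * effective, 2),
                 per_dimension_pct = round(100 * per_dim)),
            class = "nus_plan")
}

#' @export
print.nus_plan <- function(x, ...) {
  cat(sprintf("NUS plan: nominal %.3g%% x %d^%d -> effective %g%% (%d%% per indirect dimension)\n",
              100 * x$nominal_sparsity, x$oversampling_factor,
              x$n_indirect_dims, x$effective_pct, x$per_dimension_pct))
  invisible(x)
}

#' Parse a molecular formula string
#'
#' @param formula e.g. `"C13H12N2O2"`; element symbols with optional counts.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula)
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  tapply(ct, el, sum)[unique(el)]
}

#' Nominal and monoisotopic mass of a molecular formula
#'
#' Nominal mass sums the integer masses of the most abundant isotopes;
#' monoisotopic mass uses their exact masses. `protonated = TRUE` adds one
#' hydrogen (the M+H / M+ ion convention used when checking product masses
#' against an LC-MS channel).
#'
#' @param formula formula string or named count vector.
#' @param protonated add one proton.
#' @return list with `nominal` (integer Da) and `monoisotopic` (Da).
#' @export
#' @examples
#' formula_mass("C13H12N2O2", protonated = TRUE)$nominal  # 229
formula_mass <- function(formula, protonated = FALSE) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  counts <- counts[counts != 0]
  unknown <- setdiff(names(counts), names(.isotope_table))
  if (length(unknown))
    stop("element(s) not in the isotope table: ",
         paste(unknown, collapse = ", "))
  if (any(counts < 0)) stop("negative element count")
  if (protonated) {
    counts["H"] <- if ("H" %in% names(counts)) counts["H"] + 1L else 1L
  }
  tab <- .isotope_table[names(counts)]
  list(nominal = sum(vapply(tab, `[[`, numeric(1), "nominal") * counts),
       monoisotopic = sum(vapply(tab, `[[`, numeric(1), "mono") * counts))
}

#' Formula of a condensation product
#'
#' Element-wise sum of two reactant formulas minus `waters_lost` waters
#' (one per amide condensation or ring-closure step).
#'
#' @param a,b formula strings or named count vectors.
#' @param waters_lost number of H2O eliminated.
#' @return named integer count vector.
#' @export
#' @examples
#' condensation_product_formula("C7H7NO2", "C6H9NO2", waters_lost = 2)
condensation_product_formula <- function(a, b, waters_lost = 1) {
  ca <- if (is.character(a)) parse_formula(a) else a
  cb <- if (is.character(b)) parse_formula(b) else b
  els <- union(names(ca), names(cb))
  out <- stats::setNames(rep(0L, length(els)), els)
  out[names(ca)] <- out[names(ca)] + ca
  out[names(cb)] <- out[names(cb)] + cb
  if (waters_lost > 0) {
    for (el in c("H", "O")) if (!el %in% names(out)) out[el] <- 0L
    out["H"] <- out["H"] - 2L * waters_lost
    out["O"] <- out["O"] - 1L * waters_lost
  }
  if (any(out < 0))
    stop("condensation would yield negative element counts (check waters_lost)")
  out[out > 0]
}
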