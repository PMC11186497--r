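#' The PRE distance prefactor kappa_H
#'
#' \deqn{\kappa_H = (\gamma_H g_e \beta)^2 (\mu_0/4\pi)^2 S(S+1)/15}
#' evaluated in SI and converted to Angstrom^6 s^-2 (factor 1e60). With the
#' default constant bundle this is 1.2311e16 A^6 s^-2, the standard value
#' used to convert nitroxide PREs to electron-nucleus distances.
#'
#' @param constants a [physical_constants()] bundle.
#' @param si return the SI value (m^6 s^-2) instead of Angstrom^6 s^-2.
#' @return numeric scalar.
#' @export
#' @examples
#' signif(kappa_h(), 5)
kappa_h <- function(constants = physical_constants(), si = FALSE) {
  s <- constants$spin_s
  k <- (constants$gamma_h * constants$g_e * constants$beta)^2 *
    constants$mu0_over_4pi^2 * s * (s + 1) / 15
  if (si) k else k * 1e60
}

#' Solomon-Bloembergen model-free parameters
#'
#' Correlation times and order parameter of the electron-nucleus spectral
#' density. The effective correlation time combines global tumbling and
#' longitudinal electron relaxation, \eqn{1/\tau_1 = 1/\tau_m + 1/T_{1e}};
#' internal motion of the electron-nucleus vector (correlation time
#' \eqn{\tau_i}, order parameter \eqn{S^2}) enters through
#' \eqn{1/\tau_t = 1/\tau_1 + 1/\tau_i}. Either supply `tau_1` directly or
#' `tau_m` (+ optionally `t1e`).
#'
#' @param tau_1 effective electron-nucleus correlation time, seconds
#'   (default 20 ns, the value used for restraint conversion here).
#' @param tau_m rotational correlation time, seconds (used if `tau_1` NULL).
#' @param t1e electronic longitudinal relaxation time, seconds (Inf: no
#'   electronic contribution).
#' @param tau_i internal-motion correlation time, seconds (Inf: rigid tag).
#' @param s2 squared order parameter in [0, 1] (default 1).
#' @param field_mhz 1H Larmor frequency, MHz.
#' @return object of class `sbmf_parameters` with derived `tau_t` and
#'   `omega_h` (rad s^-1).
#' @export
sbmf_parameters <- function(tau_1 = 20e-9, tau_m = NULL, t1e = Inf,
                            tau_i = Inf, s2 = 1.0, field_mhz = 850) {
  if (is.null(tau_1)) {
    stopifnot(!is.null(tau_m), tau_m > 0, t1e > 0)
    tau_1 <- 1 / (1 / tau_m + 1 / t1e)
  }
  stopifnot(tau_1 > 0, tau_i > 0, s2 >= 0, s2 <= 1, field_mhz > 0)
  tau_t <- 1 / (1 / tau_1 + 1 / tau_i)
  structure(list(tau_m = tau_m, t1e = t1e, tau_1 = tau_1, tau_i = tau_i,
                 tau_t = tau_t, s2 = s2, field_mhz = field_mhz,
                 omega_h = 2 * pi * field_mhz * 1e6),
            class = "sbmf_parameters")
}

#' Model-free spectral density
#'
#' \deqn{J(\omega) = \frac{S^2\tau_1}{1+\omega^2\tau_1^2} +
#'   \frac{(1-S^2)\tau_t}{1+\omega^2\tau_t^2}}
#'
#' @param omega angular frequency, rad s^-1 (vectorized, >= 0).
#' @param params an [sbmf_parameters()].
#' @return spectral density in seconds.
#' @export
j_sbmf <- function(omega, params) {
  stopifnot(all(omega >= 0))
  params$s2 * params$tau_1 / (1 + omega^2 * params$tau_1^2) +
    (1 - params$s2) * params$tau_t / (1 + omega^2 * params$tau_t^2)
}

# the (4 + 3/(1+w^2 t1^2)) factor of the simplified expression
.sbmf_simple_factor <- function(params) {
  4 + 3 / (1 + params$omega_h^2 * params$tau_1^2)
}

#' PRE rate from an electron-nucleus distance
#'
#' Simplified Solomon-Bloembergen expression (internal-motion term
#' neglected, appropriate for fast internal motion and S^2 > 0.5):
#' \deqn{\Gamma_2^H = \frac{\kappa_H}{r^6} S^2 \tau_1
#'   \left(4 + \frac{3}{1+\omega_H^2\tau_1^2}\right)}
#' Set `full = TRUE` to use the complete spectral density
#' \eqn{\Gamma_2 = \kappa/r^6 (4 J(0) + 3 J(\omega_H))}.
#'
#' @param r_en electron-nucleus distance, Angstrom (vectorized, > 0).
#' @param params an [sbmf_parameters()].
#' @param kappa prefactor in Angstrom^6 s^-2 (default [kappa_h()]).
#' @param full use the full two-term spectral density.
#' @return Gamma2 in s^-1.
#' @export
gamma2_from_distance <- function(r_en, params, kappa = kappa_h(),
                                 full = FALSE) {
  stopifnot(all(r_en > 0))
  if (full) {
    kappa / r_en^6 * (4 * j_sbmf(0, params) + 3 * j_sbmf(params$omega_h, params))
  } else {
    kappa / r_en^6 * params$s2 * params$tau_1 * .sbmf_simple_factor(params)
  }
}

#' Electron-nucleus distance from a PRE rate
#'
#' Inverse of [gamma2_from_distance()] (simplified form):
#' \deqn{r = \left[\kappa_H S^2 \tau_1 (4 + 3/(1+\omega_H^2\tau_1^2)) /
#'   \Gamma_2\right]^{1/6}}
#'
#' @param gamma2 PRE rate, s^-1 (vectorized, > 0).
#' @param params an [sbmf_parameters()].
#' @param kappa prefactor, Angstrom^6 s^-2.
#' @return distance in Angstrom.
#' @export
distance_from_gamma2 <- function(gamma2, params, kappa = kappa_h()) {
  if (any(gamma2 <= 0))
    stop("distance undefined for non-positive Gamma2; handle no_pre/bleached upstream")
  (kappa * params$s2 * params$tau_1 * .sbmf_simple_factor(params) /
     gamma2)^(1 / 6)
}

#' Spin-label tag site with a conformer ensemble
#'
#' @param site_id mutant label (e.g. "A36C").
#' @param attachment [atom_sel()] of the attachment atom (Cbeta of the
#'   engineered cysteine).
#' @param conformers numeric matrix (n x 3) of paramagnetic-centre
#'   positions, Angstrom.
#' @return object of class `tag_site`.
#' @export
tag_site <- function(site_id, attachment, conformers) {
  conformers <- as.matrix(conformers)
  stopifnot(ncol(conformers) == 3, nrow(conformers) >= 1,
            all(is.finite(conformers)))
  structure(list(site_id = site_id, attachment = attachment,
                 conformers = conformers), class = "tag_site")
}

#' Default nitroxide conformer cloud for a tag site
#'
#' Places the paramagnetic-centre ensemble as points drawn uniformly on a
#' sphere (default radius 7 A) centred 7 A outward from the attachment
#' Cbeta along the Calpha-to-Cbeta direction — a stand-in for a full
#' molecular-dynamics tag-conformer optimization that preserves the
#' r^-6-averaged geometry a flexible PROXYL tag samples.
#'
#' @param model a [structure_model()].
#' @param chain,resno identify the tagged residue (needs CA and CB atoms).
#' @param site_id label for the site.
#' @param n_conformers ensemble size (default 10).
#' @param shell_radius radius of the conformer sphere, Angstrom.
#' @param offset displacement of the sphere centre from Cbeta, Angstrom.
#' @param seed integer seed for the sphere sampling.
#' @return a [tag_site()].
#' @export
default_tag_conformers <- function(model, chain, resno, site_id = NULL,
                                   n_conformers = 10, shell_radius = 7,
                                   offset = 7, seed = 1) {
  ca <- match_atoms(model, atom_sel(chain, resno, "CA"))
  cb <- match_atoms(model, atom_sel(chain, resno, "CB"))
  if (length(ca) != 1 || length(cb) != 1)
    stop("tag residue ", chain, ":", resno, " must have unique CA and CB atoms")
  pca <- as.numeric(.coords(model, ca))
  pcb <- as.numeric(.coords(model, cb))
  dir <- (pcb - pca) / sqrt(sum((pcb - pca)^2))
  centre <- pcb + offset * dir
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n_conformers), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * shell_radius
  conf <- sweep(v, 2, centre, "+")
  if (is.null(site_id)) site_id <- paste0(chain, resno, "C")
  tag_site(site_id, atom_sel(chain, resno, "CB"), conf)
}

# per-probe <r^-6> over the tag conformer ensemble
.ensemble_r6inv <- function(model, tag, probe_idx) {
  conf <- tag$conformers
  vapply(probe_idx, function(i) {
    p <- as.numeric(.coords(model, i))
    d2 <- rowSums(sweep(conf, 2, p, "-")^2)
    mean(d2^(-3))
  }, numeric(1))
}

#' Back-calculate a PRE profile from a structure and tag ensemble
#'
#' For each probe atom, averages \eqn{r^{-6}} over the tag conformer
#' positions (PRE-appropriate ensemble averaging) and converts to a PRE via
#' the simplified Solomon-Bloembergen expression.
#'
#' @param model a [structure_model()].
#' @param tag a [tag_site()].
#' @param probes data.frame with columns `chain`, `resno`, `atom`
#'   identifying the probe atoms (e.g. amide N or methyl C).
#' @param params an [sbmf_parameters()].
#' @param kappa prefactor, Angstrom^6 s^-2.
#' @return `probes` with added `r_eff` (effective distance
#'   \eqn{\langle r^{-6}\rangle^{-1/6}}, Angstrom) and `gamma2` (s^-1);
#'   probes not resolvable in the model are dropped and listed in the
#'   attribute `unresolved`.
#' @export
back_calculate_pre_profile <- function(model, tag, probes, params,
                                       kappa = kappa_h()) {
  idx <- vapply(seq_len(nrow(probes)), function(k) {
    i <- match_atoms(model, atom_sel(probes$chain[k], probes$resno[k],
                                     probes$atom[k]))
    if (length(i) == 1L) i else NA_integer_
  }, integer(1))
  unresolved <- probes[is.na(idx), , drop = FALSE]
  keep <- !is.na(idx)
  probes <- probes[keep, , drop = FALSE]
  r6inv <- .ensemble_r6inv(model, tag, idx[keep])
  probes$r_eff <- r6inv^(-1 / 6)
  probes$gamma2 <- kappa * r6inv * params$s2 * params$tau_1 *
    .sbmf_simple_factor(params)
  attr(probes, "unresolved") <- unresolved
  probes
}

#' Fit the electron-nucleus correlation time to measured PREs
#'
#' Weighted least squares of measured against back-calculated PREs as a
#' function of \eqn{\tau_1}, with the probe geometry (ensemble-averaged
#' \eqn{r^{-6}}) fixed by the structure and tag ensemble. One-dimensional
#' bounded optimization (golden section/Brent); uncertainty by
#' nonparametric bootstrap over probes.
#'
#' @param measurements data.frame with `chain`, `resno`, `atom`, `gamma2`
#'   and optionally `gamma2_err` (weights 1/err^2) and `status` (only
#'   `"quantified"` rows are used).
#' @param model a [structure_model()].
#' @param tag a [tag_site()].
#' @param params an [sbmf_parameters()]; its `s2` and field are kept fixed.
#' @param bounds search interval for tau_1, seconds (default 5-40 ns).
#' @param kappa prefactor, Angstrom^6 s^-2.
#' @param n_boot bootstrap resamples (0 disables).
#' @param seed integer seed for the bootstrap.
#' @return list: `tau_1` (s), `tau_1_se` (s, NA if `n_boot = 0`), `rss`,
#'   `n_probes`.
#' @export
fit_correlation_time <- function(measurements, model, tag, params,
                                 bounds = c(5e-9, 40e-9), kappa = kappa_h(),
                                 n_boot = 500, seed = 1) {
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1])
  m <- measurements
  if (!is.null(m$status)) m <- m[m$status == "quantified", , drop = FALSE]
  m <- m[is.finite(m$gamma2) & m$gamma2 > 0, , drop = FALSE]
  if (nrow(m) < 5) stop("need at least 5 quantified PREs to fit tau_1")
  idx <- vapply(seq_len(nrow(m)), function(k) {
    i <- match_atoms(model, atom_sel(m$chain[k], m$resno[k], m$atom[k]))
    if (length(i) == 1L) i else NA_integer_
  }, integer(1))
  if (anyNA(idx)) stop("unresolvable probe atoms in the fit input")
  r6inv <- .ensemble_r6inv(model, tag, idx)
  w <- if (!is.null(m$gamma2_err) && all(is.finite(m$gamma2_err)) &&
           all(m$gamma2_err > 0)) 1 / m$gamma2_err^2 else rep(1, nrow(m))
  omega <- params$omega_h
  # optimize in nanoseconds so the optimizer tolerance is well-scaled
  objective_ns <- function(tau_ns, sub = seq_len(nrow(m))) {
    tau1 <- tau_ns * 1e-9
    gcalc <- kappa * r6inv[sub] * params$s2 * tau1 *
      (4 + 3 / (1 + omega^2 * tau1^2))
    sum(w[sub] * (m$gamma2[sub] - gcalc)^2)
  }
  bounds_ns <- bounds * 1e9
  opt <- stats::optimize(objective_ns, interval = bounds_ns, tol = 1e-6)
  tau_se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      sub <- sample.int(nrow(m), replace = TRUE)
      stats::optimize(function(t) objective_ns(t, sub),
                      interval = bounds_ns, tol = 1e-6)$minimum
    }, numeric(1))
    tau_se <- stats::sd(boots) * 1e-9
  }
  list(tau_1 = opt$minimum * 1e-9, tau_1_se = tau_se, rss = opt$objective,
       n_probes = nrow(m))
}
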