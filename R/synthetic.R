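# Synthetic ground-truth generator: toy two-domain complexes with known
# geometry, tag conformer clouds, forward-simulated PRE peak tables,
# planted-interface CSP tables and exponential decay series. Everything a
# pipeline stage consumes can be generated here with a known answer.

.helix_atoms <- function(n_res, chain) {
  i <- seq_len(n_res)
  a <- i * 100 * pi / 180            # 100 degrees per residue
  er <- cbind(cos(a), sin(a), 0)
  et <- cbind(-sin(a), cos(a), 0)
  ez <- matrix(rep(c(0, 0, 1), each = n_res), ncol = 3)
  ca <- cbind(2.3 * cos(a), 2.3 * sin(a), 1.5 * i)
  nn <- ca + 1.46 * (-0.57 * et - 0.77 * ez)
  cb <- ca + 1.53 * (0.92 * er + 0.39 * ez)
  at <- function(name, elem, xyz) {
    data.frame(chain = chain, resno = i, resname = "ALA", atom = name,
               element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }
  out <- rbind(at("N", "N", nn), at("CA", "C", ca), at("CB", "C", cb))
  out[order(out$resno, match(out$atom, c("N", "CA", "CB"))), ]
}

#' Generate a toy two-domain complex with known ground truth
#'
#' Builds two ideal poly-alanine helices (N, CA, CB per residue), places
#' partner B at `pose_offset`, attaches nitroxide tag conformer clouds to
#' chosen residues of chain B, and records the true electron-nucleus
#' effective distances and PREs (simplified Solomon-Bloembergen model at
#' `tau_1`) for every amide nitrogen probe of chain A.
#'
#' @param n_residues_a,n_residues_b residues per domain (>= 10).
#' @param pose_offset 3-vector displacement of domain B, Angstrom.
#' @param seed integer seed (tag conformer sampling).
#' @param tag_resnos chain-B residues carrying a spin label.
#' @param tau_1 true electron-nucleus correlation time, seconds.
#' @param s2 true squared order parameter.
#' @param field_mhz 1H frequency, MHz.
#' @param clash_threshold minimum allowed interdomain atom distance, A.
#' @return list of class `synthetic_truth`: `complex_model`, `free_models`,
#'   `tag_sites`, `params`, `true_tau1`, `probes`, `true_distances`,
#'   `true_gamma2` (per tag site), `planted_interface`, `seed`.
#' @export
make_toy_complex <- function(n_residues_a = 20, n_residues_b = 20,
                             pose_offset = c(25, 0, 0), seed = 1,
                             tag_resnos = NULL, tau_1 = 20e-9, s2 = 1.0,
                             field_mhz = 850, clash_threshold = 2.0) {
  stopifnot(n_residues_a >= 10, n_residues_b >= 10, length(pose_offset) == 3)
  aa <- .helix_atoms(n_residues_a, "A")
  bb <- .helix_atoms(n_residues_b, "B")
  bb$x <- bb$x + pose_offset[1]
  bb$y <- bb$y + pose_offset[2]
  bb$z <- bb$z + pose_offset[3]
  ca <- as.matrix(aa[c("x", "y", "z")]); cb <- as.matrix(bb[c("x", "y", "z")])
  mind <- sqrt(min(outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)))
  if (mind < clash_threshold)
    stop("domains clash at this pose offset (min distance ",
         signif(mind, 3), " A)")
  complex_model <- structure_model(rbind(aa, bb), "toy_complex")
  free_a <- structure_model(aa, "free_A")
  free_b <- structure_model(.helix_atoms(n_residues_b, "B"), "free_B")
  if (is.null(tag_resnos))
    tag_resnos <- unique(pmax(1, round(n_residues_b * c(0.25, 0.5, 0.8))))
  # compact conformer cloud: centroid offset + shell radius stay within the
  # 6 A restraint padding, so proxy-atom (probe-to-CB) restraints built from
  # the simulated PREs are satisfied by the generating pose by construction
  tags <- lapply(seq_along(tag_resnos), function(k) {
    default_tag_conformers(complex_model, "B", tag_resnos[k],
                           shell_radius = 2.5, offset = 3.5,
                           seed = seed + k)
  })
  names(tags) <- vapply(tags, `[[`, character(1), "site_id")
  params <- sbmf_parameters(tau_1 = tau_1, s2 = s2, field_mhz = field_mhz)
  probes <- data.frame(chain = "A", resno = seq_len(n_residues_a),
                       atom = "N", stringsAsFactors = FALSE)
  per_tag <- lapply(tags, function(tg)
    back_calculate_pre_profile(complex_model, tg, probes, params))
  d2min <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  res_min <- tapply(sqrt(pmax(apply(d2min, 1, min), 0)), aa$resno, min)
  planted <- as.integer(names(res_min)[res_min <= 5])
  structure(list(complex_model = complex_model,
                 free_models = list(A = free_a, B = free_b),
                 tag_sites = tags, params = params, true_tau1 = tau_1,
                 probes = probes,
                 true_distances = lapply(per_tag, `[[`, "r_eff"),
                 true_gamma2 = lapply(per_tag, `[[`, "gamma2"),
                 planted_interface = list(A = planted),
                 seed = seed),
            class = "synthetic_truth")
}

#' Forward-simulate a PRE peak table from a synthetic truth
#'
#' For every (tag site, probe) pair the true PRE is pushed through the
#' peak-height forward model to an intensity ratio; diamagnetic heights are
#' drawn around a nominal value, paramagnetic heights follow the ratio, and
#' multiplicative Gaussian noise of fractional width `noise_sigma` is
#' applied to both. The output table feeds [extract_pre()] directly.
#'
#' @param truth a `synthetic_truth` from [make_toy_complex()].
#' @param settings an [acquisition_settings()].
#' @param noise_sigma fractional intensity noise (0 = noiseless).
#' @param seed integer seed.
#' @param nominal_intensity diamagnetic peak-height scale.
#' @param constants a [physical_constants()] bundle.
#' @return data.frame in the peak-table layout (`tag_site`, `chain`,
#'   `resnum`, `probe`, `i_para`, `i_dia`, `v_para`, `v_dia`, `sigma_i`)
#'   with truth columns `true_gamma2`, `true_distance`, `true_ratio`.
#' @export
simulate_pre_dataset <- function(truth, settings, noise_sigma = 0, seed = 1,
                                 nominal_intensity = 1000,
                                 constants = physical_constants()) {
  stopifnot(noise_sigma >= 0)
  set.seed(seed)
  tabs <- lapply(names(truth$tag_sites), function(site) {
    g <- truth$true_gamma2[[site]]
    ratio <- forward_height_ratio(g, settings, constants)
    n <- length(g)
    i_dia <- nominal_intensity * (1 + 0.1 * stats::rnorm(n))
    i_para <- ratio * i_dia
    i_dia <- i_dia * (1 + noise_sigma * stats::rnorm(n))
    i_para <- i_para * (1 + noise_sigma * stats::rnorm(n))
    data.frame(tag_site = site, chain = truth$probes$chain,
               resnum = truth$probes$resno, probe = truth$probes$atom,
               i_para = i_para, i_dia = i_dia,
               v_para = NA_real_, v_dia = NA_real_,
               sigma_i = noise_sigma * nominal_intensity,
               true_gamma2 = g,
               true_distance = truth$true_distances[[site]],
               true_ratio = ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

#' Simulate planted-interface chemical shift tables
#'
#' Per residue of each partner, the true CSP decays exponentially with the
#' minimum distance to the other molecule in the bound pose,
#' \eqn{|\Delta\delta| = A e^{-d/\lambda}}, split evenly (in quadrature)
#' between the 1H and 15N channels with seeded random signs, plus Gaussian
#' channel noise. Relative accessibilities come from the free monomers.
#'
#' @param truth a `synthetic_truth`.
#' @param amplitude contact-CSP amplitude A, ppm.
#' @param decay_length decay constant lambda, Angstrom.
#' @param noise_sigma per-channel 1H-equivalent noise, ppm.
#' @param seed integer seed.
#' @param weight nitrogen weight of the CSP combination.
#' @return named list of two data.frames (`A`, `B`) with columns `chain`,
#'   `resno`, `resname`, `delta_h`, `delta_n`, `rel_sasa`,
#'   `intensity_loss`, `d_interface`.
#' @export
simulate_csp_dataset <- function(truth, amplitude = 0.2, decay_length = 5,
                                 noise_sigma = 0, seed = 1, weight = 0.15) {
  stopifnot(amplitude >= 0, decay_length > 0, noise_sigma >= 0)
  set.seed(seed)
  cm <- truth$complex_model$atoms
  one <- function(chain) {
    own <- cm[cm$chain == chain, ]
    oth <- cm[cm$chain != chain, ]
    co <- as.matrix(own[c("x", "y", "z")]); ct <- as.matrix(oth[c("x", "y", "z")])
    d2 <- outer(rowSums(co^2), rowSums(ct^2), "+") - 2 * co %*% t(ct)
    dmin <- tapply(sqrt(pmax(apply(d2, 1, min), 0)), own$resno, min)
    resno <- as.integer(names(dmin))
    n <- length(resno)
    mag <- amplitude * exp(-as.numeric(dmin) / decay_length)
    sh <- sample(c(-1, 1), n, replace = TRUE)
    sn <- sample(c(-1, 1), n, replace = TRUE)
    delta_h <- sh * mag / sqrt(2) + noise_sigma * stats::rnorm(n)
    delta_n <- sn * mag / (sqrt(2) * weight) +
      noise_sigma / weight * stats::rnorm(n)
    acc <- residue_accessibility(truth$free_models[[chain]])
    data.frame(chain = chain, resno = resno, resname = "ALA",
               delta_h = delta_h, delta_n = delta_n,
               rel_sasa = acc$rel_sasa[match(resno, acc$resno)],
               intensity_loss = FALSE, d_interface = as.numeric(dmin),
               stringsAsFactors = FALSE)
  }
  list(A = one("A"), B = one("B"))
}

#' Simulate an exponential relaxation decay series
#'
#' \eqn{I(t) = I_0 e^{-Rt}} with multiplicative Gaussian noise, on the
#' standard 8-delay schedule (0, 2, 5, 10, 15, 20, 30, 40 ms) by default.
#'
#' @param rate decay rate R, s^-1.
#' @param delays delay list, seconds.
#' @param noise_sigma fractional noise.
#' @param seed integer seed.
#' @param i0 intensity at zero delay.
#' @return data.frame with `delay` and `intensity`.
#' @export
simulate_decay_series <- function(rate,
                                  delays = c(0, 2, 5, 10, 15, 20, 30, 40) / 1e3,
                                  noise_sigma = 0, seed = 1, i0 = 1000) {
  stopifnot(length(delays) >= 1, rate >= 0, noise_sigma >= 0)
  set.seed(seed)
  ideal <- i0 * exp(-rate * delays)
  data.frame(delay = delays,
             intensity = ideal * (1 + noise_sigma * stats::rnorm(length(delays))))
}
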