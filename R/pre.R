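#' Acquisition settings for PRE experiments
#'
#' Collects the spectrometer and processing parameters needed to relate peak
#' heights to transverse PRE rates: the total fixed transverse 1H delay of
#' the transfer pathway, the two relaxation delays of the two-time-point
#' experiment, the exponential apodization line-broadening factors of the
#' indirect (F1) and direct (F2) dimensions, and the diamagnetic transverse
#' rates of the 1H single-quantum and 1H/13C multiple-quantum coherences.
#'
#' @param field_mhz 1H Larmor frequency, MHz.
#' @param delta_total total fixed transverse 1H delay Delta, seconds
#'   (amide HSQC here: 10.3 ms; methyl HMQC: 7.7 ms).
#' @param delay_a,delay_b relaxation delays of the two-plane experiment,
#'   seconds (defaults 0 and 10 ms).
#' @param lb_f1,lb_f2 line-broadening factors, Hz.
#' @param r2_dia_h diamagnetic 1H transverse rate, s^-1.
#' @param r2_dia_mq diamagnetic 1H/13C multiple-quantum rate, s^-1.
#' @return object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(field_mhz = 850, delta_total = 7.7e-3,
                                 delay_a = 0, delay_b = 10e-3,
                                 lb_f1 = 15, lb_f2 = 15,
                                 r2_dia_h = 25, r2_dia_mq = 30) {
  stopifnot(field_mhz > 0, delta_total > 0, delay_b > delay_a, delay_a >= 0,
            lb_f1 >= 0, lb_f2 >= 0, r2_dia_h >= 0, r2_dia_mq >= 0)
  structure(list(field_mhz = field_mhz, delta_total = delta_total,
                 delay_a = delay_a, delay_b = delay_b,
                 lb_f1 = lb_f1, lb_f2 = lb_f2,
                 r2_dia_h = r2_dia_h, r2_dia_mq = r2_dia_mq),
            class = "acquisition_settings")
}

#' Multiple-quantum PRE factor
#'
#' Ratio of the 1H/13C multiple-quantum PRE to the 1H PRE under the usual
#' approximations (identical electron-nucleus distances and order
#' parameters for the methyl 1H and 13C, spectral density dominated by the
#' zero-frequency term): \eqn{1 + (\gamma_C/\gamma_H)^2 \approx 1.063}.
#'
#' @param constants a [physical_constants()] bundle.
#' @return numeric scalar.
#' @export
mq_pre_factor <- function(constants = physical_constants()) {
  1 + (constants$gamma_c / constants$gamma_h)^2
}

.pre_clamp <- function(gamma2) {
  status <- ifelse(is.na(gamma2), "bleached",
                   ifelse(gamma2 < 0, "no_pre", "quantified"))
  gamma2 <- ifelse(is.na(gamma2), NA_real_, pmax(gamma2, 0))
  data.frame(gamma2 = gamma2, status = status, stringsAsFactors = FALSE)
}

#' PRE from the two-time-point intensity ratios
#'
#' \eqn{\Gamma_2 = -\ln(I_{ratio,para}/I_{ratio,dia}) / (\tau_2-\tau_1)}
#' where each ratio is the peak intensity at the longer relaxation delay
#' over that at the shorter delay, for the paramagnetic and diamagnetic
#' samples respectively. Negative rates (noise) are clamped to zero and
#' flagged `no_pre`; non-positive ratios are flagged `bleached`.
#'
#' @param i_ratio_para,i_ratio_dia intensity ratios (vectorized).
#' @param delay_a,delay_b the two relaxation delays, seconds.
#' @return data.frame with columns `gamma2` (s^-1) and `status`.
#' @export
pre_two_point <- function(i_ratio_para, i_ratio_dia, delay_a = 0,
                          delay_b = 10e-3) {
  stopifnot(delay_b > delay_a)
  bad <- !(i_ratio_para > 0 & i_ratio_dia > 0)
  g <- ifelse(bad, NA_real_,
              -log(i_ratio_para / i_ratio_dia) / (delay_b - delay_a))
  .pre_clamp(g)
}

#' PRE from paramagnetic/diamagnetic peak volumes
#'
#' Single-time-point volume protocol:
#' \eqn{\Gamma_2 = -\ln(V_{para}/V_{dia})/\Delta} with \eqn{\Delta} the
#' total fixed transverse 1H delay. Clamp/flag rules as in
#' [pre_two_point()].
#'
#' @param v_para,v_dia peak volumes (vectorized).
#' @param delta_total total transverse delay, seconds.
#' @return data.frame with columns `gamma2` (s^-1) and `status`.
#' @export
pre_volume_ratio <- function(v_para, v_dia, delta_total) {
  stopifnot(delta_total > 0, all(v_dia > 0))
  g <- ifelse(v_para > 0, -log(v_para / v_dia) / delta_total, NA_real_)
  .pre_clamp(g)
}

#' Forward model: methyl HMQC peak-height ratio from a 1H PRE
#'
#' Single-time-point peak-height model for the paramagnetic/diamagnetic
#' height ratio of a methyl HMQC peak:
#' \deqn{I_{para}/I_{dia} = e^{-\Gamma_2^H \Delta}
#'   \frac{(R_2^{MQ}+\pi LB_1)(R_2^H+\pi LB_2)}
#'        {(R_2^{MQ}+\pi LB_1+ c\,\Gamma_2^H)(R_2^H+\pi LB_2+\Gamma_2^H)}}
#' with \eqn{c} the multiple-quantum factor ([mq_pre_factor()], ~1.063).
#' The ratio equals 1 at \eqn{\Gamma_2^H = 0} and decreases strictly with
#' increasing PRE, which guarantees a unique numerical inverse.
#'
#' @param gamma2_h 1H transverse PRE, s^-1 (vectorized, >= 0).
#' @param settings an [acquisition_settings()].
#' @param constants a [physical_constants()] bundle (for the MQ factor).
#' @return height ratio in (0, 1].
#' @export
forward_height_ratio <- function(gamma2_h, settings,
                                 constants = physical_constants()) {
  stopifnot(all(gamma2_h >= 0))
  cmq <- mq_pre_factor(constants)
  a1 <- settings$r2_dia_mq + pi * settings$lb_f1
  a2 <- settings$r2_dia_h + pi * settings$lb_f2
  exp(-gamma2_h * settings$delta_total) * (a1 * a2) /
    ((a1 + cmq * gamma2_h) * (a2 + gamma2_h))
}

#' Invert the peak-height model to extract the 1H PRE
#'
#' Numerically inverts [forward_height_ratio()] by bracketed root finding
#' (the forward model is strictly decreasing, so the bracket is expanded
#' geometrically until it encloses the root and then refined with Brent's
#' method). Ratios above 1 are clamped to zero PRE (`no_pre`); non-positive
#' ratios are flagged `bleached`.
#'
#' @param ratio observed I_para/I_dia height ratio (vectorized).
#' @param settings an [acquisition_settings()].
#' @param constants a [physical_constants()] bundle.
#' @param f_tol residual tolerance on the ratio at the root.
#' @return data.frame with columns `gamma2` (s^-1) and `status`.
#' @export
invert_height_ratio <- function(ratio, settings,
                                constants = physical_constants(),
                                f_tol = 1e-12) {
  one <- function(r) {
    if (is.na(r) || r <= 0) return(NA_real_)
    if (r >= 1) return(-1e-12)  # clamps to 0 / no_pre downstream
    f <- function(g) forward_height_ratio(g, settings, constants) - r
    hi <- 1e3
    while (f(hi) > 0) {
      hi <- hi * 4
      if (hi > 1e12) stop("failed to bracket PRE root for ratio ", r)
    }
    root <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps^0.6)$root
    # polish with Newton steps on the log-ratio (well-conditioned)
    for (k in 1:4) {
      fr <- forward_height_ratio(root, settings, constants)
      if (abs(fr - r) < f_tol) break
      dlog <- (log(forward_height_ratio(root * (1 + 1e-7) + 1e-12,
                                        settings, constants)) - log(fr)) /
        (root * 1e-7 + 1e-12)
      root <- max(0, root - (log(fr) - log(r)) / dlog)
    }
    root
  }
  out <- .pre_clamp(vapply(ratio, one, numeric(1)))
  out$status[!is.na(out$gamma2) & out$gamma2 < 0] <- "no_pre"
  out$gamma2 <- pmax(out$gamma2, 0)
  out
}

#' Fit a single-exponential relaxation decay
#'
#' Nonlinear least-squares fit of \eqn{I(t) = I_0 e^{-Rt}} to an intensity
#' series (used to extract diamagnetic transverse rates from pseudo-3D
#' relaxation series). Starting values come from the log-linear fit.
#'
#' @param delays relaxation delays, seconds (>= 3 unique values for
#'   standard errors; 2 points give the closed-form rate).
#' @param intensities positive peak intensities.
#' @return list with `rate`, `i0`, `rate_se`, `i0_se` and the `fit` object
#'   (NULL for the 2-point closed form).
#' @export
fit_exponential_decay <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities), length(delays) >= 2,
            all(intensities > 0))
  if (length(unique(delays)) < 2) stop("singular design: all delays equal")
  if (length(delays) == 2) {
    r <- -log(intensities[2] / intensities[1]) / (delays[2] - delays[1])
    i0 <- intensities[1] * exp(r * delays[1])
    return(list(rate = r, i0 = i0, rate_se = NA_real_, i0_se = NA_real_,
                fit = NULL))
  }
  lf <- stats::lm(log(intensities) ~ delays)
  start <- list(i0 = exp(unname(stats::coef(lf)[1])),
                r = max(-unname(stats::coef(lf)[2]), 1e-6))
  if (sum(stats::residuals(lf)^2) < 1e-18) {
    # exact exponential: the log-linear fit is already the solution and a
    # zero-residual nonlinear fit would not converge meaningfully
    sl <- suppressWarnings(summary(lf))$coefficients
    return(list(rate = start$r, i0 = start$i0,
                rate_se = sl["delays", "Std. Error"],
                i0_se = start$i0 * sl["(Intercept)", "Std. Error"],
                fit = lf))
  }
  fit <- stats::nls(intensities ~ i0 * exp(-r * delays), start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  co <- summary(fit)$coefficients
  list(rate = co["r", "Estimate"], i0 = co["i0", "Estimate"],
       rate_se = co["r", "Std. Error"], i0_se = co["i0", "Std. Error"],
       fit = fit)
}

#' Combine split peaks by intensity summation
#'
#' When a probe shows distinct peaks for the free and bound states, the
#' intensity entering the PRE ratio is the sum over the component peaks
#' (applied to the paramagnetic and diamagnetic spectra alike).
#'
#' @param heights numeric vector of component peak heights.
#' @return combined height (arithmetic sum).
#' @export
merge_split_peaks <- function(heights) {
  stopifnot(length(heights) >= 1)
  sum(heights)
}

#' Monte Carlo uncertainty of an extracted PRE
#'
#' Resamples the measured quantities (paramagnetic and diamagnetic peak
#' heights, diamagnetic 1H and MQ rates) from Gaussians centred on the
#' observations, re-inverts the peak-height model for each replicate, and
#' returns the sample standard deviation (n-1) of the replicate PREs.
#' Replicates with a non-positive intensity ratio are redrawn (count
#' reported as attribute `n_redrawn`).
#'
#' @param i_para,i_dia observed peak heights.
#' @param settings an [acquisition_settings()].
#' @param errors list of standard errors: `i_para`, `i_dia`, `r2_dia_h`,
#'   `r2_dia_mq` (absent entries default to 0).
#' @param n_reps number of replicates (>= 100).
#' @param seed integer seed (mandatory for reproducibility).
#' @param constants a [physical_constants()] bundle.
#' @return standard uncertainty of Gamma2 (s^-1), with attributes
#'   `n_redrawn` and `replicates`.
#' @export
monte_carlo_pre_uncertainty <- function(i_para, i_dia, settings,
                                        errors = list(), n_reps = 500, seed,
                                        constants = physical_constants()) {
  stopifnot(n_reps >= 100, i_dia > 0)
  e <- function(nm) if (is.null(errors[[nm]])) 0 else errors[[nm]]
  stopifnot(e("i_para") >= 0, e("i_dia") >= 0,
            e("r2_dia_h") >= 0, e("r2_dia_mq") >= 0)
  set.seed(seed)
  gam <- numeric(n_reps)
  n_redrawn <- 0L
  for (k in seq_len(n_reps)) {
    repeat {
      ip <- stats::rnorm(1, i_para, e("i_para"))
      id <- stats::rnorm(1, i_dia, e("i_dia"))
      if (id > 0 && ip > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    s <- settings
    s$r2_dia_h <- max(stats::rnorm(1, settings$r2_dia_h, e("r2_dia_h")), 0)
    s$r2_dia_mq <- max(stats::rnorm(1, settings$r2_dia_mq, e("r2_dia_mq")), 0)
    gam[k] <- invert_height_ratio(ip / id, s, constants)$gamma2
  }
  out <- stats::sd(gam)
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "replicates") <- gam
  out
}

#' Read a peak table
#'
#' Strictly validated delimited peak table with columns `tag_site`, `chain`,
#' `resnum`, `probe`, `i_para`, `i_dia`, `v_para`, `v_dia`, `sigma_i`
#' (volumes and sigma may be NA).
#'
#' @param path TSV/CSV file (delimiter inferred from extension; `.csv` is
#'   comma, anything else tab).
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("tag_site", "chain", "resnum", "probe", "i_para", "i_dia",
            "v_para", "v_dia", "sigma_i")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("peak table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  tab[need]
}

#' Extract PREs from a peak table
#'
#' Applies the protocol-appropriate extraction to every row of a peak
#' table: `"height"` inverts the methyl HMQC peak-height model
#' ([invert_height_ratio()]), `"volume"` uses the single-time-point volume
#' ratio, `"two_point"` interprets `i_para`/`i_dia` as the two-plane
#' intensity ratios.
#'
#' @param peaks data.frame as from [read_peak_table()].
#' @param settings an [acquisition_settings()].
#' @param mode one of `"height"`, `"volume"`, `"two_point"`.
#' @param constants a [physical_constants()] bundle.
#' @return `peaks` with added columns `ratio`, `gamma2`, `status`.
#' @export
extract_pre <- function(peaks, settings,
                        mode = c("height", "volume", "two_point"),
                        constants = physical_constants()) {
  mode <- match.arg(mode)
  res <- switch(mode,
    height = {
      ratio <- peaks$i_para / peaks$i_dia
      cbind(ratio = ratio, invert_height_ratio(ratio, settings, constants))
    },
    volume = {
      ratio <- peaks$v_para / peaks$v_dia
      cbind(ratio = ratio,
            pre_volume_ratio(peaks$v_para, peaks$v_dia,
                             settings$delta_total))
    },
    two_point = {
      ratio <- peaks$i_para / peaks$i_dia
      cbind(ratio = ratio,
            pre_two_point(peaks$i_para, peaks$i_dia,
                          settings$delay_a, settings$delay_b))
    })
  cbind(peaks, res)
}
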