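#' Simulate a tensile stress-strain record
#'
#' Linear elastic segment of slope `modulus_mpa`, optionally followed by a
#' perfectly plastic plateau past `yield_strain`; Gaussian noise is additive
#' on the stress.
#'
#' @param modulus_mpa Young's modulus of the elastic segment (MPa).
#' @param max_strain final strain of the record (dimensionless).
#' @param noise_sd standard deviation of the stress noise (MPa).
#' @param seed integer seed.
#' @param n_points number of strain samples (strictly increasing from 0).
#' @param yield_strain optional strain beyond which stress plateaus.
#' @return a `stress_strain_curve`: data frame with `strain`, `stress_mpa`.
#' @export
simulate_stress_strain <- function(modulus_mpa, max_strain = 0.5,
                                   noise_sd = 0, seed = NULL,
                                   n_points = 200, yield_strain = NULL) {
  check_positive(modulus_mpa, "modulus_mpa")
  if (n_points < 2 || max_strain <= 0) {
    stop_field("max_strain/n_points", "zero-length curve rejected")
  }
  strain <- seq(0, max_strain, length.out = n_points)
  stress <- modulus_mpa * if (is.null(yield_strain)) strain else pmin(strain, yield_strain)
  stress <- with_seed(seed, stress + stats::rnorm(n_points, 0, noise_sd))
  structure(data.frame(strain = strain, stress_mpa = stress),
            class = c("stress_strain_curve", "data.frame"))
}

#' Young's modulus from a stress-strain record
#'
#' Least-squares slope of stress versus strain over the linear elastic
#' region. If `linear_region` is not given, the region is selected as the
#' maximal leading strain window (of at least `min_points` samples) whose
#' linear fit has a coefficient of determination of at least `r2_threshold`;
#' an error reports the best window found if none qualifies.
#'
#' @param curve a `stress_strain_curve` (or data frame with `strain`,
#'   `stress_mpa`).
#' @param linear_region optional `c(min_strain, max_strain)` window fitted
#'   as-is (no R^2 criterion).
#' @param min_points minimum number of points in the fitted window.
#' @param r2_threshold R^2 required of the automatic leading window.
#' @return list with `modulus_mpa`, `intercept_mpa`, `r_squared`, `window`
#'   (strain range used), `n_points`, `std_error` and the 95% confidence
#'   interval `ci_mpa`.
#' @export
young_modulus <- function(curve, linear_region = NULL, min_points = 5,
                          r2_threshold = 0.99) {
  strain <- curve$strain; stress <- curve$stress_mpa
  if (length(strain) < min_points) {
    stop(sprintf("need >= %d points in the fitted window", min_points),
         call. = FALSE)
  }
  if (any(diff(strain) <= 0)) {
    stop_field("strain", "must be strictly increasing")
  }
  fit_window <- function(idx) {
    fit <- stats::lm(stress[idx] ~ strain[idx])
    # suppress the "essentially perfect fit" note: noiseless synthetic
    # curves are expected inputs here
    list(fit = fit, r2 = suppressWarnings(summary(fit)$r.squared), idx = idx)
  }
  if (!is.null(linear_region)) {
    idx <- which(strain >= linear_region[1] & strain <= linear_region[2])
    if (length(idx) < min_points) {
      stop("linear_region contains fewer than min_points samples", call. = FALSE)
    }
    res <- fit_window(idx)
  } else {
    res <- NULL; best <- NULL
    for (k in seq(min_points, length(strain))) {
      cand <- fit_window(seq_len(k))
      if (is.null(best) || cand$r2 > best$r2) best <- cand
      if (cand$r2 >= r2_threshold) res <- cand
    }
    if (is.null(res)) {
      stop(sprintf(
        "no leading window reaches R^2 >= %g (best: %d points, R^2 = %.4f)",
        r2_threshold, length(best$idx), best$r2), call. = FALSE)
    }
  }
  sm <- suppressWarnings(summary(res$fit))
  slope <- stats::coef(res$fit)[2]
  se <- sm$coefficients[2, 2]
  ci <- slope + c(-1, 1) * stats::qt(0.975, res$fit$df.residual) * se
  list(modulus_mpa = unname(slope),
       intercept_mpa = unname(stats::coef(res$fit)[1]),
       r_squared = res$r2,
       window = range(strain[res$idx]),
       n_points = length(res$idx),
       std_error = unname(se),
       ci_mpa = unname(ci))
}
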