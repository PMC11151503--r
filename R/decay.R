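#' Specification of a simulated fluorescence decay
#'
#' Describes a mono- or multi-exponential fluorescence decay to be binned into
#' a photon-count histogram, emulating time-correlated single photon counting
#' (TCSPC) acquisition: a laser repetition period (default 50 ns) divided into
#' `n_bins` time bins (default 256). Decays are ideal exponentials with no
#' instrument response function; wrap-around of the tail past the period is
#' ignored (truncated-decay convention, an accurate approximation for
#' lifetimes well below the period).
#'
#' @param lifetimes_ns positive decay lifetimes in ns, one per component.
#' @param amplitude_fractions amplitude-domain fractional contributions
#'   (the `alpha_i` of the multi-exponential model); must sum to 1.
#' @param total_photons expected total photon count of the histogram.
#' @param period_ns laser repetition period in ns.
#' @param n_bins number of time bins the period is divided into.
#' @param noise `"none"` for exact (real-valued) expected counts, `"poisson"`
#'   for independent Poisson draws per bin.
#' @param seed integer seed used when `noise = "poisson"`.
#' @return an object of class `decay_sim_spec`.
#' @seealso [simulate_decay()]
#' @export
decay_sim_spec <- function(lifetimes_ns,
                           amplitude_fractions = rep(1 / length(lifetimes_ns),
                                                     length(lifetimes_ns)),
                           total_photons = 5000,
                           period_ns = 50,
                           n_bins = 256,
                           noise = c("none", "poisson"),
                           seed = NULL) {
  check_positive(lifetimes_ns, "lifetimes_ns")
  check_positive(total_photons, "total_photons")
  check_positive(period_ns, "period_ns")
  if (!is.numeric(n_bins) || n_bins < 2) stop_field("n_bins", "must be >= 2")
  noise <- match.arg(noise)
  check_positive(amplitude_fractions, "amplitude_fractions", strict = FALSE)
  if (length(amplitude_fractions) != length(lifetimes_ns)) {
    stop_field("amplitude_fractions", "must match length of lifetimes_ns")
  }
  if (abs(sum(amplitude_fractions) - 1) > 1e-9) {
    stop_field("amplitude_fractions", "must sum to 1 (within 1e-9)")
  }
  structure(
    list(lifetimes_ns = as.numeric(lifetimes_ns),
         amplitude_fractions = as.numeric(amplitude_fractions),
         total_photons = total_photons,
         period_ns = period_ns,
         n_bins = as.integer(n_bins),
         noise = noise,
         seed = seed),
    class = "decay_sim_spec"
  )
}

#' Photon-count decay histogram
#'
#' Container for one fluorescence decay histogram: non-negative photon counts
#' per time bin over one laser repetition period.
#'
#' @param counts non-negative photon counts, one per bin.
#' @param period_ns laser repetition period in ns.
#' @param origin optional pixel coordinate or region id for error messages.
#' @return an object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, period_ns = 50, origin = NULL) {
  check_positive(counts, "counts", strict = FALSE)
  check_positive(period_ns, "period_ns")
  structure(
    list(counts = as.numeric(counts),
         n_bins = length(counts),
         period_ns = period_ns,
         origin = origin),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins over %g ns, %0.4g photons\n",
              x$n_bins, x$period_ns, sum(x$counts)))
  invisible(x)
}

# Expected fraction of photons in each bin for a truncated multi-exponential
# decay: bin value = integral of the decay over the bin (photon-counting
# convention), normalized over the period.
decay_bin_fractions <- function(lifetimes_ns, amplitude_fractions,
                                period_ns, n_bins) {
  edges <- seq(0, period_ns, length.out = n_bins + 1)
  expected <- numeric(n_bins)
  for (i in seq_along(lifetimes_ns)) {
    tau <- lifetimes_ns[i]
    expected <- expected + amplitude_fractions[i] * tau *
      (exp(-edges[-(n_bins + 1)] / tau) - exp(-edges[-1] / tau))
  }
  expected / sum(expected)
}

#' Simulate a TCSPC decay histogram
#'
#' Bins a truncated multi-exponential decay into `n_bins` time bins. With
#' `noise = "none"` the counts are the exact (real-valued) expectations scaled
#' to `total_photons`; with `noise = "poisson"` each bin is an independent
#' Poisson draw with that expectation, reproducible from `seed`.
#'
#' @param spec a [decay_sim_spec()].
#' @return a [decay_histogram()].
#' @examples
#' h <- simulate_decay(decay_sim_spec(3.6, 1, total_photons = 1e5))
#' sum(h$counts)
#' @export
simulate_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  frac <- decay_bin_fractions(spec$lifetimes_ns, spec$amplitude_fractions,
                              spec$period_ns, spec$n_bins)
  expected <- spec$total_photons * frac
  counts <- if (spec$noise == "poisson") {
    with_seed(spec$seed, stats::rpois(spec$n_bins, expected))
  } else {
    expected
  }
  decay_histogram(counts, period_ns = spec$period_ns)
}
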