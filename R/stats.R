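# Kolmogorov asymptotic survival function with Stephens' finite-sample
# factor: lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D.
ks_p_asymptotic <- function(d, n_a, n_b) {
  ne <- n_a * n_b / (n_a + n_b)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Exact two-sample KS p-value P(D >= d) by lattice-path counting (valid
# without ties): count monotone paths from (0,0) to (m,n) whose partial
# sums keep |i*n - j*m| strictly below d*m*n.
ks_p_exact <- function(d, n_a, n_b) {
  m <- n_a; n <- n_b
  dint <- round(d * m * n) # observed sup-distance on the integer grid
  if (dint <= 0) return(1)
  u <- numeric(n + 1)
  u[1] <- 1
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 && j == 0) next
      if (abs(i * n - j * m) >= dint) {
        u[j + 1] <- 0
      } else {
        left <- if (j > 0) u[j] else 0
        up <- if (i > 0) u[j + 1] else 0
        u[j + 1] <- left + up
      }
    }
  }
  1 - u[n + 1] / choose(m + n, n)
}

#' Two-group comparison (Welch's t, Student's t, or Kolmogorov-Smirnov)
#'
#' Computes the statistic and p-value from first principles: Welch's t with
#' Welch-Satterthwaite degrees of freedom, Student's pooled-variance t, or
#' the two-sample KS test (exact lattice-path enumeration when both groups
#' have fewer than 10 observations and no ties; otherwise the asymptotic
#' Kolmogorov distribution with Stephens' finite-sample factor). Percent
#' change is reported as `100 * (mean_a - mean_b) / mean_b`, i.e. relative
#' to group b (the baseline).
#'
#' @param values_a,values_b numeric samples.
#' @param test `"welch_t"`, `"student_t"` or `"ks"`.
#' @param group_a,group_b optional condition tags carried into the result.
#' @return a `comparison_result`: one-row data frame with group summaries
#'   (`mean`, `sem`, `n` per group), `percent_change`, `test`, `statistic`,
#'   `p_value`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch_t", "student_t", "ks"),
                           group_a = "a", group_b = "b") {
  test <- match.arg(test)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  n_a <- length(a); n_b <- length(b)
  if (test != "ks" && (n_a < 2 || n_b < 2)) {
    stop("t-tests need n >= 2 per group", call. = FALSE)
  }
  if (test == "ks" && (n_a < 1 || n_b < 1)) {
    stop("KS test needs non-empty groups", call. = FALSE)
  }
  m_a <- mean(a); m_b <- mean(b)
  v_a <- if (n_a > 1) stats::var(a) else NA_real_
  v_b <- if (n_b > 1) stats::var(b) else NA_real_

  if (test == "welch_t") {
    se2 <- v_a / n_a + v_b / n_b
    if (se2 == 0) {
      statistic <- 0
      p <- if (m_a == m_b) 1 else 0
      df <- n_a + n_b - 2
    } else {
      statistic <- (m_a - m_b) / sqrt(se2)
      df <- se2^2 / ((v_a / n_a)^2 / (n_a - 1) + (v_b / n_b)^2 / (n_b - 1))
      p <- 2 * stats::pt(-abs(statistic), df)
    }
  } else if (test == "student_t") {
    sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / (n_a + n_b - 2)
    if (sp2 == 0) {
      statistic <- 0
      p <- if (m_a == m_b) 1 else 0
    } else {
      statistic <- (m_a - m_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
      p <- 2 * stats::pt(-abs(statistic), n_a + n_b - 2)
    }
  } else {
    pooled <- c(a, b)
    ord <- order(pooled)
    srt <- pooled[ord]
    z <- cumsum(ifelse(ord <= n_a, 1 / n_a, -1 / n_b))
    # evaluate the ECDF difference only where the pooled value changes
    at_jump <- c(diff(srt) != 0, TRUE)
    statistic <- max(abs(z[at_jump]))
    ties <- any(duplicated(pooled))
    if (n_a < 10 && n_b < 10 && !ties) {
      p <- ks_p_exact(statistic, n_a, n_b)
    } else {
      if (ties && n_a < 10 && n_b < 10) {
        warning("ties present; using asymptotic KS p-value", call. = FALSE)
      }
      p <- ks_p_asymptotic(statistic, n_a, n_b)
    }
  }

  structure(
    data.frame(group_a = group_a, group_b = group_b,
               n_a = n_a, n_b = n_b,
               mean_a = m_a, mean_b = m_b,
               sem_a = if (n_a > 1) sqrt(v_a / n_a) else NA_real_,
               sem_b = if (n_b > 1) sqrt(v_b / n_b) else NA_real_,
               percent_change = 100 * (m_a - m_b) / m_b,
               test = test, statistic = unname(statistic),
               p_value = unname(p)),
    class = c("comparison_result", "data.frame")
  )
}

#' Summary statistics for one condition
#'
#' Mean, sample standard deviation (n-1 denominator) and the standard error
#' of the mean `sem = sd / sqrt(n)`. A single value yields `NA` for both
#' dispersion measures.
#'
#' @param values numeric vector.
#' @param condition optional condition tag carried into the result.
#' @return one-row data frame with `condition`, `mean`, `sd`, `sem`, `n`.
#' @export
summarize_condition <- function(values, condition = NA_character_) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 1) stop("summarize_condition needs at least one value", call. = FALSE)
  s <- if (n > 1) stats::sd(v) else NA_real_
  data.frame(condition = condition, mean = mean(v), sd = s,
             sem = if (n > 1) s / sqrt(n) else NA_real_, n = n)
}
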