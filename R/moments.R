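# Distribution-shape summaries shared by the episode-window and 90-day
# feature groups. Conventions:
#   * skewness   g1 = m3 / m2^(3/2)     (biased sample moments, m_k = mean((x - xbar)^k))
#   * kurtosis   g2 = m4 / m2^2 - 3     (excess kurtosis)
# Undefined quantities (too few points, zero variance) are NA_real_, never NaN.

sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

excess_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2 - 3
}

population_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Rate of mean-value crossing
#'
#' Number of sign changes of the consecutive deviations (x_t - mean(x)),
#' divided by the number of samples. Zero deviations are skipped, i.e. a
#' crossing is counted between consecutive non-zero signs of opposite sense.
#' @noRd
mean_crossing_rate <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- sign(x - mean(x))
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(s[-1] != s[-length(s)]) / n
}
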