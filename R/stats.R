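#' Mean, population SD, and SEM of a performance vector
#'
#' Follows the summary conventions used throughout the package: the SD is
#' normalised by n (population form), and the SEM is approximated as
#' SD / sqrt(n).
#'
#' @param values Numeric vector (length >= 1).
#' @return Named numeric vector `c(mean, sd, sem)`.
#' @examples
#' mean_sd_sem(c(1, 2, 3)) # sd = sqrt(2/3) ~ 0.8165, sem ~ 0.4714
#' @export
mean_sd_sem <- function(values) {
  n <- length(values)
  if (n < 1L) stop("`values` must have length >= 1", call. = FALSE)
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / n)
  c(mean = m, sd = s, sem = s / sqrt(n))
}

#' Deterministic child seeds from a master seed
#'
#' Spawns one independent child seed per (condition, simulation) so that
#' sweeps are reproducible and individual runs can be re-executed in
#' isolation. Seeds are sampled without replacement from 1..2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
child_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}
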