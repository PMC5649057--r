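#' Beta-binomial probability mass function
#'
#' Exact pmf of the beta-binomial distribution, computed in log space via
#' log-gamma so it is stable for depths up to at least 1e5. With `a = b = 1`
#' (uniform Beta) the pmf is `1/(n + 1)` for every `k`.
#'
#' @param k Number of successes (vectorized, `0 <= k <= n`).
#' @param n Number of trials (`>= 0`).
#' @param a,b Positive Beta shape parameters; here `a = W * phi`,
#'   `b = W * (1 - phi)` where `W` controls the spread of the allelic fraction
#'   distribution around the expected fraction `phi`.
#' @param log Return the log pmf.
#' @return Probability (or log probability); `pmf(0, 0, a, b) = 1` by
#'   convention.
#' @export
#' @examples
#' betabinomial_pmf(1, 2, 1, 1) # 1/3
betabinomial_pmf <- function(k, n, a, b, log = FALSE) {
  if (any(a <= 0) || any(b <= 0)) stop("beta-binomial shapes must be > 0")
  if (any(k < 0) || any(k > n)) stop("require 0 <= k <= n")
  v <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) v else exp(v)
}

#' Likelihood of an observed exon depth
#'
#' Poisson likelihood of the rounded tumor exon depth around the rounded
#' expected depth. A zero expected depth is floored at `eps` so that observed
#' reads at a predicted-absent exon receive a finite (tiny) likelihood.
#'
#' @param r_t Observed tumor exon depth(s).
#' @param r_hat Expected depth(s) from [expected_exon_depth()].
#' @param eps Floor for the Poisson mean.
#' @param log Return log likelihood.
#' @return Likelihood value(s).
#' @export
exon_depth_likelihood <- function(r_t, r_hat, eps = 1e-3, log = FALSE) {
  lambda <- pmax(round(r_hat), eps)
  stats::dpois(round(r_t), lambda, log = log)
}

#' Prior density of a clone sample fraction
#'
#' Beta prior on the sample fraction `f`, parameterized so that `f_pi` is the
#' mode: `Beta(alpha_pi, (alpha_pi - 1)/f_pi - alpha_pi + 2)`.
#'
#' @param f Sample fraction(s) in (0, 1).
#' @param f_pi Mode of the prior.
#' @param alpha_pi First shape parameter; must exceed 1 for the mode to exist.
#' @param log Return log density.
#' @return Density value(s).
#' @export
#' @examples
#' f_prior_density(0.5, 0.5, 1.5) # Beta(1.5, 1.5) density at its mode
f_prior_density <- function(f, f_pi, alpha_pi, log = FALSE) {
  if (alpha_pi <= 1) stop("alpha_pi must be > 1")
  beta_b <- (alpha_pi - 1) / f_pi - alpha_pi + 2
  stats::dbeta(f, alpha_pi, beta_b, log = log)
}

#' Beta-binomial likelihood of heterozygous-site B-allele counts
#'
#' @param r_b,r_t B-allele and total read counts at the het site.
#' @param phi Expected germline het allele fraction (from [expected_het_af()]).
#' @param W Dispersion weight of the clone.
#' @param log Return log likelihood.
#' @return Likelihood value(s). `phi` is clamped away from 0/1 so the Beta
#'   shapes stay positive.
#' @export
het_af_likelihood <- function(r_b, r_t, phi, W, log = FALSE) {
  phi <- pmin(pmax(phi, 1e-6), 1 - 1e-6)
  betabinomial_pmf(r_b, r_t, W * phi, W * (1 - phi), log = log)
}

#' Beta-binomial likelihood of somatic-site B-allele counts
#'
#' The expected somatic fraction is folded to its minor form by taking
#' `a = min(W * phi, W * (1 - phi))`, `b = max(...)`, so the likelihood is
#' invariant under `phi -> 1 - phi`. Set `unfolded = TRUE` to disable the fold.
#'
#' @param r_b,r_t B-allele and total read counts at the somatic candidate.
#' @param phi Expected somatic allele fraction (from [expected_somatic_af()]).
#' @param W Dispersion weight of the clone.
#' @param unfolded Disable the min/max fold.
#' @param log Return log likelihood.
#' @return Likelihood value(s).
#' @export
somatic_af_likelihood <- function(r_b, r_t, phi, W, unfolded = FALSE,
                                  log = FALSE) {
  phi <- pmin(pmax(phi, 1e-6), 1 - 1e-6)
  a <- W * phi
  b <- W * (1 - phi)
  if (!unfolded) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    a <- lo
    b <- hi
  }
  betabinomial_pmf(r_b, r_t, a, b, log = log)
}

# log-likelihood of het B counts with unknown parental phase: equal-weight
# mixture over the B allele sitting on the minor (phi) or major (1 - phi)
# parental copy; reduces to the plain beta-binomial when phi = 0.5
het_af_loglik_phased <- function(r_b, r_t, phi, W) {
  phi <- pmin(pmax(phi, 1e-6), 1 - 1e-6)
  l1 <- betabinomial_pmf(r_b, r_t, W * phi, W * (1 - phi), log = TRUE)
  l2 <- betabinomial_pmf(r_b, r_t, W * (1 - phi), W * phi, log = TRUE)
  hi <- pmax(l1, l2)
  hi + log(0.5 * exp(l1 - hi) + 0.5 * exp(l2 - hi))
}

# round half away from zero; base round() uses banker's rounding at .5 ties
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stable log(sum(exp(x))) over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
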