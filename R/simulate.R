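#' Draw per-variant sequencing depths
#'
#' Depths follow a lognormal distribution whose arithmetic mean equals the
#' mean target coverage: `log R_T ~ Normal(log(mean) - sigma_log^2/2,
#' sigma_log)`. Draws are rounded and floored at 1.
#'
#' @param mean_coverage Mean target coverage (> 0).
#' @param n Number of draws.
#' @param sigma_log Log-scale standard deviation (default 1; `0` gives
#'   constant depths).
#' @return Integer depths >= 1.
#' @export
draw_depths <- function(mean_coverage, n, sigma_log = 1) {
  stopifnot(mean_coverage > 0, sigma_log >= 0)
  if (sigma_log == 0) return(rep(as.integer(round(mean_coverage)), n))
  mu <- log(mean_coverage) - sigma_log^2 / 2
  pmax(1L, as.integer(round(stats::rlnorm(n, mu, sigma_log))))
}

#' Simulate somatic variant read counts for one condition
#'
#' Depth from [draw_depths()]; B-allele reads binomial at the expected somatic
#' fraction for the condition's `(f, N, M)`.
#'
#' @param mean_coverage Mean target coverage.
#' @param f Clone sample fraction.
#' @param N,M Copy state of the variant's segment (variant on the major
#'   allele).
#' @param n Number of variants.
#' @param sigma_log Depth spread (see [draw_depths()]).
#' @return Data frame with `r_t`, `r_b` and the condition's `phi_s`.
#' @export
simulate_variant_reads <- function(mean_coverage, f, N, M, n = 1000,
                                   sigma_log = 1) {
  phi_s <- expected_somatic_af(f, N, M)
  r_t <- draw_depths(mean_coverage, n, sigma_log)
  r_b <- stats::rbinom(n, r_t, phi_s)
  data.frame(r_t = r_t, r_b = r_b, phi_s = phi_s)
}

# somatic posterior for clean simulated reads under a known one-clone model
power_posterior <- function(r_t, r_b, f, N, M, config, W, qb = 30) {
  phi_s <- expected_somatic_af(f, N, M)
  phi_g <- expected_het_af(f, N, M)
  err <- 10^(-qb / 10)
  r_a <- r_t - r_b
  ll <- list(
    s = somatic_af_likelihood(r_b, r_t, phi_s, W,
                              unfolded = config$unfolded_somatic_bb,
                              log = TRUE),
    ab = het_af_loglik_phased(r_b, r_t, phi_g, W),
    aa = betabinomial_pmf(r_a, r_t, W * (1 - err), W * err, log = TRUE),
    o = betabinomial_pmf(r_t - r_a - r_b, r_t, W * (1 - err), W * err,
                         log = TRUE)
  )
  fb <- config$F_p_snv
  pri <- call_priors(rep(1 - fb, length(r_t)), rep(fb, length(r_t)), 0,
                     config)
  somatic_posterior(ll, pri)$p_somatic
}

#' Detection power over a coverage / sample-fraction / copy-state grid
#'
#' For each condition, simulates `n` somatic variants
#' ([simulate_variant_reads()]) and reports the fraction with somatic
#' posterior at or above `T_somatic`, evaluated with the true `(f, N, M)`
#' known to the caller (single clone). The evaluation dispersion defaults to
#' the upper fitting bound of `W` — the binomial limit matching the binomial
#' read simulator.
#'
#' @param coverages Numeric vector of mean target coverages.
#' @param fractions Numeric vector of sample fractions.
#' @param cn_states List of `c(N, M)` pairs.
#' @param config A `lumos_config`.
#' @param n Variants per condition.
#' @param seed RNG seed (one stream for the whole grid).
#' @param W Evaluation dispersion weight.
#' @param qb Simulated mean base quality (Phred).
#' @return Data frame `coverage, f, N, M, detected` (fraction in \[0, 1\]).
#' @export
#' @examples
#' \donttest{
#' power_grid(200, 0.5, list(c(2, 1)), n = 200, seed = 1)
#' }
power_grid <- function(coverages, fractions, cn_states,
                       config = default_config(), n = 1000, seed = 1,
                       W = config$W_bounds[2], qb = 30) {
  set.seed(seed)
  grid <- expand.grid(ci = seq_along(coverages), fi = seq_along(fractions),
                      si = seq_along(cn_states))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cov <- coverages[grid$ci[g]]
    f <- fractions[grid$fi[g]]
    st <- cn_states[[grid$si[g]]]
    reads <- simulate_variant_reads(cov, f, st[1], st[2], n,
                                    config$sigma_log)
    p <- power_posterior(reads$r_t, reads$r_b, f, st[1], st[2], config, W, qb)
    data.frame(coverage = cov, f = f, N = st[1], M = st[2],
               detected = mean(p >= config$T_somatic))
  })
  do.call(rbind, rows)
}

#' Generate a synthetic tumor cohort with known truth
#'
#' Emulates the inputs of a targeted tumor/controls experiment: per-exon mean
#' depths for the tumor and each control, per-site allele counts for germline
#' heterozygous sites (common and private), clonal/subclonal somatic variants,
#' and artifact sites (strand-skewed, low mapping quality), plus a priors
#' table. Germline genotypes follow Hardy-Weinberg; B-allele counts are
#' beta-binomial with dispersion `W_gen`; exon depths follow the copy-state
#' depth model with multiplicative target-unevenness noise.
#'
#' @param fractions Clone sample fractions, descending (the truth).
#' @param segments_spec Data frame `n_exons, N, M, clone` (clone `0` =
#'   diploid in every clone). Variants are scattered uniformly over exons.
#' @param n_hets,n_somatics,n_artifacts Site counts.
#' @param private_frac Fraction of hets that are private (population frequency
#'   at the unseen-allele floor).
#' @param mean_depth_tumor,mean_depth_control Mean exon depths.
#' @param n_controls Number of unmatched controls.
#' @param W_gen Beta-binomial dispersion of the generated allele fractions.
#' @param config A `lumos_config`.
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @return A list: `tumor` (counts), `controls` (list of counts),
#'   `exon_depths` (BED + per-sample depth columns, controls named
#'   `control_1..m`), `tumor_exons`, `priors`, `truth` (per-site class, clone,
#'   segment), `segment_truth`.
#' @export
synthesize_cohort <- function(fractions = c(0.6, 0.3),
                              segments_spec = default_segments_spec(),
                              n_hets = 200, n_somatics = 80,
                              n_artifacts = 30, private_frac = 0.25,
                              mean_depth_tumor = 600,
                              mean_depth_control = 400,
                              n_controls = 2, W_gen = 200,
                              config = default_config(), seed = 1) {
  set.seed(seed)
  stopifnot(all(diff(fractions) < 0), all(fractions > 0), all(fractions < 1))
  sspec <- segments_spec
  if (any(sspec$clone > length(fractions))) {
    stop("segments_spec references clone ", max(sspec$clone),
         " but only ", length(fractions), " fraction(s) were given")
  }
  X <- sum(sspec$n_exons)
  exon_seg <- rep(seq_len(nrow(sspec)), sspec$n_exons)
  exon_start <- (seq_len(X) - 1L) * 300L
  exon_end <- exon_start + 150L
  base <- mean_depth_control * stats::rlnorm(X, -0.15^2 / 2, 0.15)
  controls_depth <- sapply(seq_len(n_controls), function(c) {
    base * stats::rlnorm(X, -0.05^2 / 2, 0.05)
  })
  colnames(controls_depth) <- paste0("control_", seq_len(n_controls))
  f_seg <- ifelse(sspec$clone > 0, fractions[pmax(sspec$clone, 1L)], 0)
  cn_mult <- (f_seg * sspec$N + 2 * (1 - f_seg)) / 2
  tumor_depth <- base * (mean_depth_tumor / mean_depth_control) *
    cn_mult[exon_seg] * stats::rlnorm(X, -0.05^2 / 2, 0.05)
  exon_depths <- data.frame(chrom = "chr1", start = exon_start,
                            end = exon_end)
  exon_depths <- cbind(exon_depths, as.data.frame(controls_depth))
  tumor_exons <- data.frame(chrom = "chr1", start = exon_start,
                            end = exon_end, depth_tumor = tumor_depth)

  place_sites <- function(n) {
    ex <- sample.int(X, n, replace = TRUE)
    pos <- exon_start[ex] + sample.int(150L, n, replace = TRUE)
    list(exon = ex, pos = pos)
  }
  rbb <- function(n, size, phi, W) {
    phi <- pmin(pmax(phi, 1e-6), 1 - 1e-6)
    p <- stats::rbeta(n, W * phi, W * (1 - phi))
    stats::rbinom(n, size, p)
  }
  clean_site <- function(pos, r_t, r_b, is_artifact = FALSE) {
    n <- length(pos)
    fwd <- if (is_artifact) r_b else stats::rbinom(n, r_b, 0.5)
    data.frame(
      chrom = rep("chr1", n), pos = pos, ref = rep("A", n),
      alt = rep("T", n),
      r_t = r_t, r_a = pmax(r_t - r_b - stats::rbinom(n, r_t, 1e-3), 0),
      r_b = r_b,
      qb_a = rep(30, n), qb_b = rep(if (is_artifact) 22 else 30, n),
      qm_a = rep(60, n), qm_b = rep(if (is_artifact) 15 else 60, n),
      strand_b_fwd = fwd, strand_b_rev = r_b - fwd,
      is_indel = rep(0, n),
      softclip_frac = rep(if (is_artifact) 0.4 else 0.02, n),
      low_mapq_frac = rep(if (is_artifact) 0.5 else 0.01, n),
      homopolymer = rep(0, n),
      stringsAsFactors = FALSE
    )
  }

  # germline hets: minor-allele copy chosen at random (B on major or minor)
  hp <- place_sites(n_hets)
  het_seg <- exon_seg[hp$exon]
  is_private <- stats::runif(n_hets) < private_frac
  f_b_pop <- ifelse(is_private, config$F_p_snv,
                    0.01 + 0.48 * stats::rbeta(n_hets, 0.5, 0.5))
  fH <- f_seg[het_seg]
  NH <- sspec$N[het_seg]
  MH <- sspec$M[het_seg]
  on_minor <- stats::runif(n_hets) < 0.5
  phi_het <- ifelse(on_minor, expected_het_af(fH, NH, MH),
                    1 - expected_het_af(fH, NH, MH))
  r_t_h <- stats::rpois(n_hets, tumor_depth[hp$exon])
  r_b_h <- rbb(n_hets, r_t_h, phi_het, W_gen)
  tumor_hets <- clean_site(hp$pos, r_t_h, r_b_h)

  # somatic variants: clone drawn per site; in the CN clone's segment the
  # variant rides the major allele, otherwise one copy
  sp <- place_sites(n_somatics)
  som_seg <- exon_seg[sp$exon]
  som_clone <- sample(seq_along(fractions), n_somatics, replace = TRUE)
  redraw <- sspec$clone[som_seg] == som_clone & sspec$N[som_seg] == 0
  while (any(redraw)) { # deleted in its own clone: impossible, move the site
    np <- place_sites(sum(redraw))
    sp$exon[redraw] <- np$exon
    sp$pos[redraw] <- np$pos
    som_seg <- exon_seg[sp$exon]
    redraw <- sspec$clone[som_seg] == som_clone & sspec$N[som_seg] == 0
  }
  f_i <- fractions[som_clone]
  f_cn <- f_seg[som_seg]
  same <- sspec$clone[som_seg] == som_clone & sspec$clone[som_seg] > 0
  phi_som <- numeric(n_somatics)
  diploid <- sspec$clone[som_seg] == 0
  phi_som[diploid] <- f_i[diploid] / 2
  phi_som[same] <- expected_somatic_af(f_cn[same], sspec$N[som_seg][same],
                                       sspec$M[som_seg][same])
  other <- !diploid & !same
  phi_som[other] <- expected_somatic_af_piecewise(
    f_i[other], f_cn[other], sspec$N[som_seg][other],
    sspec$M[som_seg][other], FALSE)
  r_t_s <- stats::rpois(n_somatics, tumor_depth[sp$exon])
  r_b_s <- rbb(n_somatics, r_t_s, phi_som, W_gen)
  tumor_soms <- clean_site(sp$pos, r_t_s, r_b_s)

  # artifacts: skewed strand, degraded qualities, modest allele fraction
  ap <- place_sites(n_artifacts)
  r_t_a <- stats::rpois(n_artifacts, tumor_depth[ap$exon])
  r_b_a <- stats::rbinom(n_artifacts, r_t_a,
                         stats::runif(n_artifacts, 0.05, 0.3))
  tumor_arts <- clean_site(ap$pos, r_t_a, r_b_a, is_artifact = TRUE)

  tumor <- rbind(tumor_hets, tumor_soms, tumor_arts)
  truth <- data.frame(
    chrom = "chr1",
    pos = c(hp$pos, sp$pos, ap$pos),
    class = c(ifelse(is_private, "germline_het_private",
                     "germline_het_common"),
              rep("somatic", n_somatics), rep("artifact", n_artifacts)),
    clone = c(rep(NA_integer_, n_hets), som_clone,
              rep(NA_integer_, n_artifacts)),
    segment = c(het_seg, som_seg, exon_seg[ap$exon]),
    phi = c(phi_het, phi_som, rep(NA_real_, n_artifacts))
  )
  ord <- order(tumor$pos)
  tumor <- tumor[ord, ]
  truth <- truth[ord, ]
  rownames(tumor) <- rownames(truth) <- NULL

  # controls: HWE genotypes at every tumor candidate position
  all_pos <- tumor$pos
  all_fb <- c(f_b_pop, rep(config$F_p_snv, n_somatics),
              rep(config$F_p_snv, n_artifacts))[ord]
  all_art <- truth$class == "artifact"
  controls <- lapply(seq_len(n_controls), function(c) {
    ex <- findInterval(all_pos - 1L, exon_start)
    r_t <- stats::rpois(length(all_pos), controls_depth[ex, c])
    g <- stats::rbinom(length(all_pos), 2, all_fb) # copies of B allele
    p <- c(1e-3, 0.5, 1 - 1e-3)[g + 1]
    art_p <- stats::runif(length(all_pos), 0.05, 0.3)
    p <- ifelse(all_art, art_p, p)
    r_b <- stats::rbinom(length(all_pos), r_t, p)
    df <- clean_site(all_pos, r_t, r_b)
    df$qm_a <- ifelse(all_art, 25, 60)
    df$qm_b <- ifelse(all_art, 15, 60)
    df
  })

  priors <- data.frame(chrom = "chr1", pos = all_pos, allele = "T",
                       f_b = ifelse(all_fb >= 0.01, all_fb, 0),
                       omega = 0L,
                       known_germline = as.integer(all_fb >= 0.01))
  priors <- priors[priors$f_b > 0, , drop = FALSE]

  seg_truth <- sspec
  seg_truth$f <- f_seg
  list(tumor = tumor, controls = controls, exon_depths = exon_depths,
       tumor_exons = tumor_exons, priors = priors, truth = truth,
       segment_truth = seg_truth)
}

#' Default synthetic segment layout
#'
#' A diploid background, a one-copy loss and a copy-neutral LOH segment in the
#' main clone, and a one-copy gain in the second clone.
#'
#' @return Data frame `n_exons, N, M, clone`.
#' @export
default_segments_spec <- function() {
  data.frame(
    n_exons = c(120L, 60L, 60L, 60L),
    N = c(2L, 1L, 2L, 3L),
    M = c(1L, 0L, 0L, 1L),
    clone = c(0L, 1L, 1L, 2L)
  )
}
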