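test_that("expected somatic allele fraction matches closed forms", {
  expect_equal(expected_somatic_af(0.5, 2, 1), 0.25)
  expect_equal(expected_somatic_af(1, 2, 1), 0.5)
  expect_equal(expected_somatic_af(0.2, 2, 1), 0.10)
  expect_equal(expected_somatic_af(0, 2, 1), 0)
  expect_warning(v <- expected_somatic_af(1, 0, 0), "degenerate")
  expect_equal(v, 0)
})

test_that("expected het allele fraction matches closed forms", {
  expect_equal(expected_het_af(1, 2, 1), 0.5)
  expect_equal(expected_het_af(0.6, 3, 1), 0.4)
  expect_equal(expected_het_af(0, 5, 2), 0.5) # pure normal
  expect_warning(v <- expected_het_af(0.6, 0, 0), "N = 0")
  expect_equal(v, 0.2)
})

test_that("piecewise somatic fraction covers its three cases", {
  # same clone: reduces to Eq. 1
  expect_equal(expected_somatic_af_piecewise(0.5, 0.5, 2, 1, TRUE), 0.25)
  # other clone, N > 0
  expect_equal(expected_somatic_af_piecewise(0.2, 0.5, 3, 1, FALSE), 0.08)
  # other clone, segment deleted
  expect_equal(expected_somatic_af_piecewise(0.5, 0.6, 0, 0, FALSE), 0.2)
  # vectorized over mixed cases
  out <- expected_somatic_af_piecewise(c(0.5, 0.2, 0.5), c(0.5, 0.5, 0.6),
                                       c(2, 3, 0), c(1, 1, 0),
                                       c(TRUE, FALSE, FALSE))
  expect_equal(out, c(0.25, 0.08, 0.2))
})

test_that("expected exon depth matches closed forms", {
  expect_equal(expected_exon_depth(1, 2, 100, 2), 100)
  expect_equal(expected_exon_depth(0.5, 4, 100, 2), 150)
  expect_equal(expected_exon_depth(1, 0, 100, 2), 0)
  expect_error(expected_exon_depth(0.5, 2, 100, 0))
})

test_that("copy state inversion recovers simple cases", {
  expect_equal(copy_state_for_clone(1, 1.0, 0.5, 2), list(N = 2L, M = 1L))
  expect_equal(copy_state_for_clone(0.5, 1.5, NA, 2)$N, 4L)
  expect_equal(copy_state_for_clone(1, 1.0, 0.5, 2)$M, 1L)
  # degenerate ratios give the null state
  expect_equal(copy_state_for_clone(0.5, 0, 0.5, 2), list(N = 0L, M = 0L))
  expect_equal(copy_state_for_clone(0.5, NA, 0.5, 2), list(N = 0L, M = 0L))
  # no hets: diploid minor fallback
  expect_equal(copy_state_for_clone(1, 1.5, NA, 2)$M, 1L)
})

test_that("copy state inversion is exact on noise-free segment summaries", {
  states <- list(c(1, 0), c(2, 0), c(2, 1), c(3, 1), c(4, 1))
  for (f in c(0.3, 0.6, 0.9)) {
    for (st in states) {
      N <- st[1]; M <- st[2]
      ratio <- (f * N + 2 * (1 - f)) / 2
      phi <- suppressWarnings(expected_het_af(f, N, M))
      baf <- min(phi, 1 - phi)
      got <- copy_state_for_clone(f, ratio, baf, 2)
      expect_equal(c(got$N, got$M), c(N, M),
                   info = sprintf("f=%.1f N=%d M=%d", f, N, M))
    }
  }
})

test_that("exon depth likelihood matches the Poisson oracle", {
  oracle <- exp(100 * log(100) - 100 - lgamma(101))
  expect_equal(exon_depth_likelihood(100, 100), oracle, tolerance = 1e-12)
  expect_equal(exon_depth_likelihood(0, 0), exp(-1e-3))
  # unimodal decay away from the mean
  lik <- exon_depth_likelihood(seq(100, 160, by = 10), 100)
  expect_true(all(diff(lik) < 0))
})

test_that("beta-binomial pmf matches closed forms", {
  expect_equal(betabinomial_pmf(1, 2, 1, 1), 1 / 3)
  expect_equal(betabinomial_pmf(0, 0, 2, 3), 1)
  expect_equal(sum(betabinomial_pmf(0:30, 30, 7.5, 7.5)), 1, tolerance = 1e-12)
  expect_error(betabinomial_pmf(1, 2, 0, 1), "> 0")
  expect_error(betabinomial_pmf(3, 2, 1, 1), "<= k")
  # no underflow to -Inf at high depth
  expect_true(is.finite(betabinomial_pmf(5e4, 1e5, 50, 50, log = TRUE)))
})

test_that("het likelihood is the beta-binomial with W-scaled shapes", {
  expect_equal(het_af_likelihood(15, 30, 0.5, 30),
               betabinomial_pmf(15, 30, 15, 15))
  # symmetric at phi = 0.5
  expect_equal(het_af_likelihood(10, 30, 0.5, 30),
               het_af_likelihood(20, 30, 0.5, 30))
  # clamping keeps phi in the open interval
  expect_true(is.finite(het_af_likelihood(0, 30, 0, 30, log = TRUE)))
  expect_true(is.finite(het_af_likelihood(30, 30, 1, 30, log = TRUE)))
})

test_that("somatic likelihood folds the expected fraction as printed", {
  expect_equal(somatic_af_likelihood(10, 40, 0.25, 40),
               betabinomial_pmf(10, 40, 10, 30))
  expect_equal(somatic_af_likelihood(10, 40, 0.75, 40),
               somatic_af_likelihood(10, 40, 0.25, 40))
  # the config switch disables the fold
  expect_false(isTRUE(all.equal(
    somatic_af_likelihood(10, 40, 0.75, 40, unfolded = TRUE),
    somatic_af_likelihood(10, 40, 0.25, 40, unfolded = TRUE))))
})

test_that("the f prior is a Beta with mode f_pi", {
  expect_equal(f_prior_density(0.5, 0.5, 1.5), 4 / pi)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 1e4)
  for (fp in c(0.3, 0.5, 0.7)) {
    d <- f_prior_density(grid, fp, 1.5)
    expect_equal(grid[which.max(d)], fp, tolerance = 2e-4)
  }
  q <- integrate(f_prior_density, 0, 1, f_pi = 0.5, alpha_pi = 1.5)
  expect_equal(q$value, 1, tolerance = 1e-6)
  expect_error(f_prior_density(0.5, 0.5, 1), "alpha_pi")
})

test_that("segment clone assignment recovers the generating clone", {
  set.seed(21)
  model <- structure(list(f = c(0.6, 0.3), W = c(200, 200), C = 2),
                     class = "clone_model")
  # segment generated under clone 2's (f=0.3, N=3, M=1)
  f <- 0.3; N <- 3; M <- 1
  n_ex <- 200; n_het <- 50; depth <- 400
  rc <- rpois(n_ex, depth)
  rt <- rpois(n_ex, rc * (f * N + 2 * (1 - f)) / 2)
  seg_exons <- data.frame(depth_tumor = rt, depth_control = rc)
  phi <- expected_het_af(f, N, M)
  ht <- rpois(n_het, depth)
  on_minor <- runif(n_het) < 0.5
  hb <- rbinom(n_het, ht, ifelse(on_minor, phi, 1 - phi))
  seg_hets <- data.frame(r_b = hb, r_t = ht)
  ratio <- mean(rt / rc)
  baf <- mean(pmin(hb, ht - hb)) / mean(ht)
  states <- lapply(model$f, function(fi)
    copy_state_for_clone(fi, ratio, baf, model$C))
  expect_equal(assign_segment_clone(model, seg_exons, seg_hets, states), 2L)

  # K = 1 always assigns clone 1
  m1 <- structure(list(f = 0.6, W = 200, C = 2), class = "clone_model")
  expect_equal(assign_segment_clone(m1, seg_exons, seg_hets,
                                    states[1]), 1L)
})

test_that("variant clone assignment picks the matching allele fraction", {
  # diploid segment, phi_s per clone = f/2
  expect_equal(assign_variant_clone(50, 200, c(0.25, 0.10), c(100, 100)), 1L)
  expect_equal(assign_variant_clone(20, 200, c(0.25, 0.10), c(100, 100)), 2L)
})

test_that("variant clone recovery exceeds 90% at 500x", {
  set.seed(22)
  f <- c(0.6, 0.3, 0.1)
  phi <- f / 2 # diploid segment
  n <- 300
  truth <- sample(1:3, n, replace = TRUE)
  rt <- draw_depths(500, n, sigma_log = 0.3)
  rb <- rbinom(n, rt, phi[truth])
  got <- vapply(seq_len(n), function(i)
    assign_variant_clone(rb[i], rt[i], phi, rep(1e4, 3)), integer(1))
  expect_gt(mean(got == truth), 0.9)
})

test_that("fit_clone_model requires het variants", {
  ex <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                   depth_tumor = 100, depth_control = 100)
  expect_error(fit_clone_model(ex, ex[0, ]), "unidentifiable")
})

test_that("EM recovers f on a small single-clone cohort", {
  sp <- data.frame(n_exons = c(60L, 40L), N = c(2L, 1L), M = c(1L, 0L),
                   clone = c(0L, 1L))
  coh <- synthesize_cohort(fractions = 0.6, segments_spec = sp,
                           n_hets = 120, n_somatics = 30, n_artifacts = 0,
                           seed = 2)
  cfg <- default_config()
  cfg$K <- 1L
  fit <- suppressWarnings(fit_clone_model(cohort_exons(coh), cohort_hets(coh),
                                          cohort_somatics(coh), cfg))
  expect_lt(abs(fit$model$f - 0.6), 0.05)
  expect_true(all(diff(fit$objective_trace) >= -1e-9))
  # the loss segment is recovered as (1, 0)
  loss <- fit$segments[fit$segments$mean_ratio < 0.85, ]
  expect_true(nrow(loss) >= 1)
  expect_true(all(loss$N == 1 & loss$M == 0))
})

test_that("diluting the tumor lowers the fitted f linearly", {
  # mix a fixed f=0.8 tumor with a matched diploid profile
  sp <- data.frame(n_exons = c(60L, 40L), N = c(2L, 1L), M = c(1L, 0L),
                   clone = c(0L, 1L))
  coh <- synthesize_cohort(fractions = 0.8, segments_spec = sp,
                           n_hets = 120, n_somatics = 0, n_artifacts = 0,
                           seed = 4)
  norm <- synthesize_cohort(fractions = 0.01, segments_spec = sp,
                            n_hets = 120, n_somatics = 0, n_artifacts = 0,
                            seed = 4)
  cfg <- default_config()
  cfg$K <- 1L
  for (d in c(0.75, 0.5)) {
    mixed <- coh
    mixed$tumor$r_t <- round(d * coh$tumor$r_t + (1 - d) * norm$tumor$r_t)
    mixed$tumor$r_b <- round(d * coh$tumor$r_b + (1 - d) * norm$tumor$r_b)
    mixed$tumor$r_a <- mixed$tumor$r_t - mixed$tumor$r_b
    mixed$tumor_exons$depth_tumor <-
      d * coh$tumor_exons$depth_tumor + (1 - d) * norm$tumor_exons$depth_tumor
    fit <- suppressWarnings(fit_clone_model(cohort_exons(mixed),
                                            cohort_hets(mixed),
                                            config = cfg))
    expect_lt(abs(fit$model$f - 0.8 * d), 0.08)
  }
})
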