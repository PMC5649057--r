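#' Expected somatic allele fraction
#'
#' For a variant carried by the clone that also carries the copy number
#' alteration: `phi_S = f (N - M) / (f N + 2 (1 - f))` — the variant sits on
#' the major allele (all `N - M` copies) in the altered fraction `f` of cells,
#' over the total copies at the locus.
#'
#' @param f Sample fraction in \[0, 1\].
#' @param N Total copy number (>= 0).
#' @param M Minor allele copy number (`0 <= M <= N`).
#' @return Expected fraction in \[0, 1\]; the degenerate denominator
#'   (`f = 1, N = 0`) returns 0 with a warning.
#' @export
#' @examples
#' expected_somatic_af(0.5, 2, 1) # 0.25
expected_somatic_af <- function(f, N, M) {
  stopifnot(all(N >= 0), all(M >= 0), all(M <= N), all(f >= 0), all(f <= 1))
  den <- f * N + 2 * (1 - f)
  out <- ifelse(den > 0, f * (N - M) / pmax(den, .Machine$double.eps), 0)
  if (any(den == 0)) warning("degenerate denominator (f=1, N=0); returning 0")
  pmin(pmax(out, 0), 1)
}

#' Expected germline heterozygous allele fraction
#'
#' `phi_G = f M / N + (1 - f) / 2`: the minor allele contributes `M` of `N`
#' copies in the altered fraction and one of two copies in the diploid
#' remainder.
#'
#' @inheritParams expected_somatic_af
#' @return Expected fraction, clamped to \[0, 1\]. `N = 0` drops the `M/N`
#'   term with a warning.
#' @export
#' @examples
#' expected_het_af(0.6, 3, 1) # 0.4
expected_het_af <- function(f, N, M) {
  term <- ifelse(N > 0, f * M / pmax(N, 1), 0)
  if (any(N == 0)) warning("N = 0: het fraction reduces to (1 - f)/2")
  pmin(pmax(term + (1 - f) / 2, 0), 1)
}

#' Expected somatic allele fraction, piecewise over clones
#'
#' For clone `i` against a segment whose copy number alteration belongs to
#' clone `I_j` with state `(N_j, M_j)`:
#' * `i == I_j`: the variant rides the major allele —
#'   [expected_somatic_af()] at `(f_Ij, N_j, M_j)`.
#' * `i != I_j`, `N_j > 0`: the variant occupies exactly one chromosomal copy
#'   in fraction `f_i` — `f_i / (f_Ij N_j + 2 (1 - f_Ij))`.
#' * `i != I_j`, `N_j = 0`: the locus survives only outside the deleted
#'   fraction — `min(1 - f_Ij, f_i) / 2`.
#'
#' @param f_i Sample fraction of the variant's clone.
#' @param f_Ij Sample fraction of the segment's copy-number clone.
#' @param N_j,M_j Segment copy state.
#' @param same_clone Logical: is the variant's clone the segment's clone?
#' @return Expected fraction in \[0, 1\].
#' @export
expected_somatic_af_piecewise <- function(f_i, f_Ij, N_j, M_j, same_clone) {
  out <- numeric(length(f_i))
  same_clone <- rep_len(same_clone, length(f_i))
  N_j <- rep_len(N_j, length(f_i))
  M_j <- rep_len(M_j, length(f_i))
  f_Ij <- rep_len(f_Ij, length(f_i))
  s <- same_clone
  if (any(s)) out[s] <- expected_somatic_af(f_Ij[s], N_j[s], M_j[s])
  o1 <- !s & N_j > 0
  out[o1] <- f_i[o1] / (f_Ij[o1] * N_j[o1] + 2 * (1 - f_Ij[o1]))
  o2 <- !s & N_j == 0
  out[o2] <- pmin(1 - f_Ij[o2], f_i[o2]) / 2
  pmin(pmax(out, 0), 1)
}

#' Expected exon read depth
#'
#' `R_hat = (f R_Cn N + 2 (1 - f) R_Cn) / C`: the control depth scaled by the
#' mixture of `N` copies in the altered fraction and 2 copies elsewhere,
#' divided by the centering parameter `C` (about 2 for centered diploid data).
#'
#' @param f Clone sample fraction.
#' @param N Segment total copy number.
#' @param r_cn Control mean depth of the exon.
#' @param C Centering parameter (> 0).
#' @return Expected depth (>= 0).
#' @export
expected_exon_depth <- function(f, N, r_cn, C) {
  stopifnot(all(C > 0))
  (f * r_cn * N + 2 * (1 - f) * r_cn) / C
}

#' Copy state implied by segment summaries for one clone
#'
#' Inverts the depth model for the total copy number,
#' `N = max(round((C * ratio - 2 (1 - f)) / f), 0)`, and the het allele
#' fraction model for the minor copy number,
#' `M = round(N (Rhb/Rt - (1 - f)/2) / f)`, where `ratio` is the segment mean
#' tumor/control depth ratio and `Rhb/Rt` the segment mean het minor-allele
#' fraction. Rounding is half-away-from-zero; `M` is clamped to
#' `[0, N]` and folded to minor status (`M <= N - M`); `N` is capped at
#' `N_max`.
#'
#' @param f Clone sample fraction (> 0).
#' @param ratio Segment mean depth ratio `Rbar_T / Rbar_C`.
#' @param het_baf Segment mean folded het B-allele fraction
#'   (`Rbar_HB / Rbar_T`), or `NA` when the segment has no hets (then `M`
#'   defaults to the diploid minor state `floor(N/2)`).
#' @param C Centering parameter.
#' @param N_max Cap on the total copy number.
#' @return List with integer `N` and `M`.
#' @export
copy_state_for_clone <- function(f, ratio, het_baf, C, N_max = 8L) {
  stopifnot(f > 0)
  if (!is.finite(ratio) || ratio <= 0) return(list(N = 0L, M = 0L))
  N <- max(round_half_away((C * ratio - 2 * (1 - f)) / f), 0)
  N <- min(N, N_max)
  if (N == 0) return(list(N = 0L, M = 0L))
  if (is.na(het_baf)) {
    M <- floor(N / 2)
  } else {
    M <- round_half_away(N * (het_baf - (1 - f) / 2) / f)
    M <- min(max(M, 0), N)
    M <- min(M, N - M) # minor allele by definition
  }
  list(N = as.integer(N), M = as.integer(M))
}

#' Assign the copy-number clone of a segment
#'
#' Picks the clone maximizing the depth-ratio and het-allele-fraction
#' evidence, each term averaged over its observations:
#' `argmax_i [ mean exon log-lik + mean het log-lik ]`. Ties break toward the
#' larger sample fraction (clones are kept sorted by descending `f`).
#'
#' @param model A `clone_model` (fields `f`, `W`, `C`).
#' @param seg_exons Data frame of the segment's exons (`depth_tumor`,
#'   `depth_control`).
#' @param seg_hets Data frame of the segment's het sites (`r_b`, `r_t`;
#'   unfolded — the likelihood marginalizes the parental phase), possibly
#'   empty.
#' @param states Per-clone list of `(N, M)` from [copy_state_for_clone()].
#' @return Integer clone index.
#' @export
assign_segment_clone <- function(model, seg_exons, seg_hets, states) {
  K <- length(model$f)
  score <- vapply(seq_len(K), function(i) {
    st <- states[[i]]
    rhat <- expected_exon_depth(model$f[i], st$N, seg_exons$depth_control,
                                model$C)
    s <- mean(exon_depth_likelihood(seg_exons$depth_tumor, rhat, log = TRUE))
    if (nrow(seg_hets) > 0) {
      phi <- expected_het_af(model$f[i], st$N, st$M)
      s <- s + mean(het_af_loglik_phased(seg_hets$r_b, seg_hets$r_t, phi,
                                         model$W[i]))
    }
    s
  }, numeric(1))
  which.max(score) # first max = largest f under descending sort
}

#' Assign the clone of a somatic variant
#'
#' `argmax_i` of the folded beta-binomial likelihood at the clone's piecewise
#' expected somatic fraction; ties break toward larger `f`.
#'
#' @param r_b,r_t Variant B-allele and total counts.
#' @param phi_s Numeric vector of per-clone expected somatic fractions for the
#'   variant's segment.
#' @param W Per-clone dispersion weights.
#' @param unfolded Disable the beta-binomial fold.
#' @return Integer clone index.
#' @export
assign_variant_clone <- function(r_b, r_t, phi_s, W, unfolded = FALSE) {
  ll <- vapply(seq_along(phi_s), function(i) {
    somatic_af_likelihood(r_b, r_t, phi_s[i], W[i], unfolded = unfolded,
                          log = TRUE)
  }, numeric(1))
  which.max(ll)
}

# ---- EM fit -----------------------------------------------------------------

#' Fit clone fractions, dispersion and centering by EM
#'
#' Alternates an E-step (per-clone copy states from [copy_state_for_clone()],
#' segment clone assignment, piecewise somatic fractions, variant clone
#' assignment) with an M-step (bounded Nelder-Mead maximization of the
#' normalized log-likelihood-plus-priors objective over `f`, `W`, `C` with the
#' integer states held fixed). The whole loop is run from three deterministic
#' starts and the best final objective wins. The recorded objective trace is
#' non-decreasing: an iteration that would decrease the objective reverts and
#' stops.
#'
#' The objective is the sum of exon Poisson log-likelihoods, het and somatic
#' beta-binomial log-likelihoods, copy-state log-priors per exon, and Beta
#' log-priors on the sample fractions of somatic variants and copy-altered
#' exons, normalized by `3 X + X* + V + 2 Y` (exons, copy-altered exons, hets,
#' somatics).
#'
#' @param exons Data frame `chrom, start, end, depth_tumor, depth_control`.
#' @param hets Counts data frame of likely germline heterozygous sites (the
#'   het likelihood marginalizes over the unknown parental phase, so `r_b`
#'   stays unfolded; only the copy-state inversion uses the folded mean BAF).
#' @param somatics Counts data frame of likely somatic sites (may be empty).
#' @param config A `lumos_config`.
#' @param segments Optional precomputed segmentation (else computed here).
#' @return A list: `model` (`clone_model` with `f`, `W`, `C`), `segments`
#'   (with per-segment `clone`, `N`, `M`, `f`), `het_assign`, `somatic_assign`
#'   (per-variant segment, clone and expected fraction), `objective_trace`,
#'   `converged`.
#' @export
fit_clone_model <- function(exons, hets, somatics = NULL,
                            config = default_config(), segments = NULL) {
  if (is.null(hets) || nrow(hets) == 0) {
    stop("no heterozygous variants: clone model is unidentifiable")
  }
  if (is.null(somatics)) somatics <- empty_counts()
  exons <- exons[exons$depth_control > 0, , drop = FALSE]
  # median-center the depth ratio so a mostly-diploid genome sits near 1;
  # the centering parameter C absorbs the residual shift
  scale <- stats::median(exons$depth_tumor / exons$depth_control)
  if (is.finite(scale) && scale > 0) exons$depth_tumor <- exons$depth_tumor / scale
  if (is.null(segments)) {
    segments <- segment_depth_ratio(exons, config$alpha_seg,
                                    config$min_seg_width)
  }
  dat <- index_em_data(exons, hets, somatics, segments)

  K <- config$K
  starts <- list(
    seq(0.7, 0.2, length.out = K),
    seq(0.9, 0.35, length.out = K),
    seq(0.5, 0.1, length.out = K)
  )
  starts <- lapply(starts, function(f) {
    sort(pmin(pmax(f, config$f_bounds[1] + 1e-3),
              config$f_bounds[2] - 1e-3), decreasing = TRUE)
  })
  best <- NULL
  for (f0 in starts) {
    theta <- list(f = f0, W = rep(30, K), C = 2)
    res <- em_loop(theta, dat, config)
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  if (K > 1 && any(abs(diff(best$model$f)) < 1e-3)) {
    warning("duplicate clone fractions after convergence")
  }
  best
}

# precompute segment membership of exons/hets/somatics
index_em_data <- function(exons, hets, somatics, segments) {
  seg_of <- function(chrom, pos) {
    idx <- rep(NA_integer_, length(pos))
    for (j in seq_len(nrow(segments))) {
      hit <- chrom == segments$chrom[j] & pos > segments$start[j] &
        pos <= segments$end[j]
      idx[hit] <- j
    }
    idx
  }
  exon_seg <- seg_of(exons$chrom, exons$end) # exon end is 1-based-ish anchor
  # exons were segmented in order; recover via first/last indices per chrom
  exon_seg <- integer(nrow(exons))
  for (j in seq_len(nrow(segments))) {
    rows <- which(exons$chrom == segments$chrom[j])
    exon_seg[rows[segments$first_exon[j]:segments$last_exon[j]]] <- j
  }
  hets <- hets[order(hets$chrom, hets$pos), , drop = FALSE]
  somatics <- somatics[order(somatics$chrom, somatics$pos), , drop = FALSE]
  het_seg <- seg_of(hets$chrom, hets$pos)
  som_seg <- seg_of(somatics$chrom, somatics$pos)
  # sites outside any segment are treated as diploid background later
  hets$r_b_fold <- pmin(hets$r_b, hets$r_t - hets$r_b)
  seg_stats <- lapply(seq_len(nrow(segments)), function(j) {
    e <- exons[exon_seg == j, , drop = FALSE]
    h <- hets[!is.na(het_seg) & het_seg == j, , drop = FALSE]
    list(
      ratio = mean(e$depth_tumor / e$depth_control),
      rbar_t = mean(e$depth_tumor),
      het_baf = if (nrow(h) > 0) mean(h$r_b_fold) / mean(h$r_t) else NA_real_,
      exons = e, hets = h, n_exons = nrow(e)
    )
  })
  list(exons = exons, hets = hets, somatics = somatics, segments = segments,
       exon_seg = exon_seg, het_seg = het_seg, som_seg = som_seg,
       seg_stats = seg_stats)
}

em_loop <- function(theta, dat, config) {
  prev_obj <- -Inf
  trace <- numeric()
  state <- NULL
  best <- NULL
  for (it in seq_len(config$max_em_iters)) {
    new_state <- e_step(theta, dat, config)
    new_theta <- m_step(theta, new_state, dat, config)
    obj <- em_objective(new_theta, new_state, dat, config)
    if (obj < prev_obj - 1e-9) break # revert: keep previous state
    theta <- new_theta
    state <- new_state
    trace <- c(trace, obj)
    if (obj - prev_obj < config$em_tol && it > 1) {
      prev_obj <- obj
      break
    }
    prev_obj <- obj
  }
  finalize_em(theta, state, dat, config, trace)
}

e_step <- function(theta, dat, config) {
  K <- length(theta$f)
  G <- nrow(dat$segments)
  states <- vector("list", G)
  I_j <- integer(G)
  model <- structure(list(f = theta$f, W = theta$W, C = theta$C),
                     class = "clone_model")
  for (j in seq_len(G)) {
    ss <- dat$seg_stats[[j]]
    per_clone <- lapply(seq_len(K), function(i) {
      copy_state_for_clone(theta$f[i], ss$ratio, ss$het_baf, theta$C,
                           config$N_max)
    })
    I_j[j] <- assign_segment_clone(model, ss$exons, ss$hets, per_clone)
    states[[j]] <- per_clone
  }
  seg_N <- vapply(seq_len(G), function(j) states[[j]][[I_j[j]]]$N, integer(1))
  seg_M <- vapply(seq_len(G), function(j) states[[j]][[I_j[j]]]$M, integer(1))
  # somatic clone assignment under the piecewise expected fractions
  Y <- nrow(dat$somatics)
  I_s <- integer(Y)
  if (Y > 0) {
    for (s in seq_len(Y)) {
      j <- dat$som_seg[s]
      if (is.na(j)) {
        phi <- expected_somatic_af_piecewise(
          theta$f, theta$f[1], 2L, 1L, seq_len(K) == 1L)
      } else {
        phi <- expected_somatic_af_piecewise(
          theta$f, theta$f[I_j[j]], seg_N[j], seg_M[j], seq_len(K) == I_j[j])
      }
      I_s[s] <- assign_variant_clone(dat$somatics$r_b[s], dat$somatics$r_t[s],
                                     phi, theta$W,
                                     unfolded = config$unfolded_somatic_bb)
    }
  }
  list(I_j = I_j, seg_N = seg_N, seg_M = seg_M, I_s = I_s)
}

# objective with integer states fixed; continuous in (f, W, C)
em_objective <- function(theta, state, dat, config) {
  f <- theta$f; W <- theta$W; C <- theta$C
  segs <- dat$segments
  G <- nrow(segs)
  X <- nrow(dat$exons)
  V <- nrow(dat$hets)
  Y <- nrow(dat$somatics)

  exon_ll <- 0
  prior_ll <- 0
  x_star <- 0L
  cn_pri <- config$cn_priors # P(N=0..3), P(N>=4)
  m_pri <- config$m_priors # P(M=0), P(M=1), P(M>=2)
  for (j in seq_len(G)) {
    ss <- dat$seg_stats[[j]]
    i <- state$I_j[j]
    N <- state$seg_N[j]; M <- state$seg_M[j]
    rhat <- expected_exon_depth(f[i], N, ss$exons$depth_control, C)
    exon_ll <- exon_ll +
      sum(exon_depth_likelihood(ss$exons$depth_tumor, rhat, log = TRUE))
    prior_ll <- prior_ll + ss$n_exons *
      (log(cn_pri[min(N, 4) + 1]) + log(m_pri[min(M, 2) + 1]))
    if (!(N == 2L && M == 1L)) {
      x_star <- x_star + ss$n_exons
      prior_ll <- prior_ll + ss$n_exons *
        f_prior_density(f[i], config$f_pi, config$alpha_pi, log = TRUE)
    }
  }
  het_ll <- 0
  if (V > 0) {
    hj <- dat$het_seg
    i_h <- ifelse(is.na(hj), 1L, state$I_j[pmax(hj, 1L)])
    N_h <- ifelse(is.na(hj), 2L, state$seg_N[pmax(hj, 1L)])
    M_h <- ifelse(is.na(hj), 1L, state$seg_M[pmax(hj, 1L)])
    phi <- expected_het_af(f[i_h], N_h, M_h)
    het_ll <- sum(het_af_loglik_phased(dat$hets$r_b, dat$hets$r_t, phi,
                                       W[i_h]))
  }
  som_ll <- 0
  if (Y > 0) {
    sj <- dat$som_seg
    i_cn <- ifelse(is.na(sj), 1L, state$I_j[pmax(sj, 1L)])
    N_s <- ifelse(is.na(sj), 2L, state$seg_N[pmax(sj, 1L)])
    M_s <- ifelse(is.na(sj), 1L, state$seg_M[pmax(sj, 1L)])
    phi <- expected_somatic_af_piecewise(f[state$I_s], f[i_cn], N_s, M_s,
                                         state$I_s == i_cn)
    som_ll <- sum(somatic_af_likelihood(dat$somatics$r_b, dat$somatics$r_t,
                                        phi, W[state$I_s],
                                        unfolded = config$unfolded_somatic_bb,
                                        log = TRUE))
    prior_ll <- prior_ll + sum(f_prior_density(f[state$I_s], config$f_pi,
                                               config$alpha_pi, log = TRUE))
  }
  (exon_ll + het_ll + som_ll + prior_ll) / (3 * X + x_star + V + 2 * Y)
}

m_step <- function(theta, state, dat, config) {
  K <- length(theta$f)
  fb <- config$f_bounds; wb <- config$W_bounds; cb <- config$C_bounds
  to_unit <- function(x, b) stats::qlogis((x - b[1]) / (b[2] - b[1]))
  from_unit <- function(z, b) b[1] + (b[2] - b[1]) * stats::plogis(z)
  pack <- function(th) c(to_unit(th$f, fb), to_unit(th$W, wb),
                         to_unit(th$C, cb))
  unpack <- function(p) {
    f <- from_unit(p[seq_len(K)], fb)
    ord <- order(f, decreasing = TRUE) # identifiability
    list(f = f[ord], W = from_unit(p[K + seq_len(K)], wb)[ord],
         C = from_unit(p[2 * K + 1], cb))
  }
  negobj <- function(p) -em_objective(unpack(p), state, dat, config)
  # restart from the incoming point and deterministic alternatives; the best
  # candidate wins, and never hand back something worse than the incoming theta
  starts <- list(theta,
                 list(f = theta$f, W = rep(30, K), C = 2),
                 list(f = pmin(pmax(seq(0.7, 0.2, length.out = K),
                                    fb[1] + 1e-3), fb[2] - 1e-3),
                      W = rep(30, K), C = theta$C))
  best <- theta
  best_obj <- em_objective(theta, state, dat, config)
  for (st in starts) {
    opt <- stats::optim(pack(st), negobj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    cand <- unpack(opt$par)
    obj <- em_objective(cand, state, dat, config)
    if (obj > best_obj) {
      best <- cand
      best_obj <- obj
    }
  }
  best
}

finalize_em <- function(theta, state, dat, config, trace) {
  segs <- dat$segments
  G <- nrow(segs)
  segs$clone <- state$I_j
  segs$f <- theta$f[state$I_j]
  segs$N <- state$seg_N
  segs$M <- state$seg_M
  Y <- nrow(dat$somatics)
  som_assign <- NULL
  if (Y > 0) {
    sj <- dat$som_seg
    i_cn <- ifelse(is.na(sj), 1L, state$I_j[pmax(sj, 1L)])
    N_s <- ifelse(is.na(sj), 2L, state$seg_N[pmax(sj, 1L)])
    M_s <- ifelse(is.na(sj), 1L, state$seg_M[pmax(sj, 1L)])
    phi <- expected_somatic_af_piecewise(theta$f[state$I_s], theta$f[i_cn],
                                         N_s, M_s, state$I_s == i_cn)
    som_assign <- data.frame(chrom = dat$somatics$chrom,
                             pos = dat$somatics$pos,
                             segment = sj, clone = state$I_s, exp_af = phi)
  }
  model <- structure(list(f = theta$f, W = theta$W, C = theta$C,
                          K = length(theta$f)),
                     class = "clone_model")
  list(model = model, segments = segs, somatic_assign = som_assign,
       het_seg = dat$het_seg, objective = utils::tail(trace, 1),
       objective_trace = trace,
       converged = length(trace) < config$max_em_iters)
}

#' @export
print.clone_model <- function(x, ...) {
  cat("clone model: K =", x$K, "\n")
  cat("  f =", paste(formatC(x$f, digits = 3, format = "f"),
                     collapse = ", "), "\n")
  cat("  W =", paste(formatC(x$W, digits = 1, format = "f"),
                     collapse = ", "), "\n")
  cat("  C =", formatC(x$C, digits = 3, format = "f"), "\n")
  invisible(x)
}
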