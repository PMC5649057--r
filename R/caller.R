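#' Prior probabilities of the four site models
#'
#' `pi_s = rho (omega + 1)` from the cancer-database count `omega`;
#' germline priors from Hardy-Weinberg scaled by `1 - pi_s`; `pi_O` is the
#' complement. Sites whose population B-allele frequency exceeds
#' `F_max_somatic` get `pi_s = 0` (too common to be somatic).
#'
#' @param F_A,F_B Population allele frequencies (vectorized).
#' @param omega Cancer-database mutation count at the position.
#' @param config A `lumos_config`.
#' @param is_indel Logical; selects `rho_indel` over `rho_snv`.
#' @return Data frame with columns `s`, `ab`, `aa`, `o`, rows summing to 1.
#' @export
#' @examples
#' call_priors(1 - 7.14e-5, 7.14e-5, 0, default_config())$s # 1e-5
call_priors <- function(F_A, F_B, omega, config = default_config(),
                        is_indel = FALSE) {
  if (any(omega < 0)) stop("omega must be >= 0")
  m <- max(length(F_A), length(F_B), length(omega), length(is_indel))
  rho <- ifelse(rep_len(is_indel, m), config$rho_indel, config$rho_snv)
  pi_s <- rho * (rep_len(omega, m) + 1)
  F_A <- rep_len(F_A, m)
  F_B <- rep_len(F_B, m)
  pi_s[F_B > config$F_max_somatic] <- 0
  pi_ab <- 2 * F_A * F_B * (1 - pi_s)
  pi_aa <- F_A^2 * (1 - pi_s)
  pi_o <- 1 - pi_s - pi_ab - pi_aa
  bad <- pi_o < 0
  if (any(bad)) {
    warning("renormalizing germline priors at ", sum(bad), " site(s)")
    scale <- (1 - pi_s[bad]) / (pi_ab[bad] + pi_aa[bad])
    pi_ab[bad] <- pi_ab[bad] * scale
    pi_aa[bad] <- pi_aa[bad] * scale
    pi_o[bad] <- 0
  }
  data.frame(s = pi_s, ab = pi_ab, aa = pi_aa, o = pi_o)
}

#' Likelihoods of the four site models
#'
#' * `P(D|S)`: max over clones of the folded beta-binomial at the clone's
#'   piecewise expected somatic fraction.
#' * `P(D|G_AB)`: beta-binomial at the segment clone's expected het fraction.
#' * `P(D|G_AA)`: beta-binomial of the A counts with the B base-call error
#'   rate `10^(-qb_b/10)`.
#' * `P(D|O)`: beta-binomial of the residual (non-A, non-B) counts with the A
#'   base-call error rate.
#'
#' The dispersion for the `G_AA`/`O`/`G_AB` terms is the `W` of the clone that
#' maximizes `P(D|S)`.
#'
#' @param sites Counts data frame.
#' @param model A `clone_model`.
#' @param seg_info Data frame aligned with `sites`: columns `clone_cn` (the
#'   segment's copy-number clone), `N`, `M`. Sites outside all segments should
#'   already carry the diploid fallback (`clone_cn` of the largest-`f` clone,
#'   `N = 2`, `M = 1`).
#' @param config A `lumos_config`.
#' @return List with log-likelihood vectors `s`, `ab`, `aa`, `o`, plus
#'   `clone` (argmax somatic clone) and `exp_af`.
#' @export
model_likelihoods <- function(sites, model, seg_info,
                              config = default_config()) {
  n <- nrow(sites)
  K <- model$K
  ll_s_k <- matrix(-Inf, n, K)
  phi_k <- matrix(NA_real_, n, K)
  for (i in seq_len(K)) {
    phi <- expected_somatic_af_piecewise(
      rep(model$f[i], n), model$f[seg_info$clone_cn],
      seg_info$N, seg_info$M, i == seg_info$clone_cn)
    phi_k[, i] <- phi
    ll_s_k[, i] <- somatic_af_likelihood(sites$r_b, sites$r_t, phi,
                                         model$W[i],
                                         unfolded = config$unfolded_somatic_bb,
                                         log = TRUE)
  }
  best <- max.col(ll_s_k, ties.method = "first")
  idx <- cbind(seq_len(n), best)
  ll_s <- ll_s_k[idx]
  W_site <- model$W[best]
  phi_g <- expected_het_af(model$f[seg_info$clone_cn], seg_info$N, seg_info$M)
  ll_ab <- het_af_loglik_phased(sites$r_b, sites$r_t, phi_g,
                                model$W[seg_info$clone_cn])
  err_b <- pmin(pmax(10^(-sites$qb_b / 10), 1e-6), 1 - 1e-6)
  err_a <- pmin(pmax(10^(-sites$qb_a / 10), 1e-6), 1 - 1e-6)
  ll_aa <- betabinomial_pmf(sites$r_a, sites$r_t,
                            W_site * (1 - err_b), W_site * err_b, log = TRUE)
  ll_o <- betabinomial_pmf(sites$r_t - sites$r_a - sites$r_b, sites$r_t,
                           W_site * (1 - err_a), W_site * err_a, log = TRUE)
  list(s = ll_s, ab = ll_ab, aa = ll_aa, o = ll_o,
       clone = best, exp_af = phi_k[idx])
}

#' Four-way posterior probabilities
#'
#' Bayes rule over the somatic, germline het, germline hom and other models
#' with one shared denominator. A zero denominator yields all-`NA` posteriors
#' (the site is uncallable).
#'
#' @param lik List of log-likelihoods from [model_likelihoods()].
#' @param priors Data frame from [call_priors()].
#' @return Data frame `p_somatic, p_germline_het, p_hom, p_other`; rows sum
#'   to 1 where defined.
#' @export
somatic_posterior <- function(lik, priors) {
  lp <- cbind(lik$s + log(priors$s), lik$ab + log(priors$ab),
              lik$aa + log(priors$aa), lik$o + log(priors$o))
  lp[is.nan(lp)] <- -Inf # log(0) priors
  den <- row_logsumexp(lp)
  out <- exp(lp - den)
  out[!is.finite(den), ] <- NA_real_
  data.frame(p_somatic = out[, 1], p_germline_het = out[, 2],
             p_hom = out[, 3], p_other = out[, 4])
}

#' Classify a site from its posteriors
#'
#' `SOMATIC` iff `P(S|D) >= T_somatic`; `GERMLINE_HET` / `GERMLINE_HOM` iff
#' the corresponding posterior reaches `T_germline`; `OTHER` iff the other
#' posterior reaches `T_germline`; otherwise `UNCALLED`.
#'
#' @param post Data frame from [somatic_posterior()].
#' @param config A `lumos_config`.
#' @return Character vector of labels.
#' @export
classify <- function(post, config = default_config()) {
  lab <- rep("UNCALLED", nrow(post))
  lab[!is.na(post$p_other) & post$p_other >= config$T_germline] <- "OTHER"
  lab[!is.na(post$p_hom) & post$p_hom >= config$T_germline] <- "GERMLINE_HOM"
  lab[!is.na(post$p_germline_het) &
        post$p_germline_het >= config$T_germline] <- "GERMLINE_HET"
  lab[!is.na(post$p_somatic) & post$p_somatic >= config$T_somatic] <- "SOMATIC"
  lab
}

# map sites to segments; diploid fallback outside all segments
site_segment_info <- function(sites, segments, model) {
  n <- nrow(sites)
  seg_idx <- rep(NA_integer_, n)
  for (j in seq_len(nrow(segments))) {
    hit <- sites$chrom == segments$chrom[j] & sites$pos > segments$start[j] &
      sites$pos <= segments$end[j]
    seg_idx[hit] <- j
  }
  out <- data.frame(
    segment = seg_idx,
    clone_cn = ifelse(is.na(seg_idx), 1L, segments$clone[pmax(seg_idx, 1L)]),
    N = ifelse(is.na(seg_idx), 2L, segments$N[pmax(seg_idx, 1L)]),
    M = ifelse(is.na(seg_idx), 1L, segments$M[pmax(seg_idx, 1L)])
  )
  if (any(is.na(seg_idx))) {
    warning(sum(is.na(seg_idx)),
            " site(s) outside all segments treated as diploid")
  }
  out
}

#' Run the full tumor-only caller
#'
#' Steps two to four: score site quality, seed likely germline and somatic
#' sets from database frequencies, then alternate the clone-model EM with
#' four-way classification until the called set memberships stabilize (or
#' `max_outer_iters`).
#'
#' @param tumor Counts data frame for the tumor sample.
#' @param panel A `lumos_panel` built from unmatched controls.
#' @param tumor_exons Data frame `chrom, start, end, depth_tumor` of tumor
#'   mean exon depths (control depths come from the panel).
#' @param priors Priors table ([load_priors()]), or `NULL` (all sites then get
#'   the unseen-allele frequency floor).
#' @param config A `lumos_config`.
#' @param use_qc Set `FALSE` to skip the quality model (all sites treated as
#'   high tier), e.g. for synthetic reads carrying no artifact signal.
#' @return A list: `calls` (one row per input site: posteriors, label, clone,
#'   expected AF, copy state, PT/PV, FILTER), `model`, `segments`,
#'   `iterations`, plus a `report` list (clone fractions, `C`, `W`, iteration
#'   count, objective trace).
#' @export
run_caller <- function(tumor, panel, tumor_exons, priors = NULL,
                       config = default_config(), use_qc = TRUE) {
  tumor <- validate_counts(tumor, "tumor counts")
  tumor <- tumor[order(tumor$chrom, tumor$pos), , drop = FALSE]
  rownames(tumor) <- NULL
  n <- nrow(tumor)
  if (use_qc) {
    qc <- tryCatch(score_sites(tumor, panel, config), error = function(e) {
      warning("quality model unavailable (", conditionMessage(e),
              "); all sites treated as high tier")
      data.frame(pt = rep(NA_real_, n), pv = rep(NA_real_, n), tier = "high")
    })
  } else {
    qc <- data.frame(pt = rep(NA_real_, n), pv = rep(NA_real_, n),
                     tier = rep("high", n))
  }
  exons <- merge_panel_depths(tumor_exons, panel)
  fb <- lookup_f_b(tumor, priors, config)
  omega <- lookup_omega(tumor, priors)
  known <- lookup_known_germline(tumor, priors)
  fa <- pmax(1 - fb, 0)
  baf <- ifelse(tumor$r_t > 0, tumor$r_b / tumor$r_t, 0)
  eligible <- qc$tier == "high" & tumor$r_t > 0

  # initial seeds from database frequencies
  som_set <- eligible & fb <= config$F_max_somatic & tumor$r_b >= 3 &
    baf <= 0.95
  germ_set <- eligible & fb >= 0.01 & baf >= 0.1 & baf <= 0.9
  if (!any(germ_set)) stop("no candidate germline heterozygous sites to seed")

  fit <- NULL
  iterations <- 0L
  for (it in seq_len(config$max_outer_iters)) {
    iterations <- it
    fit <- fit_clone_model(exons, tumor[germ_set, , drop = FALSE],
                           tumor[som_set, , drop = FALSE], config)
    seg_info <- site_segment_info(tumor, fit$segments, fit$model)
    lik <- model_likelihoods(tumor, fit$model, seg_info, config)
    pri <- call_priors(fa, fb, omega, config, tumor$is_indel > 0)
    post <- somatic_posterior(lik, pri)
    lab <- classify(post, config)
    new_som <- eligible & lab == "SOMATIC"
    new_germ <- eligible & lab == "GERMLINE_HET"
    if (!any(new_germ)) new_germ <- germ_set # keep model identifiable
    stable <- identical(new_som, som_set) && identical(new_germ, germ_set)
    som_set <- new_som
    germ_set <- new_germ
    if (stable) break
  }
  if (iterations == config$max_outer_iters) {
    warning("outer loop hit max_outer_iters without stable membership")
  }
  lab[qc$tier != "high"] <- "UNCALLED"
  filter <- ifelse(qc$tier == "artifact", "REJECT",
                   ifelse(qc$tier == "low", "LowQual",
                          ifelse(lab == "UNCALLED", "LowQual", "PASS")))
  calls <- data.frame(
    chrom = tumor$chrom, pos = tumor$pos, ref = tumor$ref, alt = tumor$alt,
    p_somatic = post$p_somatic, p_germline_het = post$p_germline_het,
    p_hom = post$p_hom, p_other = post$p_other,
    label = lab, clone = lik$clone, exp_af = lik$exp_af,
    cn = seg_info$N, minor_cn = seg_info$M,
    pt = qc$pt, pv = qc$pv, filter = filter,
    known_germline = known,
    stringsAsFactors = FALSE
  )
  list(calls = calls, model = fit$model, segments = fit$segments,
       iterations = iterations,
       report = list(f = fit$model$f, W = fit$model$W, C = fit$model$C,
                     iterations = iterations,
                     objective_trace = fit$objective_trace))
}

merge_panel_depths <- function(tumor_exons, panel) {
  key_t <- paste(tumor_exons$chrom, tumor_exons$start, tumor_exons$end)
  key_p <- paste(panel$exons$chrom, panel$exons$start, panel$exons$end)
  idx <- match(key_t, key_p)
  if (any(is.na(idx))) stop("tumor exons missing from the panel")
  data.frame(chrom = tumor_exons$chrom, start = tumor_exons$start,
             end = tumor_exons$end, depth_tumor = tumor_exons$depth_tumor,
             depth_control = panel$exons$depth_mean[idx],
             stringsAsFactors = FALSE)
}

lookup_omega <- function(df, priors) {
  if (is.null(priors)) return(rep(0, nrow(df)))
  idx <- match(paste(df$chrom, df$pos, df$alt),
               paste(priors$chrom, priors$pos, priors$allele))
  out <- priors$omega[idx]
  out[is.na(out)] <- 0
  out
}

lookup_known_germline <- function(df, priors) {
  if (is.null(priors)) return(rep(FALSE, nrow(df)))
  idx <- match(paste(df$chrom, df$pos, df$alt),
               paste(priors$chrom, priors$pos, priors$allele))
  out <- priors$known_germline[idx] > 0
  out[is.na(out)] <- FALSE
  out
}
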