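#' Per-site quality metrics
#'
#' Computes the 16 site-level quality metrics used to seed and score the
#' quality model: panel reliability, depth, allele fraction, base/mapping
#' qualities and their A-B differences, strand balance of the B-supporting
#' reads, and context proxies carried on the counts table.
#'
#' @param sites Counts data frame (see [load_counts()]).
#' @param panel A `lumos_panel` covering the sites.
#' @return A numeric matrix with one row per site and 16 named columns;
#'   guaranteed NaN-free (degenerate counts are imputed to 0).
#' @export
compute_metrics <- function(sites, panel) {
  pl <- panel_lookup(panel, sites)
  nb <- sites$strand_b_fwd + sites$strand_b_rev
  # strand-bias z score: |fwd - rev| / sqrt(n); 0 when balanced
  strand_z <- ifelse(nb > 0,
                     abs(sites$strand_b_fwd - sites$strand_b_rev) / sqrt(nb),
                     0)
  fwd_frac <- ifelse(nb > 0, sites$strand_b_fwd / nb, 0.5)
  baf <- ifelse(sites$r_t > 0, sites$r_b / sites$r_t, 0)
  indel_len <- abs(nchar(sites$alt) - nchar(sites$ref))
  m <- cbind(
    panel_phred = pl$phred,
    log_depth = log10(sites$r_t + 1),
    baf = baf,
    qb_a = sites$qb_a,
    qb_b = sites$qb_b,
    qm_a = sites$qm_a,
    qm_b = sites$qm_b,
    strand_z = strand_z,
    fwd_frac = fwd_frac,
    softclip_frac = sites$softclip_frac,
    indel_len = indel_len,
    qm_diff = sites$qm_a - sites$qm_b,
    qb_diff = sites$qb_a - sites$qb_b,
    low_mapq_frac = sites$low_mapq_frac,
    panel_unreliable = pl$mean_unreliable,
    homopolymer = as.numeric(sites$homopolymer)
  )
  m[!is.finite(m)] <- 0
  m
}

#' Label sites for quality-model training
#'
#' A site enters the PASS training group only if it passes *all* PASS
#' thresholds, and the REJECT group if it meets *any* REJECT criterion;
#' REJECT wins on conflict. Everything else is UNLABELED.
#'
#' @param metrics Metric matrix from [compute_metrics()].
#' @param config A `lumos_config` carrying `qc_pass` / `qc_reject` thresholds.
#' @return Factor of labels in `{PASS, REJECT, UNLABELED}`.
#' @export
label_training_sites <- function(metrics, config = default_config()) {
  p <- config$qc_pass
  r <- config$qc_reject
  pass <- metrics[, "qm_a"] >= p$qm_a &
    metrics[, "qm_b"] >= p$qm_b &
    metrics[, "qb_a"] >= p$qb_a &
    metrics[, "qb_b"] >= p$qb_b &
    metrics[, "strand_z"] <= p$strand_z_max &
    metrics[, "panel_phred"] >= p$panel_phred
  reject <- metrics[, "qm_b"] < r$qm_b |
    metrics[, "qb_b"] < r$qb_b |
    metrics[, "panel_phred"] < r$panel_phred |
    metrics[, "strand_z"] > r$strand_z_min
  labels <- rep("UNLABELED", nrow(metrics))
  labels[pass] <- "PASS"
  labels[reject] <- "REJECT" # any-of REJECT overrides PASS
  if (!any(labels == "PASS") || !any(labels == "REJECT")) {
    stop("empty PASS or REJECT training group; relax qc_pass/qc_reject ",
         "thresholds in the config")
  }
  factor(labels, levels = c("PASS", "REJECT", "UNLABELED"))
}

#' Fit a quadratic discriminant quality model
#'
#' Gaussian class-conditional model with per-class mean and covariance and
#' class priors taken from the training proportions. Singular covariances
#' (constant metrics, tiny classes) are ridge-regularized with
#' `lambda = 1e-6 * trace / d` (escalated until positive definite) with a
#' warning.
#'
#' @param metrics Metric matrix.
#' @param labels Two-class character/factor vector aligned with `metrics`
#'   (rows labeled anything else are ignored).
#' @param classes Length-2 character vector naming the positive and negative
#'   class.
#' @return A `quality_model` with means, covariance inverses, log
#'   determinants, and log priors.
#' @export
fit_quality_model <- function(metrics, labels,
                              classes = c("PASS", "REJECT")) {
  labels <- as.character(labels)
  keep <- labels %in% classes
  x <- metrics[keep, , drop = FALSE]
  y <- labels[keep]
  d <- ncol(x)
  fit_class <- function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    if (nrow(xi) < 2) stop("class ", cl, " has fewer than 2 training sites")
    mu <- colMeans(xi)
    sigma <- stats::cov(xi)
    lambda <- 1e-6 * sum(diag(sigma)) / d
    if (lambda <= 0) lambda <- 1e-8
    ok <- FALSE
    tries <- 0
    while (!ok && tries < 12) {
      ev <- suppressWarnings(min(eigen(sigma, symmetric = TRUE,
                                       only.values = TRUE)$values))
      if (is.finite(ev) && ev > 1e-10 * max(1, sum(diag(sigma)) / d)) {
        ok <- TRUE
      } else {
        sigma <- sigma + lambda * diag(d)
        lambda <- lambda * 10
        tries <- tries + 1
      }
    }
    if (tries > 0) {
      warning("covariance for class ", cl, " was ridge-regularized")
    }
    ch <- chol(sigma)
    list(mu = mu,
         inv = chol2inv(ch),
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(mean(y == cl)))
  }
  mods <- lapply(classes, fit_class)
  names(mods) <- classes
  structure(list(classes = classes, class_models = mods, d = d),
            class = "quality_model")
}

# log Gaussian density under one class of a quality model
qda_logdens <- function(mod, x) {
  xc <- sweep(x, 2, mod$mu)
  q <- rowSums((xc %*% mod$inv) * xc)
  -0.5 * (q + mod$logdet + length(mod$mu) * log(2 * pi)) + mod$logprior
}

#' Posterior of the first class under a quality model
#'
#' @param model A `quality_model`.
#' @param metrics Metric matrix.
#' @return Numeric vector of posterior probabilities of `model$classes[1]`.
#' @export
quality_posterior <- function(model, metrics) {
  l1 <- qda_logdens(model$class_models[[1]], metrics)
  l2 <- qda_logdens(model$class_models[[2]], metrics)
  1 / (1 + exp(l2 - l1))
}

#' Two-tier quality scores
#'
#' Fits two quadratic discriminant models per variant class (SNV and indel
#' separately): a strict model trained PASS vs REJECT whose PASS posterior is
#' `PT`, and a lenient model trained (PASS + UNLABELED) vs REJECT whose
#' non-artifact posterior is `PV`. Sites tier as: high quality
#' (`PT > T_pass`, eligible for calling), low quality (`PV > T_pass` only;
#' reported but not used in the EM), artifact (the rest; dropped).
#'
#' @param sites Counts data frame.
#' @param panel A `lumos_panel`.
#' @param config A `lumos_config`.
#' @return Data frame with `pt`, `pv`, `tier` in
#'   `{high, low, artifact}` per site.
#' @export
score_sites <- function(sites, panel, config = default_config()) {
  metrics <- compute_metrics(sites, panel)
  is_indel <- sites$is_indel > 0
  pt <- pv <- rep(NA_real_, nrow(sites))
  for (cls in unique(is_indel)) {
    sel <- is_indel == cls
    m <- metrics[sel, , drop = FALSE]
    labels <- label_training_sites(m, config)
    strict <- fit_quality_model(m, labels, c("PASS", "REJECT"))
    lenient_labels <- ifelse(labels == "REJECT", "REJECT", "VARIANT")
    lenient <- fit_quality_model(m, lenient_labels, c("VARIANT", "REJECT"))
    pt[sel] <- quality_posterior(strict, m)
    pv[sel] <- quality_posterior(lenient, m)
  }
  tier <- ifelse(pt > config$T_pass, "high",
                 ifelse(pv > config$T_pass, "low", "artifact"))
  data.frame(pt = pt, pv = pv, tier = tier, stringsAsFactors = FALSE)
}
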