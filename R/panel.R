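#' Genotype-state likelihoods for a control sample site
#'
#' Likelihood of the observed B-allele counts under the four states used to
#' score position reliability in unmatched controls: germline homozygous
#' reference (B reads are base-call errors at rate `10^(-qb_b/10)`), germline
#' heterozygous (B reads binomial at 0.5), germline homozygous alternate
#' (A reads are base-call errors at rate `10^(-qb_a/10)`), and
#' unreliable/poorly mapped (a flat likelihood set by the worse of the two
#' mean mapping qualities).
#'
#' @param r_b,r_t B-allele and total read counts (vectorized).
#' @param qb_b Mean base quality of B-supporting bases (Phred).
#' @param qm_a,qm_b Mean mapping quality of A-/B-supporting reads (Phred).
#' @param qb_a Mean base quality of A-supporting bases (Phred); defaults to
#'   `qb_b`.
#' @return A list with components `g_aa`, `g_ab`, `g_bb`, `u`, each in
#'   \[0, 1\].
#' @export
#' @examples
#' control_state_likelihoods(5, 10, 30, 60, 60)$g_ab # choose(10,5)/2^10
control_state_likelihoods <- function(r_b, r_t, qb_b, qm_a, qm_b,
                                      qb_a = qb_b) {
  if (any(qb_b < 0) || any(qb_a < 0) || any(qm_a < 0) || any(qm_b < 0)) {
    stop("qualities must be nonnegative")
  }
  if (any(r_b > r_t)) stop("r_b must not exceed r_t")
  err_b <- 10^(-qb_b / 10)
  err_a <- 10^(-qb_a / 10)
  list(
    g_aa = stats::dbinom(r_b, r_t, err_b),
    g_ab = stats::dbinom(r_b, r_t, 0.5),
    g_bb = stats::dbinom(r_t - r_b, r_t, err_a),
    u = 10^(-pmin(qm_a, qm_b) / 10)
  )
}

#' Posterior probability that a position is unreliable
#'
#' Bayes rule over the four control states, with Hardy-Weinberg genotype
#' priors `pi_AA = F_A^2`, `pi_AB = 2 F_A F_B`, `pi_BB = F_B^2` and a
#' constant unreliable prior `pi_U`.
#'
#' @param lik List from [control_state_likelihoods()].
#' @param F_A,F_B Population allele frequencies of the A and B alleles
#'   (`F_A + F_B <= 1`).
#' @param pi_U Prior probability the position is unreliable.
#' @return Posterior probability in \[0, 1\] (vectorized).
#' @export
unreliable_posterior <- function(lik, F_A, F_B, pi_U) {
  if (any(F_A + F_B > 1 + 1e-12)) stop("F_A + F_B must be <= 1")
  pi_aa <- F_A^2
  pi_ab <- 2 * F_A * F_B
  pi_bb <- F_B^2
  den <- lik$g_aa * pi_aa + lik$g_ab * pi_ab + lik$g_bb * pi_bb +
    lik$u * pi_U
  if (any(den == 0)) stop("degenerate site: all state likelihoods are zero")
  lik$u * pi_U / den
}

#' Build a panel of unmatched controls
#'
#' Step one of the caller: for every position seen in the controls, compute
#' the mean posterior probability that the position is unreliable and its
#' Phred-like transform `-10 log10(mean)`, and record per-exon mean control
#' depths for the copy-number model.
#'
#' @param controls A list of >= 2 per-sample counts data frames
#'   (see [load_counts()]).
#' @param exon_depths Data frame with `chrom, start, end` and one depth column
#'   per control (see [load_exon_depths()]).
#' @param priors Optional priors table ([load_priors()]) supplying `F_B`;
#'   alleles absent from it receive `F_p_snv` / `F_p_indel`. `F_A = 1 - F_B`.
#' @param config A `lumos_config`.
#' @param phred_cap Upper cap on the Phred score (a perfectly diploid panel
#'   would otherwise give `-log10(0)`).
#' @return A `lumos_panel`: `positions` (chrom, pos, mean_unreliable, phred,
#'   n_obs, flagged), `exons` (chrom, start, end, depth_mean and per-control
#'   depths), `n_controls`.
#' @export
build_panel <- function(controls, exon_depths, priors = NULL,
                        config = default_config(), phred_cap = 250) {
  if (length(controls) < 2) stop("need at least 2 unmatched controls")
  per_control <- lapply(controls, function(df) {
    df <- validate_counts(df, "control counts")
    lik <- control_state_likelihoods(df$r_b, df$r_t, df$qb_b, df$qm_a,
                                     df$qm_b, df$qb_a)
    fb <- lookup_f_b(df, priors, config)
    fa <- pmax(1 - fb, 0)
    data.frame(chrom = df$chrom, pos = df$pos,
               p_u = unreliable_posterior(lik, fa, fb, config$pi_U))
  })
  all_obs <- do.call(rbind, per_control)
  key <- paste(all_obs$chrom, all_obs$pos)
  agg <- stats::aggregate(all_obs$p_u, by = list(key = key), FUN = mean)
  nobs <- stats::aggregate(all_obs$p_u, by = list(key = key), FUN = length)
  first <- !duplicated(key)
  pos_tab <- data.frame(chrom = all_obs$chrom[first], pos = all_obs$pos[first],
                        key = key[first], stringsAsFactors = FALSE)
  pos_tab <- merge(pos_tab, agg, by = "key")
  names(pos_tab)[names(pos_tab) == "x"] <- "mean_unreliable"
  pos_tab <- merge(pos_tab, nobs, by = "key")
  names(pos_tab)[names(pos_tab) == "x"] <- "n_obs"
  pos_tab$key <- NULL
  pos_tab$phred <- pmin(-10 * log10(pmax(pos_tab$mean_unreliable, 0)),
                        phred_cap)
  pos_tab$phred <- pmax(pos_tab$phred, 0)
  pos_tab$flagged <- pos_tab$n_obs < length(controls)
  pos_tab <- pos_tab[order(pos_tab$chrom, pos_tab$pos), ]
  rownames(pos_tab) <- NULL

  depth_cols <- setdiff(names(exon_depths), c("chrom", "start", "end"))
  if (length(depth_cols) == 0) stop("exon_depths has no depth columns")
  exons <- exon_depths
  exons$depth_mean <- rowMeans(exons[, depth_cols, drop = FALSE])
  structure(list(positions = pos_tab, exons = exons,
                 n_controls = length(controls)),
            class = "lumos_panel")
}

# B-allele population frequency per row; unseen alleles get the class floor
lookup_f_b <- function(df, priors, config) {
  floor_fb <- ifelse(df$is_indel > 0, config$F_p_indel, config$F_p_snv)
  if (is.null(priors)) return(floor_fb)
  key <- paste(df$chrom, df$pos, df$alt)
  pk <- paste(priors$chrom, priors$pos, priors$allele)
  idx <- match(key, pk)
  out <- priors$f_b[idx]
  out[is.na(out)] <- floor_fb[is.na(out)]
  out
}

#' Look up panel reliability for tumor sites
#'
#' Positions absent from the panel get the worst (floor) score and are
#' flagged.
#'
#' @param panel A `lumos_panel`.
#' @param sites Counts data frame of tumor sites.
#' @return Data frame with `phred`, `mean_unreliable`, `in_panel` per site.
#' @export
panel_lookup <- function(panel, sites) {
  key <- paste(sites$chrom, sites$pos)
  pk <- paste(panel$positions$chrom, panel$positions$pos)
  idx <- match(key, pk)
  out <- data.frame(
    phred = panel$positions$phred[idx],
    mean_unreliable = panel$positions$mean_unreliable[idx],
    in_panel = !is.na(idx)
  )
  out$phred[is.na(out$phred)] <- 0
  out$mean_unreliable[is.na(out$mean_unreliable)] <- 1
  out
}
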