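#' Default caller configuration
#'
#' Returns the full set of model parameters with their shipped defaults.
#' Every value can be overridden through [load_config()] or by editing the
#' returned list.
#'
#' @details Parameters:
#' * `K`: number of clonal subsets fit by the copy-number model.
#' * `f_pi`, `alpha_pi`: mode and shape of the Beta prior on clone sample
#'   fractions (see [f_prior_density()]).
#' * `cn_priors`: prior on total copy number, `P(N = 0) .. P(N = 3), P(N >= 4)`.
#' * `m_priors`: prior on minor allele copy number, `P(M = 0), P(M = 1),
#'   P(M >= 2)`.
#' * `alpha_seg`: segmentation significance cutoff.
#' * `rho_snv`, `rho_indel`: constants for the somatic prior
#'   `pi_s = rho * (omega + 1)` where `omega` is the cancer-database mutation
#'   count at the position.
#' * `F_p_snv`, `F_p_indel`: population allele frequency assigned to alleles
#'   absent from the input population database.
#' * `F_max_somatic`: maximum population allele frequency for a site to remain
#'   a somatic candidate.
#' * `Qm_min`, `Qb_min`: minimum mapping/base quality for a read/base to be
#'   counted (used by upstream count extraction; recorded here for provenance).
#' * `T_pass`: quality-posterior threshold separating the high/low/artifact
#'   tiers (PT/PV).
#' * `T_somatic`, `T_germline`: posterior thresholds for calling a site
#'   somatic or germline.
#' * `pi_U`: prior probability that a position is unreliable (poorly mapped).
#' * `em_tol`, `max_em_iters`, `max_outer_iters`: EM and outer-loop controls.
#' * `f_bounds`, `W_bounds`, `C_bounds`: box constraints for the M-step.
#' * `N_max`: largest total copy number considered when inverting depth ratios.
#' * `unfolded_somatic_bb`: disable the min/max fold of the somatic
#'   beta-binomial (the folded form is the default).
#' * `sigma_log`: log-scale standard deviation of the simulated depth
#'   distribution.
#' * `qc_pass`, `qc_reject`: per-metric PASS / REJECT threshold lists for the
#'   quality model training labels (see [label_training_sites()]).
#'
#' @return A named list of class `lumos_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$rho_snv
default_config <- function() {
  cfg <- list(
    K = 3L,
    f_pi = 0.5,
    alpha_pi = 1.5,
    cn_priors = c(0.1, 0.15, 0.5, 0.15, 0.1),
    m_priors = c(0.25, 0.5, 0.25),
    alpha_seg = 1e-5,
    rho_snv = 1e-5,
    rho_indel = 1e-6,
    F_p_snv = 7.14e-5,
    F_p_indel = 1.43e-5,
    F_max_somatic = 1e-3,
    Qm_min = 10,
    Qb_min = 5,
    T_pass = 0.99,
    T_somatic = 0.8,
    T_germline = 0.8,
    pi_U = 0.05,
    em_tol = 1e-6,
    max_em_iters = 25L,
    max_outer_iters = 10L,
    f_bounds = c(0.01, 0.99),
    W_bounds = c(2, 1e4),
    C_bounds = c(0.5, 4),
    N_max = 8L,
    min_seg_width = 5L,
    unfolded_somatic_bb = FALSE,
    sigma_log = 1,
    rng_seed = 1L,
    qc_pass = list(
      qm_a = 50, qm_b = 50, qb_a = 28, qb_b = 28,
      strand_z_max = 2, panel_phred = 30
    ),
    qc_reject = list(
      qm_b = 20, qb_b = 15, panel_phred = 10, strand_z_min = 5
    )
  )
  class(cfg) <- "lumos_config"
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML file of parameter overrides on top of [default_config()].
#' A missing or `NULL` path returns the defaults unchanged.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @return A validated `lumos_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             "; valid keys: ", paste(names(cfg), collapse = ", "))
      }
      for (k in names(user)) {
        if (is.list(cfg[[k]]) && is.list(user[[k]])) {
          cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
        } else {
          cfg[[k]] <- user[[k]]
        }
      }
    }
  }
  validate_config(cfg)
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$K < 1) stop("K must be >= 1")
  for (nm in c("cn_priors", "m_priors")) {
    if (abs(sum(cfg[[nm]]) - 1) > 1e-12) {
      stop(nm, " must sum to 1 (got ", sum(cfg[[nm]]), ")")
    }
    if (any(cfg[[nm]] < 0)) stop(nm, " must be nonnegative")
  }
  for (nm in c("T_pass", "T_somatic", "T_germline", "pi_U",
               "F_max_somatic", "f_pi")) {
    v <- cfg[[nm]]
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]")
  }
  if (cfg$alpha_pi <= 1) stop("alpha_pi must be > 1 (Beta prior with a mode)")
  class(cfg) <- "lumos_config"
  cfg
}
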