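# shared fixtures for the test suite

# merge the pooled control depth into the tumor exon table, as run_caller does
cohort_exons <- function(coh) {
  ex <- coh$tumor_exons
  ctl <- grep("^control", names(coh$exon_depths))
  ex$depth_control <- rowMeans(coh$exon_depths[, ctl, drop = FALSE])
  ex
}

cohort_hets <- function(coh) {
  coh$tumor[grepl("germline_het", coh$truth$class), , drop = FALSE]
}

cohort_somatics <- function(coh) {
  coh$tumor[coh$truth$class == "somatic", , drop = FALSE]
}

# a minimal valid counts row, overridable field by field
counts_row <- function(...) {
  row <- data.frame(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T",
    r_t = 50, r_a = 30, r_b = 20,
    qb_a = 30, qb_b = 30, qm_a = 60, qm_b = 60,
    strand_b_fwd = 10, strand_b_rev = 10, is_indel = 0,
    softclip_frac = 0, low_mapq_frac = 0, homopolymer = 0,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# a small panel over the given positions: two clean diploid-looking controls
tiny_panel <- function(pos = c(100L, 200L, 300L), depth = 100) {
  ctl <- function() {
    df <- do.call(rbind, lapply(pos, function(p) {
      counts_row(pos = p, r_t = depth, r_a = depth / 2, r_b = depth / 2,
                 strand_b_fwd = depth / 4, strand_b_rev = depth / 4)
    }))
    df
  }
  exons <- data.frame(chrom = "chr1", start = 0L, end = 1000L,
                      control_1 = depth, control_2 = depth,
                      stringsAsFactors = FALSE)
  pr <- data.frame(chrom = "chr1", pos = pos, allele = "T", f_b = 0.5,
                   omega = 0L, known_germline = 1L, stringsAsFactors = FALSE)
  build_panel(list(ctl(), ctl()), exons, priors = pr)
}

# independent log-gamma oracle for the beta-binomial pmf
bb_oracle <- function(k, n, a, b) {
  exp(lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
        lgamma(k + a) + lgamma(n - k + b) - lgamma(n + a + b) +
        lgamma(a + b) - lgamma(a) - lgamma(b))
}
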