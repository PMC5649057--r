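test_that("default config matches the documented parameter table", {
  cfg <- default_config()
  expect_identical(cfg$K, 3L)
  expect_equal(cfg$f_pi, 0.5)
  expect_equal(cfg$alpha_pi, 1.5)
  expect_equal(cfg$cn_priors, c(0.1, 0.15, 0.5, 0.15, 0.1))
  expect_equal(cfg$m_priors, c(0.25, 0.5, 0.25))
  expect_equal(cfg$alpha_seg, 1e-5)
  expect_equal(cfg$rho_snv, 1e-5)
  expect_equal(cfg$rho_indel, 1e-6)
  expect_equal(cfg$F_p_snv, 7.14e-5)
  expect_equal(cfg$F_p_indel, 1.43e-5)
  expect_equal(cfg$F_max_somatic, 1e-3)
  expect_equal(cfg$Qm_min, 10)
  expect_equal(cfg$Qb_min, 5)
  expect_equal(cfg$T_pass, 0.99)
  expect_equal(cfg$T_somatic, 0.8)
  expect_equal(cfg$T_germline, 0.8)
  expect_equal(cfg$pi_U, 0.05)
  expect_equal(sum(cfg$cn_priors), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$m_priors), 1, tolerance = 1e-12)
})

test_that("load_config reads overrides and rejects bad input", {
  expect_equal(load_config(NULL)$rho_snv, 1e-5)

  f <- tempfile(fileext = ".yaml")
  writeLines("K: 2", f)
  cfg <- load_config(f)
  expect_equal(cfg$K, 2)
  expect_equal(cfg$rho_snv, 1e-5) # untouched default

  writeLines("not_a_key: 1", f)
  expect_error(load_config(f), "unknown config key")

  writeLines("cn_priors: [0.1, 0.15, 0.5, 0.15, 0.0]", f)
  expect_error(load_config(f), "must sum to 1")

  expect_error(load_config("/nonexistent/file.yaml"), "not found")
})

test_that("counts tables round-trip through write/load", {
  df <- rbind(counts_row(), counts_row(pos = 200L, alt = "G", r_b = 5,
                                       r_a = 40))
  f <- tempfile(fileext = ".tsv")
  write_counts(df, f)
  back <- load_counts(f)
  expect_equal(back, df)
})

test_that("counts validation rejects invariant violations with row numbers", {
  bad <- counts_row(r_a = 40, r_b = 20, r_t = 50)
  expect_error(validate_counts(bad), "r_a \\+ r_b exceeds r_t.*row")
  expect_error(validate_counts(counts_row(pos = 0L)), "pos must be >= 1")
  expect_error(validate_counts(counts_row(r_b = -1, r_a = 0)),
               "negative read count")
  expect_error(validate_counts(counts_row(qb_b = -5)), "negative quality")
  expect_error(validate_counts(counts_row()[, -5]), "missing column")
})

test_that("malformed values are reported with the row number", {
  f <- tempfile(fileext = ".tsv")
  df <- counts_row()
  df$r_t <- "oops"
  write_counts(df, f)
  expect_error(load_counts(f), "malformed value in column 'r_t' at row 1")
})

test_that("empty counts file yields an empty frame with a warning", {
  f <- tempfile(fileext = ".tsv")
  write_counts(counts_row()[0, ], f)
  expect_warning(out <- load_counts(f), "empty")
  expect_equal(nrow(out), 0)
  expect_true(all(c("chrom", "pos", "r_t", "softclip_frac") %in% names(out)))
})

test_that("optional metric columns default to 0", {
  df <- counts_row()
  df$softclip_frac <- NULL
  df$low_mapq_frac <- NULL
  df$homopolymer <- NULL
  out <- validate_counts(df)
  expect_equal(out$softclip_frac, 0)
  expect_equal(out$low_mapq_frac, 0)
  expect_equal(out$homopolymer, 0)
})

test_that("exon depth loader enforces the BED invariants", {
  f <- tempfile(fileext = ".tsv")
  ex <- data.frame(chrom = "chr1", start = 0L, end = 100L, s1 = 50, s2 = 60)
  write.table(ex, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_exon_depths(f), ex)

  ex$end <- 0L
  write.table(ex, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_exon_depths(f), "end > start")
})

test_that("priors loader validates frequencies and counts", {
  f <- tempfile(fileext = ".tsv")
  pr <- data.frame(chrom = "chr1", pos = 100L, allele = "T", f_b = 0.2,
                   omega = 3L, known_germline = 1L)
  write_priors(pr, f)
  expect_equal(load_priors(f), pr)

  pr$f_b <- 1.2
  write_priors(pr, f)
  expect_error(load_priors(f), "f_b")

  pr$f_b <- 0.2
  pr$omega <- 1.5
  write_priors(pr, f)
  expect_error(load_priors(f), "omega")
})

test_that("VCF output round-trips through a standard parser", {
  calls <- data.frame(
    chrom = c("chr1", "chr1"), pos = c(100L, 250L),
    ref = c("A", "C"), alt = c("T", "G"),
    p_somatic = c(0.95, 0.01), p_germline_het = c(0.03, 0.97),
    p_hom = c(0.01, 0.01), p_other = c(0.01, 0.01),
    label = c("SOMATIC", "GERMLINE_HET"), clone = c(1L, 1L),
    exp_af = c(0.25, 0.5), cn = c(2L, 2L), minor_cn = c(1L, 1L),
    pt = c(0.999, 0.995), pv = c(0.999, 0.999),
    filter = c("PASS", "PASS"), known_germline = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, f)

  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(as.character(v@fix[, "CHROM"]), calls$chrom)
  expect_equal(as.integer(v@fix[, "POS"]), calls$pos)
  expect_equal(as.character(v@fix[, "REF"]), calls$ref)
  expect_equal(as.character(v@fix[, "ALT"]), calls$alt)
  expect_equal(as.character(v@fix[, "FILTER"]), calls$filter)
  ps <- as.numeric(vcfR::extract.info(v, "P_SOMATIC"))
  expect_equal(ps, calls$p_somatic, tolerance = 1e-6)
  lab <- vcfR::extract.info(v, "LABEL")
  expect_equal(as.character(lab), calls$label)
  kg <- grepl("KNOWN_GERMLINE", v@fix[, "INFO"], fixed = TRUE)
  expect_equal(kg, calls$known_germline)
})

test_that("VCF writer rejects unsorted records and handles zero calls", {
  calls <- data.frame(
    chrom = "chr1", pos = c(250L, 100L), ref = "A", alt = "T",
    p_somatic = 0.5, p_germline_het = 0.3, p_hom = 0.1, p_other = 0.1,
    label = "UNCALLED", clone = 1L, exp_af = 0.25, cn = 2L, minor_cn = 1L,
    pt = 0.5, pv = 0.5, filter = "LowQual", known_germline = FALSE,
    stringsAsFactors = FALSE
  )
  f <- tempfile(fileext = ".vcf")
  expect_error(write_calls_vcf(calls, f), "sorted")

  write_calls_vcf(calls[0, ], f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "##fileformat=VCFv4.2"))
  expect_true(startsWith(lines[length(lines)], "#CHROM"))
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(nrow(v@fix), 0)
})

test_that("segments TSV carries the documented columns", {
  seg <- data.frame(chrom = "chr1", start = 0L, end = 1000L, clone = 1L,
                    f = 0.6, N = 2L, M = 1L, n_exons = 10L, mean_ratio = 1.0,
                    first_exon = 1L, last_exon = 10L)
  f <- tempfile(fileext = ".tsv")
  write_segments(seg, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(back),
               c("chrom", "start", "end", "clone", "f", "N", "M",
                 "n_exons", "mean_ratio"))
  expect_equal(back$f, 0.6)
})

test_that("panel bundles round-trip through the directory format", {
  panel <- tiny_panel()
  d <- file.path(tempdir(), "panel_bundle")
  write_panel(panel, d)
  expect_true(file.exists(file.path(d, "meta.json")))
  back <- read_panel(d)
  expect_equal(back$n_controls, panel$n_controls)
  expect_equal(back$positions$phred, panel$positions$phred)
  expect_equal(back$exons$depth_mean, panel$exons$depth_mean)

  writeLines('{"format": "other"}', file.path(d, "meta.json"))
  expect_error(read_panel(d), "not a lumoscall panel")
})
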