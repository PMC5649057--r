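#' Read a per-site allele counts table
#'
#' The counts table is a TSV with one row per candidate site per sample and a
#' header naming at least the columns `chrom, pos, ref, alt, r_t, r_a, r_b,
#' qb_a, qb_b, qm_a, qm_b, strand_b_fwd, strand_b_rev, is_indel`. Optional
#' columns `softclip_frac`, `low_mapq_frac` and `homopolymer` feed the quality
#' metrics and default to 0 when absent. Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of validated site counts.
#' @export
load_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  if (nrow(df) == 0) {
    warning("counts file is empty: ", path)
    return(empty_counts())
  }
  validate_counts(df, context = path)
}

required_count_cols <- c(
  "chrom", "pos", "ref", "alt", "r_t", "r_a", "r_b",
  "qb_a", "qb_b", "qm_a", "qm_b", "strand_b_fwd", "strand_b_rev", "is_indel"
)

optional_count_cols <- c(softclip_frac = 0, low_mapq_frac = 0, homopolymer = 0)

empty_counts <- function() {
  df <- as.data.frame(
    c(
      stats::setNames(
        list(character(), integer(), character(), character()),
        c("chrom", "pos", "ref", "alt")
      ),
      stats::setNames(
        rep(list(numeric()), 10),
        c("r_t", "r_a", "r_b", "qb_a", "qb_b", "qm_a", "qm_b",
          "strand_b_fwd", "strand_b_rev", "is_indel")
      ),
      as.list(optional_count_cols)[0]
    )
  )
  for (nm in names(optional_count_cols)) df[[nm]] <- numeric()
  df
}

#' Validate a site-counts data frame
#'
#' Enforces the counts invariants (`r_a + r_b <= r_t`, nonnegative counts and
#' qualities, `pos >= 1`) and fills the optional metric columns.
#'
#' @param df A data.frame of counts rows.
#' @param context Name used in error messages (file path or object name).
#' @return The validated data frame, with optional columns populated.
#' @export
validate_counts <- function(df, context = "counts") {
  missing_cols <- setdiff(required_count_cols, names(df))
  if (length(missing_cols)) {
    stop(context, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (nm in names(optional_count_cols)) {
    if (is.null(df[[nm]])) df[[nm]] <- optional_count_cols[[nm]]
  }
  num_cols <- setdiff(names(df), c("chrom", "ref", "alt"))
  for (nm in num_cols) {
    if (!is.numeric(df[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      stop(context, ": malformed value in column '", nm, "' at row ", bad)
    }
  }
  fail <- function(rows, what) {
    stop(context, ": ", what, " at row(s) ",
         paste(utils::head(rows, 5), collapse = ", "))
  }
  bad <- which(df$pos < 1)
  if (length(bad)) fail(bad, "pos must be >= 1")
  cnt <- c("r_t", "r_a", "r_b", "strand_b_fwd", "strand_b_rev")
  bad <- which(Reduce(`|`, lapply(df[cnt], function(x) x < 0)))
  if (length(bad)) fail(bad, "negative read count")
  bad <- which(df$r_a + df$r_b > df$r_t)
  if (length(bad)) fail(bad, "r_a + r_b exceeds r_t")
  bad <- which(df$qb_a < 0 | df$qb_b < 0 | df$qm_a < 0 | df$qm_b < 0)
  if (length(bad)) fail(bad, "negative quality")
  df$pos <- as.integer(df$pos)
  df
}

#' Write a counts table
#'
#' @param counts Data frame as returned by [load_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-exon mean depths over a target BED
#'
#' TSV with columns `chrom, start, end` (0-based half-open, BED convention)
#' followed by one mean-depth column per sample.
#'
#' @param path Path to the depth table.
#' @return A data.frame with the BED columns and depth columns.
#' @export
load_exon_depths <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("exon depth table needs chrom, start, end columns: ", path)
  }
  if (any(df$end <= df$start)) stop("exon intervals must satisfy end > start")
  depth_cols <- setdiff(names(df), c("chrom", "start", "end"))
  if (any(unlist(df[depth_cols]) < 0)) stop("depths must be nonnegative")
  df
}

#' Read a priors table
#'
#' TSV mapping positions/alleles to population allele frequencies and
#' cancer-database mutation counts: columns `chrom, pos, allele, f_b, omega,
#' known_germline`.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame.
#' @export
load_priors <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         allele = "character"))
  need <- c("chrom", "pos", "allele", "f_b", "omega", "known_germline")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("priors table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$f_b < 0 | df$f_b > 1)) stop("f_b must lie in [0, 1]")
  if (any(df$omega < 0 | df$omega != round(df$omega))) {
    stop("omega must be a nonnegative integer")
  }
  df
}

#' Write a priors table
#' @param priors Data frame with priors columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_priors <- function(priors, path) {
  utils::write.table(priors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write called segments as a BED-like TSV
#'
#' Columns: `chrom, start, end, clone, f, N, M, n_exons, mean_ratio`.
#'
#' @param segments Segment data frame from [fit_clone_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- c("chrom", "start", "end", "clone", "f", "N", "M",
            "n_exons", "mean_ratio")
  utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write call records to VCF
#'
#' Emits VCF 4.2 with INFO fields `P_SOMATIC, P_GERMLINE_HET, P_HOM, P_OTHER,
#' CLONE, EXP_AF, CN, MINOR_CN, PT, PV` and `FILTER` in
#' `{PASS, LowQual, REJECT}`. Records must be coordinate-sorted.
#'
#' @param calls Call records from [run_caller()].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lumoscall",
    "##FILTER=<ID=LowQual,Description=\"Quality posterior below the strict tier or no posterior above its calling threshold\">",
    "##FILTER=<ID=REJECT,Description=\"Classified as artifact (PV below threshold)\">",
    "##INFO=<ID=P_SOMATIC,Number=1,Type=Float,Description=\"Posterior probability the variant is somatic\">",
    "##INFO=<ID=P_GERMLINE_HET,Number=1,Type=Float,Description=\"Posterior probability of germline heterozygous\">",
    "##INFO=<ID=P_HOM,Number=1,Type=Float,Description=\"Posterior probability of germline homozygous reference\">",
    "##INFO=<ID=P_OTHER,Number=1,Type=Float,Description=\"Posterior probability of the other model\">",
    "##INFO=<ID=CLONE,Number=1,Type=Integer,Description=\"Index of the most likely clonal subset\">",
    "##INFO=<ID=EXP_AF,Number=1,Type=Float,Description=\"Expected somatic allele fraction for the assigned clone\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Total copy number of the containing segment\">",
    "##INFO=<ID=MINOR_CN,Number=1,Type=Integer,Description=\"Minor allele copy number of the containing segment\">",
    "##INFO=<ID=PT,Number=1,Type=Float,Description=\"Strict-tier quality posterior\">",
    "##INFO=<ID=PV,Number=1,Type=Float,Description=\"Variant-vs-artifact quality posterior\">",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Call label\">",
    "##INFO=<ID=KNOWN_GERMLINE,Number=0,Type=Flag,Description=\"Allele present in a germline database\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  ord_ok <- !is.unsorted(order(calls$chrom, calls$pos)) &&
    all(diff(order(calls$chrom, calls$pos)) == 1)
  if (!ord_ok) stop("call records must be sorted by chrom, pos")
  fmtp <- function(x) ifelse(is.na(x), ".", formatC(x, digits = 6,
                                                    format = "g"))
  info <- paste0(
    "P_SOMATIC=", fmtp(calls$p_somatic),
    ";P_GERMLINE_HET=", fmtp(calls$p_germline_het),
    ";P_HOM=", fmtp(calls$p_hom),
    ";P_OTHER=", fmtp(calls$p_other),
    ";CLONE=", ifelse(is.na(calls$clone), ".", calls$clone),
    ";EXP_AF=", fmtp(calls$exp_af),
    ";CN=", ifelse(is.na(calls$cn), ".", calls$cn),
    ";MINOR_CN=", ifelse(is.na(calls$minor_cn), ".", calls$minor_cn),
    ";PT=", fmtp(calls$pt),
    ";PV=", fmtp(calls$pv),
    ";LABEL=", calls$label,
    ifelse(!is.null(calls$known_germline) & calls$known_germline %in% TRUE,
           ";KNOWN_GERMLINE", "")
  )
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                calls$filter, info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Persist a control panel to a directory bundle
#'
#' Writes the panel as a plain-text bundle: `positions.tsv` (per-position
#' reliability), `exons.tsv` (per-exon control depths) and `meta.json`
#' (format version, number of controls).
#'
#' @param panel A `lumos_panel` from [build_panel()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "lumos_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(panel$positions, file.path(dir, "positions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$exons, file.path(dir, "exons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(format = "lumoscall-panel", version = 1L,
               n_controls = panel$n_controls)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Load a control panel bundle
#'
#' @param dir Directory written by [write_panel()].
#' @return A `lumos_panel` object.
#' @export
read_panel <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  if (!identical(meta$format, "lumoscall-panel")) {
    stop("not a lumoscall panel bundle: ", dir)
  }
  positions <- utils::read.table(file.path(dir, "positions.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 colClasses = c(chrom = "character"))
  exons <- utils::read.table(file.path(dir, "exons.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
  structure(list(positions = positions, exons = exons,
                 n_controls = meta$n_controls),
            class = "lumos_panel")
}
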