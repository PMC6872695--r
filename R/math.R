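#' Variant allele fraction from read counts
#'
#' The variant allele fraction (VAF) at a locus is the fraction of
#' sequencing reads supporting the alternate allele,
#' `alt / (alt + ref)`.
#'
#' @param alt_count Integer vector, reads supporting the alternate allele.
#' @param ref_count Integer vector, reads supporting the reference allele.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' compute_vaf(5, 5)
#' compute_vaf(c(3, 0), c(7, 10))
#' @export
compute_vaf <- function(alt_count, ref_count) {
  if (length(alt_count) != length(ref_count)) {
    abort("`alt_count` and `ref_count` must have the same length.",
          class = "hetpet_input_error")
  }
  if (any(alt_count < 0, na.rm = TRUE) || any(ref_count < 0, na.rm = TRUE)) {
    abort("Read counts must be non-negative.", class = "hetpet_input_error")
  }
  depth <- alt_count + ref_count
  if (any(depth == 0, na.rm = TRUE)) {
    abort("Zero total read depth: VAF is undefined.",
          class = "hetpet_depth_error")
  }
  alt_count / depth
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' MATH summarizes intratumor genetic heterogeneity as the ratio of the
#' median absolute deviation (MAD) to the median of the tumor's variant
#' allele fractions, on a percent scale:
#' `MATH = 100 * MAD(vaf) / median(vaf)`. The MAD is scaled by the
#' normal-consistency constant 1.4826, matching the original definition
#' used by maftools. Tumors whose mutations form a single tight VAF
#' cluster score near 0; subclonal structure spreads the VAFs and
#' inflates the score.
#'
#' @param vafs Numeric vector of variant allele fractions in `(0, 1]`.
#' @param min_variants Minimum number of usable variants; fewer is an
#'   error (MATH on very few loci is unstable). Default 5.
#' @param mad_constant Scale constant applied to the raw MAD.
#'   Default 1.4826 (normal consistency).
#' @return A one-row tibble with columns `n_variants`, `median_vaf`,
#'   `mad_vaf` and `math`.
#' @examples
#' compute_math(c(0.2, 0.25, 0.3, 0.35, 0.5))
#' @export
compute_math <- function(vafs, min_variants = 5, mad_constant = 1.4826) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_variants) {
    abort(
      sprintf("MATH requires at least %d usable variants; got %d.",
              min_variants, length(vafs)),
      class = "hetpet_insufficient_data"
    )
  }
  if (any(vafs <= 0) || any(vafs > 1)) {
    abort("VAFs must lie in (0, 1].", class = "hetpet_input_error")
  }
  med <- median(vafs)
  if (med == 0) {
    abort("Median VAF is zero; MATH undefined.", class = "hetpet_degenerate")
  }
  mad_vaf <- mad_constant * median(abs(vafs - med))
  tibble(
    n_variants = length(vafs),
    median_vaf = med,
    mad_vaf = mad_vaf,
    math = 100 * mad_vaf / med
  )
}

#' Per-sample MATH scores from a variant table
#'
#' Groups a variant table by sample and computes one MATH score per
#' sample. A variant is usable when it yields a VAF in `(0, 1]`: read
#' counts take precedence when present (`t_alt_count`/`t_ref_count`
#' with positive depth), otherwise a precomputed `vaf` column is used.
#' Samples with fewer than `min_variants` usable variants are retained
#' in the output with `excluded = TRUE` and `math = NA`, never silently
#' dropped.
#'
#' @param variants A data frame with a `sample_id` column plus either
#'   `t_alt_count`/`t_ref_count` or a `vaf` column (see [read_maf()]).
#' @param min_depth Optional minimum total read depth per variant;
#'   default 0 (no depth filter).
#' @inheritParams compute_math
#' @return A tibble with one row per sample: `sample_id`, `n_variants`
#'   (usable count), `median_vaf`, `mad_vaf`, `math`, `excluded`.
#' @export
math_per_sample <- function(variants, min_variants = 5, mad_constant = 1.4826,
                            min_depth = 0) {
  if (!"sample_id" %in% names(variants)) {
    abort("`variants` must have a `sample_id` column.",
          class = "hetpet_input_error")
  }
  out_cols <- tibble(
    sample_id = character(), n_variants = integer(),
    median_vaf = double(), mad_vaf = double(), math = double(),
    excluded = logical()
  )
  if (nrow(variants) == 0) {
    warn("Empty variant table: returning empty MATH result.")
    return(out_cols)
  }
  variants <- as_tibble(variants)
  has_counts <- all(c("t_alt_count", "t_ref_count") %in% names(variants))
  has_vaf <- "vaf" %in% names(variants)
  if (!has_counts && !has_vaf) {
    abort("`variants` needs t_alt_count/t_ref_count or a vaf column.",
          class = "hetpet_input_error")
  }
  v <- variants
  if (has_counts) {
    depth <- v$t_alt_count + v$t_ref_count
    count_vaf <- ifelse(!is.na(depth) & depth > 0,
                        v$t_alt_count / depth, NA_real_)
    v$.vaf <- count_vaf
    v$.depth <- depth
    if (has_vaf) {
      # counts take precedence; fall back to the precomputed column
      v$.vaf <- ifelse(is.na(v$.vaf), v$vaf, v$.vaf)
      v$.depth <- ifelse(is.na(depth), Inf, depth)
    }
  } else {
    v$.vaf <- v$vaf
    v$.depth <- Inf
  }
  v$.usable <- !is.na(v$.vaf) & v$.vaf > 0 & v$.vaf <= 1 & v$.depth >= min_depth

  dplyr::group_by(v, .data$sample_id) |>
    dplyr::summarise(res = {
      u <- .data$.vaf[.data$.usable]
      if (length(u) >= min_variants) {
        dplyr::mutate(compute_math(u, min_variants, mad_constant),
                      excluded = FALSE)
      } else {
        tibble(n_variants = length(u), median_vaf = NA_real_,
               mad_vaf = NA_real_, math = NA_real_, excluded = TRUE)
      }
    }, .groups = "drop") |>
    tidyr::unpack("res")
}

#' Read a MAF-style variant table
#'
#' Reads a Mutation Annotation Format (MAF)-style TSV. Header matching is
#' case-insensitive and `#`-prefixed comment lines are skipped. Required
#' columns: `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`, plus either
#' `t_ref_count`/`t_alt_count` or a precomputed VAF column
#' (`vaf`, `t_vaf` or `tumor_vaf`).
#'
#' @param path Path to the TSV file.
#' @return A tibble with normalized column names: `sample_id`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele` and whichever of `t_ref_count`,
#'   `t_alt_count`, `vaf` are present.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  lookup <- c(
    tumor_sample_barcode = "sample_id",
    chromosome = "chrom",
    start_position = "pos",
    reference_allele = "ref_allele",
    tumor_seq_allele2 = "alt_allele",
    t_ref_count = "t_ref_count",
    t_alt_count = "t_alt_count",
    vaf = "vaf",
    t_vaf = "vaf",
    tumor_vaf = "vaf"
  )
  lc <- tolower(names(raw))
  keep <- lc %in% names(lookup)
  out <- raw[keep]
  names(out) <- unname(lookup[lc[keep]])
  required <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0("MAF file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "hetpet_input_error")
  }
  has_counts <- all(c("t_ref_count", "t_alt_count") %in% names(out))
  if (!has_counts && !"vaf" %in% names(out)) {
    abort("MAF file needs t_ref_count/t_alt_count or a VAF column.",
          class = "hetpet_input_error")
  }
  as_tibble(out)
}
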