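test_that("compute_vaf returns alt/(alt+ref) and rejects zero depth", {
  expect_equal(compute_vaf(5, 5), 0.5)
  expect_equal(compute_vaf(0, 10), 0)
  expect_equal(compute_vaf(3, 7), 0.3)
  expect_equal(compute_vaf(c(5, 3), c(5, 7)), c(0.5, 0.3))
  expect_error(compute_vaf(0, 0), class = "hetpet_depth_error")
  expect_error(compute_vaf(-1, 5), class = "hetpet_input_error")
})

test_that("MATH matches direct MAD/median arithmetic", {
  # frozen from the independent oracle: median 0.3, MAD 1.4826 * 0.05
  res <- compute_math(c(0.2, 0.25, 0.3, 0.35, 0.5))
  expect_equal(res$math, 100 * 1.4826 * 0.05 / 0.3, tolerance = 1e-12)
  expect_equal(res$math, oracle_math(c(0.2, 0.25, 0.3, 0.35, 0.5)),
               tolerance = 1e-12)
  expect_equal(res$median_vaf, 0.3)
  expect_equal(res$n_variants, 5L)
})

test_that("MATH is zero iff dispersion is zero, and never negative", {
  expect_equal(compute_math(rep(0.3, 10))$math, 0)
  withr::with_seed(42, {
    for (i in 1:50) {
      v <- runif(sample(5:50, 1), 0.05, 0.95)
      expect_gte(compute_math(v)$math, 0)
    }
  })
})

test_that("MATH is invariant to VAF rescaling and variant order", {
  v <- c(0.2, 0.25, 0.3, 0.35, 0.5)
  base <- compute_math(v)$math
  expect_equal(compute_math(v * 0.5)$math, base, tolerance = 1e-12)
  expect_equal(compute_math(v * 1.7)$math, base, tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:10) {
      expect_identical(compute_math(sample(v))$math, compute_math(v)$math)
    }
  })
})

test_that("MATH agrees with the brute-force oracle on random VAF sets", {
  withr::with_seed(2024, {
    for (i in 1:300) {
      n <- sample(5:500, 1)
      v <- if (i %% 2 == 0) {
        runif(n, 0.01, 1)
      } else {
        # clonal + subclonal mixture draw
        pmin(pmax(c(rnorm(ceiling(n / 2), 0.45, 0.05),
                    rnorm(floor(n / 2), 0.2, 0.05)), 0.01), 1)
      }
      expect_equal(compute_math(v)$math, oracle_math(v), tolerance = 1e-9)
    }
  })
})

test_that("widening a subclonal mixture never decreases MATH", {
  clonal <- rep(0.45, 30)
  prev <- -Inf
  for (delta in seq(0.05, 0.35, by = 0.05)) {
    cur <- compute_math(c(clonal, rep(0.45 - delta, 20)))$math
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("compute_math validates its inputs", {
  expect_error(compute_math(c(0.1, 0.2)), class = "hetpet_insufficient_data")
  expect_error(compute_math(runif(10), min_variants = 11),
               class = "hetpet_insufficient_data")
  expect_error(compute_math(c(0, 0.2, 0.3, 0.4, 0.5)),
               class = "hetpet_input_error")
  expect_error(compute_math(c(1.2, 0.2, 0.3, 0.4, 0.5)),
               class = "hetpet_input_error")
})

test_that("math_per_sample scores each sample and reports exclusions", {
  tbl <- tibble::tibble(
    sample_id = rep(c("A", "B", "C"), c(6, 6, 1)),
    t_alt_count = c(rep(30, 6), c(10, 20, 30, 40, 50, 60), 5),
    t_ref_count = c(rep(70, 6), c(90, 80, 70, 60, 50, 40), 5)
  )
  res <- math_per_sample(tbl, min_variants = 5)
  expect_equal(nrow(res), 3)
  a <- res[res$sample_id == "A", ]
  b <- res[res$sample_id == "B", ]
  cc <- res[res$sample_id == "C", ]
  expect_equal(a$math, 0)          # constant VAFs
  expect_gt(b$math, 0)             # dispersed VAFs
  expect_false(a$excluded)
  expect_true(cc$excluded)         # 1 variant < min_variants, kept visible
  expect_true(is.na(cc$math))
})

test_that("math_per_sample prefers counts over a precomputed vaf column", {
  tbl <- tibble::tibble(
    sample_id = "S",
    t_alt_count = c(rep(25, 5), NA),
    t_ref_count = c(rep(75, 5), NA),
    vaf = c(rep(0.9, 5), 0.25)   # counts disagree on purpose
  )
  res <- math_per_sample(tbl, min_variants = 5)
  # 5 count-derived VAFs at 0.25 plus one fallback 0.25 => MATH 0
  expect_equal(res$n_variants, 6L)
  expect_equal(res$math, 0)
  expect_equal(res$median_vaf, 0.25)
})

test_that("math_per_sample honors a minimum depth filter", {
  tbl <- tibble::tibble(
    sample_id = "S",
    t_alt_count = c(rep(30, 5), 1),
    t_ref_count = c(rep(70, 5), 1)
  )
  expect_equal(math_per_sample(tbl)$n_variants, 6L)
  expect_equal(math_per_sample(tbl, min_depth = 50)$n_variants, 5L)
})

test_that("empty variant tables warn and return an empty result", {
  empty <- tibble::tibble(sample_id = character(),
                          t_alt_count = integer(), t_ref_count = integer())
  expect_warning(res <- math_per_sample(empty), "Empty")
  expect_equal(nrow(res), 0)
})

test_that("read_maf parses comment lines and case-insensitive headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#version 2.4",
    "#comment line",
    paste("TUMOR_SAMPLE_BARCODE", "chromosome", "Start_Position",
          "Reference_Allele", "Tumor_Seq_Allele2", "T_REF_COUNT",
          "t_alt_count", "Extra_Col", sep = "\t"),
    paste("S1", "1", "12345", "A", "T", "70", "30", "x", sep = "\t"),
    paste("S1", "2", "999", "G", "C", "50", "50", "y", sep = "\t")
  ), path)
  maf <- read_maf(path)
  expect_named(maf, c("sample_id", "chrom", "pos", "ref_allele",
                      "alt_allele", "t_ref_count", "t_alt_count"),
               ignore.order = TRUE)
  expect_equal(nrow(maf), 2)
  expect_equal(compute_vaf(maf$t_alt_count, maf$t_ref_count), c(0.3, 0.5))
})

test_that("read_maf rejects files missing required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chromosome\tStart_Position", "1\t5"), path)
  expect_error(read_maf(path), class = "hetpet_input_error")
})
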