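test_that("copy-number correction divides and rounds half-up", {
  m <- matrix(c(10, 9), 1, 2, dimnames = list("S1", c("a", "b")))
  out <- correct_copy_number(m, c(a = 2, b = 3))
  expect_equal(unname(out["S1", ]), c(5, 3))

  expect_equal(correct_copy_number(m, c(a = 1, b = 1)), m)

  m2 <- matrix(7, 1, 1, dimnames = list("S1", "a"))
  expect_equal(as.numeric(correct_copy_number(m2, c(a = 2))), 4) # 3.5 up

  expect_error(correct_copy_number(m, c(a = 0, b = 1)), "positive")
  expect_warning(correct_copy_number(m, c(a = 2)), "without a copy number")
})

test_that("rarefaction equalizes depths, is seeded, and preserves support", {
  m <- matrix(c(6, 4, 0, 3, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("a", "b", "c")))
  r <- rarefy_counts(m, seed = 42)
  expect_equal(unname(rowSums(r)), c(4, 4)) # min row sum
  expect_equal(rarefy_counts(m, seed = 42), r) # deterministic
  expect_true(all(r[, "c"] == 0)) # absent stays absent
  expect_true(all(r <= m))

  same <- matrix(c(2, 2, 3, 1), 2, 2, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("a", "b")))
  expect_equal(unname(rowSums(rarefy_counts(same, seed = 1))), c(4, 4))

  bad <- matrix(c(5, 0), 2, 1, dimnames = list(c("S1", "S2"), "a"))
  expect_error(rarefy_counts(bad, seed = 1), "at least one read")
})

test_that("rarefaction is unbiased: expected counts proportional to input", {
  row <- matrix(c(60, 30, 10), 1, 3, dimnames = list("S1", c("a", "b", "c")))
  draws <- vapply(1:1000, function(s) rarefy_counts(row, seed = s, depth = 50)[1, ],
                  numeric(3))
  m <- rowMeans(draws)
  expected <- c(30, 15, 5)
  # hypergeometric SE of the mean over 1000 draws
  se <- sqrt(50 * (expected / 50) * (1 - expected / 50) * (100 - 50) / 99 / 1000)
  expect_true(all(abs(m - expected) < 3 * pmax(se, 1e-8) + 1e-8))
})

test_that("relative abundance normalizes rows", {
  m <- matrix(c(2, 2, 4, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("a", "b")))
  out <- relative_abundance(m)
  expect_equal(unname(out["S1", ]), c(0.5, 0.5))
  expect_equal(unname(out["S2", ]), c(1, 0))
  m3 <- matrix(c(1, 2, 5), 1, 3, dimnames = list("S1", c("a", "b", "c")))
  expect_equal(unname(relative_abundance(m3)[1, ]), c(0.125, 0.25, 0.625))
  zero <- matrix(c(0, 0), 1, 2, dimnames = list("S1", c("a", "b")))
  expect_error(relative_abundance(zero), "positive total")
})

test_that("water-mass classification follows the salinity thresholds", {
  expect_equal(as.character(classify_water_mass(32.9)), "plume")
  expect_equal(as.character(classify_water_mass(33)), "mixed")
  expect_equal(as.character(classify_water_mass(33.75)), "mixed")
  expect_equal(as.character(classify_water_mass(34.0)), "scs")
  expect_error(classify_water_mass(NaN), "missing")
  expect_error(classify_water_mass(-1), "non-negative")

  # partition + monotonicity over a fine grid
  s <- seq(0, 40, by = 0.01)
  lab <- classify_water_mass(s)
  expect_false(anyNA(lab))
  expect_true(all(diff(as.integer(lab)) >= 0))
})

test_that("productivity derivation follows the leucine-to-carbon algebra", {
  expect_equal(derive_productivity(100)$bp, 0.84)
  expect_equal(derive_productivity(0)$bp, 0)
  # bp 2.0 at ba 5e5 -> sbp 4.0 fg C cell-1 d-1
  out <- derive_productivity(2.0 / 0.0084, 5e5)
  expect_equal(out$bp, 2.0)
  expect_equal(out$sbp, 4.0)

  # linearity and bp = sbp * ba consistency
  leu <- c(1, 10, 250)
  ba <- c(2e5, 5e5, 1e6)
  out <- derive_productivity(leu, ba)
  expect_equal(out$bp, leu * 0.0084)
  expect_equal(out$sbp * ba / 1e6, out$bp, tolerance = 1e-9)
  expect_error(derive_productivity(1, 0), "positive")
})

test_that("tables, trees and copy numbers round-trip through disk", {
  dir <- withr::local_tempdir()
  ds <- fixture_dataset(seed = 3)
  paths <- write_dataset(ds, dir)
  counts <- read_count_table(paths[["counts"]])
  expect_equal(counts, ds$counts)
  tree <- read_phylogeny(paths[["tree"]])
  expect_equal(sort(tree$tip.label), sort(ds$tree$tip.label))
  meta <- read_sample_table(paths[["metadata"]])
  expect_equal(meta$sample_id, ds$samples$sample_id)
  expect_equal(as.character(meta$water_mass),
               as.character(ds$samples$water_mass))
  cn <- read_copy_numbers(paths[["copy_numbers"]])
  expect_equal(cn, ds$copy_numbers)
})

test_that("BIOM count tables are read to the same matrix as TSV", {
  m <- random_counts(5, 8, seed = 9)
  dir <- withr::local_tempdir()
  biom_path <- file.path(dir, "x.biom")
  biomformat::write_biom(biomformat::make_biom(t(m)), biom_path)
  out <- read_count_table(biom_path)
  expect_equal(out[rownames(m), colnames(m)], m)
})

test_that("metadata validation derives productivity and flags inconsistency", {
  df <- tibble::tibble(sample_id = c("a", "b"), salinity = c(30, 34),
                       leu_rate = c(100, 10), ba = c(5e5, 2e5))
  out <- validate_sample_table(df)
  expect_equal(out$bp, c(0.84, 0.084))
  expect_equal(out$sbp, out$bp * 1e6 / out$ba)
  expect_equal(as.character(out$water_mass), c("plume", "scs"))

  bad <- tibble::tibble(sample_id = "a", salinity = 30,
                        bp = 1, ba = 5e5, sbp = 99)
  expect_error(validate_sample_table(bad), "inconsistent")
  expect_error(validate_sample_table(tibble::tibble(sample_id = "a")),
               "salinity")
})
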