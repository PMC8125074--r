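test_that("refractometry converts to density by the linear calibration", {
  expect_equal(suppressWarnings(refraction_to_density(13.593 / 10.927)), 0)
  expect_equal(refraction_to_density(1.4040), 1.74851, tolerance = 1e-5)
  expect_equal(refraction_to_density(1.4000), 1.70480, tolerance = 1e-5)
  # affine: density differences are exactly 10.927x refraction differences
  n <- c(1.38, 1.40, 1.4123, 1.45)
  expect_equal(diff(refraction_to_density(n)), 10.927 * diff(n))
  expect_warning(refraction_to_density(1.50), "plausible CsCl range")
  expect_error(refraction_to_density(c(1.40, NA)), "position\\(s\\) 2")
  expect_equal(refraction_to_density(density_to_refraction(1.72)), 1.72)
})

test_that("gradient tables survive a read-write-read round trip", {
  dir <- withr::local_tempdir()
  set.seed(11)
  dens <- seq(1.67, 1.73, length.out = 8)
  cnt <- matrix(rpois(16, 50), 8, 2, dimnames = list(NULL, c("A", "B")))
  prof <- make_profile(dens, runif(8, 1, 20), cnt, "g1", "13C")
  path <- file.path(dir, "g1.tsv")
  write_gradient_table(prof, path)
  back <- read_gradient_table(path, quiet = TRUE)
  expect_equal(back$sample_id, "g1")
  expect_equal(back$isotope, "13C")
  expect_equal(back$fractions$density, prof$fractions$density,
               tolerance = 1e-6)
  expect_equal(back$fractions$dna_ng, prof$fractions$dna_ng,
               tolerance = 1e-6)
  expect_equal(unname(back$counts), unname(prof$counts))
  # second round trip is the identity
  path2 <- file.path(dir, "g2.tsv")
  write_gradient_table(back, path2)
  expect_identical(readLines(path)[-1], readLines(path2)[-1])
})

test_that("density monotonicity is validated with fraction context", {
  cnt <- matrix(5, 3, 1, dimnames = list(NULL, "A"))
  expect_error(
    make_profile(c(1.70, 1.69, 1.71), c(5, 5, 5), cnt),
    "not strictly monotone"
  )
  # heavy-to-light collection order is accepted and reordered
  suppressWarnings(
    p <- make_profile(c(1.73, 1.71, 1.69), c(5, 5, 5), cnt)
  )
  expect_equal(p$fractions$density, c(1.69, 1.71, 1.73))
  expect_equal(p$fractions$fraction, c(3, 2, 1))
})

test_that("density is filled from refraction when absent", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nc_only.tsv")
  n_c <- c(1.3990, 1.4005, 1.4020, 1.4035, 1.4050)
  writeLines(c("# isotope: 12C",
               paste("fraction", "n_c", "dna_ng", "A", "B", sep = "\t"),
               paste(1:5, n_c, 10, c(1, 5, 20, 5, 1), c(2, 2, 2, 2, 2),
                     sep = "\t")), path)
  prof <- read_gradient_table(path, quiet = TRUE)
  expect_equal(prof$fractions$density, refraction_to_density(n_c))
})

test_that("malformed gradient tables are rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  writeLines(c(paste("fraction", "density", "A", sep = "\t"),
               paste(1:5, seq(1.68, 1.72, 0.01), 3, sep = "\t")), path)
  expect_error(read_gradient_table(path, quiet = TRUE), "dna_ng")
  cnt <- matrix(5, 2, 1, dimnames = list(NULL, "A"))
  expect_error(
    gradient_profile(data.frame(fraction = c(1, 1),
                                density = c(1.70, 1.71),
                                dna_ng = c(5, 5)), cnt),
    "duplicate fraction ids"
  )
  expect_error(
    gradient_profile(data.frame(fraction = 1:2, n_c = c(1.40, 1.40),
                                density = c(1.70, 1.71),
                                dna_ng = c(5, 5)), cnt),
    "disagree"
  )
})

test_that("results tables round-trip and reject empty input", {
  dir <- withr::local_tempdir()
  res <- data.frame(otu_id = c("A", "B"), taxonomy = c("tax1", NA),
                    ks_p_12C = c(0.51234567, 0.9), ks_p_13C = c(0.6, 0.7),
                    wm_12C = c(1.6912345, 1.70), wm_13C = c(1.7012345, 1.70),
                    delta_wm = c(0.01, 0), significant = c(TRUE, FALSE),
                    eaf = c(0.1812345, 0), ape = c(18.12345, 0))
  path <- file.path(dir, "res.tsv")
  write_results_table(res, path, header = "seed: 1")
  expect_equal(length(readLines(path)), 4)  # header comment + colnames + 2
  back <- read_results_table(path)
  for (col in c("ks_p_12C", "wm_12C", "wm_13C", "delta_wm", "eaf", "ape"))
    expect_equal(back[[col]], res[[col]], tolerance = 1e-6)
  expect_equal(back$significant, res$significant)
  expect_error(write_results_table(res[0, ], file.path(dir, "empty.tsv")),
               "non-empty")
  expect_false(file.exists(file.path(dir, "empty.tsv")))
})
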