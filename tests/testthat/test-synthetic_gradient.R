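test_that("community construction validates its ground truth", {
  expect_error(synthetic_community("a", 0.5, 0.9, 0), "sum to 1")
  comm <- synthetic_community(c("a", "b"), c(0.4, 0.6), c(0.5, 0.5),
                              c(0, 0.3))
  expect_s3_class(comm, "synthetic_community")
  expect_equal(nrow(comm), 2)
})

test_that("unlabeled communities band identically in both gradients", {
  comm <- synthetic_community(paste0("t", 1:4),
                              gc = c(0.35, 0.45, 0.55, 0.60),
                              rel_abundance = rep(0.25, 4),
                              true_eaf = rep(0, 4))
  sim <- simulate_pair(comm, gradient_sim_config(seed = 5))
  expect_equal(sim$truth$labeled_center, sim$truth$control_center)
  expect_equal(sim$truth$true_delta, rep(0, 4))
})

test_that("noise-free simulation recovers the labeled band shift", {
  comm <- synthetic_community("solo", gc = 0.5, rel_abundance = 1,
                              true_eaf = 0.5)
  cfg <- gradient_sim_config(reads_per_fraction = 1e6, dna_noise_cv = 0,
                             refraction_noise_sd = 0,
                             background_mass = 0, seed = 17)
  sim <- simulate_pair(comm, cfg)
  d13 <- build_distribution(sim$labeled, "solo")
  d12 <- build_distribution(sim$control, "solo")
  delta <- weighted_mean_density(d13) - weighted_mean_density(d12)
  expect_equal(delta, sim$truth$true_delta, tolerance = 2e-4)
})

test_that("every fraction's reads are conserved by the multinomial draw", {
  comm <- study_community(seed = 2)
  cfg <- gradient_sim_config(seed = 3)
  sim <- simulate_pair(comm, cfg)
  expect_true(all(rowSums(sim$labeled$counts) == cfg$reads_per_fraction))
  expect_true(all(rowSums(sim$control$counts) == cfg$reads_per_fraction))
})

test_that("identical seeds give byte-identical fixtures", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_study_fixture(seed = 4, dir = d1)
  fx2 <- make_study_fixture(seed = 4, dir = d2)
  for (f in names(fx1$paths))
    expect_identical(readLines(fx1$paths[[f]]), readLines(fx2$paths[[f]]))
  expect_equal(nrow(fx1$truth), nrow(study_community(seed = 4)))
})

test_that("analysis of the study fixture recovers the labeled taxa", {
  fx <- make_study_fixture(seed = 6, dir = withr::local_tempdir())
  labeled <- read_gradient_table(fx$paths[["labeled"]], quiet = TRUE)
  control <- read_gradient_table(fx$paths[["control"]], quiet = TRUE)
  res <- compare_gradients(labeled, control)
  mg <- merge(res, fx$truth, by = "otu_id")
  elig <- mg$true_eaf >= 0.09 & mg$rel_abundance >= 0.005
  expect_gte(sum(mg$significant[elig]) / sum(elig), 0.9)
})

test_that("out-of-range band centers trigger a warning naming the taxon", {
  comm <- synthetic_community(c("inside", "outside"), c(0.45, 0.45),
                              c(0.5, 0.5), c(0, 0.9))
  cfg <- gradient_sim_config(density_min = 1.66, density_max = 1.70,
                             seed = 8)
  expect_warning(simulate_pair(comm, cfg), "outside")
})

test_that("detection power rises with label strength and abundance", {
  eafs <- c(0.05, 0.15, 0.40)
  abund <- c(0.002, 0.01, 0.05)
  set.seed(30)
  seeds <- sample.int(1e6, 6)
  hits <- matrix(0, 3, 3)
  for (s in seeds) {
    # one focal taxon per (eaf, abundance) cell plus shared background
    grid <- expand.grid(e = eafs, a = abund)
    ids <- sprintf("f%02d", seq_len(nrow(grid)))
    rest <- 1 - sum(grid$a)
    comm <- synthetic_community(
      c(ids, paste0("bg", 1:20)),
      gc = c(rep(0.45, nrow(grid)), seq(0.35, 0.58, length.out = 20)),
      rel_abundance = c(grid$a, rep(rest / 20, 20)),
      true_eaf = c(grid$e, rep(0, 20)))
    sim <- simulate_pair(comm, gradient_sim_config(seed = s))
    res <- compare_gradients(sim$labeled, sim$control)
    sig <- res$significant[match(ids, res$otu_id)]
    hits <- hits + matrix(as.numeric(sig), 3, 3)
  }
  # power is non-decreasing in true EAF at every abundance...
  for (j in 1:3) expect_true(all(diff(hits[, j]) >= 0))
  # ...and the strongest cell beats the weakest
  expect_gt(hits[3, 3], hits[1, 1])
})
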