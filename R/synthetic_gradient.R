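#' Define a ground-truth synthetic community
#'
#' @param otu_id Character vector of taxon ids.
#' @param gc GC fraction per taxon (0-1).
#' @param rel_abundance Relative abundances, must sum to 1 (within 1e-9).
#' @param true_eaf True excess atom fraction per taxon (0-1); 0 means
#'   unlabeled.
#' @param band_sigma Gaussian band width in density units (g/ml). The
#'   diffusion-sedimentation equilibrium band of genomic DNA is
#'   approximately Gaussian in density; 0.006 g/ml is a typical spread
#'   for fragmented environmental DNA.
#' @return Data frame of class `synthetic_community`.
#' @export
synthetic_community <- function(otu_id, gc, rel_abundance, true_eaf,
                                band_sigma = 0.006) {
  stopifnot(length(otu_id) == length(gc),
            length(gc) == length(rel_abundance),
            length(rel_abundance) == length(true_eaf),
            all(gc >= 0 & gc <= 1),
            all(true_eaf >= 0 & true_eaf <= 1),
            all(rel_abundance >= 0))
  if (abs(sum(rel_abundance) - 1) > 1e-9)
    stop("rel_abundance must sum to 1")
  out <- data.frame(otu_id = as.character(otu_id), gc = gc,
                    rel_abundance = rel_abundance, true_eaf = true_eaf,
                    band_sigma = band_sigma,
                    stringsAsFactors = FALSE)
  class(out) <- c("synthetic_community", "data.frame")
  out
}

#' Simulator settings for paired gradients
#'
#' Defaults emulate a typical marine Tag-SIP run: 50 fractions spanning
#' 1.66-1.77 g/ml, per-fraction amplicon libraries of 20,000 reads, 500 ng
#' of DNA recovered per gradient, 5% CV lognormal noise on per-fraction
#' DNA quantification, and refractometer noise of 1e-4 refractive-index
#' units (about 1.1e-3 g/ml on the density axis).
#'
#' @param n_fractions Number of fractions (>= 5).
#' @param density_min,density_max Gradient span in g/ml.
#' @param reads_per_fraction Amplicon reads sequenced per fraction.
#' @param dna_total Total DNA recovered over the gradient (ng).
#' @param dna_noise_cv Lognormal CV of per-fraction DNA quantification.
#' @param refraction_noise_sd SD of refractometer noise (refractive-index
#'   units).
#' @param background_mass Fraction of total DNA mass spread uniformly
#'   across fractions (carryover/smear between fractions), keeping every
#'   fraction's sequencing library non-empty.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return Object of class `gradient_sim_config`.
#' @export
gradient_sim_config <- function(n_fractions = 50, density_min = 1.66,
                                density_max = 1.77,
                                reads_per_fraction = 20000,
                                dna_total = 500, dna_noise_cv = 0.05,
                                refraction_noise_sd = 1e-4,
                                background_mass = 1e-4, seed = 1L) {
  stopifnot(density_min < density_max, n_fractions >= 5,
            reads_per_fraction > 0, dna_total > 0, dna_noise_cv >= 0,
            refraction_noise_sd >= 0, background_mass >= 0)
  structure(list(n_fractions = n_fractions, density_min = density_min,
                 density_max = density_max,
                 reads_per_fraction = reads_per_fraction,
                 dna_total = dna_total, dna_noise_cv = dna_noise_cv,
                 refraction_noise_sd = refraction_noise_sd,
                 background_mass = background_mass,
                 seed = as.integer(seed)),
            class = "gradient_sim_config")
}

# Expected per-fraction mass matrix (fractions x taxa): each taxon's
# Gaussian band integrated over each fraction's half-open density
# interval, plus a uniform background smear. Columns sum to taxon
# relative abundance (up to tail truncation outside the gradient span).
.band_mass <- function(community, centers, cfg) {
  bounds <- seq(cfg$density_min, cfg$density_max,
                length.out = cfg$n_fractions + 1)
  m <- vapply(seq_len(nrow(community)), function(i) {
    cdf <- stats::pnorm(bounds, mean = centers[i],
                        sd = community$band_sigma[i])
    band <- diff(cdf)
    community$rel_abundance[i] *
      ((1 - cfg$background_mass) * band +
         cfg$background_mass / cfg$n_fractions)
  }, numeric(cfg$n_fractions))
  colnames(m) <- community$otu_id
  m
}

# One gradient: multinomial reads per fraction, noisy DNA quantification,
# noisy refractometry (sorted to preserve monotone fraction order).
.simulate_gradient <- function(community, centers, cfg, sample_id,
                               isotope) {
  mass <- .band_mass(community, centers, cfg)
  mids <- cfg$density_min +
    (seq_len(cfg$n_fractions) - 0.5) *
    (cfg$density_max - cfg$density_min) / cfg$n_fractions

  counts <- vapply(seq_len(cfg$n_fractions), function(f) {
    pr <- mass[f, ]
    if (sum(pr) <= 0) return(integer(ncol(mass)))
    as.integer(stats::rmultinom(1, cfg$reads_per_fraction, pr))
  }, integer(ncol(mass)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- t(counts)
  colnames(counts) <- colnames(mass)

  ln_sd <- sqrt(log(1 + cfg$dna_noise_cv^2))
  dna <- cfg$dna_total * rowSums(mass) *
    stats::rlnorm(cfg$n_fractions, -ln_sd^2 / 2, ln_sd)

  n_c <- density_to_refraction(mids) +
    stats::rnorm(cfg$n_fractions, 0, cfg$refraction_noise_sd)
  # fraction order is known from collection; sorting the noisy readings
  # is the minimal monotone repair of refractometer noise
  n_c <- sort(n_c)

  gradient_profile(
    data.frame(fraction = seq_len(cfg$n_fractions), n_c = n_c,
               density = refraction_to_density(n_c), dna_ng = dna),
    counts, sample_id = sample_id, isotope = isotope
  )
}

#' Simulate a paired 13C/12C gradient fractionation
#'
#' Forward model of the Tag-SIP experiment. Each taxon bands as a
#' Gaussian in density centered at [gc_to_density()] of its GC in the
#' control gradient; in the labeled gradient the center is shifted by
#' [density_shift_for_eaf()] of its true EAF. Per-fraction taxon masses
#' integrate the band over each fraction's density interval; amplicon
#' counts are multinomial draws of `reads_per_fraction` reads per
#' fraction; DNA quantification and refractometry carry the configured
#' noise.
#'
#' @param community A [synthetic_community()].
#' @param cfg A [gradient_sim_config()].
#' @param model A [labeling_model()].
#' @return List with `labeled` and `control` [gradient_profile()]s and a
#'   `truth` data frame (`otu_id, gc, rel_abundance, true_eaf,
#'   control_center, labeled_center, true_delta`).
#' @export
simulate_pair <- function(community, cfg = gradient_sim_config(),
                          model = labeling_model()) {
  stopifnot(inherits(community, "synthetic_community"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ctr_center <- gc_to_density(community$gc, model)
  lab_center <- ctr_center +
    density_shift_for_eaf(ctr_center, community$true_eaf, model)
  out_of_range <-
    pmin(ctr_center, lab_center) <
      cfg$density_min - 3 * community$band_sigma |
    pmax(ctr_center, lab_center) >
      cfg$density_max + 3 * community$band_sigma
  if (any(out_of_range))
    warning("band center(s) outside gradient span by > 3 sigma: ",
            paste(community$otu_id[out_of_range], collapse = ", "))

  control <- .simulate_gradient(community, ctr_center, cfg,
                                "sim_12C", "12C")
  labeled <- .simulate_gradient(community, lab_center, cfg,
                                "sim_13C", "13C")
  truth <- data.frame(otu_id = community$otu_id, gc = community$gc,
                      rel_abundance = community$rel_abundance,
                      true_eaf = community$true_eaf,
                      control_center = ctr_center,
                      labeled_center = lab_center,
                      true_delta = lab_center - ctr_center,
                      stringsAsFactors = FALSE)
  list(labeled = labeled, control = control, truth = truth)
}

#' Draw a study-like ground-truth community
#'
#' Emulates the structure of a naphthalene-amended coastal seawater
#' community after incubation: `n` taxa with lognormal relative
#' abundances (sdlog 1.5, so a handful of taxa above 1%), GC drawn
#' uniformly from the marine range \[0.32, 0.62\], `n_labeled` taxa
#' labeled at EAF uniform on \[0.09, 0.55\], and the two most abundant
#' taxa labeled heavily (EAF 0.53 and 0.47) mirroring dominant primary
#' degraders.
#'
#' @param seed Integer seed.
#' @param n Community size.
#' @param n_labeled Number of labeled taxa.
#' @return A [synthetic_community()].
#' @export
study_community <- function(seed = 1L, n = 200, n_labeled = 30) {
  set.seed(seed)
  ab <- stats::rlnorm(n, 0, 1.5)
  ab <- ab / sum(ab)
  gc <- stats::runif(n, 0.32, 0.62)
  eaf <- numeric(n)
  ord <- order(-ab)
  labeled_idx <- c(ord[1:2],
                   sample(setdiff(seq_len(n), ord[1:2]), n_labeled - 2))
  eaf[labeled_idx] <- stats::runif(n_labeled, 0.09, 0.55)
  eaf[ord[1]] <- 0.53
  eaf[ord[2]] <- 0.47
  ids <- sprintf("OTU%03d", seq_len(n))
  synthetic_community(ids, gc, ab, eaf)
}

#' Write a paired-gradient study fixture to disk
#'
#' Generates a study-like community with [study_community()], simulates a
#' labeled/control gradient pair at default settings, and writes
#' `gradient_13C.tsv`, `gradient_12C.tsv` and `truth.tsv` into `dir`.
#' Deterministic: a fixed seed yields byte-identical files.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param cfg A [gradient_sim_config()]; its seed is derived from `seed`.
#' @return Invisibly, a list with the file `paths`, the simulated
#'   `labeled`/`control` profiles, and the `truth` table.
#' @export
make_study_fixture <- function(seed = 1L, dir = tempfile("fixture"),
                               cfg = gradient_sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  community <- study_community(seed)
  cfg$seed <- sample.int(.Machine$integer.max - 1, 1)  # derived sub-seed
  sim <- simulate_pair(community, cfg)
  paths <- file.path(dir, c("gradient_13C.tsv", "gradient_12C.tsv",
                            "truth.tsv"))
  write_gradient_table(sim$labeled, paths[1])
  write_gradient_table(sim$control, paths[2])
  utils::write.table(sim$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = stats::setNames(paths,
                                         c("labeled", "control", "truth")),
                 labeled = sim$labeled, control = sim$control,
                 truth = sim$truth))
}
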