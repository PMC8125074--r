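# Independent oracles and small builders used across the suite.

# Brute-force weighted mean: expand each density into floor(1e6 * p)
# copies and average.
brute_force_wm <- function(densities, weights) {
  reps <- floor(1e6 * weights)
  mean(rep(densities, reps))
}

# Brute-force one-sided rank-sum p-value: enumerate every assignment of
# the pooled values into a group of size length(x), score by rank sum.
brute_force_ranksum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(pooled), m)
  w_all <- apply(combs, 2, function(i) sum(r[i]))
  mean(w_all >= w_obs - 1e-12)
}

# Hand-trimmed Q2Q3 mean: drop floor(n/4) from each end of the sorted
# vector, average the rest.
brute_force_q2q3 <- function(x) {
  n <- length(x)
  k <- n %/% 4
  s <- sort(x)
  mean(s[(k + 1):(n - k)])
}

# Brute-force KS discrepancy between a weighted step CDF and a normal
# CDF, evaluated on a fine grid spanning the support.
brute_force_ks_d <- function(densities, weights, mean, sd) {
  grid <- seq(min(densities) - 5 * sd, max(densities) + 5 * sd,
              length.out = 200000)
  ecdf_w <- vapply(grid, function(g) sum(weights[densities <= g]),
                   numeric(1))
  max(abs(ecdf_w - stats::pnorm(grid, mean, sd)))
}

# A distribution object without going through a gradient profile.
make_dist <- function(densities, weights, otu_id = "otu",
                      total_reads = 1000L) {
  structure(list(otu_id = otu_id, densities = densities,
                 weights = weights / sum(weights),
                 total_reads = total_reads),
            class = "otu_density_distribution")
}

# A small gradient profile from a density vector, DNA vector and counts.
make_profile <- function(density, dna_ng, counts, sample_id = "p",
                         isotope = "12C") {
  gradient_profile(
    data.frame(fraction = seq_along(density), density = density,
               dna_ng = dna_ng),
    counts, sample_id = sample_id, isotope = isotope
  )
}
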