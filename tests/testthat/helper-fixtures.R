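# Shared fixtures, generated in code at test time.

# Fingerprint-like design matrix: mildly correlated columns on a z-ish scale.
synth_fingerprints <- function(n, p, seed, n_factors = 6, noise_sd = 0.5) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(n * n_factors), n, n_factors)
    load <- matrix(rnorm(n_factors * p, sd = 0.25), n_factors, p)
    0.2 + f %*% load + matrix(rnorm(n * p, sd = noise_sd), n, p)
  })
}

# Parcellation with one L/R homolog pair per entry of `pair_sizes`
# (left region gets the stated size, right gets `right_size`).
toy_parcellation <- function(pair_sizes, right_size = pair_sizes) {
  m <- length(pair_sizes)
  lobes <- rep(c("occipital", "temporal", "parietal", "frontal", "cingulate",
                 "subcortical"), length.out = m)
  meta <- data.frame(
    region_id = c(sprintf("L%02d", 1:m), sprintf("R%02d", 1:m)),
    hemisphere = rep(c("L", "R"), each = m),
    lobe = rep(lobes, 2),
    modeled = TRUE,
    homolog_id = c(sprintf("R%02d", 1:m), sprintf("L%02d", 1:m)),
    n_vertices = c(pair_sizes, right_size),
    stringsAsFactors = FALSE)
  structure(list(vertex_region = rep.int(seq_len(2 * m),
                                         c(pair_sizes, right_size)),
                 region_meta = meta,
                 n_vertices = sum(pair_sizes) + sum(right_size)),
            class = "parcellation")
}

# Plant a single constant R-squared on arbitrary fingerprints.
plant_flat <- function(X, parc, rho, seed, n_domains = 1) {
  n_modeled <- sum(parc$region_meta$modeled)
  cfg <- synthetic_config(n_vertices = nrow(X), n_domains = n_domains,
                          seed = seed,
                          planted_r2 = matrix(rho, n_modeled, n_domains))
  plant_activation(X, parc, cfg, seed = seed)
}

# One small end-to-end synthetic study, generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- maker()
  .fixture_cache[[key]]
}

small_config <- function(seed = 42) {
  synthetic_config(n_vertices = 360, n_regions_per_hemisphere = 4,
                   n_extra_targets = 1, n_subjects = 2, n_runs = 2,
                   n_timepoints = 80, n_domains = 7, n_categories = 7,
                   seed = seed)
}

small_study <- function() {
  cached_fixture("small_study", function() simulate_study(small_config()))
}

# Generator fingerprints at the full 89-target scale (shared by the
# permutation-calibration and detection checks).
fullscale_connectivity <- function(vertices_per_region, n_subjects = 2,
                                   n_runs = 2, seed = 11) {
  key <- sprintf("conn_%d_%d_%d", vertices_per_region, n_subjects, n_runs)
  cached_fixture(key, function() {
    cfg <- synthetic_config(n_vertices = 89 * vertices_per_region,
                            n_regions_per_hemisphere = 41,
                            n_extra_targets = 7, n_subjects = n_subjects,
                            n_runs = n_runs, n_timepoints = 120,
                            n_domains = 1, n_categories = 1,
                            planted_r2 = matrix(0, 82, 1), seed = seed)
    parc <- make_parcellation(cfg)
    sim <- simulate_timeseries(parc, cfg)
    conn <- compute_connectivity(sim$timeseries, parc, sim$compartments)
    list(config = cfg, parcellation = parc, connectivity = conn)
  })
}
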