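# Synthetic study generator: latent AR(1) regional signals, vertex
# timecourses with dense cross-region mixing and shared nuisance
# compartments, and activation maps planted as noisy linear functions of
# the resulting connectivity fingerprints.

# Rows are independent AR(1) processes with unit stationary variance.
ar1_rows <- function(n_rows, n_time, phi) {
  innov <- matrix(rnorm(n_rows * n_time), n_rows, n_time)
  x <- matrix(0, n_rows, n_time)
  x[, 1] <- innov[, 1] / sqrt(1 - phi^2)
  for (t in seq_len(n_time)[-1]) x[, t] <- phi * x[, t - 1] + innov[, t]
  x * sqrt(1 - phi^2)
}

#' Simulate multi-subject, multi-run vertex timeseries
#'
#' Each connectivity-target region carries a latent AR(1) signal per run.
#' A vertex's timecourse is its loading on the own-region latent, plus dense
#' random mixing onto every target's latent (fixed by the seed, shared
#' across subjects and runs, so group-average fingerprints are stable), plus
#' leakage from two shared nuisance compartments (WM-like and CSF-like
#' multichannel signals, the aCompCor targets), plus white noise.
#'
#' @param parcellation a `parcellation` from [make_parcellation()].
#' @param config a [synthetic_config()].
#' @param seed master seed (defaults to `config$seed`). Identical
#'   (parcellation, config, seed) gives bitwise-identical output.
#' @return list with `timeseries` (per subject, per run, vertices x time
#'   matrix) and `compartments` (per subject, per run, a list of two
#'   channels x time matrices named `wm` and `csf`).
#' @export
simulate_timeseries <- function(parcellation, config, seed = config$seed) {
  validate_parcellation(parcellation)
  if (config$n_timepoints <= 0) stop("n_timepoints must be positive")
  n <- parcellation$n_vertices
  K <- nrow(parcellation$region_meta)
  Tn <- config$n_timepoints
  nf <- config$n_compartment_factors
  nch <- config$n_compartment_channels
  vr <- parcellation$vertex_region

  fixed <- with_substream(derive_seed(seed, "loadings"), {
    list(a = runif(n, config$loading_range[1], config$loading_range[2]),
         mix = matrix(rnorm(n * K, sd = config$mixing_sd), n, K),
         u_wm = matrix(rnorm(n * nf), n, nf),
         u_csf = matrix(rnorm(n * nf), n, nf),
         g_wm = matrix(rnorm(nch * nf), nch, nf),
         g_csf = matrix(rnorm(nch * nf), nch, nf))
  })

  ts <- vector("list", config$n_subjects)
  comps <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    ts[[s]] <- vector("list", config$n_runs)
    comps[[s]] <- vector("list", config$n_runs)
    for (r in seq_len(config$n_runs)) {
      out <- with_substream(derive_seed(seed, "timeseries", s, r), {
        L <- ar1_rows(K, Tn, config$noise_ar_coefficient)
        f_wm <- ar1_rows(nf, Tn, config$noise_ar_coefficient)
        f_csf <- ar1_rows(nf, Tn, config$noise_ar_coefficient)
        wm <- fixed$g_wm %*% f_wm + 0.5 * matrix(rnorm(nch * Tn), nch, Tn)
        csf <- fixed$g_csf %*% f_csf + 0.5 * matrix(rnorm(nch * Tn), nch, Tn)
        y <- fixed$a * L[vr, , drop = FALSE] +
          fixed$mix %*% L +
          config$compartment_loading *
            (fixed$u_wm %*% f_wm + fixed$u_csf %*% f_csf) +
          config$white_noise_sd * matrix(rnorm(n * Tn), n, Tn)
        list(y = y, wm = wm, csf = csf)
      })
      ts[[s]][[r]] <- out$y
      comps[[s]][[r]] <- list(wm = out$wm, csf = out$csf)
    }
  }
  list(timeseries = ts, compartments = comps)
}

#' Default planted R-squared grid
#'
#' A deterministic grid over (modeled region, domain) spanning exactly
#' `config$planted_r2_range`, so the planted heterogeneity covers the
#' configured range by construction.
#'
#' @param config a [synthetic_config()].
#' @return numeric matrix, modeled regions x domains, values in the range.
#' @export
default_planted_r2 <- function(config) {
  M <- 2L * config$n_regions_per_hemisphere
  D <- config$n_domains
  lo <- config$planted_r2_range[1]
  hi <- config$planted_r2_range[2]
  cells <- M * D
  vals <- if (cells == 1) (lo + hi) / 2 else
    lo + (hi - lo) * (seq_len(cells) - 1) / (cells - 1)
  matrix(vals, M, D)
}

#' Plant activation maps on connectivity fingerprints
#'
#' For each (modeled region, domain): draws a weight vector over
#' connectivity targets, forms the signal `s = X_region %*% w`, and
#' calibrates the i.i.d. Gaussian noise SD so that
#' `var(s) / (var(s) + noise_sd^2)` equals the planted R-squared exactly.
#' The region's activation values are `s + noise`, standardized to a
#' z-like scale; vertices of unmodeled regions receive standard-normal
#' background. Ground truth records the (rescaled) weights, noise SD, and
#' achieved R-squared.
#'
#' @param fingerprints a `connectivity_matrix` (or plain vertices x targets
#'   matrix) of Fisher-z fingerprints for all vertices.
#' @param parcellation the matching `parcellation`.
#' @param config a [synthetic_config()]; `planted_r2` (matrix modeled
#'   regions x domains) comes from the config or [default_planted_r2()].
#' @param seed master seed (defaults to `config$seed`).
#' @return list with `activation` (vertices x domains matrix, columns named
#'   by domain), `labels` (domain-to-category table), and `ground_truth`
#'   (list: `table` with region_id, domain_id, planted_r2, noise_sd,
#'   achieved_r2; `weights`, a targets x regions x domains array).
#' @export
plant_activation <- function(fingerprints, parcellation, config,
                             seed = config$seed) {
  X <- if (inherits(fingerprints, "connectivity_matrix"))
    fingerprints$values else as.matrix(fingerprints)
  validate_parcellation(parcellation)
  if (nrow(X) != parcellation$n_vertices)
    stop(sprintf("fingerprints have %d rows but parcellation has %d vertices",
                 nrow(X), parcellation$n_vertices))
  planted <- if (is.null(config$planted_r2)) default_planted_r2(config)
    else config$planted_r2
  mids <- modeled_region_ids(parcellation)
  D <- config$n_domains
  planted <- matrix(planted, length(mids), D)
  if (any(planted < 0 | planted > 1)) stop("planted_r2 must lie in [0, 1]")

  labels <- domain_labels(config)
  K <- ncol(X)
  n <- nrow(X)
  activation <- with_substream(derive_seed(seed, "background"),
                               matrix(rnorm(n * D), n, D))
  colnames(activation) <- labels$domain_id
  weights <- array(0, dim = c(K, length(mids), D),
                   dimnames = list(NULL, mids, labels$domain_id))
  gt <- expand.grid(region_id = mids, domain_id = labels$domain_id,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gt$planted_r2 <- as.vector(planted)
  gt$noise_sd <- NA_real_
  gt$achieved_r2 <- NA_real_

  for (j in seq_len(D)) {
    for (i in seq_along(mids)) {
      vidx <- region_vertices(parcellation, mids[i])
      rho <- planted[i, j]
      draw <- with_substream(derive_seed(seed, "plant", mids[i],
                                         labels$domain_id[j]), {
        list(w = rnorm(K), eps = rnorm(length(vidx)))
      })
      w <- draw$w
      s <- as.vector(X[vidx, , drop = FALSE] %*% w)
      vs <- var(s)
      if (rho == 0) {
        w <- rep(0, K)
        s <- rep(0, length(vidx))
        vs <- 0
        noise_sd <- 1
      } else if (rho == 1) {
        if (vs <= 0)
          stop(sprintf("planted_r2 = 1 requires nonzero signal variance in region %s",
                       mids[i]))
        noise_sd <- 0
      } else {
        if (vs <= 0)
          stop(sprintf("zero-variance signal in region %s", mids[i]))
        noise_sd <- sqrt(vs * (1 - rho) / rho)
      }
      a_raw <- s + noise_sd * draw$eps
      sd_raw <- sd(a_raw)
      if (sd_raw <= 0)
        stop(sprintf("degenerate activation in region %s domain %s",
                     mids[i], labels$domain_id[j]))
      activation[vidx, j] <- (a_raw - mean(a_raw)) / sd_raw
      row <- (j - 1L) * length(mids) + i
      weights[, i, j] <- w / sd_raw
      gt$noise_sd[row] <- noise_sd / sd_raw
      gt$achieved_r2[row] <- if (vs == 0) 0 else vs / (vs + noise_sd^2)
    }
  }
  list(activation = activation, labels = labels,
       ground_truth = list(table = gt, weights = weights))
}

#' Simulate a complete synthetic study
#'
#' Runs the generator end to end: parcellation, multi-run timeseries,
#' group connectivity fingerprints (with optional compartment-PC nuisance
#' regression), and planted activation maps with ground truth.
#'
#' @param config a [synthetic_config()].
#' @param nuisance logical; regress compartment PCs out of vertex
#'   timecourses before computing connectivity (default `TRUE`).
#' @param n_nuisance_components PCs per compartment (default 5).
#' @return list: `config`, `parcellation`, `timeseries`, `compartments`,
#'   `connectivity` (a `connectivity_matrix`), `activation`, `labels`,
#'   `ground_truth`.
#' @examples
#' cfg <- synthetic_config(n_vertices = 180, n_regions_per_hemisphere = 4,
#'                         n_extra_targets = 1, n_subjects = 2, n_runs = 2,
#'                         n_timepoints = 60, n_domains = 4,
#'                         n_categories = 2, seed = 7)
#' study <- simulate_study(cfg)
#' dim(study$connectivity$values)  # 180 x 9
#' @export
simulate_study <- function(config, nuisance = TRUE,
                           n_nuisance_components = 5L) {
  parc <- make_parcellation(config)
  sim <- simulate_timeseries(parc, config)
  conn <- compute_connectivity(sim$timeseries, parc,
                               compartments = if (nuisance) sim$compartments,
                               n_components = n_nuisance_components)
  planted <- plant_activation(conn, parc, config)
  c(list(config = config, parcellation = parc), sim,
    list(connectivity = conn), planted)
}
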