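#' Construct the synthetic-study configuration
#'
#' Bundles every knob of the synthetic generator. The defaults emulate the
#' design of a whole-brain connectivity-fingerprint study: a
#' Desikan-Killiany-like parcellation with 41 modeled regions per hemisphere
#' (82 modeled regions), 7 additional connectivity-target-only regions
#' (89 targets in total), 4 resting-state runs per subject, and 33 cognitive
#' domains spread over 7 categories.
#'
#' @param n_vertices total number of vertices (grayordinates). Must be at
#'   least 4 x the number of connectivity targets.
#' @param n_regions_per_hemisphere modeled regions per hemisphere (default 41).
#' @param n_extra_targets connectivity-target-only regions that receive no
#'   models (default 7).
#' @param n_subjects,n_runs,n_timepoints resting-state dimensions; each
#'   subject contributes `n_runs` runs of `n_timepoints` samples.
#' @param n_domains number of cognitive domains (activation maps).
#' @param n_categories number of domain categories (<= 7 named categories).
#' @param planted_r2 optional numeric matrix (modeled regions x domains) of
#'   generative R-squared values in `[0, 1]`; if `NULL`, a deterministic grid
#'   spanning `planted_r2_range` is used.
#' @param planted_r2_range length-2 range used to build the default
#'   `planted_r2` grid.
#' @param noise_ar_coefficient AR(1) coefficient of every latent regional
#'   signal, in `[0, 1)`.
#' @param loading_range range of each vertex's loading onto its own region's
#'   latent signal.
#' @param mixing_sd standard deviation of the dense cross-region mixing
#'   loadings (what makes fingerprints heterogeneous).
#' @param white_noise_sd standard deviation of i.i.d. vertex noise.
#' @param compartment_loading strength of the shared nuisance-compartment
#'   (WM-like / CSF-like) signal leaking into vertex timecourses.
#' @param n_compartment_channels,n_compartment_factors channels per noise
#'   compartment and latent factors driving them.
#' @param size_dispersion 0 for near-equal region sizes; larger values give
#'   lognormal size heterogeneity (real parcel sizes vary widely).
#' @param seed master seed; all stages derive named substreams from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_vertices = 2670,
                             n_regions_per_hemisphere = 41,
                             n_extra_targets = 7,
                             n_subjects = 8,
                             n_runs = 4,
                             n_timepoints = 150,
                             n_domains = 33,
                             n_categories = 7,
                             planted_r2 = NULL,
                             planted_r2_range = c(0.2, 0.95),
                             noise_ar_coefficient = 0.4,
                             loading_range = c(0.8, 1.2),
                             mixing_sd = 0.15,
                             white_noise_sd = 1,
                             compartment_loading = 0.3,
                             n_compartment_channels = 12,
                             n_compartment_factors = 3,
                             size_dispersion = 0,
                             seed = 1L) {
  cfg <- list(n_vertices = as.integer(n_vertices),
              n_regions_per_hemisphere = as.integer(n_regions_per_hemisphere),
              n_extra_targets = as.integer(n_extra_targets),
              n_subjects = as.integer(n_subjects),
              n_runs = as.integer(n_runs),
              n_timepoints = as.integer(n_timepoints),
              n_domains = as.integer(n_domains),
              n_categories = as.integer(n_categories),
              planted_r2 = planted_r2,
              planted_r2_range = as.numeric(planted_r2_range),
              noise_ar_coefficient = as.numeric(noise_ar_coefficient),
              loading_range = as.numeric(loading_range),
              mixing_sd = as.numeric(mixing_sd),
              white_noise_sd = as.numeric(white_noise_sd),
              compartment_loading = as.numeric(compartment_loading),
              n_compartment_channels = as.integer(n_compartment_channels),
              n_compartment_factors = as.integer(n_compartment_factors),
              size_dispersion = as.numeric(size_dispersion),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_vertices > 0, cfg$n_regions_per_hemisphere > 0,
            cfg$n_extra_targets >= 0, cfg$n_subjects > 0, cfg$n_runs > 0,
            cfg$n_domains > 0, cfg$n_categories > 0)
  if (cfg$n_timepoints <= 10)
    stop("n_timepoints must exceed 10")
  if (cfg$noise_ar_coefficient < 0 || cfg$noise_ar_coefficient >= 1)
    stop("noise_ar_coefficient must lie in [0, 1)")
  if (!is.null(cfg$planted_r2)) {
    if (any(cfg$planted_r2 < 0 | cfg$planted_r2 > 1))
      stop("every planted_r2 must lie in [0, 1]")
  }
  if (any(cfg$planted_r2_range < 0 | cfg$planted_r2_range > 1))
    stop("planted_r2_range must lie within [0, 1]")
  invisible(cfg)
}

.lobe_cycle <- c("occipital", "temporal", "parietal", "frontal",
                 "cingulate", "subcortical")

.category_names <- c("sensory", "somatosensory", "language",
                     "decision-making", "social", "memory",
                     "executive function")

#' Build a synthetic parcellation
#'
#' Partitions vertices into connectivity-target regions, mirroring a
#' Desikan-Killiany-style scheme: `n_regions_per_hemisphere` modeled regions
#' in each hemisphere (each left-hemisphere region paired with exactly one
#' right homolog, sharing a lobe drawn round-robin from occipital, temporal,
#' parietal, frontal, cingulate, subcortical) plus `n_extra_targets` midline
#' regions that serve as connectivity targets only and are flagged
#' unmodeled. Region sizes are near-equal unless `size_dispersion > 0`.
#'
#' @param config a [synthetic_config()].
#' @return a `parcellation` object: `vertex_region` (integer index per
#'   vertex into `region_meta`), and `region_meta`, a data frame with
#'   columns `region_id`, `hemisphere` (`"L"`, `"R"`, `"midline"`), `lobe`,
#'   `modeled`, `homolog_id`, `n_vertices`.
#' @examples
#' p <- make_parcellation(synthetic_config(n_vertices = 820,
#'                                         n_extra_targets = 0))
#' table(p$region_meta$n_vertices)  # 82 regions of 10 vertices
#' @export
make_parcellation <- function(config) {
  n_modeled <- 2L * config$n_regions_per_hemisphere
  n_targets <- n_modeled + config$n_extra_targets
  if (config$n_vertices < 4L * n_targets)
    stop(sprintf(paste0("too few vertices: %d cannot give each of %d target",
                        " regions at least 4 vertices (need >= %d)"),
                 config$n_vertices, n_targets, 4L * n_targets))

  nrph <- config$n_regions_per_hemisphere
  pair_lobe <- .lobe_cycle[((seq_len(nrph) - 1L) %% length(.lobe_cycle)) + 1L]
  l_ids <- sprintf("L%02d", seq_len(nrph))
  r_ids <- sprintf("R%02d", seq_len(nrph))
  x_ids <- if (config$n_extra_targets > 0)
    sprintf("X%02d", seq_len(config$n_extra_targets)) else character(0)

  region_meta <- data.frame(
    region_id = c(l_ids, r_ids, x_ids),
    hemisphere = c(rep("L", nrph), rep("R", nrph),
                   rep("midline", config$n_extra_targets)),
    lobe = c(pair_lobe, pair_lobe, rep(NA_character_, config$n_extra_targets)),
    modeled = c(rep(TRUE, n_modeled), rep(FALSE, config$n_extra_targets)),
    homolog_id = c(r_ids, l_ids, rep(NA_character_, config$n_extra_targets)),
    stringsAsFactors = FALSE)

  sizes <- allocate_region_sizes(config$n_vertices, n_targets,
                                 config$size_dispersion, config$seed)
  region_meta$n_vertices <- sizes
  vertex_region <- rep.int(seq_len(n_targets), sizes)

  structure(list(vertex_region = vertex_region,
                 region_meta = region_meta,
                 n_vertices = config$n_vertices),
            class = "parcellation")
}

# Largest-remainder allocation with a floor of 4 vertices per region.
allocate_region_sizes <- function(n_vertices, n_regions, dispersion, seed) {
  w <- if (dispersion > 0) {
    with_substream(derive_seed(seed, "parcel_sizes"),
                   exp(rnorm(n_regions, sd = dispersion)))
  } else rep(1, n_regions)
  share <- n_vertices * w / sum(w)
  sizes <- pmax(4L, as.integer(floor(share)))
  excess <- sum(sizes) - n_vertices
  if (excess > 0) { # floors pushed us over; trim the largest regions
    for (i in order(sizes, decreasing = TRUE)) {
      if (excess == 0) break
      take <- min(excess, sizes[i] - 4L)
      sizes[i] <- sizes[i] - take
      excess <- excess - take
    }
  } else if (excess < 0) {
    frac <- share - floor(share)
    add <- order(frac, decreasing = TRUE)[seq_len(-excess)]
    sizes[add] <- sizes[add] + 1L
  }
  stopifnot(sum(sizes) == n_vertices, all(sizes >= 4L))
  sizes
}

#' @export
print.parcellation <- function(x, ...) {
  m <- x$region_meta
  cat(sprintf("parcellation: %d vertices, %d target regions (%d modeled)\n",
              x$n_vertices, nrow(m), sum(m$modeled)))
  invisible(x)
}

validate_parcellation <- function(parc) {
  m <- parc$region_meta
  stopifnot(inherits(parc, "parcellation"),
            length(parc$vertex_region) == parc$n_vertices,
            all(parc$vertex_region >= 1L),
            all(parc$vertex_region <= nrow(m)))
  counts <- tabulate(parc$vertex_region, nbins = nrow(m))
  if (any(counts[m$modeled] < 1L))
    stop(sprintf("modeled region(s) without vertices: %s",
                 paste(m$region_id[m$modeled & counts < 1L], collapse = ", ")))
  hom <- match(m$homolog_id, m$region_id)
  paired <- which(!is.na(hom))
  if (any(m$homolog_id[hom[paired]] != m$region_id[paired]))
    stop("homolog pairing is not symmetric")
  invisible(parc)
}

#' Vertex indices of one region
#'
#' Row indices (into timeseries and connectivity matrices) of the vertices
#' assigned to `region_id`.
#'
#' @param parc a `parcellation`.
#' @param region_id a region identifier from `parc$region_meta$region_id`.
#' @return integer vector of vertex indices.
#' @export
region_vertices <- function(parc, region_id) {
  idx <- match(region_id, parc$region_meta$region_id)
  if (is.na(idx)) stop(sprintf("unknown region '%s'", region_id))
  which(parc$vertex_region == idx)
}

#' @rdname region_vertices
#' @return `modeled_region_ids` returns the identifiers of regions that
#'   receive models.
#' @export
modeled_region_ids <- function(parc) {
  parc$region_meta$region_id[parc$region_meta$modeled]
}

#' Enumerate the model design
#'
#' One ridge model is fitted per (modeled region, domain) pair; this returns
#' that grid. At the full design scale (41 regions per hemisphere, 33
#' domains) it enumerates 82 x 33 = 2,706 models.
#'
#' @param parcellation a `parcellation`.
#' @param domain_ids character vector of domain identifiers.
#' @return data frame with columns `region_id`, `domain_id`.
#' @export
design_table <- function(parcellation, domain_ids) {
  validate_parcellation(parcellation)
  stopifnot(length(domain_ids) >= 1)
  expand.grid(region_id = modeled_region_ids(parcellation),
              domain_id = as.character(domain_ids),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Default domain-to-category labels
#'
#' Assigns `n_domains` domains round-robin to the first `n_categories` of
#' the seven canonical categories (sensory, somatosensory, language,
#' decision-making, social, memory, executive function).
#'
#' @param config a [synthetic_config()].
#' @return data frame with columns `domain_id`, `category`.
#' @export
domain_labels <- function(config) {
  k <- min(config$n_categories, length(.category_names))
  data.frame(
    domain_id = sprintf("domain_%02d", seq_len(config$n_domains)),
    category = .category_names[((seq_len(config$n_domains) - 1L) %% k) + 1L],
    stringsAsFactors = FALSE)
}

#' Write / read a parcellation as TSV
#'
#' Two plain-text tables: `<stem>_vertices.tsv` (`vertex_id`, `region_id`)
#' and `<stem>_regions.tsv` (region metadata).
#'
#' @param parcellation a `parcellation`.
#' @param stem path stem for the two files.
#' @return `write_parcellation_tsv` returns the two paths invisibly;
#'   `read_parcellation_tsv` returns a `parcellation`.
#' @export
write_parcellation_tsv <- function(parcellation, stem) {
  validate_parcellation(parcellation)
  vp <- paste0(stem, "_vertices.tsv")
  rp <- paste0(stem, "_regions.tsv")
  vtab <- data.frame(
    vertex_id = seq_len(parcellation$n_vertices),
    region_id = parcellation$region_meta$region_id[parcellation$vertex_region])
  write.table(vtab, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(parcellation$region_meta, rp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vertices = vp, regions = rp))
}

#' @rdname write_parcellation_tsv
#' @export
read_parcellation_tsv <- function(stem) {
  vtab <- read.delim(paste0(stem, "_vertices.tsv"), stringsAsFactors = FALSE)
  meta <- read.delim(paste0(stem, "_regions.tsv"), stringsAsFactors = FALSE)
  meta$lobe <- as.character(meta$lobe)
  meta$homolog_id <- as.character(meta$homolog_id)
  parc <- structure(list(vertex_region = match(vtab$region_id, meta$region_id),
                         region_meta = meta,
                         n_vertices = nrow(vtab)),
                    class = "parcellation")
  validate_parcellation(parc)
  parc
}
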