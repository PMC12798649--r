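# End-to-end orchestration: config, staged execution, result bundle,
# manifest with checksums, and file-format adapters.

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (generator-driven) or `"real"` (file inputs).
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param inputs named list of paths for real mode: `connectivity` (RDS of
#'   a `connectivity_matrix` or vertices x targets matrix), `activation`
#'   (TSV, vertices x domains), `parcellation` (TSV stem), `labels`
#'   (domain-to-category TSV).
#' @param ridge a [ridge_fit_spec()].
#' @param n_permutations permutations per model (default 1000).
#' @param master_seed explicit master seed (no wall-clock seeding).
#' @param laterality_domains domains for the paired hemispheric tests.
#' @param output_dir directory for the result bundle (`NULL` keeps results
#'   in memory only).
#' @param workers parallel workers over models; results are identical for
#'   any worker count.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       synthetic = synthetic_config(),
                       inputs = list(),
                       ridge = ridge_fit_spec(),
                       n_permutations = 1000L,
                       master_seed = 1L,
                       laterality_domains = NULL,
                       output_dir = NULL,
                       workers = 1L) {
  mode <- match.arg(mode)
  if (mode == "real") {
    need <- c("connectivity", "activation", "parcellation", "labels")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0)
      stop(sprintf("real mode needs input paths: %s",
                   paste(miss, collapse = ", ")))
    for (nm in setdiff(need, "parcellation"))
      if (!file.exists(inputs[[nm]]))
        stop(sprintf("input file not found: %s", inputs[[nm]]))
  }
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  structure(list(mode = mode, synthetic = synthetic, inputs = inputs,
                 ridge = ridge, n_permutations = as.integer(n_permutations),
                 master_seed = as.integer(master_seed),
                 laterality_domains = laterality_domains,
                 output_dir = output_dir, workers = as.integer(workers)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds a flat mapping of the [run_config()] arguments; nested
#' `synthetic` and `ridge` mappings override the corresponding defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml/.yml or .json file")
  syn <- do.call(synthetic_config,
                 modifyList(list(), raw$synthetic %||% list()))
  rid <- do.call(ridge_fit_spec, modifyList(list(), raw$ridge %||% list()))
  run_config(mode = raw$mode %||% "synthetic",
             synthetic = syn,
             inputs = raw$inputs %||% list(),
             ridge = rid,
             n_permutations = raw$n_permutations %||% 1000L,
             master_seed = raw$master_seed %||% 1L,
             laterality_domains = raw$laterality_domains,
             output_dir = raw$output_dir,
             workers = raw$workers %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Executes the stages in order — simulate/ingest, group connectivity,
#' one ridge model per (modeled region, domain), a permutation null per
#' model, then the group-statistics layer — and returns the complete
#' result bundle plus a manifest (config hash, stage timings, output
#' checksums). Rerunning with an identical config reproduces identical
#' results.
#'
#' @param config a [run_config()].
#' @return list: `parcellation`, `connectivity`, `activation`, `labels`,
#'   `ground_truth` (synthetic mode), `fits`, `perms`, `fit_table`,
#'   `stats`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tick <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[label]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  if (config$mode == "synthetic") {
    syn <- config$synthetic
    syn$seed <- config$master_seed
    study <- tick("simulate", simulate_study(syn))
    parc <- study$parcellation
    conn <- study$connectivity
    activation <- study$activation
    labels <- study$labels
    ground_truth <- study$ground_truth
  } else {
    parc <- tick("ingest", read_parcellation_tsv(config$inputs$parcellation))
    conn <- readRDS(config$inputs$connectivity)
    if (!inherits(conn, "connectivity_matrix"))
      conn <- structure(list(values = as.matrix(conn),
                             target_region_ids = parc$region_meta$region_id,
                             n_subjects = NA_integer_, n_runs = NA_integer_),
                        class = "connectivity_matrix")
    act_tab <- read.delim(config$inputs$activation, check.names = FALSE)
    activation <- as.matrix(act_tab)
    labels <- read.delim(config$inputs$labels, stringsAsFactors = FALSE)
    ground_truth <- NULL
    if (nrow(activation) != parc$n_vertices)
      stop(sprintf("activation has %d vertices but parcellation has %d",
                   nrow(activation), parc$n_vertices))
  }

  spec <- config$ridge
  spec$seed <- derive_seed(config$master_seed, "cv_folds")
  fits <- tick("fit", fit_all_models(conn, activation, parc, spec,
                                     workers = config$workers))
  perms <- tick("permute",
                permute_all_models(conn, activation, parc, fits,
                                   n_permutations = config$n_permutations,
                                   seed = config$master_seed,
                                   workers = config$workers))
  fit_table <- build_fit_table(fits, perms, parc, labels)
  stats <- tick("stats",
                group_statistics(fit_table, parc,
                                 laterality_domains =
                                   config$laterality_domains,
                                 seed = config$master_seed))

  bundle <- list(parcellation = parc, connectivity = conn,
                 activation = activation, labels = labels,
                 ground_truth = ground_truth, fits = fits, perms = perms,
                 fit_table = fit_table, stats = stats)
  manifest <- list(package_version = as.character(utils::packageVersion("connfit")),
                   config_hash = config_hash(config),
                   n_models = nrow(fits),
                   timings = as.list(timings))
  if (!is.null(config$output_dir)) {
    files <- write_result_bundle(bundle, config$output_dir)
    manifest$checksums <- as.list(tools::md5sum(files))
  }
  bundle$manifest <- manifest
  bundle
}

# Stable hash of the configuration: md5 of its canonical JSON form.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), function(x)
    if (is.function(x)) NULL else x, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write the result bundle to a directory
#'
#' TSV tables (fits + permutation summaries, medians, ANOVA, contrasts,
#' laterality), the parcellation TSV pair, and a ground-truth JSON in
#' synthetic mode.
#'
#' @param bundle result list from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_result_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  fit_full <- merge(bundle$fits, bundle$perms,
                    by = c("region_id", "domain_id"), sort = TRUE)
  wt(fit_full, "fits.tsv")
  wt(bundle$fit_table, "fit_table.tsv")
  wt(bundle$stats$medians$domain, "medians_domain.tsv")
  wt(bundle$stats$medians$category, "medians_category.tsv")
  wt(bundle$stats$medians$lobe, "medians_lobe.tsv")
  an <- bundle$stats$anova
  wt(data.frame(f_stat = an$f_stat, df_between = an$df_between,
                df_within = an$df_within, p_value = an$p_value,
                eta_squared = an$eta_squared), "anova.tsv")
  wt(bundle$stats$contrasts, "contrasts.tsv")
  wt(bundle$stats$laterality, "laterality.tsv")
  paths <- c(paths, write_parcellation_tsv(bundle$parcellation,
                                           file.path(out_dir, "parcellation")))
  if (!is.null(bundle$ground_truth)) {
    p <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(bundle$ground_truth$table, p, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a per-vertex activation map (adapter)
#'
#' Reads an already vertex-aligned scalar map: a NIfTI volume/vector (via
#' the RNifti package) or a plain-text file with one value per line. A
#' vertex-count mismatch against `n_vertices` is an error printing both
#' counts. Exact-zero entries (conventionally masked-out vertices) are
#' counted in attribute `"n_zero"`.
#'
#' @param path `.nii` / `.nii.gz`, or text file of one value per line.
#' @param n_vertices expected vertex count (optional).
#' @return numeric vector, one value per vertex.
#' @export
read_activation_volume <- function(path, n_vertices = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  v <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    as.vector(RNifti::readNifti(path))
  } else {
    scan(path, what = numeric(), quiet = TRUE)
  }
  if (!is.null(n_vertices) && length(v) != n_vertices)
    stop(sprintf("activation map has %d values but parcellation has %d vertices",
                 length(v), n_vertices))
  attr(v, "n_zero") <- sum(v == 0)
  v
}
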