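# Connectivity preprocessing: aCompCor-style nuisance regression, region
# mean timecourses, vertex-to-region Pearson correlation, Fisher z, and
# two-stage (runs-then-subjects) group averaging in z-space.

#' Regress compartment principal components out of vertex timecourses
#'
#' aCompCor-style denoising: extracts the top `n_components` temporal
#' principal components from each noise compartment (e.g. white-matter-like
#' and CSF-like channel sets) independently, concatenates them with an
#' intercept, and returns the least-squares residual of every vertex
#' timecourse. Residuals are orthogonal to every regressor.
#'
#' @param vertex_ts vertices x time matrix.
#' @param compartments list of compartment matrices (channels x time); each
#'   must span the same timepoints as `vertex_ts`.
#' @param n_components temporal PCs per compartment (default 5). If a
#'   compartment supports fewer components, the available rank is used with
#'   a warning.
#' @return vertices x time residual matrix.
#' @export
nuisance_regress <- function(vertex_ts, compartments, n_components = 5L) {
  vertex_ts <- as.matrix(vertex_ts)
  Tn <- ncol(vertex_ts)
  pcs <- lapply(compartments, function(comp) {
    comp <- as.matrix(comp)
    if (ncol(comp) != Tn)
      stop(sprintf("compartment has %d timepoints but timeseries has %d",
                   ncol(comp), Tn))
    avail <- min(nrow(comp), Tn - 1L)
    k <- n_components
    if (avail < n_components) {
      warning(sprintf("compartment supports only %d components (%d requested)",
                      avail, n_components))
      k <- avail
    }
    # temporal PCs: component scores of the time x channel matrix
    prcomp(t(comp), center = TRUE, rank. = k)$x
  })
  reg <- cbind(1, do.call(cbind, pcs))
  q <- qr.Q(qr(reg))
  yt <- t(vertex_ts)                     # time x vertices
  t(yt - q %*% crossprod(q, yt))
}

#' Region mean timecourses
#'
#' Unweighted mean over member vertices per timepoint, for every
#' connectivity-target region in the parcellation.
#'
#' @param vertex_ts vertices x time matrix.
#' @param parcellation a `parcellation`.
#' @return regions x time matrix with rownames set to region ids.
#' @export
region_mean_timecourses <- function(vertex_ts, parcellation) {
  validate_parcellation(parcellation)
  vertex_ts <- as.matrix(vertex_ts)
  if (nrow(vertex_ts) != parcellation$n_vertices)
    stop("timeseries rows do not match parcellation vertex count")
  ids <- parcellation$region_meta$region_id
  counts <- tabulate(parcellation$vertex_region, nbins = length(ids))
  empty <- which(counts == 0L)
  if (length(empty) > 0)
    stop(sprintf("region(s) without vertices: %s",
                 paste(ids[empty], collapse = ", ")))
  sums <- rowsum(vertex_ts, group = parcellation$vertex_region, reorder = TRUE)
  out <- sums / counts
  rownames(out) <- ids
  out
}

#' Vertex-to-region Pearson connectivity
#'
#' Entry (v, R) is the Pearson correlation between vertex v's timecourse
#' and region R's mean timecourse. Zero-variance timecourses are a hard
#' error (identified by row) rather than silent NaN.
#'
#' @param vertex_ts vertices x time matrix.
#' @param region_ts regions x time matrix.
#' @return vertices x regions correlation matrix, values in `[-1, 1]`.
#' @export
vertex_region_connectivity <- function(vertex_ts, region_ts) {
  vertex_ts <- as.matrix(vertex_ts)
  region_ts <- as.matrix(region_ts)
  if (ncol(vertex_ts) != ncol(region_ts))
    stop("vertex and region timeseries must share timepoints")
  vv <- apply(vertex_ts, 1, var)
  if (any(vv <= 0))
    stop(sprintf("zero-variance vertex timecourse(s) at row(s): %s",
                 paste(utils::head(which(vv <= 0), 5), collapse = ", ")))
  rv <- apply(region_ts, 1, var)
  if (any(rv <= 0))
    stop(sprintf("zero-variance region timecourse(s) at row(s): %s",
                 paste(utils::head(which(rv <= 0), 5), collapse = ", ")))
  out <- cor(t(vertex_ts), t(region_ts))
  colnames(out) <- rownames(region_ts)
  out
}

#' Fisher z transform
#'
#' `atanh(r)` after clipping `|r|` to `1 - 1e-7`, so perfect correlations
#' map to a large finite value and downstream regression stays finite.
#' Entries beyond `1 + 1e-12` in absolute value are invalid correlations
#' and raise an error.
#'
#' @param r_matrix correlations (any numeric array).
#' @return z-transformed values, same shape.
#' @examples
#' fisher_z(0.8)  # 0.5 * log(9) = 1.0986...
#' @export
fisher_z <- function(r_matrix) {
  if (any(abs(r_matrix) > 1 + 1e-12, na.rm = TRUE))
    stop("invalid correlation: |r| > 1")
  atanh(pmin(pmax(r_matrix, -(1 - 1e-7)), 1 - 1e-7))
}

#' Group-average Fisher-z connectivity
#'
#' Two-stage mean in z-space: mean over runs within subject, then mean over
#' subjects. No back-transform is applied (fingerprints stay on the z
#' scale).
#'
#' @param per_run_z list over subjects, each a list over runs of
#'   vertices x targets z-matrices, all sharing a shape.
#' @param target_region_ids optional character vector of target ids
#'   (defaults to the column names of the first matrix).
#' @return a `connectivity_matrix`: `values` (vertices x targets),
#'   `target_region_ids`, `n_subjects`, `n_runs`.
#' @export
group_average <- function(per_run_z, target_region_ids = NULL) {
  if (length(per_run_z) == 0) stop("no subjects supplied")
  first <- per_run_z[[1]][[1]]
  dims <- dim(first)
  subj_means <- lapply(per_run_z, function(runs) {
    if (length(runs) == 0) stop("subject with no runs")
    for (m in runs)
      if (!identical(dim(m), dims)) stop("connectivity matrices differ in shape")
    Reduce(`+`, runs) / length(runs)
  })
  values <- Reduce(`+`, subj_means) / length(subj_means)
  if (is.null(target_region_ids)) target_region_ids <- colnames(first)
  structure(list(values = values,
                 target_region_ids = target_region_ids,
                 n_subjects = length(per_run_z),
                 n_runs = length(per_run_z[[1]])),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d vertices x %d targets (Fisher z), %d subjects x %d runs\n",
              nrow(x$values), ncol(x$values), x$n_subjects, x$n_runs))
  invisible(x)
}

#' Compute group connectivity fingerprints from raw timeseries
#'
#' Convenience pipeline over one study: per subject and run, optionally
#' regress out compartment PCs, compute region mean timecourses,
#' vertex-to-region Pearson correlations, Fisher-transform, then average
#' across runs and subjects in z-space.
#'
#' @param timeseries list over subjects of lists over runs of
#'   vertices x time matrices.
#' @param parcellation a `parcellation`.
#' @param compartments optional matching nested list of compartment lists
#'   (as produced by [simulate_timeseries()]); `NULL` disables nuisance
#'   regression.
#' @param n_components PCs per compartment for [nuisance_regress()].
#' @return a `connectivity_matrix`.
#' @export
compute_connectivity <- function(timeseries, parcellation,
                                 compartments = NULL, n_components = 5L) {
  validate_parcellation(parcellation)
  per_run_z <- lapply(seq_along(timeseries), function(s) {
    lapply(seq_along(timeseries[[s]]), function(r) {
      y <- timeseries[[s]][[r]]
      if (!is.null(compartments))
        y <- nuisance_regress(y, compartments[[s]][[r]], n_components)
      rm_ts <- region_mean_timecourses(y, parcellation)
      fisher_z(vertex_region_connectivity(y, rm_ts))
    })
  })
  group_average(per_run_z,
                target_region_ids = parcellation$region_meta$region_id)
}
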