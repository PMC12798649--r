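# Within-region permutation null: shuffle activation values across a
# region's vertices (fingerprints intact), refit at the true model's
# penalty, and summarize the chance distribution of fits.

#' Permute activation values within a region
#'
#' Uniformly random permutation (sampling without replacement over
#' vertices) of the region's activation values; each vertex keeps its
#' connectivity fingerprint but receives another vertex's activation.
#'
#' @param y region activation vector, length >= 2.
#' @param seed integer seed; the same seed reproduces the permutation.
#' @return permuted vector (same multiset of values).
#' @export
permute_within_region <- function(y, seed) {
  if (length(y) < 2) stop("need at least 2 values to permute")
  with_substream(seed, y[sample.int(length(y))])
}

#' Build the permutation null for one model
#'
#' Generates `n_permutations` within-region permutations of the activation
#' vector and refits the ridge model at the true model's penalty
#' (`lambda_true`; no re-optimization), recording each in-sample
#' R-squared. Permutation draws come from a substream derived from
#' `(seed, region_id, domain_id)`, so every model's null is reproducible
#' independently of execution order.
#'
#' @param X_region region vertices x targets fingerprint matrix.
#' @param y_region region activation vector.
#' @param lambda_true penalty selected for the true model.
#' @param n_permutations number of permutations (default 1000).
#' @param seed master seed.
#' @param region_id,domain_id labels; also key the permutation substream.
#' @return a `permutation_result`: `region_id`, `domain_id`,
#'   `n_permutations`, `perm_r2`, `true_r2`, `p_value` (strict-inequality
#'   exceedance fraction), `q99` (nearest-rank 99th percentile).
#' @export
permutation_distribution <- function(X_region, y_region, lambda_true,
                                     n_permutations = 1000L, seed = 1L,
                                     region_id = NA, domain_id = NA) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  X <- as.matrix(X_region)
  n <- nrow(X)
  if (n != length(y_region)) stop("X rows must match length(y)")
  if (n < 2) stop("need at least 2 vertices")
  if (var(y_region) == 0) stop("constant activation: null undefined")

  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  ybar <- mean(y_region)
  sst <- sum((y_region - ybar)^2)

  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  M <- Xc %*% eg$vectors                  # n x p
  shrink <- 1 / (d + lambda_true)

  # permutations preserve mean(y) and SStot, so centering is a constant
  perms <- with_substream(derive_seed(seed, "perm", region_id, domain_id), {
    vapply(seq_len(n_permutations), function(i) y_region[sample.int(n)],
           numeric(n))
  })
  Yc <- perms - ybar                      # n x n_permutations
  A <- crossprod(M, Yc) * shrink          # p x n_permutations
  resid <- Yc - M %*% A
  perm_r2 <- clamp_unit(1 - colSums(resid^2) / sst)

  yc <- y_region - ybar
  a_true <- crossprod(M, yc) * shrink
  true_r2 <- clamp_unit(1 - sum((yc - M %*% a_true)^2) / sst)

  structure(list(region_id = region_id, domain_id = domain_id,
                 n_permutations = as.integer(n_permutations),
                 perm_r2 = as.vector(perm_r2), true_r2 = true_r2,
                 p_value = empirical_p(perm_r2, true_r2),
                 q99 = percentile_99(perm_r2)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result %s / %s: true R2 = %.4f, p = %.4g, q99 = %.4f (%d permutations)\n",
    x$region_id, x$domain_id, x$true_r2, x$p_value, x$q99, x$n_permutations))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' The fraction of permuted fits that strictly exceed the true fit
#' (`count(perm_r2 > true_r2) / n`), exactly as printed by the strict
#' exceedance formula. A smoothed variant `(count + 1) / (n + 1)` is
#' available behind `smoothed` (off by default).
#'
#' @param perm_r2 nonempty vector of permuted fits.
#' @param true_r2 the true model's fit.
#' @param smoothed use the add-one estimator.
#' @return a fraction in `[0, 1]`.
#' @export
empirical_p <- function(perm_r2, true_r2, smoothed = FALSE) {
  if (length(perm_r2) == 0) stop("empty permutation distribution")
  k <- sum(perm_r2 > true_r2)
  if (smoothed) (k + 1) / (length(perm_r2) + 1) else k / length(perm_r2)
}

#' Nearest-rank 99th percentile
#'
#' The `ceiling(0.99 * n)`-th order statistic of the permuted fits (the
#' 990th of 1,000 sorted values). Warns below 100 values, where the
#' nearest-rank percentile is coarse.
#'
#' @param perm_r2 nonempty numeric vector.
#' @param p percentile level (default 0.99).
#' @param method `"nearest_rank"` (default) or `"linear"`
#'   (interpolating, [stats::quantile()] type 7).
#' @return the order statistic.
#' @export
percentile_99 <- function(perm_r2, p = 0.99,
                          method = c("nearest_rank", "linear")) {
  method <- match.arg(method)
  n <- length(perm_r2)
  if (n == 0) stop("empty vector")
  if (n < 100) warning("fewer than 100 values: nearest-rank percentile is coarse")
  if (method == "linear") return(unname(quantile(perm_r2, p, type = 7)))
  sort(perm_r2)[ceiling(p * n)]
}

#' Permutation nulls for every fitted model
#'
#' @param conn a `connectivity_matrix`.
#' @param activation vertices x domains matrix.
#' @param parcellation a `parcellation`.
#' @param fits fit table from [fit_all_models()] (uses its `lambda`).
#' @param n_permutations permutations per model (default 1000).
#' @param seed master seed.
#' @param workers parallel workers over models.
#' @return data frame keyed by (region_id, domain_id) with `p_value`,
#'   `q99`, `perm_mean`, `perm_sd`; full `permutation_result` objects
#'   attached as attribute `"results"`.
#' @export
permute_all_models <- function(conn, activation, parcellation, fits,
                               n_permutations = 1000L, seed = 1L,
                               workers = 1L) {
  X_all <- conn$values
  run_one <- function(i) {
    vidx <- region_vertices(parcellation, fits$region_id[i])
    permutation_distribution(X_all[vidx, , drop = FALSE],
                             activation[vidx, fits$domain_id[i]],
                             lambda_true = fits$lambda[i],
                             n_permutations = n_permutations, seed = seed,
                             region_id = fits$region_id[i],
                             domain_id = fits$domain_id[i])
  }
  res <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seq_len(nrow(fits)), run_one, mc.cores = workers)
  } else lapply(seq_len(nrow(fits)), run_one)
  out <- data.frame(region_id = fits$region_id, domain_id = fits$domain_id,
                    p_value = vapply(res, `[[`, numeric(1), "p_value"),
                    q99 = vapply(res, `[[`, numeric(1), "q99"),
                    perm_mean = vapply(res, function(r) mean(r$perm_r2),
                                       numeric(1)),
                    perm_sd = vapply(res, function(r) sd(r$perm_r2),
                                     numeric(1)),
                    stringsAsFactors = FALSE)
  attr(out, "results") <- res
  out
}
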