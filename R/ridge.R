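# Per-(region, domain) ridge models: closed-form solver on centered data
# with an unpenalized intercept, deterministic log-grid cross-validation
# for the penalty, and in-sample coefficient of determination.

#' Ridge fit specification
#'
#' @param n_folds cross-validation folds for the penalty search (default 5).
#' @param max_evaluations number of candidate penalties evaluated
#'   (default 100).
#' @param lambda_grid_bounds positive `(low, high)` bounds of the raw
#'   log-spaced grid; candidates are these values scaled by the mean
#'   diagonal of the centered Gram matrix, so the grid adapts to predictor
#'   scale.
#' @param standardize center and unit-scale predictor columns before
#'   fitting (coefficients are reported on the raw scale). Off by default:
#'   fingerprints already share the Fisher-z scale.
#' @param seed seed for the fold assignment.
#' @return a `ridge_fit_spec` list.
#' @export
ridge_fit_spec <- function(n_folds = 5L, max_evaluations = 100L,
                           lambda_grid_bounds = c(1e-6, 1e4),
                           standardize = FALSE, seed = 1L) {
  stopifnot(n_folds >= 2, max_evaluations >= 1,
            length(lambda_grid_bounds) == 2,
            all(lambda_grid_bounds > 0),
            lambda_grid_bounds[1] < lambda_grid_bounds[2])
  structure(list(n_folds = as.integer(n_folds),
                 max_evaluations = as.integer(max_evaluations),
                 lambda_grid_bounds = as.numeric(lambda_grid_bounds),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "ridge_fit_spec")
}

#' Fit a ridge regression with unpenalized intercept
#'
#' Minimizes `sum((y - X w - b)^2) + lambda * sum(w^2)` with the intercept
#' `b` unpenalized: solves the centered normal equations
#' `(Xc' Xc + lambda I) w = Xc' yc` and sets
#' `b = mean(y) - colMeans(X) %*% w`. Leaving the intercept unpenalized
#' guarantees the in-sample R-squared is nonnegative.
#'
#' @param X rows x predictors matrix (at least 2 rows).
#' @param y response vector.
#' @param lambda penalty, `>= 0`; `0` is permitted only when the centered
#'   `X` has full column rank.
#' @param standardize unit-scale predictor columns internally; returned
#'   coefficients are on the raw scale.
#' @return list with `coefficients` and `intercept`.
#' @examples
#' fit_ridge(cbind(c(1, 2, 3)), c(2, 4, 6), lambda = 2)
#' # coefficient 4/(2+2) = 1, intercept 4 - 2*1 = 2
#' @export
fit_ridge <- function(X, y, lambda, standardize = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("nonfinite values in X or y")
  if (nrow(X) < 2 || nrow(X) != length(y))
    stop("X needs >= 2 rows matching length(y)")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be nonnegative")
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  scale_ <- rep(1, ncol(X))
  if (standardize) {
    scale_ <- apply(Xc, 2, sd)
    scale_[scale_ == 0] <- 1
    Xc <- sweep(Xc, 2, scale_, "/")
  }
  yc <- y - ybar
  G <- crossprod(Xc)
  if (lambda == 0 && qr(Xc)$rank < ncol(Xc))
    stop("lambda = 0 requires X of full column rank")
  w <- solve(G + diag(lambda, ncol(X)), crossprod(Xc, yc))
  w <- as.vector(w) / scale_
  list(coefficients = w, intercept = ybar - sum(xbar * w))
}

#' In-sample coefficient of determination
#'
#' `1 - SSres/SStot` where `SStot` is taken around the mean of `y`.
#'
#' @param y observed values (must have nonzero variance).
#' @param y_hat fitted values.
#' @return a scalar; for ridge fits with unpenalized intercept it lies in
#'   `[0, 1]`.
#' @export
r_squared <- function(y, y_hat) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("R-squared undefined: y is constant")
  1 - sum((y - y_hat)^2) / sst
}

# Eigen-decomposition path: coefficients for many lambdas at once.
# Returns predictors x lambdas matrix; Xc and yc must be pre-centered.
ridge_path <- function(Xc, yc, lambdas) {
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  alpha <- as.vector(crossprod(eg$vectors, crossprod(Xc, yc)))
  eg$vectors %*% (alpha / outer(d, lambdas, `+`))
}

# The candidate grid: log-spaced raw bounds scaled by the mean diagonal of
# the centered Gram matrix (adapting the grid to predictor scale).
lambda_grid <- function(Xc, spec) {
  g <- exp(seq(log(spec$lambda_grid_bounds[1]),
               log(spec$lambda_grid_bounds[2]),
               length.out = spec$max_evaluations))
  g * mean(diag(crossprod(Xc)))
}

#' Select the ridge penalty by cross-validation
#'
#' Evaluates up to `max_evaluations` candidate penalties on a deterministic
#' log-spaced grid (bounds scaled by the mean diagonal of the centered Gram
#' matrix). For each candidate, the mean out-of-fold squared error is
#' computed over a seeded fold assignment (shuffle, then contiguous
#' blocks). Returns the error-minimizing penalty; ties go to the larger
#' (more regularized) value. If there are fewer than `2 * n_folds` rows,
#' the fold count drops to `max(2, floor(n/2))` with a warning; fewer than
#' 4 rows is an error.
#'
#' @param X rows x predictors matrix.
#' @param y response vector (non-constant).
#' @param spec a [ridge_fit_spec()].
#' @return list with `lambda_selected` and `cv_curve`, a data frame of
#'   `(lambda, cv_error)` pairs.
#' @export
optimize_lambda <- function(X, y, spec = ridge_fit_spec()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 rows to cross-validate the penalty")
  if (n != length(y)) stop("X rows must match length(y)")
  if (var(y) == 0) stop("y is constant; penalty selection undefined")
  n_folds <- spec$n_folds
  if (n < 2L * n_folds) {
    n_folds <- max(2L, n %/% 2L)
    warning(sprintf("only %d rows: reducing to %d folds", n, n_folds))
  }
  Xc_all <- sweep(X, 2, colMeans(X))
  if (spec$standardize) {
    sds <- apply(Xc_all, 2, sd); sds[sds == 0] <- 1
    X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
    Xc_all <- X
  }
  lambdas <- lambda_grid(Xc_all, spec)

  # seeded shuffle, then contiguous blocks of the shuffled order
  perm <- with_substream(spec$seed, sample.int(n))
  fold_id <- integer(n)
  bounds <- floor(seq(0, n, length.out = n_folds + 1))
  for (f in seq_len(n_folds))
    fold_id[perm[(bounds[f] + 1):bounds[f + 1]]] <- f

  fold_mse <- matrix(NA_real_, n_folds, length(lambdas))
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    xbar <- colMeans(Xtr)
    W <- ridge_path(sweep(Xtr, 2, xbar), ytr - mean(ytr), lambdas)
    Xva <- sweep(X[!tr, , drop = FALSE], 2, xbar)
    pred <- Xva %*% W + mean(ytr)
    fold_mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv <- colMeans(fold_mse)
  sel <- max(which(cv == min(cv)))          # ties -> larger lambda
  list(lambda_selected = lambdas[sel],
       cv_curve = data.frame(lambda = lambdas, cv_error = cv))
}

#' Fit one (region, domain) model
#'
#' Restricts the connectivity matrix to the region's vertices, selects the
#' penalty by cross-validation, refits on all the region's vertices at the
#' selected penalty, and reports the in-sample R-squared — the study's
#' goodness-of-fit statistic (there is no out-of-sample activation map to
#' predict).
#'
#' @param conn a `connectivity_matrix` (or vertices x targets matrix).
#' @param activation per-vertex activation vector for one domain (full
#'   length; the region's values are extracted internally).
#' @param parcellation a `parcellation`.
#' @param region_id a modeled region id.
#' @param spec a [ridge_fit_spec()].
#' @param domain_id optional label stored in the result.
#' @return a `model_fit` list: `region_id`, `domain_id`, `lambda_selected`,
#'   `coefficients`, `intercept`, `r_squared`, `n_vertices`, `cv_curve`.
#' @export
fit_region_domain <- function(conn, activation, parcellation, region_id,
                              spec = ridge_fit_spec(), domain_id = NA) {
  X_all <- if (inherits(conn, "connectivity_matrix")) conn$values else
    as.matrix(conn)
  validate_parcellation(parcellation)
  meta <- parcellation$region_meta
  ri <- match(region_id, meta$region_id)
  if (is.na(ri)) stop(sprintf("unknown region '%s'", region_id))
  if (!meta$modeled[ri])
    stop(sprintf("region '%s' is not a modeled region", region_id))
  vidx <- region_vertices(parcellation, region_id)
  X <- X_all[vidx, , drop = FALSE]
  y <- activation[vidx]
  if (!all(is.finite(y)) || var(y) == 0)
    stop(sprintf("degenerate activation in region '%s'", region_id))
  opt <- optimize_lambda(X, y, spec)
  fit <- fit_ridge(X, y, opt$lambda_selected, standardize = spec$standardize)
  yhat <- as.vector(X %*% fit$coefficients) + fit$intercept
  r2 <- clamp_unit(r_squared(y, yhat))
  structure(list(region_id = region_id, domain_id = domain_id,
                 lambda_selected = opt$lambda_selected,
                 coefficients = fit$coefficients, intercept = fit$intercept,
                 r_squared = r2, n_vertices = length(vidx),
                 cv_curve = opt$cv_curve),
            class = "model_fit")
}

# Ridge R-squared is >= 0 in exact arithmetic; clip floating dust, but
# refuse genuinely out-of-range values.
clamp_unit <- function(x, tol = 1e-8) {
  if (any(x < -tol | x > 1 + tol))
    stop("R-squared outside [0, 1] beyond numerical tolerance")
  pmin(pmax(x, 0), 1)
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit %s / %s: R2 = %.4f, lambda = %.4g, n = %d\n",
              x$region_id, x$domain_id, x$r_squared, x$lambda_selected,
              x$n_vertices))
  invisible(x)
}

#' Fit every (modeled region, domain) model
#'
#' @param conn a `connectivity_matrix`.
#' @param activation vertices x domains matrix (columns named by domain).
#' @param parcellation a `parcellation`.
#' @param spec a [ridge_fit_spec()].
#' @param workers number of parallel workers over models (forked;
#'   results are identical for any worker count).
#' @return data frame with one row per model: `region_id`, `domain_id`,
#'   `lambda`, `r2`, `n_vertices`; the full `model_fit` objects are
#'   attached as attribute `"fits"`.
#' @export
fit_all_models <- function(conn, activation, parcellation,
                           spec = ridge_fit_spec(), workers = 1L) {
  design <- design_table(parcellation, colnames(activation))
  fit_one <- function(i) {
    fit_region_domain(conn, activation[, design$domain_id[i]], parcellation,
                      design$region_id[i], spec,
                      domain_id = design$domain_id[i])
  }
  fits <- if (workers > 1L && requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(seq_len(nrow(design)), fit_one, mc.cores = workers)
  } else lapply(seq_len(nrow(design)), fit_one)
  out <- data.frame(region_id = design$region_id,
                    domain_id = design$domain_id,
                    lambda = vapply(fits, `[[`, numeric(1), "lambda_selected"),
                    r2 = vapply(fits, `[[`, numeric(1), "r_squared"),
                    n_vertices = vapply(fits, `[[`, integer(1), "n_vertices"),
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}
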