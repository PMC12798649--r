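# Group-level inference over model fits: medians by domain/category/lobe,
# arcsine-square-root transform, one-way ANOVA with eta-squared,
# Holm-corrected pairwise contrasts with Cohen's d, and paired hemispheric
# laterality tests over homologous region pairs.

#' Assemble the per-model fit table
#'
#' Joins the fit and permutation summaries with region metadata
#' (hemisphere, lobe) and domain categories, and adds the
#' arcsine-square-root transformed fit used by the inferential layer.
#'
#' @param fits data frame from [fit_all_models()].
#' @param perms data frame from [permute_all_models()] (optional).
#' @param parcellation a `parcellation`.
#' @param labels domain-to-category table ([domain_labels()]).
#' @return data frame with one row per (modeled region, domain):
#'   `region_id`, `domain_id`, `category`, `lobe`, `hemisphere`, `r2`,
#'   `r2_transformed`, and (if `perms` given) `p_perm`, `q99`.
#' @export
build_fit_table <- function(fits, perms = NULL, parcellation, labels) {
  meta <- parcellation$region_meta
  out <- fits[, c("region_id", "domain_id", "r2")]
  mi <- match(out$region_id, meta$region_id)
  out$category <- labels$category[match(out$domain_id, labels$domain_id)]
  out$lobe <- meta$lobe[mi]
  out$hemisphere <- meta$hemisphere[mi]
  out$r2_transformed <- arcsine_sqrt(out$r2)
  if (!is.null(perms)) {
    key <- paste(out$region_id, out$domain_id)
    pkey <- paste(perms$region_id, perms$domain_id)
    out$p_perm <- perms$p_value[match(key, pkey)]
    out$q99 <- perms$q99[match(key, pkey)]
  }
  out[, c("region_id", "domain_id", "category", "lobe", "hemisphere", "r2",
          "r2_transformed", intersect(c("p_perm", "q99"), names(out)))]
}

#' Median model fit by grouping
#'
#' Median fit per group (domain, category, or lobe) with dispersion: the
#' interquartile range and a seeded bootstrap standard error of the median.
#'
#' @param fit_table table from [build_fit_table()].
#' @param grouping one of `"domain"`, `"category"`, `"lobe"`.
#' @param value column to summarize (default `"r2"`).
#' @param n_boot bootstrap resamples for the SE (default 1000).
#' @param seed bootstrap seed.
#' @return data frame: group, `n`, `median`, `iqr`, `boot_se`.
#' @export
median_by <- function(fit_table, grouping = c("domain", "category", "lobe"),
                      value = "r2", n_boot = 1000L, seed = 1L) {
  grouping <- match.arg(grouping)
  col <- switch(grouping, domain = "domain_id", category = "category",
                lobe = "lobe")
  tab <- fit_table[!is.na(fit_table[[col]]), ]
  groups <- split(tab[[value]], tab[[col]])
  if (length(groups) == 0) stop("no groups to summarize")
  out <- data.frame(group = names(groups),
                    n = vapply(groups, length, integer(1)),
                    median = vapply(groups, median, numeric(1)),
                    iqr = vapply(groups, function(v)
                      unname(diff(quantile(v, c(0.25, 0.75)))), numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$boot_se <- vapply(seq_along(groups), function(i) {
    v <- groups[[i]]
    with_substream(derive_seed(seed, "median_boot", names(groups)[i]), {
      sd(vapply(seq_len(n_boot), function(b)
        median(v[sample.int(length(v), replace = TRUE)]), numeric(1)))
    })
  }, numeric(1))
  names(out)[1] <- grouping
  out
}

#' Arcsine-square-root transform
#'
#' `asin(sqrt(x))`, mapping `[0, 1]` onto `[0, pi/2]`; applied to
#' R-squared values before ANOVA and t-tests to reduce their left skew.
#'
#' @param r2_values values in `[0, 1]` (tolerance 1e-12).
#' @return transformed values.
#' @export
arcsine_sqrt <- function(r2_values) {
  if (any(r2_values < -1e-12 | r2_values > 1 + 1e-12, na.rm = TRUE))
    stop("values outside [0, 1]")
  asin(sqrt(pmin(pmax(r2_values, 0), 1)))
}

#' One-way ANOVA with eta-squared
#'
#' Classical between/within decomposition via [stats::lm()]:
#' `F = MS_between / MS_within`, p from the F distribution, and effect
#' size `eta^2 = SS_between / SS_total`.
#'
#' @param values numeric response (e.g. transformed fits).
#' @param groups group labels, >= 2 groups with >= 2 observations each.
#' @return an `anova_result` list: `f_stat`, `df_between`, `df_within`,
#'   `p_value`, `eta_squared`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  tab <- anova(lm(values ~ groups))
  ssb <- tab$`Sum Sq`[1]
  ssw <- tab$`Sum Sq`[2]
  structure(list(f_stat = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 p_value = tab$`Pr(>F)`[1],
                 eta_squared = ssb / (ssb + ssw),
                 ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.3g, eta^2 = %.4f\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$eta_squared))
  invisible(x)
}

#' Recover eta-squared from reported F and degrees of freedom
#'
#' The algebraic identity `eta^2 = df1 * F / (df1 * F + df2)` for a one-way
#' design, useful for checking published effect sizes.
#'
#' @param f_stat F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return eta-squared.
#' @export
eta_squared_from_f <- function(f_stat, df1, df2) {
  df1 * f_stat / (df1 * f_stat + df2)
}

#' Pairwise two-sample t-tests over all group pairs
#'
#' For every unordered pair of groups (`choose(k, 2)` tests; 7 categories
#' give 21), a two-tailed two-sample t-test — pooled-variance Student by
#' default, Welch behind `var_equal = FALSE` — with Cohen's d from the
#' pooled SD, Holm-adjusted over the full family.
#'
#' @param values numeric response.
#' @param groups group labels (each group >= 2 observations).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data frame of contrasts: `group1`, `group2`, `t_stat`, `df`,
#'   `p_raw`, `p_holm`, `cohen_d`, `test_kind`.
#' @export
pairwise_t_tests <- function(values, groups, var_equal = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 observations")
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- values[groups == pairs[1, i]]
    y <- values[groups == pairs[2, i]]
    tt <- t.test(x, y, var.equal = var_equal)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               t_stat = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               cohen_d = if (sp > 0) (mean(x) - mean(y)) / sp else 0,
               test_kind = "independent", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out[, c("group1", "group2", "t_stat", "df", "p_raw", "p_holm", "cohen_d",
          "test_kind")]
}

#' Holm step-down adjustment
#'
#' Bonferroni-Holm family-wise error control: sort ascending, multiply the
#' i-th smallest by `(m - i + 1)`, enforce the running maximum, cap at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values, original order.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Hemispheric laterality tests for selected domains
#'
#' For each requested domain, pairs every left-hemisphere modeled region's
#' fit with its right-hemisphere homolog's fit and runs a paired two-tailed
#' t-test on LH - RH (41 homolog pairs at the full design give df = 40).
#' p-values are Holm-adjusted over the requested family. Both paired
#' effect-size conventions are reported: `d_z = mean(diff) / sd(diff)` and
#' `d_av = mean(diff) / mean(sd_LH, sd_RH)`.
#'
#' @param fit_table table from [build_fit_table()].
#' @param domains character vector of domain ids to test.
#' @param parcellation the `parcellation` providing homolog pairing.
#' @param value column to compare (default `"r2_transformed"`).
#' @return data frame: `domain_id`, `n_pairs`, `t_stat`, `df`, `p_raw`,
#'   `p_holm`, `d_z`, `d_av`, `test_kind`.
#' @export
laterality_tests <- function(fit_table, domains, parcellation,
                             value = "r2_transformed") {
  meta <- parcellation$region_meta
  lh <- meta[meta$modeled & meta$hemisphere == "L", ]
  if (any(is.na(lh$homolog_id)))
    stop("every modeled LH region needs an RH homolog")
  missing <- setdiff(domains, unique(fit_table$domain_id))
  if (length(missing) > 0)
    stop(sprintf("unknown domain(s): %s", paste(missing, collapse = ", ")))
  rows <- lapply(domains, function(d) {
    sub <- fit_table[fit_table$domain_id == d, ]
    x <- sub[[value]][match(lh$region_id, sub$region_id)]
    y <- sub[[value]][match(lh$homolog_id, sub$region_id)]
    if (any(is.na(x)) || any(is.na(y)))
      stop(sprintf("missing homolog fits for domain %s", d))
    if (length(x) < 2) stop("need at least 2 homolog pairs")
    diffs <- x - y
    if (sd(diffs) <= 1e-10 * max(1, abs(mean(diffs))))
      stop(sprintf("zero-variance difference for domain %s: paired t undefined", d))
    tt <- tryCatch(t.test(x, y, paired = TRUE), error = function(e)
      stop(sprintf("zero-variance difference for domain %s: paired t undefined",
                   d)))
    data.frame(domain_id = d, n_pairs = length(x),
               t_stat = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               d_z = mean(diffs) / sd(diffs),
               d_av = mean(diffs) / mean(c(sd(x), sd(y))),
               test_kind = "paired", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out[, c("domain_id", "n_pairs", "t_stat", "df", "p_raw", "p_holm", "d_z",
          "d_av", "test_kind")]
}

#' Run the full group-statistics layer
#'
#' Medians by domain, category, and lobe; one-way ANOVA of the
#' arcsine-square-root transformed fit across categories with eta-squared;
#' Holm-corrected pairwise category contrasts; and paired laterality tests
#' for the requested domains.
#'
#' @param fit_table table from [build_fit_table()].
#' @param parcellation a `parcellation`.
#' @param laterality_domains domains for the paired hemispheric tests
#'   (default: the first `min(6, n)` domains).
#' @param seed bootstrap seed for median SEs.
#' @return list: `medians` (by domain/category/lobe), `anova`,
#'   `contrasts`, `laterality`.
#' @export
group_statistics <- function(fit_table, parcellation,
                             laterality_domains = NULL, seed = 1L) {
  if (is.null(laterality_domains)) {
    doms <- unique(fit_table$domain_id)
    laterality_domains <- doms[seq_len(min(6L, length(doms)))]
  }
  list(
    medians = list(
      domain = median_by(fit_table, "domain", seed = seed),
      category = median_by(fit_table, "category", seed = seed),
      lobe = median_by(fit_table, "lobe", seed = seed)),
    anova = one_way_anova(fit_table$r2_transformed, fit_table$category),
    contrasts = pairwise_t_tests(fit_table$r2_transformed,
                                 fit_table$category),
    laterality = laterality_tests(fit_table, laterality_domains,
                                  parcellation))
}
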