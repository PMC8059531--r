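# Does the collection reflect natural abundances? If so, species in
# higher independent abundance categories (an external Red-List-style
# classification) should have more records. Tested with a single-factor
# log-linear Poisson model of record counts on category.

#' Poisson regression of counts on a categorical factor
#'
#' Fits a log-linear Poisson model with one categorical predictor via
#' [stats::glm()] and tests the factor against the intercept-only model
#' with a likelihood-ratio (deviance) chi-square test. For this model the
#' fitted mean of each category is its sample mean, which serves as a
#' closed-form cross-check.
#'
#' @param counts non-negative integer vector (records per species).
#' @param groups parallel vector of category labels; if a factor, its
#'   level order is honoured and the first level is the reference.
#' @return object of class `poisson_factor_fit`: list with
#'   `fitted_means` (named, per category), `coefficients` (log scale,
#'   relative to the reference category; `-Inf` for all-zero categories),
#'   `deviance`, `null_deviance`, `lrt_stat`, `df`, `p_value`,
#'   `reference`, `n`.
#' @export
poisson_factor_glm <- function(counts, groups) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (length(counts) != length(groups))
    stop("counts and groups must have equal length")
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 distinct groups")
  if (sum(counts) == 0)
    stop("need at least one positive count")
  fit <- stats::glm(counts ~ groups, family = stats::poisson())
  null <- stats::glm(counts ~ 1, family = stats::poisson())
  means <- c(tapply(counts, groups, mean))  # named vector, no dim
  ref <- levels(groups)[1L]
  coefs <- log(means / means[[ref]])
  zero_cat <- names(means)[means == 0]
  if (length(zero_cat) > 0L)
    warning("all-zero category: ", paste(zero_cat, collapse = ", "),
            " (coefficient reported as -Inf)")
  lrt <- null$deviance - fit$deviance
  df <- nlevels(groups) - 1L
  structure(list(
    fitted_means  = means,
    coefficients  = coefs[setdiff(names(coefs), ref)],
    deviance      = fit$deviance,
    null_deviance = null$deviance,
    lrt_stat      = lrt,
    df            = df,
    p_value       = stats::pchisq(lrt, df = df, lower.tail = FALSE),
    reference     = ref,
    n             = length(counts)
  ), class = "poisson_factor_fit")
}

#' @export
print.poisson_factor_fit <- function(x, ...) {
  cat("Poisson factor regression (reference:", x$reference, ")\n")
  cat("  fitted means:",
      paste(sprintf("%s=%.3g", names(x$fitted_means), x$fitted_means),
            collapse = ", "), "\n")
  cat(sprintf("  LRT = %.4g on %d df, p = %.4g (n = %d)\n",
              x$lrt_stat, x$df, x$p_value, x$n))
  invisible(x)
}

#' Concordance of record counts with an external abundance classification
#'
#' Restricts to the species shared between the collection and the
#' abundance table, then regresses record counts on the ordered abundance
#' category with [poisson_factor_glm()]. Categories are treated as an
#' unordered factor in the declared order (the first declared category is
#' the reference); descriptive per-category count summaries are attached.
#'
#' @param species_counts named numeric vector: species -> record count.
#' @param abundance data frame with columns `species`, `category`.
#' @param category_order character vector giving the category order from
#'   least to most abundant; defaults to order of appearance.
#' @return list with `fit` (a `poisson_factor_fit`), `n_species_shared`,
#'   and `category_summary` (tibble of n, min, median, max per category).
#' @export
abundance_concordance <- function(species_counts, abundance,
                                  category_order = NULL) {
  shared <- intersect(names(species_counts), abundance$species)
  if (length(shared) == 0L)
    stop("no species shared between the collection and the abundance table")
  if (is.null(category_order)) category_order <- unique(abundance$category)
  cat_of <- abundance$category[match(shared, abundance$species)]
  keep <- cat_of %in% category_order
  shared <- shared[keep]; cat_of <- cat_of[keep]
  if (length(shared) == 0L)
    stop("no shared species with a declared category")
  groups <- factor(cat_of, levels = category_order)
  groups <- droplevels(groups)
  counts <- as.numeric(species_counts[shared])
  fit <- poisson_factor_glm(counts, groups)
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- counts[groups == g]
    data.frame(category = g, n_species = length(v), min = min(v),
               median = stats::median(v), max = max(v))
  }))
  list(fit = fit,
       n_species_shared = length(shared),
       category_summary = tibble::as_tibble(summ))
}
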