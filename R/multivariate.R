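#' Genotype-mean trait matrix for one treatment
#'
#' Averages replicates per genotype and pivots to the genotype x trait
#' layout used by the correlation and principal-component summaries.
#'
#' @param table A phenotype tibble.
#' @param treatment One of `"C"`, `"Ds"`, `"Dd"`.
#' @param row_type Optional `"2R"`/`"6R"` subset.
#' @return A tibble with a `genotype` column and one column per trait.
#' @export
trait_means <- function(table, treatment = "C", row_type = NULL) {
  table <- as_phenotype_table(table)
  sub <- dplyr::filter(table, .data$treatment == !!treatment)
  if (!is.null(row_type)) {
    sub <- dplyr::filter(sub, .data$row_type == !!row_type)
  }
  if (nrow(sub) == 0) {
    abort(paste0("No data for treatment ", treatment),
          class = "droughtphen_lookup_error")
  }
  sub |>
    dplyr::group_by(.data$genotype, .data$trait) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "mean")
}

#' Pearson correlation matrix with P values
#'
#' Pairwise-complete Pearson correlations between traits over genotypes,
#' with two-sided P values from the t transform
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`. Traits with zero variance are
#' excluded with a warning; pairs with fewer than 3 complete observations
#' are reported missing.
#'
#' @param means A genotype x trait tibble as from [trait_means()] (or a
#'   plain numeric matrix with traits in columns).
#' @param p_adjust Optional multiple-testing adjustment method for the P
#'   values ([stats::p.adjust()] method, e.g. `"BH"`); default `"none"`.
#' @return An object of class `trait_correlation`: list with matrices `r`,
#'   `p`, `n` and the adjustment method.
#' @export
correlation_matrix <- function(means, p_adjust = "none") {
  m <- if (is.data.frame(means)) {
    as.matrix(means[setdiff(names(means), c("genotype", "row_type"))])
  } else as.matrix(means)
  if (nrow(m) < 3) {
    abort("Need at least 3 genotypes.", class = "droughtphen_domain_error")
  }
  sds <- apply(m, 2, sd, na.rm = TRUE)
  zero <- !is.na(sds) & sds == 0
  if (any(zero)) {
    warn(paste0("Excluding zero-variance trait(s): ",
                paste(colnames(m)[zero], collapse = ", ")))
    m <- m[, !zero, drop = FALSE]
  }
  r <- cor(m, use = "pairwise.complete.obs", method = "pearson")
  cmp <- !is.na(m)
  n <- crossprod(cmp)
  tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tstat), df = pmax(n - 2, 1), lower.tail = FALSE)
  p[n < 3] <- NA_real_
  r[n < 3] <- NA_real_
  diag(p) <- NA_real_
  if (p_adjust != "none") {
    idx <- upper.tri(p)
    p_adj <- p
    p_adj[idx] <- stats::p.adjust(p[idx], method = p_adjust)
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    p <- p_adj
  }
  structure(list(r = r, p = p, n = n, p_adjust = p_adjust),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, ...) {
  cat("<trait_correlation>", ncol(x$r), "traits\n")
  print(round(x$r, 2))
  invisible(x)
}

#' Thresholded correlation network
#'
#' Edge list of trait pairs with `|r| >= threshold`; the signed correlation
#' is kept as the edge weight. Edges are ordered by descending `|r|`, ties
#' broken alphabetically, so the listing is deterministic. Raising the
#' threshold never adds an edge.
#'
#' @param corr A `trait_correlation`.
#' @param threshold Absolute-correlation cut-off in `[0, 1]`.
#' @return Tibble `trait_a`, `trait_b`, `r`, `p`.
#' @export
correlation_network <- function(corr, threshold = 0.6) {
  stopifnot(inherits(corr, "trait_correlation"),
            threshold >= 0, threshold <= 1)
  traits <- colnames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  edges <- tibble::tibble(
    trait_a = traits[idx[, 1]], trait_b = traits[idx[, 2]],
    r = corr$r[idx], p = corr$p[idx])
  edges <- dplyr::filter(edges, !is.na(.data$r), abs(.data$r) >= threshold)
  dplyr::arrange(edges, dplyr::desc(abs(.data$r)), .data$trait_a,
                 .data$trait_b)
}

#' Principal component analysis of genotype-mean traits
#'
#' Eigen decomposition of the correlation matrix (`standardize = TRUE`,
#' default) or covariance matrix of the genotype x trait means, via
#' [stats::prcomp()]. Signs are fixed so the largest-magnitude loading of
#' each component is positive, making results reproducible across eigen
#' solvers. Variance-explained percentages sum to 100 over all components.
#'
#' @param means A genotype x trait tibble as from [trait_means()].
#' @param standardize Scale traits to unit variance first (default `TRUE`;
#'   zero-variance traits are an error when standardizing).
#' @return Object of class `trait_pca`: list with `eigenvalues`,
#'   `var_explained` (percent), `cum_var_explained`, `scores` (tibble with
#'   `genotype`), `loadings` (tibble with `trait`), `center`, `scale`.
#' @export
pca_traits <- function(means, standardize = TRUE) {
  genos <- means$genotype
  m <- as.matrix(means[setdiff(names(means), c("genotype", "row_type"))])
  if (any(is.na(m))) {
    abort("PCA input must have no missing entries.",
          class = "droughtphen_domain_error")
  }
  sds <- apply(m, 2, sd)
  if (standardize && any(sds == 0)) {
    abort(paste0("Zero-variance trait(s) cannot be standardized: ",
                 paste(colnames(m)[sds == 0], collapse = ", ")),
          class = "droughtphen_domain_error")
  }
  if (ncol(m) > nrow(m)) {
    warn("More traits than genotypes; trailing components are null.")
  }
  pc <- prcomp(m, center = TRUE, scale. = standardize)
  ## sign convention: largest |loading| per component positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(
    eigenvalues = ev,
    var_explained = 100 * ev / sum(ev),
    cum_var_explained = cumsum(100 * ev / sum(ev)),
    scores = dplyr::bind_cols(tibble::tibble(genotype = genos),
                              tibble::as_tibble(pc$x)),
    loadings = dplyr::bind_cols(
      tibble::tibble(trait = rownames(pc$rotation)),
      tibble::as_tibble(pc$rotation)),
    center = pc$center,
    scale = if (standardize) pc$scale else rep(1, ncol(m)),
    standardize = standardize), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- min(4, length(x$eigenvalues))
  cat("<trait_pca>", length(x$eigenvalues), "components\n")
  cat("  eigenvalues:", paste(round(x$eigenvalues[1:k], 3), collapse = ", "),
      "...\n")
  cat("  PC1+PC2 variance explained:",
      round(x$cum_var_explained[min(2, length(x$cum_var_explained))], 1),
      "%\n")
  invisible(x)
}

#' @describeIn pca_traits eigenvalue table (one row per component).
#' @param x A `trait_pca`.
#' @param ... Unused.
#' @export
tidy.trait_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    var_explained = x$var_explained,
    cum_var_explained = x$cum_var_explained)
}
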