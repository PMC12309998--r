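#' Change percent-of-control matrix
#'
#' For each (trait, genotype), the stress-treatment cell mean expressed as a
#' percentage of the control cell mean (`100 * stress / control`); 100 means
#' no change. This is the scale-free unit used for tolerance typing: it is
#' invariant to uniform rescaling of a trait. Cells with a zero control mean
#' are set missing with a warning, never infinity.
#'
#' @param table A phenotype tibble.
#' @param treatment `"Ds"` or `"Dd"` (requesting `"C"` is an error).
#' @param traits Trait codes to include (default: all present).
#' @return A tibble `trait`, `genotype`, `row_type`, `change_pct` of class
#'   `change_matrix`, with the treatment tag stored as an attribute.
#' @export
change_percent_matrix <- function(table, treatment = c("Ds", "Dd"),
                                  traits = NULL) {
  if (identical(treatment[1], "C")) {
    abort("Change percent is defined against control; request Ds or Dd.",
          class = "droughtphen_argument_error")
  }
  treatment <- match.arg(treatment)
  table <- as_phenotype_table(table)
  traits <- traits %||% intersect(trait_codes(), unique(table$trait))
  cm <- table |>
    dplyr::filter(.data$trait %in% traits,
                  .data$treatment %in% c("C", !!treatment)) |>
    dplyr::group_by(.data$trait, .data$genotype, .data$row_type,
                    .data$treatment) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "mean")
  zero <- !is.na(cm$C) & cm$C == 0
  if (any(zero)) {
    warn(sprintf("%d cell(s) with zero control mean set to NA.", sum(zero)))
  }
  cm$change_pct <- ifelse(zero, NA_real_, 100 * cm[[treatment]] / cm$C)
  out <- dplyr::select(cm, "trait", "genotype", "row_type", "change_pct")
  out <- dplyr::arrange(out, .data$trait, .data$genotype)
  structure(tibble::new_tibble(out, class = "change_matrix"),
            treatment = treatment)
}

#' Change matrix in wide (traits x genotypes) form
#'
#' @param x A `change_matrix` tibble.
#' @return A numeric matrix, traits in rows, genotypes in columns.
#' @export
change_matrix_wide <- function(x) {
  wide <- tidyr::pivot_wider(x[c("trait", "genotype", "change_pct")],
                             names_from = "genotype",
                             values_from = "change_pct")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$trait
  m
}

#' Hierarchical clustering of a change matrix
#'
#' Agglomerative clustering of genotypes (columns) or traits (rows) of the
#' change percent-of-control matrix. Defaults (Euclidean distance, complete
#' linkage, raw unstandardised change% values, `k = 3`) reproduce the usual
#' heatmap-dendrogram tooling. Cluster labels are renumbered by descending
#' cluster-mean grain-yield change% (overall mean change% when `GY` is not
#' in the matrix) so that group `k` is always the most affected group and
#' group identities are deterministic.
#'
#' @param x A `change_matrix` tibble.
#' @param axis `"genotypes"` (default) or `"traits"`.
#' @param k Number of clusters to cut (1 to axis length).
#' @param distance Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list of class `axis_clustering`: `hclust` (the tree), `labels`
#'   (tibble `item`, `cluster`), `k`, `axis`.
#' @export
cluster_axis <- function(x, axis = c("genotypes", "traits"), k = 3,
                         distance = "euclidean", linkage = "complete") {
  axis <- match.arg(axis)
  m <- change_matrix_wide(x)
  if (axis == "genotypes") m <- t(m)
  drop <- rowSums(is.na(m)) > 0
  if (any(drop)) {
    warn(paste0("Dropping ", sum(drop), " ", axis,
                " with missing change% entries: ",
                paste(rownames(m)[drop], collapse = ", ")))
    m <- m[!drop, , drop = FALSE]
  }
  if (k > nrow(m)) {
    abort(sprintf("k = %d exceeds the number of %s (%d).", k, axis, nrow(m)),
          class = "droughtphen_argument_error")
  }
  hc <- hclust(dist(m, method = distance), method = linkage)
  raw <- cutree(hc, k = k)
  ## renumber clusters by descending mean GY change% (most affected last)
  key <- if (axis == "genotypes" && "GY" %in% colnames(m)) m[, "GY"] else
    rowMeans(m)
  cl_means <- tapply(key, raw, mean)
  new_id <- rank(-cl_means, ties.method = "first")
  labels <- tibble::tibble(item = rownames(m),
                           cluster = as.integer(new_id[as.character(raw)]))
  structure(list(hclust = hc, labels = labels, k = as.integer(k),
                 axis = axis), class = "axis_clustering")
}

#' Export a clustering tree as Newick
#'
#' Leaf names are the clustered items; branch lengths are the merge heights.
#'
#' @param clustering An `axis_clustering` (or a bare `hclust`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "axis_clustering")) clustering$hclust else
    clustering
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export needs the ape package.",
          class = "droughtphen_dependency_error")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Tolerance-group response profiles
#'
#' Per group and trait, the group's mean change% expressed as a proportion
#' of the grand mean change% over all genotypes (unweighted), times 100.
#' With a single group every profile value is 100 by construction. Empty
#' groups are excluded with a warning. Also reports the raw group mean
#' change% (`group_change_pct`) alongside the normalised `profile`.
#'
#' @param x A `change_matrix` tibble.
#' @param labels Tibble `item`, `cluster` (as from [cluster_axis()]) covering
#'   every genotype column.
#' @return Tibble `cluster`, `trait`, `n_members`, `group_change_pct`,
#'   `grand_change_pct`, `profile`.
#' @export
group_profile <- function(x, labels) {
  miss <- setdiff(unique(x$genotype), labels$item)
  if (length(miss) > 0) {
    abort(paste0("Labels do not cover genotype(s): ",
                 paste(miss, collapse = ", ")),
          class = "droughtphen_argument_error")
  }
  joined <- dplyr::left_join(x, labels, by = c(genotype = "item"))
  grand <- joined |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(grand_change_pct = mean(.data$change_pct, na.rm = TRUE),
                     .groups = "drop")
  out <- joined |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$cluster, .data$trait) |>
    dplyr::summarise(n_members = dplyr::n_distinct(.data$genotype),
                     group_change_pct = mean(.data$change_pct, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::left_join(grand, by = "trait") |>
    dplyr::mutate(profile = 100 * .data$group_change_pct /
                    .data$grand_change_pct)
  dplyr::arrange(out, .data$cluster, .data$trait)
}

#' Compact letter display for group separation
#'
#' One-way ANOVA across groups followed by Tukey HSD pairwise comparisons;
#' groups sharing a letter are not significantly different at `alpha`.
#' Letters come from [multcomp::cld()] on the Tukey contrasts. Degenerate
#' input (zero variance everywhere) returns a shared letter `"a"`.
#'
#' @param values Numeric vector, one value per genotype (e.g. change%).
#' @param labels Group label per genotype.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letters, one per group.
#' @export
group_separation_letters <- function(values, labels, alpha = 0.05) {
  g <- factor(labels)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("Need >= 2 groups with >= 2 members each.",
          class = "droughtphen_argument_error")
  }
  keep <- !is.na(values)
  d <- data.frame(y = values[keep], g = droplevels(g[keep]))
  if (isTRUE(all.equal(var(d$y), 0)) || sd(d$y) == 0) {
    return(setNames(rep("a", nlevels(d$g)), levels(d$g)))
  }
  fit <- aov(y ~ g, data = d)
  if (summary(fit)[[1]]["Residuals", "Mean Sq"] < .Machine$double.eps) {
    ## perfect within-group agreement: fall back on exact equality of means
    mns <- tapply(d$y, d$g, mean)
    return(setNames(letters[as.integer(factor(rank(mns,
                                                   ties.method = "min")))],
                    levels(d$g)))
  }
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  lt <- multcomp::cld(glt, level = alpha)$mcletters$Letters
  lt[levels(d$g)]
}

#' Two-way ANOVA sum-of-squares partition
#'
#' Fixed-effects genotype x treatment ANOVA on the replicate-level data of
#' one trait, with each factor's contribution expressed as a percentage of
#' the total sum of squares (`SS% = SS / SS_total * 100`; the components sum
#' to 100). Significance stars at 0.05 / 0.01 / 0.001 come from the F tests.
#' Requires a balanced layout within the chosen subset.
#'
#' @param table A phenotype tibble.
#' @param trait Trait code.
#' @param row_type Optional `"2R"`/`"6R"` subset.
#' @return Tibble `term`, `df`, `ss`, `ss_pct`, `p_value`, `stars` with the
#'   trait and subset as attributes.
#' @export
anova_ss_partition <- function(table, trait, row_type = NULL) {
  table <- as_phenotype_table(table)
  sub <- dplyr::filter(table, .data$trait == !!trait)
  if (!is.null(row_type)) {
    sub <- dplyr::filter(sub, .data$row_type == !!row_type)
  }
  if (nrow(sub) == 0) {
    abort(paste0("No data for trait ", trait),
          class = "droughtphen_lookup_error")
  }
  if (!is_balanced(sub, quiet = TRUE)) {
    abort("Unbalanced genotype x treatment layout; run is_balanced()/validate_balance() on the subset.",
          class = "droughtphen_balance_error")
  }
  d <- data.frame(y = sub$value, genotype = factor(sub$genotype),
                  treatment = factor(sub$treatment))
  fit <- aov(y ~ treatment * genotype, data = d)
  at <- anova(fit)
  term <- c("treatment", "genotype", "interaction", "residual")
  ss <- at[["Sum Sq"]]
  out <- tibble::tibble(
    term = term, df = at[["Df"]], ss = ss,
    ss_pct = 100 * ss / sum(ss),
    p_value = at[["Pr(>F)"]])
  out$stars <- dplyr::case_when(
    is.na(out$p_value) ~ "",
    out$p_value <= 0.001 ~ "***",
    out$p_value <= 0.01 ~ "**",
    out$p_value <= 0.05 ~ "*",
    TRUE ~ "ns")
  attr(out, "trait") <- trait
  attr(out, "row_type") <- row_type
  out
}

#' Rand index between two partitions
#'
#' Proportion of item pairs on which two partitions agree (both together or
#' both apart); 1 means identical grouping. Used to score recovery of the
#' planted archetypes by [cluster_axis()].
#'
#' @param a,b Two label vectors over the same items.
#' @return A number in (0, 1].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
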