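#' Fit the balanced random-effects model for one trait
#'
#' Model: `y_ijk = mu + g_i + tau_j + (g tau)_ij + e_ijk` with treatment
#' `tau` fixed and genotype `g` and the genotype x treatment interaction
#' random. For a balanced design the expected-mean-squares (EMS) estimators
#' are closed-form and coincide with REML whenever the estimates are
#' interior:
#' `Vr = MS_error`, `Vge = (MS_gt - MS_error) / r`,
#' `Vg = (MS_g - MS_gt) / (r t)`,
#' with `r` replicates and `t` treatments. Negative estimates are truncated
#' to 0 and flagged. Derived quantities:
#' * phenotypic variance `Vph = Vg + Vge + Vr`;
#' * plot-level broad-sense heritability `h2 = Vg / Vph`;
#' * heritability of the genotype mean
#'   `h2mg = Vg / (Vg + Vge/t + Vr/(t r))`;
#' * selective accuracy `sqrt(h2mg)`;
#' * coefficients of variation `CVg = 100 sqrt(Vg) / mu`,
#'   `CVr = 100 sqrt(Vr) / mu`.
#'
#' @param table A balanced phenotype tibble (>= 2 genotypes, >= 2
#'   treatments, >= 2 replicates).
#' @param trait Trait code.
#' @return An object of class `vc_fit`: list with `components` (tibble of
#'   the quantities above), `genotype_means` (tibble `genotype`, `ybar`),
#'   `design` (`n`, `t`, `r`), `df_error`, `truncated`, `trait`.
#' @seealso [blup_genotype_means()], [tidy.vc_fit()], [glance.vc_fit()]
#' @export
fit_random_model <- function(table, trait) {
  table <- as_phenotype_table(table)
  sub <- dplyr::filter(table, .data$trait == !!trait, !is.na(.data$value))
  if (nrow(sub) == 0) {
    abort(paste0("No data for trait ", trait),
          class = "droughtphen_lookup_error")
  }
  if (!is_balanced(sub, quiet = TRUE)) {
    abort("EMS estimation requires a balanced design; see validate_balance().",
          class = "droughtphen_balance_error")
  }
  n <- dplyr::n_distinct(sub$genotype)
  t_ <- dplyr::n_distinct(sub$treatment)
  r <- nrow(sub) / (n * t_)
  if (n < 2 || t_ < 2 || r < 2) {
    abort("Need >= 2 genotypes, >= 2 treatments and >= 2 replicates.",
          class = "droughtphen_domain_error")
  }
  d <- data.frame(y = sub$value, genotype = factor(sub$genotype),
                  treatment = factor(sub$treatment))
  at <- anova(aov(y ~ treatment + genotype + treatment:genotype, data = d))
  ms <- at[["Mean Sq"]]
  names(ms) <- rownames(at)
  ms_g <- ms[["genotype"]]; ms_gt <- ms[["treatment:genotype"]]
  ms_e <- ms[["Residuals"]]
  vr_ <- ms_e
  vge_raw <- (ms_gt - ms_e) / r
  vg_raw <- (ms_g - ms_gt) / (r * t_)
  truncated <- c(Vg = vg_raw < 0, Vge = vge_raw < 0)
  if (any(truncated)) {
    inform(paste0("Negative EMS estimate truncated to 0: ",
                  paste(names(truncated)[truncated], collapse = ", ")))
  }
  vg <- max(vg_raw, 0); vge <- max(vge_raw, 0)
  mu <- mean(d$y)
  vph <- vg + vge + vr_
  h2 <- if (vph > 0) vg / vph else 0
  h2mg_den <- vg + vge / t_ + vr_ / (t_ * r)
  h2mg <- if (h2mg_den > 0) vg / h2mg_den else 0
  cvg <- if (mu > 0) 100 * sqrt(vg) / mu else NA_real_
  cvr <- if (mu > 0) 100 * sqrt(vr_) / mu else NA_real_
  if (mu <= 0) warn("Grand mean is not positive; CVs flagged missing.")
  components <- tibble::tibble(
    trait = trait, mu = mu, Vg = vg, Vge = vge, Vr = vr_, Vph = vph,
    gen_pct = if (vph > 0) 100 * vg / vph else NA_real_,
    res_pct = if (vph > 0) 100 * vr_ / vph else NA_real_,
    h2 = h2, h2mg = h2mg, accuracy = sqrt(h2mg), CVg = cvg, CVr = cvr)
  gm <- sub |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(ybar = mean(.data$value), .groups = "drop")
  structure(list(
    components = components, genotype_means = gm,
    design = c(n = n, t = t_, r = as.integer(r)),
    df_error = at["Residuals", "Df"],
    mean_squares = ms, truncated = truncated, trait = trait),
    class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> trait", x$trait, sprintf("(n=%d genotypes, t=%d, r=%d)\n",
                                         x$design["n"], x$design["t"],
                                         x$design["r"]))
  print(as.data.frame(x$components), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn fit_random_model one row per variance component / derived
#'   statistic.
#' @param x A `vc_fit`.
#' @param ... Unused.
#' @export
tidy.vc_fit <- function(x, ...) {
  comp <- x$components
  terms <- setdiff(names(comp), "trait")
  tibble::tibble(term = terms,
                 estimate = unlist(comp[1, terms], use.names = FALSE))
}

#' @describeIn fit_random_model one-row model summary.
#' @export
glance.vc_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$components,
    tibble::tibble(n_genotypes = x$design[["n"]],
                   n_treatments = x$design[["t"]],
                   n_reps = x$design[["r"]],
                   df_error = x$df_error))
}

#' Shrinkage BLUPs of the genotype means
#'
#' For the balanced model of [fit_random_model()], the best linear unbiased
#' prediction of genotype `i`'s mean is the shrunken
#' `BLUP_i = mu + h2mg * (ybar_i - mu)`; with `h2mg = 1` predictions equal
#' the observed means, with `h2mg = 0` they collapse to the grand mean, and
#' the ordering of the observed means is always preserved. The 95% interval
#' is `BLUP_i +/- t(0.975, df_error) * sqrt((1 - h2mg) * Vg)`; the
#' prediction-error variance `(1 - h2mg) Vg` is the variance of
#' `g_i - BLUP(g_i)` in the balanced case.
#'
#' @param fit A `vc_fit`.
#' @param level Interval coverage (default 0.95).
#' @return Tibble of class `blup_tbl`: `genotype`, `ybar`, `blup`, `lwr`,
#'   `upr`, `above_mean` (logical flag against the panel mean).
#' @export
blup_genotype_means <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "vc_fit"))
  comp <- fit$components
  if (is.na(comp$h2mg)) {
    abort("h2mg is missing; cannot shrink genotype means.",
          class = "droughtphen_domain_error")
  }
  se_pred <- sqrt((1 - comp$h2mg) * comp$Vg)
  tcrit <- qt(1 - (1 - level) / 2, df = fit$df_error)
  out <- fit$genotype_means |>
    dplyr::mutate(
      blup = comp$mu + comp$h2mg * (.data$ybar - comp$mu),
      lwr = .data$blup - tcrit * se_pred,
      upr = .data$blup + tcrit * se_pred,
      above_mean = .data$blup > comp$mu) |>
    dplyr::arrange(dplyr::desc(.data$blup))
  structure(tibble::new_tibble(out, class = "blup_tbl"),
            mu = comp$mu, trait = fit$trait, level = level)
}

#' Join BLUP stability with the index consensus
#'
#' Combines the above/below-panel-mean BLUP flag with the index-based
#' consensus ranking into joint stability labels: genotypes above the BLUP
#' mean and in the top consensus fraction are `high_yield_tolerant`, those
#' below the mean and in the bottom fraction are `low_yield_susceptible`,
#' the rest `mixed`.
#'
#' @param preds A `blup_tbl` from [blup_genotype_means()].
#' @param indices An index tibble from [stress_indices()].
#' @param top_frac Fraction of the consensus ranking treated as top/bottom
#'   (default 0.25).
#' @return Tibble `genotype`, `blup`, `above_mean`, `consensus_rank`,
#'   `class`, `stability`.
#' @export
rank_stability <- function(preds, indices, top_frac = 0.25) {
  common <- intersect(preds$genotype, indices$genotype)
  if (length(common) == 0) {
    abort("BLUP and index tables share no genotypes.",
          class = "droughtphen_argument_error")
  }
  n <- nrow(indices)
  cut_top <- ceiling(top_frac * n)
  joined <- dplyr::inner_join(
    preds[c("genotype", "blup", "above_mean")],
    indices[c("genotype", "consensus_rank", "class")],
    by = "genotype")
  dplyr::mutate(
    joined,
    stability = dplyr::case_when(
      .data$above_mean & .data$consensus_rank <= cut_top ~
        "high_yield_tolerant",
      !.data$above_mean & .data$consensus_rank > n - cut_top ~
        "low_yield_susceptible",
      TRUE ~ "mixed"))
}
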