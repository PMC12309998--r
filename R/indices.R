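#' Scalar tolerance index formulas
#'
#' The five classical drought tolerance/susceptibility statistics, computed
#' from a genotype's control mean `Yp`, stress mean `Ys` and the panel grand
#' means `grand_Yp`, `grand_Ys` (unweighted means of the per-genotype
#' means):
#' * stress intensity `SI = 1 - grand_Ys / grand_Yp` (panel level);
#' * drought susceptibility index `DSI = (1 - Ys/Yp) / SI`, 1 at
#'   panel-average loss;
#' * stress tolerance index `STI = (Ys * Yp) / grand_Yp^2`;
#' * yield stability index `YSI = Ys / Yp`;
#' * tolerance `TOL = Yp - Ys` (trait units).
#'
#' All are vectorised over genotypes. `dsi()` returns `NA` with a warning
#' when `SI == 0` (no stress detected).
#'
#' @param Yp,Ys Per-genotype control and stress means (`Yp > 0`).
#' @param grand_Yp,grand_Ys Panel grand means (`grand_Yp > 0`).
#' @param SI Stress intensity as returned by `stress_intensity()`.
#' @return Numeric vector (scalar for `stress_intensity`).
#' @name tolerance-indices
NULL

#' @rdname tolerance-indices
#' @export
stress_intensity <- function(grand_Ys, grand_Yp) {
  if (!is.finite(grand_Yp) || grand_Yp <= 0) {
    abort("grand_Yp must be positive.", class = "droughtphen_domain_error")
  }
  1 - grand_Ys / grand_Yp
}

#' @rdname tolerance-indices
#' @export
dsi <- function(Yp, Ys, SI) {
  if (isTRUE(all.equal(SI, 0))) {
    warn("SI is 0 (no stress detected); DSI undefined.")
    return(rep(NA_real_, length(Yp)))
  }
  (1 - Ys / Yp) / SI
}

#' @rdname tolerance-indices
#' @export
sti <- function(Yp, Ys, grand_Yp) {
  if (!is.finite(grand_Yp) || grand_Yp <= 0) {
    abort("grand_Yp must be positive.", class = "droughtphen_domain_error")
  }
  (Ys * Yp) / grand_Yp^2
}

#' @rdname tolerance-indices
#' @export
ysi <- function(Yp, Ys) Ys / Yp

#' @rdname tolerance-indices
#' @export
tol <- function(Yp, Ys) Yp - Ys

#' Per-genotype stress means
#'
#' The stress mean of a trait is defined as the average of the single- and
#' double-drought cell means, each treatment weighted equally regardless of
#' replicate counts. `stress = "Ds"` or `"Dd"` switches to single-treatment
#' mode.
#'
#' @param table A phenotype tibble.
#' @param trait Trait code (default `"GY"`).
#' @param stress `"both"` (default), `"Ds"` or `"Dd"`.
#' @return Tibble `genotype`, `row_type`, `Yp` (control mean), `Ys`.
#' @export
stress_mean <- function(table, trait = "GY", stress = c("both", "Ds", "Dd")) {
  stress <- match.arg(stress)
  cm <- cell_means(table, trait)
  need <- if (stress == "both") c("C", "Ds", "Dd") else c("C", stress)
  absent <- setdiff(need, unique(cm$treatment))
  if (length(absent) > 0) {
    abort(paste0("Treatment(s) absent for trait ", trait, ": ",
                 paste(absent, collapse = ", "),
                 ". Consider single-treatment mode (stress = \"Ds\" or \"Dd\")."),
          class = "droughtphen_config_error")
  }
  wide <- tidyr::pivot_wider(cm[c("genotype", "row_type", "treatment",
                                  "mean")],
                             names_from = "treatment", values_from = "mean")
  wide$Ys <- switch(stress,
                    both = (wide$Ds + wide$Dd) / 2,
                    Ds = wide$Ds, Dd = wide$Dd)
  dplyr::transmute(wide, .data$genotype, .data$row_type, Yp = .data$C,
                   Ys = .data$Ys)
}

#' Tolerance/susceptibility index table
#'
#' Computes `Yp`, `Ys`, the panel `SI` and the four per-genotype indices for
#' one trait, then attaches per-index and joint tolerance classes
#' ([classify_tolerance()]) and the consensus rank ([consensus_rank()]).
#'
#' @inheritParams stress_mean
#' @param thresholds See [tolerance_thresholds()].
#' @return A tibble, one row per genotype, with columns `genotype`,
#'   `row_type`, `Yp`, `Ys`, `SI`, `DSI`, `STI`, `YSI`, `TOL`, per-index
#'   class columns, `class` (joint label) and `consensus_rank`.
#' @examples
#' sim <- simulate_cohort(default_study_spec(seed = 1))
#' idx <- stress_indices(sim$table)
#' head(idx)
#' @export
stress_indices <- function(table, trait = "GY",
                           stress = c("both", "Ds", "Dd"),
                           thresholds = tolerance_thresholds()) {
  ys <- stress_mean(table, trait, stress)
  if (any(!is.finite(ys$Yp) | ys$Yp <= 0)) {
    abort("All control means must be positive for ratio indices.",
          class = "droughtphen_domain_error")
  }
  grand_Yp <- mean(ys$Yp)
  grand_Ys <- mean(ys$Ys)
  SI <- stress_intensity(grand_Ys, grand_Yp)
  out <- dplyr::mutate(
    ys,
    SI = SI,
    DSI = dsi(.data$Yp, .data$Ys, SI),
    STI = sti(.data$Yp, .data$Ys, grand_Yp),
    YSI = ysi(.data$Yp, .data$Ys),
    TOL = tol(.data$Yp, .data$Ys))
  out <- classify_tolerance(out, thresholds)
  consensus_rank(out)
}

#' Classification thresholds
#'
#' Defaults follow the published decision rules: `DSI < 1` tolerant /
#' `DSI > 1` sensitive (boundary resolved to the sensitive side, strict
#' `<`); `STI >= 1` high, `0.5 <= STI < 1` moderate, `STI < 0.5` low
#' tolerance; joint labels `most_tolerant` (`DSI < 0.4`, `YSI >= 0.75`,
#' `STI >= 1`, `TOL` in the bottom quartile) and `most_susceptible`
#' (`DSI > 1.5`, `YSI < 0.3`, `STI < 0.2`, `TOL` in the top quartile).
#' The quartile operationalises the published "lowest/highest TOL" wording
#' and is configurable via `tol_quantile`.
#'
#' @param dsi_tolerant,sti_high,sti_moderate Per-index class cut-offs.
#' @param most_tolerant,most_susceptible Named lists of joint cut-offs.
#' @param tol_quantile Quantile defining the TOL extremes (default 0.25).
#' @return A list of thresholds for [classify_tolerance()].
#' @export
tolerance_thresholds <- function(dsi_tolerant = 1, sti_high = 1,
                                 sti_moderate = 0.5,
                                 most_tolerant = list(dsi = 0.4, ysi = 0.75,
                                                      sti = 1),
                                 most_susceptible = list(dsi = 1.5,
                                                         ysi = 0.3,
                                                         sti = 0.2),
                                 tol_quantile = 0.25) {
  list(dsi_tolerant = dsi_tolerant, sti_high = sti_high,
       sti_moderate = sti_moderate, most_tolerant = most_tolerant,
       most_susceptible = most_susceptible, tol_quantile = tol_quantile)
}

#' Classify genotypes from their index values
#'
#' @param results Tibble with columns `genotype`, `DSI`, `STI`, `YSI`,
#'   `TOL` (as produced inside [stress_indices()]).
#' @param thresholds See [tolerance_thresholds()].
#' @return `results` with `dsi_class`, `sti_class` and joint `class`
#'   (`most_tolerant` / `most_susceptible` / `intermediate`; genotypes with
#'   a missing index are `unclassified`).
#' @export
classify_tolerance <- function(results, thresholds = tolerance_thresholds()) {
  th <- thresholds
  tol_lo <- quantile(results$TOL, th$tol_quantile, na.rm = TRUE, names = FALSE)
  tol_hi <- quantile(results$TOL, 1 - th$tol_quantile, na.rm = TRUE,
                     names = FALSE)
  dplyr::mutate(
    results,
    dsi_class = dplyr::case_when(
      is.na(.data$DSI) ~ NA_character_,
      .data$DSI < th$dsi_tolerant ~ "tolerant",
      TRUE ~ "sensitive"),
    sti_class = dplyr::case_when(
      is.na(.data$STI) ~ NA_character_,
      .data$STI >= th$sti_high ~ "high",
      .data$STI >= th$sti_moderate ~ "moderate",
      TRUE ~ "low"),
    class = dplyr::case_when(
      is.na(.data$DSI) | is.na(.data$STI) | is.na(.data$YSI) |
        is.na(.data$TOL) ~ "unclassified",
      .data$DSI < th$most_tolerant$dsi &
        .data$YSI >= th$most_tolerant$ysi &
        .data$STI >= th$most_tolerant$sti &
        .data$TOL <= tol_lo ~ "most_tolerant",
      .data$DSI > th$most_susceptible$dsi &
        .data$YSI < th$most_susceptible$ysi &
        .data$STI < th$most_susceptible$sti &
        .data$TOL >= tol_hi ~ "most_susceptible",
      TRUE ~ "intermediate"))
}

#' Consensus rank across the four indices
#'
#' Average of the per-index ranks (DSI and TOL ascending - lower is better;
#' STI and YSI descending - higher is better); ties broken by genotype name
#' so the ordering is deterministic.
#'
#' @param results Tibble with `genotype`, `DSI`, `STI`, `YSI`, `TOL`.
#' @return `results` with a `consensus_rank` column, sorted by it.
#' @export
consensus_rank <- function(results) {
  if (nrow(results) < 2) {
    abort("Consensus ranking needs at least two genotypes.",
          class = "droughtphen_domain_error")
  }
  r <- function(x) rank(x, ties.method = "average")
  score <- (r(results$DSI) + r(results$TOL) + r(-results$STI) +
              r(-results$YSI)) / 4
  ord <- order(score, results$genotype)
  results$consensus_rank <- integer(nrow(results))
  results$consensus_rank[ord] <- seq_len(nrow(results))
  dplyr::arrange(results, .data$consensus_rank)
}
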