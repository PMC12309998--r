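#' Cohort specification
#'
#' A `cohort_spec` fully parameterises a synthetic drought-trial cohort:
#' the genotype panel (names, row types, planted tolerance archetypes),
#' replicate count, control baselines per trait and row type, multiplicative
#' treatment effects, archetype stress-retention modifiers, variance
#' components and a mandatory RNG seed. [simulate_cohort()] turns a spec
#' into a balanced phenotype table plus the ground truth needed for
#' recovery experiments.
#'
#' The generative model on the natural scale is
#' \deqn{y = \mu(t, row) \cdot m(t, trt, row) \cdot a(t, trt, k) \cdot p
#'   \cdot e^{g - V_g/2} e^{ge - V_{ge}/2} + \varepsilon,}
#' with genotype effect \eqn{g \sim N(0, V_g)} per (genotype, trait),
#' interaction \eqn{ge \sim N(0, V_{ge})} per (genotype, trait, treatment),
#' residual \eqn{\varepsilon \sim N(0, (cv_r \mu)^2)} and truncation at 0.
#' The lognormal effects are mean-one so every control cell's expectation
#' equals its baseline. Archetype modifiers \eqn{a} apply only under stress
#' and are normalised within each row type so row-type mean responses equal
#' the treatment multipliers exactly. The genotype-specific double-stress
#' priming factor \eqn{p \sim N(1, sd)} (truncated at 0.05) multiplies the
#' `Dd` response of yield-category traits only.
#'
#' With `variance$scale = "additive"` the model is instead
#' \eqn{y = \mu m a + g + ge + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, V_r)}; this is the parameterisation used for
#' variance-component recovery experiments.
#'
#' @param genotypes Tibble with columns `genotype`, `row_type`, `archetype`
#'   (one of `main_ear_preserver`, `side_ear_compensator`, `susceptible`).
#' @param n_reps Replicates per (genotype, treatment) cell.
#' @param baselines Tibble `trait`, `row_type`, `baseline` (> 0): control
#'   expectations.
#' @param treatment_effects Tibble `trait`, `row_type`, `treatment`
#'   (`Ds`/`Dd`), `multiplier` (> 0).
#' @param archetype_retention Tibble `trait`, `treatment`, `archetype`,
#'   `retention` (> 0 except main-ear retention of susceptibles, which may
#'   approach 0). Traits absent from this table get modifier 1.
#' @param variance List: `scale` (`"log"` or `"additive"`), `Vg`, `Vge` and
#'   `cv_r` (log scale) or `Vr` (additive scale).
#' @param priming List with `sd` and `traits` (codes whose `Dd` response is
#'   multiplied by the genotype priming factor); `sd = 0` disables priming.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @seealso [default_study_spec()], [simulate_cohort()]
#' @export
cohort_spec <- function(genotypes, n_reps, baselines, treatment_effects,
                        archetype_retention = NULL,
                        variance = list(scale = "log", Vg = 0, Vge = 0,
                                        cv_r = 0),
                        priming = list(sd = 0, traits = character()),
                        seed = 1L) {
  genotypes <- tibble::as_tibble(genotypes)
  stopifnot(all(c("genotype", "row_type", "archetype") %in% names(genotypes)))
  if (anyDuplicated(genotypes$genotype) > 0) {
    abort("Genotype names must be unique.", class = "droughtphen_spec_error")
  }
  bad_arch <- setdiff(unique(genotypes$archetype), archetype_levels())
  if (length(bad_arch) > 0) {
    abort(paste0("Unknown archetype(s): ", paste(bad_arch, collapse = ", ")),
          class = "droughtphen_spec_error")
  }
  if (!all(genotypes$row_type %in% c("2R", "6R"))) {
    abort("row_type must be 2R or 6R.", class = "droughtphen_spec_error")
  }
  baselines <- tibble::as_tibble(baselines)
  treatment_effects <- tibble::as_tibble(treatment_effects)
  if (any(baselines$baseline <= 0) || any(treatment_effects$multiplier <= 0)) {
    abort("Baselines and treatment multipliers must be positive.",
          class = "droughtphen_spec_error")
  }
  if (is.null(archetype_retention)) {
    archetype_retention <- tibble::tibble(
      trait = character(), treatment = character(),
      archetype = character(), retention = numeric())
  }
  archetype_retention <- tibble::as_tibble(archetype_retention)
  if (nrow(archetype_retention) > 0 && any(archetype_retention$retention < 0)) {
    abort("Archetype retentions must be non-negative.",
          class = "droughtphen_spec_error")
  }
  variance$scale <- match.arg(variance$scale, c("log", "additive"))
  vs <- if (variance$scale == "log") c("Vg", "Vge", "cv_r") else
    c("Vg", "Vge", "Vr")
  if (any(unlist(variance[vs]) < 0)) {
    abort("Variance components must be non-negative.",
          class = "droughtphen_spec_error")
  }
  structure(list(
    genotypes = genotypes, n_reps = as.integer(n_reps),
    baselines = baselines, treatment_effects = treatment_effects,
    archetype_retention = archetype_retention, variance = variance,
    priming = priming, seed = as.integer(seed)), class = "cohort_spec")
}

archetype_levels <- function() {
  c("main_ear_preserver", "side_ear_compensator", "susceptible")
}

#' Default study cohort specification
#'
#' The packaged reference conditions: a 28-genotype winter barley panel
#' (13 two-row, 15 six-row) under control, single drought (`Ds`) and double
#' drought (`Dd`) with 4 replicates. Control baselines are anchored to the
#' published row-type levels (two-row control grain yield 4.7 g, main-ear
#' grain number 24 vs 40.63 for six-row); treatment multipliers encode the
#' published panel-level stress responses (two-row GY 2.45 g under `Ds` and
#' 2.2 g under `Dd`; six-row GY reductions 47.52% / 44.24%; main-ear grain
#' weight reductions 53.12% / 54.42%); archetype retentions encode the three
#' published tolerance groups (GY change 64.99 / 51.7 / 27.42% of control,
#' biomass change 70.26 / 77.16 / 108.99%), with planted mix 14 main-ear
#' preservers, 6 side-ear compensators and 8 susceptibles.
#'
#' @param seed RNG seed stored in the spec.
#' @return A `cohort_spec`.
#' @export
default_study_spec <- function(seed = 1L) {
  n2 <- 13; n6 <- 15
  row_type <- c(rep(c("2R", "6R"), n2), rep("6R", n6 - n2))
  arch_for <- function(n_mep, n_sec, n_sus) {
    rep(archetype_levels(), times = c(n_mep, n_sec, n_sus))
  }
  arch <- character(28)
  arch[row_type == "2R"] <- arch_for(7, 3, 3)
  arch[row_type == "6R"] <- arch_for(7, 3, 5)
  genotypes <- tibble::tibble(
    genotype = sprintf("G%02d", 1:28), row_type = row_type, archetype = arch)

  base <- tibble::tribble(
    ~trait, ~b2R,  ~b6R,
    "LIN",  25,    22,
    "EaL",  9,     7,
    "SPS",  27,    58,
    "DENS", 3.0,   8.3,
    "BIOM", 12,    14,
    "RT",   7,     5,
    "MSSN", 0.88,  0.70,
    "MEaW", 1.5,   2.1,
    "MSW",  1.2,   1.7,
    "MSN",  24,    40.63,
    "SEaW", 6.0,   5.5,
    "SSW",  3.5,   3.0,
    "SSN",  75,    80,
    "GY",   4.7,   4.7)
  baselines <- tidyr::pivot_longer(base, cols = c("b2R", "b6R"),
                                   names_to = "row_type",
                                   values_to = "baseline")
  baselines$row_type <- ifelse(baselines$row_type == "b2R", "2R", "6R")

  ## Row-type-shared multipliers except MSN and GY, whose published stress
  ## levels differ by row type.
  shared <- tibble::tribble(
    ~trait, ~Ds,    ~Dd,
    "LIN",  0.88,   0.86,
    "EaL",  0.90,   0.88,
    "SPS",  0.95,   0.93,
    "DENS", 1.00,   1.02,
    "BIOM", 0.828,  0.8162,
    "RT",   1.05,   1.10,
    "MSSN", 0.62,   0.60,
    "MEaW", 0.50,   0.49,
    "MSW",  0.4688, 0.4558,
    "SEaW", 0.62,   0.63,
    "SSW",  0.55,   0.56,
    "SSN",  0.60,   0.61)
  shared <- tidyr::pivot_longer(shared, cols = c("Ds", "Dd"),
                                names_to = "treatment",
                                values_to = "multiplier")
  shared <- tidyr::crossing(shared, row_type = c("2R", "6R"))
  rowspec <- tibble::tribble(
    ~trait, ~row_type, ~treatment, ~multiplier,
    "MSN",  "2R", "Ds", 14.13 / 24,   "MSN", "2R", "Dd", 14.25 / 24,
    "MSN",  "6R", "Ds", 25.13 / 40.63, "MSN", "6R", "Dd", 20.5 / 40.63,
    "GY",   "2R", "Ds", 2.45 / 4.7,   "GY",  "2R", "Dd", 2.2 / 4.7,
    "GY",   "6R", "Ds", 1 - 0.4752,   "GY",  "6R", "Dd", 1 - 0.4424)
  treatment_effects <- dplyr::bind_rows(
    shared[c("trait", "row_type", "treatment", "multiplier")], rowspec)

  ret_block <- function(traits, mep, sec, sus, treatments = c("Ds", "Dd")) {
    tidyr::crossing(trait = traits, treatment = treatments) |>
      tidyr::crossing(tibble::tibble(archetype = archetype_levels(),
                                     retention = c(mep, sec, sus)))
  }
  archetype_retention <- dplyr::bind_rows(
    ret_block(c("MSSN", "MEaW", "MSW", "MSN"), 0.75, 0.45, 0.08),
    ret_block(c("SEaW", "SSW", "SSN"), 0.72, 0.62, 0.34),
    ret_block("GY", 0.6499, 0.517, 0.2742),
    ret_block("RT", 1.02, 0.98, 0.93),
    ret_block("BIOM", 0.7026, 0.7716, 1.0899, treatments = "Ds"),
    ret_block("BIOM", 0.6724, 0.8023, 1.0783, treatments = "Dd"))

  yield_traits <- trait_registry() |>
    dplyr::filter(.data$category == "yield", is.na(.data$derived_from)) |>
    dplyr::pull("trait")

  cohort_spec(
    genotypes = genotypes, n_reps = 4L, baselines = baselines,
    treatment_effects = treatment_effects,
    archetype_retention = archetype_retention,
    variance = list(scale = "log", Vg = 0.04, Vge = 0.01, cv_r = 0.08),
    priming = list(sd = 0.35, traits = yield_traits),
    seed = seed)
}

#' Deterministic cell expectations implied by a cohort spec
#'
#' The expected value of every (genotype, trait, treatment) cell: baseline
#' times treatment multiplier times row-type-normalised archetype modifier.
#' The priming factor has expectation 1 and does not appear. In the
#' noise-free limit every simulated replicate equals this expectation.
#'
#' @param spec A `cohort_spec`.
#' @return Tibble `genotype`, `row_type`, `archetype`, `trait`, `treatment`,
#'   `expectation`.
#' @export
expected_cell_means <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- tidyr::crossing(spec$genotypes,
                          trait = unique(spec$baselines$trait),
                          treatment = treatment_levels())
  grid <- dplyr::left_join(grid, spec$baselines,
                           by = c("trait", "row_type"))
  grid <- dplyr::left_join(grid, spec$treatment_effects,
                           by = c("trait", "row_type", "treatment"))
  grid$multiplier[grid$treatment == "C"] <- 1
  if (any(is.na(grid$multiplier))) {
    abort("treatment_effects must cover every trait x row_type x Ds/Dd cell.",
          class = "droughtphen_spec_error")
  }
  grid <- dplyr::left_join(
    grid, spec$archetype_retention,
    by = c("trait", "treatment", "archetype"))
  grid$retention[is.na(grid$retention)] <- 1
  grid$retention[grid$treatment == "C"] <- 1
  ## normalise archetype modifiers within row type so row-level means stay
  ## at the treatment multipliers
  grid <- grid |>
    dplyr::group_by(.data$trait, .data$treatment, .data$row_type) |>
    dplyr::mutate(modifier = .data$retention / mean(.data$retention)) |>
    dplyr::ungroup()
  grid$expectation <- grid$baseline * grid$multiplier * grid$modifier
  dplyr::select(grid, "genotype", "row_type", "archetype", "trait",
                "treatment", "expectation")
}

#' Simulate a balanced cohort
#'
#' Draws a balanced replicate-level phenotype table from a [cohort_spec()]
#' (model described there) and appends the four derived traits. Identical
#' (spec, seed) pairs give identical tables.
#'
#' @param spec A `cohort_spec`.
#' @param seed Optional override of `spec$seed`.
#' @param derive Append derived traits (`MTKW`, `ATKW`, `ASN`, `ASW`)?
#' @return A list with elements `table` (phenotype tibble) and `truth`
#'   (list: `genotypes` with archetype labels and realised priming factors,
#'   `genotype_effects`, `interaction_effects`, `spec_hash`, `spec`).
#' @export
simulate_cohort <- function(spec, seed = NULL, derive = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed %||% spec$seed)
  exp_tbl <- expected_cell_means(spec)
  genos <- spec$genotypes$genotype
  traits <- unique(spec$baselines$trait)
  n <- length(genos); p <- length(traits)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  vr <- spec$variance
  g_tbl <- tidyr::crossing(genotype = genos, trait = traits) |>
    dplyr::mutate(g = rnorm(n * p, 0, sqrt(vr$Vg)))
  ge_tbl <- tidyr::crossing(genotype = genos, trait = traits,
                            treatment = treatment_levels()) |>
    dplyr::mutate(ge = rnorm(n * p * 3, 0, sqrt(vr$Vge)))
  pr_sd <- spec$priming$sd %||% 0
  priming <- if (pr_sd > 0) pmax(rnorm(n, 1, pr_sd), 0.05) else rep(1, n)
  pr_tbl <- tibble::tibble(genotype = genos, priming = priming)

  cells <- exp_tbl |>
    dplyr::left_join(g_tbl, by = c("genotype", "trait")) |>
    dplyr::left_join(ge_tbl, by = c("genotype", "trait", "treatment")) |>
    dplyr::left_join(pr_tbl, by = "genotype")
  prime_on <- cells$treatment == "Dd" & cells$trait %in% spec$priming$traits
  cells$mu <- cells$expectation * ifelse(prime_on, cells$priming, 1)

  reps <- tidyr::crossing(cells, replicate = seq_len(spec$n_reps))
  reps <- dplyr::arrange(reps, .data$genotype, .data$trait, .data$treatment,
                         .data$replicate)
  m <- nrow(reps)
  if (vr$scale == "log") {
    het <- exp(reps$g - vr$Vg / 2 + reps$ge - vr$Vge / 2)
    eps <- rnorm(m, 0, vr$cv_r * reps$mu)
    reps$value <- pmax(reps$mu * het + eps, 0)
  } else {
    eps <- rnorm(m, 0, sqrt(vr$Vr))
    reps$value <- pmax(reps$mu + reps$g + reps$ge + eps, 0)
  }

  table <- as_phenotype_table(
    reps[c("genotype", "row_type", "treatment", "replicate", "trait",
           "value")])
  if (derive) {
    table <- suppressMessages(derive_traits(table))
  }
  truth <- list(
    genotypes = dplyr::left_join(spec$genotypes, pr_tbl, by = "genotype"),
    genotype_effects = g_tbl,
    interaction_effects = ge_tbl,
    spec_hash = rlang::hash(spec),
    spec = spec)
  list(table = table, truth = truth)
}

#' Read/write a cohort spec as YAML
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec()` returns the path invisibly;
#'   `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  ser <- list(
    genotypes = as.list(spec$genotypes),
    n_reps = spec$n_reps,
    baselines = as.list(spec$baselines),
    treatment_effects = as.list(spec$treatment_effects),
    archetype_retention = as.list(spec$archetype_retention),
    variance = spec$variance,
    priming = spec$priming,
    seed = spec$seed)
  writeLines(yaml::as.yaml(ser, precision = 17L), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  pr <- raw$priming
  pr$traits <- as.character(unlist(pr$traits))
  cohort_spec(
    genotypes = tibble::as_tibble(raw$genotypes),
    n_reps = raw$n_reps,
    baselines = tibble::as_tibble(raw$baselines),
    treatment_effects = tibble::as_tibble(raw$treatment_effects),
    archetype_retention = tibble::as_tibble(raw$archetype_retention),
    variance = raw$variance,
    priming = pr,
    seed = raw$seed)
}

#' @export
print.cohort_spec <- function(x, ...) {
  counts <- table(x$genotypes$archetype)
  cat("<cohort_spec>\n")
  cat(sprintf("  %d genotypes (%d 2R / %d 6R), %d replicates, %d traits\n",
              nrow(x$genotypes), sum(x$genotypes$row_type == "2R"),
              sum(x$genotypes$row_type == "6R"), x$n_reps,
              length(unique(x$baselines$trait))))
  cat("  archetypes:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  variance (%s scale):", x$variance$scale),
      paste(setdiff(names(x$variance), "scale"),
            unlist(x$variance[setdiff(names(x$variance), "scale")]),
            sep = "=", collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
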