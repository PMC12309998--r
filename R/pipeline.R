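#' Pipeline run configuration
#'
#' Exactly one of `input` (a phenotype CSV path) or `spec` (a
#' [cohort_spec()], simulated at run time) must be given; a seed is
#' mandatory when simulating. Remaining fields parameterise the stages of
#' [run_full_analysis()].
#'
#' @param input Path to a phenotype CSV (long or wide layout).
#' @param spec A `cohort_spec` to simulate instead of reading a file.
#' @param layout CSV layout when reading (`"long"`/`"wide"`).
#' @param trait Trait for the index and BLUP stages (default `"GY"`).
#' @param stress Stress-mean mode (`"both"`, `"Ds"`, `"Dd"`).
#' @param k Cluster count for genotype grouping.
#' @param distance,linkage Clustering parameters.
#' @param thresholds Classification thresholds ([tolerance_thresholds()]).
#' @param alpha Significance level for group separation letters.
#' @param out_dir Output directory for the report bundle.
#' @param seed RNG seed (used when simulating).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, spec = NULL, layout = "long",
                       trait = "GY", stress = "both", k = 3,
                       distance = "euclidean", linkage = "complete",
                       thresholds = tolerance_thresholds(), alpha = 0.05,
                       out_dir = tempfile("droughtphen_run_"), seed = NULL) {
  if (is.null(input) == is.null(spec)) {
    abort("Provide exactly one of `input` or `spec`.",
          class = "droughtphen_config_error")
  }
  if (!is.null(spec) && is.null(seed %||% spec$seed)) {
    abort("A seed is mandatory when simulating.",
          class = "droughtphen_config_error")
  }
  structure(list(input = input, spec = spec, layout = layout, trait = trait,
                 stress = stress, k = k, distance = distance,
                 linkage = linkage, thresholds = thresholds, alpha = alpha,
                 out_dir = out_dir, seed = seed), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Stage `", name, "` failed: ", conditionMessage(e)),
          class = "droughtphen_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - ingest or simulate, derive traits, change
#' matrices (Ds and Dd where present), genotype clustering and group
#' profiles, tolerance indices and classification, variance components and
#' BLUPs, correlations and PCA - and writes the report bundle (CSV, Newick
#' and a JSON run summary) to `config$out_dir`. Deterministic given
#' (input, config, seed); any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `report_bundle` with the in-memory
#'   results and the file manifest.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  files <- character()
  save_csv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(x), p, progress = FALSE)
    files <<- c(files, p)
    p
  }

  truth <- NULL
  table <- stage("ingest", collect({
    if (!is.null(config$spec)) {
      sim <- simulate_cohort(config$spec, seed = config$seed)
      truth <- sim$truth
      sim$table
    } else {
      read_phenotype_table(config$input, layout = config$layout)
    }
  }))
  if (nrow(table) == 0) {
    abort("Stage `ingest` produced an empty table.",
          class = "droughtphen_stage_error")
  }
  table <- stage("derive", collect({
    if (all(c("MTKW", "ATKW", "ASN", "ASW") %in% table$trait)) table else
      derive_traits(table)
  }))
  save_csv(table, "phenotypes.csv")
  if (!is.null(truth)) save_csv(truth$genotypes, "ground_truth.csv")

  stress_present <- intersect(c("Ds", "Dd"), unique(table$treatment))
  change <- list(); clusterings <- list(); profiles <- list()
  for (tr in stress_present) {
    chm <- stage(paste0("change_", tr), collect(
      change_percent_matrix(table, tr)))
    change[[tr]] <- chm
    save_csv(chm, paste0("change_", tr, ".csv"))
    cl <- stage(paste0("cluster_", tr), collect(
      cluster_axis(chm, "genotypes", k = config$k,
                   distance = config$distance, linkage = config$linkage)))
    clusterings[[tr]] <- cl
    save_csv(cl$labels, paste0("clusters_", tr, ".csv"))
    if (requireNamespace("ape", quietly = TRUE)) {
      nw <- file.path(out_dir, paste0("dendrogram_", tr, ".nwk"))
      write_newick(cl, nw)
      files <- c(files, nw)
    }
    prof <- stage(paste0("profile_", tr), collect(
      group_profile(chm, cl$labels)))
    lett <- stage(paste0("letters_", tr), collect(
      purrr::map_dfr(unique(chm$trait), function(t) {
        sub <- dplyr::inner_join(chm[chm$trait == t, ], cl$labels,
                                 by = c(genotype = "item"))
        lt <- tryCatch(
          group_separation_letters(sub$change_pct, sub$cluster,
                                   alpha = config$alpha),
          error = function(e) NULL)
        if (is.null(lt)) return(tibble::tibble(
          trait = t, cluster = integer(), letters = character()))
        tibble::tibble(trait = t, cluster = as.integer(names(lt)),
                       letters = unname(lt))
      })))
    prof <- dplyr::left_join(prof, lett, by = c("trait", "cluster"))
    profiles[[tr]] <- prof
    save_csv(prof, paste0("profiles_", tr, ".csv"))
  }

  indices <- stage("indices", collect(
    stress_indices(table, trait = config$trait, stress = config$stress,
                   thresholds = config$thresholds)))
  save_csv(indices, "indices.csv")

  vc <- stage("blup", collect(fit_random_model(table, config$trait)))
  blups <- stage("blup", collect(blup_genotype_means(vc)))
  save_csv(glance(vc), "variance_components.csv")
  save_csv(blups, "blups.csv")
  stability <- stage("stability", collect(rank_stability(blups, indices)))
  save_csv(stability, "stability.csv")

  mva <- list()
  for (tr in unique(table$treatment)) {
    means <- stage("mva", collect(trait_means(table, tr)))
    corr <- stage("mva", collect(correlation_matrix(means)))
    edges <- stage("mva", collect(correlation_network(corr)))
    pca <- stage("mva", collect(pca_traits(means)))
    mva[[tr]] <- list(correlation = corr, network = edges, pca = pca)
    save_csv(tibble::as_tibble(corr$r, rownames = "trait"),
             paste0("correlation_", tr, ".csv"))
    save_csv(edges, paste0("network_", tr, ".csv"))
    save_csv(tidy(pca), paste0("pca_eigenvalues_", tr, ".csv"))
    save_csv(pca$scores, paste0("pca_scores_", tr, ".csv"))
  }

  summary <- list(
    config = list(trait = config$trait, stress = config$stress,
                  k = config$k, distance = config$distance,
                  linkage = config$linkage, alpha = config$alpha,
                  seed = config$seed,
                  source = if (is.null(config$input)) "simulated" else
                    config$input),
    config_hash = rlang::hash(config),
    n_genotypes = dplyr::n_distinct(table$genotype),
    treatments = unique(table$treatment),
    files = basename(files),
    warnings = warnings_seen)
  sum_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, sum_path)

  invisible(structure(list(
    table = table, truth = truth, change = change,
    clusterings = clusterings, profiles = profiles, indices = indices,
    variance_components = vc, blups = blups, stability = stability,
    multivariate = mva, files = files, summary = summary),
    class = "report_bundle"))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>", length(x$files), "files in",
      dirname(x$files[1]), "\n")
  cat("  genotypes:", x$summary$n_genotypes,
      "| treatments:", paste(x$summary$treatments, collapse = ", "), "\n")
  cat("  warnings:", length(x$summary$warnings), "\n")
  invisible(x)
}
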