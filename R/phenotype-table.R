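#' Phenotype tables
#'
#' A phenotype table is the package's central data structure: a long-format
#' tibble of replicate-level observations with columns
#' `genotype`, `row_type` (`"2R"` or `"6R"`), `treatment` (`"C"`, `"Ds"`,
#' `"Dd"`), `replicate` (integer from 1), `trait` (a registered code) and
#' `value` (non-negative, possibly `NA` for explicit missingness).
#'
#' `as_phenotype_table()` validates a data frame and returns it as a tibble
#' with canonicalised treatment labels and whitespace-stripped genotype
#' names. Unknown trait codes are dropped with a warning so that external
#' tables carrying extra columns can still be ingested.
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble.
#' @export
as_phenotype_table <- function(x) {
  required <- c("genotype", "treatment", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "droughtphen_format_error")
  }
  tbl <- tibble::as_tibble(x)
  if (!"row_type" %in% names(tbl)) tbl$row_type <- NA_character_
  tbl <- dplyr::mutate(
    tbl,
    genotype = trimws(as.character(.data$genotype)),
    row_type = as.character(.data$row_type),
    treatment = canonical_treatment(.data$treatment),
    replicate = as.integer(.data$replicate),
    trait = trimws(as.character(.data$trait)),
    value = as.numeric(.data$value)
  )
  unknown <- setdiff(unique(tbl$trait), trait_codes())
  if (length(unknown) > 0) {
    warn(paste0("Dropping unregistered trait code(s): ",
                paste(unknown, collapse = ", ")))
    tbl <- dplyr::filter(tbl, .data$trait %in% trait_codes())
  }
  bad_rt <- !is.na(tbl$row_type) & !tbl$row_type %in% c("2R", "6R")
  if (any(bad_rt)) {
    abort(paste0("row_type must be 2R or 6R; found ",
                 paste(unique(tbl$row_type[bad_rt]), collapse = ", ")),
          class = "droughtphen_validation_error")
  }
  neg <- which(!is.na(tbl$value) & (tbl$value < 0 | !is.finite(tbl$value)))
  if (length(neg) > 0) {
    first <- tbl[neg[1], ]
    abort(sprintf(
      "Negative or non-finite value at genotype=%s treatment=%s replicate=%d trait=%s (%d offending record(s)).",
      first$genotype, first$treatment, first$replicate, first$trait,
      length(neg)), class = "droughtphen_validation_error")
  }
  dplyr::select(tbl, "genotype", "row_type", "treatment", "replicate",
                "trait", "value")
}

#' Read a phenotype table from CSV
#'
#' Long layout expects columns `genotype,row_type,treatment,replicate,trait,value`
#' (`row_type` optional). Wide layout expects key columns
#' `genotype,row_type,treatment,replicate` plus one column per trait code;
#' unregistered trait columns are ignored with a warning.
#'
#' @param path Path to a CSV file.
#' @param layout `"long"` (default) or `"wide"`.
#' @return A validated phenotype tibble.
#' @export
read_phenotype_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "droughtphen_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "wide") {
    keys <- intersect(c("genotype", "row_type", "treatment", "replicate"),
                      names(raw))
    if (!all(c("genotype", "treatment", "replicate") %in% keys)) {
      abort("Wide layout needs key columns genotype, treatment, replicate.",
            class = "droughtphen_format_error")
    }
    trait_cols <- setdiff(names(raw), keys)
    unknown <- setdiff(trait_cols, trait_codes())
    if (length(unknown) > 0) {
      warn(paste0("Ignoring unknown trait column(s): ",
                  paste(unknown, collapse = ", ")))
    }
    keep <- intersect(trait_cols, trait_codes())
    if (length(keep) == 0) {
      abort("No registered trait columns found in wide table.",
            class = "droughtphen_format_error")
    }
    raw <- tidyr::pivot_longer(raw[c(keys, keep)], cols = dplyr::all_of(keep),
                               names_to = "trait", values_to = "value")
  }
  as_phenotype_table(raw)
}

#' Write a phenotype table to long-format CSV
#'
#' `read_phenotype_table(write_phenotype_table(x, path))` reproduces `x`
#' record for record.
#'
#' @param table A phenotype tibble.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phenotype_table <- function(table, path) {
  table <- as_phenotype_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' Check replicate balance
#'
#' A table is balanced when every (genotype, treatment, trait) cell holds the
#' same number of non-missing replicates. `validate_balance()` errors on
#' unbalanced input; `is_balanced()` reports and (optionally) warns, listing
#' the deficient cells.
#'
#' @param table A phenotype tibble.
#' @param quiet Suppress the warning listing deficient cells.
#' @return `TRUE`/`FALSE` (`is_balanced`); the table invisibly
#'   (`validate_balance`).
#' @export
is_balanced <- function(table, quiet = FALSE) {
  table <- as_phenotype_table(table)
  counts <- dplyr::count(dplyr::filter(table, !is.na(.data$value)),
                         .data$genotype, .data$treatment, .data$trait)
  if (nrow(counts) == 0) return(TRUE)
  r <- max(counts$n)
  full <- tidyr::complete(counts, .data$genotype, .data$treatment,
                          .data$trait, fill = list(n = 0L))
  bad <- dplyr::filter(full, .data$n != r)
  if (nrow(bad) > 0 && !quiet) {
    warn(paste0(
      "Unbalanced cells (expected ", r, " replicates): ",
      paste(utils::head(sprintf("%s/%s/%s has %d", bad$genotype,
                                bad$treatment, bad$trait, bad$n), 5),
            collapse = "; "),
      if (nrow(bad) > 5) sprintf(" ... and %d more", nrow(bad) - 5) else ""))
  }
  nrow(bad) == 0
}

#' @rdname is_balanced
#' @export
validate_balance <- function(table) {
  if (!is_balanced(table, quiet = TRUE)) {
    abort("Phenotype table is not balanced; see is_balanced() for details.",
          class = "droughtphen_balance_error")
  }
  invisible(table)
}

#' Genotype-by-treatment cell means
#'
#' Arithmetic mean over replicates for one trait; missing replicates are
#' dropped from the mean, and a cell with no data at all is reported as `NA`
#' rather than silently filled.
#'
#' @param table A phenotype tibble.
#' @param trait A registered trait code present in the table.
#' @return A tibble with columns `genotype`, `row_type`, `treatment`,
#'   `mean`, `n` (replicates used).
#' @export
cell_means <- function(table, trait) {
  table <- as_phenotype_table(table)
  if (!trait %in% table$trait) {
    abort(paste0("Trait not present in table: ", trait),
          class = "droughtphen_lookup_error")
  }
  sub <- dplyr::filter(table, .data$trait == !!trait)
  out <- dplyr::summarise(
    dplyr::group_by(sub, .data$genotype, .data$row_type, .data$treatment),
    mean = if (all(is.na(.data$value))) NA_real_ else
      mean(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop")
  dplyr::arrange(out, .data$genotype, .data$treatment)
}

#' Add derived traits to a phenotype table
#'
#' Computes `MTKW`, `ATKW`, `ASN` and `ASW` per replicate from the measured
#' component traits (formulas in [trait_registry()]). Already-present
#' measured values for a derived code are left untouched and its derivation
#' skipped with a warning. Zero denominators yield `NA` with a note, never
#' infinities. The operation is idempotent.
#'
#' @param table A phenotype tibble containing the component traits.
#' @return The table with derived-trait records appended.
#' @export
derive_traits <- function(table) {
  table <- as_phenotype_table(table)
  derived <- c("MTKW", "ATKW", "ASN", "ASW")
  present <- intersect(derived, unique(table$trait))
  if (length(present) > 0) {
    warn(paste0("Derived trait(s) already present, not recomputed: ",
                paste(present, collapse = ", ")))
  }
  todo <- setdiff(derived, present)
  if (length(todo) == 0) return(table)

  wide <- tidyr::pivot_wider(table, names_from = "trait",
                             values_from = "value")
  safe_div <- function(num, den) ifelse(!is.na(den) & den == 0, NA_real_,
                                        num / den)
  need <- list(
    MTKW = c("MSW", "MSN"), ATKW = c("MSW", "SSW", "MSN", "SSN"),
    ASN = c("MSN", "SSN", "RT"), ASW = c("MSW", "SSW", "RT"))
  new_cols <- list()
  for (tr in todo) {
    if (!all(need[[tr]] %in% names(wide))) next
    new_cols[[tr]] <- switch(
      tr,
      MTKW = safe_div(1000 * wide$MSW, wide$MSN),
      ATKW = safe_div(1000 * (wide$MSW + wide$SSW), wide$MSN + wide$SSN),
      ASN  = safe_div(wide$MSN + wide$SSN, wide$RT),
      ASW  = safe_div((wide$MSW + wide$SSW), wide$RT))
  }
  if (length(new_cols) == 0) return(table)
  computed_na <- sum(unlist(lapply(new_cols, is.na)))
  if (computed_na > 0) {
    inform(paste0(computed_na,
                  " derived value(s) recorded as missing (zero or missing denominator)."))
  }
  add <- tibble::as_tibble(new_cols)
  add <- dplyr::bind_cols(
    wide[c("genotype", "row_type", "treatment", "replicate")], add)
  add <- tidyr::pivot_longer(add, cols = dplyr::all_of(names(new_cols)),
                             names_to = "trait", values_to = "value")
  out <- dplyr::bind_rows(table, add)
  dplyr::arrange(out, .data$genotype, .data$treatment, .data$replicate)
}
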