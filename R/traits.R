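#' Registry of the study traits
#'
#' Eighteen morphological and yield-related traits measured (or derived) on
#' each plant at full maturity in the drought trial design this package
#' targets. Fourteen are measured directly; four (`MTKW`, `ATKW`, `ASN`,
#' `ASW`) are computed from the measured ones by [derive_traits()].
#'
#' The derivation formulas are a documented reconstruction (the trait names
#' fix the numerators but leave the denominators implicit):
#' * `MTKW = 1000 * MSW / MSN` - thousand kernel weight of the main ear (g);
#' * `ATKW = 1000 * (MSW + SSW) / (MSN + SSN)` - average thousand kernel
#'   weight over all ears (g);
#' * `ASN = (MSN + SSN) / RT` - average grain number per spike harvested;
#' * `ASW = (MSW + SSW) / RT` - average grain weight per spike harvested (g).
#'
#' @return A tibble with columns `trait`, `name`, `category`
#'   (`"morphological"` or `"yield"`), `units` and `derived_from` (`NA` for
#'   measured traits, a formula string for computed ones).
#' @examples
#' trait_registry()
#' @export
trait_registry <- function() {
  tibble::tribble(
    ~trait,  ~name,                                         ~category,       ~units,            ~derived_from,
    "LIN",   "length of the last internode",                "morphological", "cm",              NA_character_,
    "EaL",   "length of the main ear",                      "morphological", "cm",              NA_character_,
    "SPS",   "number of spikelets in the main ear",         "morphological", "count",           NA_character_,
    "DENS",  "main ear density",                            "morphological", "spikelets/cm",    NA_character_,
    "BIOM",  "aboveground dry weight without the ears",     "morphological", "g",               NA_character_,
    "RT",    "number of reproductive tillers",              "yield",         "count",           NA_character_,
    "MSSN",  "grain number per spikelet of the main ear",   "yield",         "count",           NA_character_,
    "MEaW",  "main ear weight",                             "yield",         "g",               NA_character_,
    "MSW",   "weight of grains in the main ear",            "yield",         "g",               NA_character_,
    "MSN",   "number of grains in the main ear",            "yield",         "count",           NA_character_,
    "SEaW",  "total side ears weight",                      "yield",         "g",               NA_character_,
    "SSW",   "total grain weight in the side ears",         "yield",         "g",               NA_character_,
    "SSN",   "total grain number in the side ears",         "yield",         "count",           NA_character_,
    "GY",    "grain yield per plant",                       "yield",         "g",               NA_character_,
    "MTKW",  "thousand kernel weight in the main ear",      "yield",         "g/1000 kernels",  "1000 * MSW / MSN",
    "ATKW",  "average thousand kernel weight",              "yield",         "g/1000 kernels",  "1000 * (MSW + SSW) / (MSN + SSN)",
    "ASN",   "average grain number per spike harvested",    "yield",         "count",           "(MSN + SSN) / RT",
    "ASW",   "average grain weight per spike harvested",    "yield",         "g",               "(MSW + SSW) / RT"
  )
}

#' Registered trait codes
#'
#' @param derived If `FALSE`, only the fourteen directly measured traits.
#' @return Character vector of trait codes.
#' @export
trait_codes <- function(derived = TRUE) {
  reg <- trait_registry()
  if (!derived) reg <- reg[is.na(reg$derived_from), ]
  reg$trait
}

## Closed set of treatment labels: control, single drought (booting stage),
## double drought (first node + booting).
treatment_levels <- function() c("C", "Ds", "Dd")

## Alias map for treatment labels found in external tables. Matching is
## case-insensitive on the alias, case-sensitive on the canonical labels.
treatment_aliases <- function() {
  c(
    "c" = "C", "control" = "C", "ctrl" = "C",
    "ds" = "Ds", "single" = "Ds", "single drought" = "Ds", "drought single" = "Ds",
    "dd" = "Dd", "double" = "Dd", "combined" = "Dd", "double drought" = "Dd"
  )
}

#' Canonicalise treatment labels
#'
#' Maps common aliases (`"control"`, `"single"`, `"double"`, ...) onto the
#' closed treatment set `C`, `Ds`, `Dd` after stripping whitespace. Labels
#' already canonical are kept; unknown labels raise an error.
#'
#' @param x Character vector of treatment labels.
#' @return Character vector drawn from `c("C", "Ds", "Dd")`.
#' @export
canonical_treatment <- function(x) {
  x <- trimws(as.character(x))
  out <- ifelse(x %in% treatment_levels(), x,
                unname(treatment_aliases()[tolower(x)]))
  bad <- unique(x[is.na(out) & !is.na(x)])
  if (length(bad) > 0) {
    abort(paste0("Unknown treatment label(s): ",
                 paste(sQuote(bad), collapse = ", "),
                 ". Expected C/Ds/Dd or a documented alias."),
          class = "droughtphen_validation_error")
  }
  out
}
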