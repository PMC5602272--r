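#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# canonical column set for a municipality table
municipality_columns <- function() {
  c("id", "population", "region", "pmaq_participant", "pc_coverage",
    "physicians", "nurses", "bhu_total", "bhu_vaccination_room",
    "bhu_sonar_pinard", "home_visits", "prenatal_appointments",
    "nursing_appointments", "vaccine_third_dose", "live_births_total",
    "live_births_normal_weight", "hospitalizations_total",
    "hospitalizations_pcsc")
}

municipality_count_columns <- function() {
  setdiff(municipality_columns(),
          c("id", "region", "pmaq_participant", "pc_coverage"))
}

valid_regions <- function() {
  c("Midwest", "North", "Northeast", "South", "Southeast")
}

#' Construct a DEA model specification
#'
#' A model specification declares which municipality columns enter the
#' envelopment model as inputs, which as products, which derived columns
#' (per-1,000-inhabitant rates, percentages) are appended as control
#' products, which derived rates drive percentile trimming, and in which
#' population strata the controls are omitted.
#'
#' @param name model label.
#' @param input_vars character vector of input column names.
#' @param product_vars character vector of product column names (raw counts
#'   or derived percentages; derived names must appear in `derived`).
#' @param derived tibble of derived-variable definitions with columns
#'   `name`, `kind` (`"rate_per_1000"`, `"percentage"`,
#'   `"complement_percentage"`), `source`, `denominator`.
#' @param control_vars character vector of derived names used as controls.
#' @param controls_omitted_strata integer strata in which controls are left
#'   out of the output set (default stratum 1, where per-capita staffing is
#'   structurally high).
#' @param trim_vars derived rate names on which percentile trimming acts.
#' @param zero_input_rule `"any"` (exclude a record when any input is zero)
#'   or `"all"` (only when every input is zero).
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, input_vars, product_vars, derived,
                       control_vars, controls_omitted_strata = 1L,
                       trim_vars = character(0),
                       zero_input_rule = c("any", "all")) {
  zero_input_rule <- match.arg(zero_input_rule)
  derived <- as_tibble(derived)
  stopifnot(length(input_vars) > 0, length(product_vars) > 0)
  if (length(intersect(input_vars, product_vars)) > 0) {
    stop("a variable cannot be both an input and a product", call. = FALSE)
  }
  known <- c(municipality_columns(), derived$name)
  refs <- unique(c(input_vars, product_vars, control_vars,
                   derived$source, derived$denominator, trim_vars))
  bad <- setdiff(refs, known)
  if (length(bad)) {
    stop("model spec references unknown fields: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name,
         input_vars = input_vars,
         product_vars = product_vars,
         derived = derived,
         control_vars = control_vars,
         controls_omitted_strata = as.integer(controls_omitted_strata),
         trim_vars = trim_vars,
         zero_input_rule = zero_input_rule),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n",
      "  inputs:   ", paste(x$input_vars, collapse = ", "), "\n",
      "  products: ", paste(x$product_vars, collapse = ", "), "\n",
      "  controls: ", paste(x$control_vars, collapse = ", "),
      " (omitted in strata ",
      paste(x$controls_omitted_strata, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Built-in model specifications
#'
#' Two companion models of municipal primary care. Model 1 ("health
#' actions") relates the care workforce and equipped basic health units to
#' the volume of care delivered: home visits, prenatal and nursing
#' appointments, and third doses of tetra/pentavalent vaccine. Model 2
#' ("outcomes") relates physicians, nurses and basic health units to two
#' more-is-better outcomes: the percentage of live births with normal
#' weight and the percentage of hospitalizations NOT due to primary-care-
#' sensitive conditions. Both models append per-capita control products
#' (rates per 1,000 inhabitants, equipment percentages) so that a
#' municipality with deficient inputs cannot look efficient purely through
#' scarcity; controls are omitted for stratum 1 (up to 5,000 inhabitants),
#' where per-capita staffing is structurally high.
#'
#' @return Named list with elements `model1` and `model2`, each a
#'   [model_spec()].
#' @examples
#' specs <- builtin_model_specs()
#' specs$model1
#' @export
builtin_model_specs <- function() {
  d1 <- tibble(
    name = c("physicians_per_1000", "nurses_per_1000",
             "pct_bhu_vaccination_room", "pct_bhu_sonar_pinard",
             "home_visit_rate", "prenatal_rate", "nursing_rate"),
    kind = c("rate_per_1000", "rate_per_1000", "percentage", "percentage",
             "rate_per_1000", "rate_per_1000", "rate_per_1000"),
    source = c("physicians", "nurses", "bhu_vaccination_room",
               "bhu_sonar_pinard", "home_visits", "prenatal_appointments",
               "nursing_appointments"),
    denominator = c("population", "population", "bhu_total", "bhu_total",
                    "population", "population", "population"))
  model1 <- model_spec(
    name = "model1",
    input_vars = c("physicians", "nurses", "bhu_vaccination_room",
                   "bhu_sonar_pinard"),
    product_vars = c("home_visits", "prenatal_appointments",
                     "nursing_appointments", "vaccine_third_dose"),
    derived = d1,
    control_vars = c("physicians_per_1000", "nurses_per_1000",
                     "pct_bhu_vaccination_room", "pct_bhu_sonar_pinard"),
    trim_vars = c("home_visit_rate", "prenatal_rate",
                  "physicians_per_1000", "nurses_per_1000", "nursing_rate"),
    zero_input_rule = "any")

  d2 <- tibble(
    name = c("physicians_per_1000", "nurses_per_1000", "bhu_per_1000",
             "pct_normal_weight", "pct_non_pcsc"),
    kind = c("rate_per_1000", "rate_per_1000", "rate_per_1000",
             "percentage", "complement_percentage"),
    source = c("physicians", "nurses", "bhu_total",
               "live_births_normal_weight", "hospitalizations_pcsc"),
    denominator = c("population", "population", "population",
                    "live_births_total", "hospitalizations_total"))
  model2 <- model_spec(
    name = "model2",
    input_vars = c("physicians", "nurses", "bhu_total"),
    product_vars = c("pct_normal_weight", "pct_non_pcsc"),
    derived = d2,
    control_vars = c("physicians_per_1000", "nurses_per_1000",
                     "bhu_per_1000"),
    trim_vars = c("physicians_per_1000", "nurses_per_1000", "bhu_per_1000"),
    zero_input_rule = "all")

  list(model1 = model1, model2 = model2)
}

# raw municipality columns a spec needs (for completeness checks)
spec_required_fields <- function(spec) {
  raw <- municipality_columns()
  der <- spec$derived
  need <- c("population", "pmaq_participant", "pc_coverage",
            intersect(spec$input_vars, raw),
            intersect(spec$product_vars, raw),
            der$source[der$name %in% c(spec$product_vars, spec$control_vars,
                                       spec$trim_vars)],
            der$denominator[der$name %in% c(spec$product_vars,
                                            spec$control_vars,
                                            spec$trim_vars)])
  unique(intersect(need, raw))
}

#' Validate a municipality table
#'
#' Checks column presence, types, and the record-level invariants: counts
#' non-negative, population at least 1, equipped units not exceeding total
#' units, normal-weight births not exceeding total births, and
#' primary-care-sensitive hospitalizations not exceeding total
#' hospitalizations. Missing values are allowed (they are handled by the
#' exclusion stage); invariant violations are reported per row.
#'
#' @param table data frame of municipality records.
#' @return A tibble of violations (`row`, `id`, `problem`); zero rows when
#'   the table is valid.
#' @export
validate_municipalities <- function(table) {
  required <- municipality_columns()
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(table$id)) {
    stop("municipality ids are not unique", call. = FALSE)
  }
  probs <- list()
  note <- function(rows, msg) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<-
        tibble(row = rows, id = as.character(table$id[rows]), problem = msg)
    }
  }
  num_ok <- function(x) is.numeric(x) | is.logical(x)
  for (col in municipality_count_columns()) {
    if (!num_ok(table[[col]])) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    note(which(table[[col]] < 0), paste0(col, " is negative"))
  }
  note(which(table$population < 1), "population below 1")
  note(which(table$pc_coverage < 0 | table$pc_coverage > 100),
       "pc_coverage outside [0, 100]")
  note(which(table$bhu_vaccination_room > table$bhu_total),
       "bhu_vaccination_room exceeds bhu_total")
  note(which(table$bhu_sonar_pinard > table$bhu_total),
       "bhu_sonar_pinard exceeds bhu_total")
  note(which(table$live_births_normal_weight > table$live_births_total),
       "live_births_normal_weight exceeds live_births_total")
  note(which(table$hospitalizations_pcsc > table$hospitalizations_total),
       "hospitalizations_pcsc exceeds hospitalizations_total")
  if (!all(is.na(table$region) |
             as.character(table$region) %in% valid_regions())) {
    bad <- which(!is.na(table$region) &
                   !(as.character(table$region) %in% valid_regions()))
    note(bad, "unknown region")
  }
  if (length(probs)) dplyr::bind_rows(probs) else
    tibble(row = integer(0), id = character(0), problem = character(0))
}
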