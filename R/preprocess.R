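#' Apply the sample-homogenization exclusions
#'
#' Removes records in a fixed stage order, logging each municipality once
#' under the first stage that triggers:
#'
#' 1. `non_pmaq` — not a participant of the national quality program;
#' 2. `low_coverage` — primary-care coverage strictly below
#'    `coverage_threshold` (a record at exactly the threshold is kept);
#' 3. `inconsistent` — a field required by the active model is missing, a
#'    record-level invariant is violated, or a denominator needed for a
#'    derived product is zero;
#' 4. `zero_input` — model inputs equal to zero, under the model's rule
#'    (`"any"` input zero for the health-actions model, `"all"` inputs
#'    zero for the outcomes model).
#'
#' @param table validated municipality tibble.
#' @param spec a [model_spec()].
#' @param coverage_threshold coverage cut in percent (default 80).
#' @return A list with `retained` (tibble) and `log` (tibble with columns
#'   `id`, `stage`, `detail`).
#' @export
apply_exclusions <- function(table, spec, coverage_threshold = 80) {
  log <- list()
  drop <- function(tbl, idx, stage, detail) {
    if (length(idx)) {
      log[[length(log) + 1L]] <<- tibble(
        id = as.character(tbl$id[idx]), stage = stage,
        detail = detail[seq_along(idx)])
      tbl <- tbl[-idx, , drop = FALSE]
    }
    tbl
  }

  tbl <- table
  idx <- which(is.na(tbl$pmaq_participant) | !tbl$pmaq_participant)
  tbl <- drop(tbl, idx, "non_pmaq",
              rep("not a PMAQ participant", length(idx)))

  idx <- which(is.na(tbl$pc_coverage) | tbl$pc_coverage < coverage_threshold)
  tbl <- drop(tbl, idx, "low_coverage",
              sprintf("pc_coverage below %g", rep(coverage_threshold,
                                                  length(idx))))

  req <- spec_required_fields(spec)
  if (nrow(tbl)) {
    miss <- rowSums(is.na(tbl[, req, drop = FALSE])) > 0
    viol_tab <- validate_municipalities(tbl)
    viol <- tbl$id %in% viol_tab$id
    der <- spec$derived
    need <- der[der$name %in% c(spec$product_vars, spec$control_vars,
                                spec$trim_vars), , drop = FALSE]
    denom_zero <- rep(FALSE, nrow(tbl))
    for (d in unique(need$denominator)) {
      denom_zero <- denom_zero | (!is.na(tbl[[d]]) & tbl[[d]] <= 0)
    }
    bad <- miss | viol | denom_zero
    detail <- dplyr::case_when(
      miss ~ "missing required field",
      viol ~ "record invariant violated",
      TRUE ~ "zero denominator for derived product")
    idx <- which(bad)
    tbl <- drop(tbl, idx, "inconsistent", detail[idx])
  }

  if (nrow(tbl)) {
    X <- as.matrix(tbl[, spec$input_vars, drop = FALSE])
    zero <- if (spec$zero_input_rule == "any") {
      rowSums(X == 0) > 0
    } else {
      rowSums(X != 0) == 0
    }
    idx <- which(zero)
    tbl <- drop(tbl, idx, "zero_input",
                rep(paste0(spec$zero_input_rule, " input(s) zero"),
                    length(idx)))
  }

  log <- if (length(log)) dplyr::bind_rows(log) else
    tibble(id = character(0), stage = character(0), detail = character(0))
  if (nrow(tbl) == 0) {
    last <- if (nrow(log)) log$stage[nrow(log)] else "none"
    stop("empty sample after exclusion stage '", last, "'", call. = FALSE)
  }
  list(retained = tbl, log = log)
}

#' Derive control and percentage products
#'
#' Appends the model's derived columns: per-1,000-inhabitant rates
#' (`source / denominator * 1000`), percentages
#' (`source / denominator * 100`), and complement percentages
#' (`(denominator - source) / denominator * 100`, used for the share of
#' hospitalizations not due to primary-care-sensitive conditions).
#' Zero denominators yield `NA` (such records are normally removed by
#' [apply_exclusions()] beforehand).
#'
#' @param table municipality tibble.
#' @param spec a [model_spec()].
#' @return The table with one extra column per derived definition.
#' @export
derive_products <- function(table, spec) {
  for (i in seq_len(nrow(spec$derived))) {
    d <- spec$derived[i, ]
    num <- table[[d$source]]
    den <- table[[d$denominator]]
    den <- ifelse(!is.na(den) & den <= 0, NA_real_, den)
    table[[d$name]] <- switch(
      d$kind,
      rate_per_1000 = num / den * 1000,
      percentage = num / den * 100,
      complement_percentage = (den - num) / den * 100,
      stop("unknown derived kind: ", d$kind, call. = FALSE))
  }
  table
}

#' Trim percentile outliers on derived rates
#'
#' Computes the `low` and `high` percentile of each listed variable once,
#' on the pooled sample (no distinction of population size), then
#' eliminates every record strictly below the low threshold or strictly
#' above the high threshold in ANY listed variable. Boundary values are
#' retained. Percentiles use linear interpolation between order statistics
#' (quantile type 7).
#'
#' @param table municipality tibble carrying the derived columns.
#' @param variables derived rate names to trim on.
#' @param low,high percentile bounds (defaults 5 and 95).
#' @return A list with `retained`, `log` (id/stage/detail), and
#'   `thresholds` (tibble: variable, low, high).
#' @export
trim_percentiles <- function(table, variables, low = 5, high = 95) {
  if (nrow(table) == 0) stop("empty table", call. = FALSE)
  absent <- setdiff(variables, names(table))
  if (length(absent)) {
    stop("trim variable(s) not present: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  thr <- purrr::map_dfr(variables, function(v) {
    q <- stats::quantile(table[[v]], probs = c(low, high) / 100,
                         na.rm = TRUE, type = 7, names = FALSE)
    tibble(variable = v, low = q[1], high = q[2])
  })
  out <- rep(FALSE, nrow(table))
  why <- rep(NA_character_, nrow(table))
  for (i in seq_len(nrow(thr))) {
    v <- thr$variable[i]
    x <- table[[v]]
    hit <- !is.na(x) & (x < thr$low[i] | x > thr$high[i])
    why[hit & !out] <- sprintf("%s outside [P%g, P%g]", v, low, high)
    out <- out | hit
  }
  log <- tibble(id = as.character(table$id[out]), stage = "percentile_trim",
                detail = why[out])
  list(retained = table[!out, , drop = FALSE], log = log, thresholds = thr)
}

stratum_bounds <- function() {
  tibble(stratum = 1:5,
         lower = c(1, 5001, 10001, 20001, 50001),
         upper = c(5000, 10000, 20000, 50000, 100000))
}

#' Construct per-stratum DEA data
#'
#' @param stratum stratum id (1-5).
#' @param dmu_ids ordered DMU identifiers.
#' @param X input matrix (n x m).
#' @param Y output matrix (n x s), raw products first, then controls.
#' @param n_products number of leading raw-product columns in `Y`.
#' @return An object of class `stratum_data`.
#' @export
stratum_data <- function(stratum, dmu_ids, X, Y, n_products = ncol(Y)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("input_", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("output_", seq_len(ncol(Y)))
  stopifnot(nrow(X) == length(dmu_ids), nrow(Y) == length(dmu_ids))
  if (anyNA(X) || anyNA(Y)) stop("NA in stratum matrices", call. = FALSE)
  if (any(rowSums(X > 0) == 0)) {
    stop("every DMU needs at least one strictly positive input",
         call. = FALSE)
  }
  if (any(rowSums(Y > 0) == 0)) {
    stop("every DMU needs at least one strictly positive output",
         call. = FALSE)
  }
  structure(list(stratum = as.integer(stratum),
                 dmu_ids = as.character(dmu_ids),
                 X = X, Y = Y, n_products = as.integer(n_products)),
            class = "stratum_data")
}

#' @export
print.stratum_data <- function(x, ...) {
  cat("<stratum_data> stratum ", x$stratum, ": ", length(x$dmu_ids),
      " DMUs, ", ncol(x$X), " inputs, ", ncol(x$Y), " outputs (",
      x$n_products, " products + ", ncol(x$Y) - x$n_products,
      " controls)\n", sep = "")
  invisible(x)
}

#' Stratify municipalities by population size
#'
#' Size classes: 1 (up to 5,000 inhabitants), 2 (5,001-10,000),
#' 3 (10,001-20,000), 4 (20,001-50,000), 5 (50,001-100,000).
#' Municipalities above 100,000 inhabitants are dropped with an
#' informational message (too few per class for a frontier of their own).
#' Output matrices hold the raw products followed by the control products,
#' except in strata where the model omits controls.
#'
#' @param table municipality tibble with derived columns (see
#'   [derive_products()]).
#' @param spec a [model_spec()].
#' @return Named list (`"1"`, `"2"`, ...) of [stratum_data()] objects;
#'   empty strata are absent.
#' @export
stratify <- function(table, spec) {
  bounds <- stratum_bounds()
  too_big <- table$population > max(bounds$upper)
  if (any(too_big)) {
    message(sum(too_big),
            " municipalit(ies) above 100,000 inhabitants dropped ",
            "(size 6 not analyzed)")
    table <- table[!too_big, , drop = FALSE]
  }
  strat <- findInterval(table$population, c(bounds$lower, Inf))
  out <- list()
  for (s in sort(unique(strat))) {
    sub <- table[strat == s, , drop = FALSE]
    ycols <- spec$product_vars
    if (!(s %in% spec$controls_omitted_strata)) {
      ycols <- c(ycols, spec$control_vars)
    }
    out[[as.character(s)]] <- stratum_data(
      stratum = s,
      dmu_ids = sub$id,
      X = as.matrix(sub[, spec$input_vars, drop = FALSE]),
      Y = as.matrix(sub[, ycols, drop = FALSE]),
      n_products = length(spec$product_vars))
  }
  out
}

#' Check the DMU-count adequacy rule
#'
#' A stratum should contain at least three times as many DMUs as the sum
#' of its input and output counts; below that, the frontier over-fits and
#' most units come out efficient by construction. The check is advisory.
#'
#' @param data a [stratum_data()] object or a list of them.
#' @return Tibble with `stratum`, `n`, `m`, `s`, `required`, `ok`; a
#'   warning is emitted per failing stratum.
#' @export
check_dmu_rule <- function(data) {
  if (inherits(data, "stratum_data")) data <- list(data)
  rep <- purrr::map_dfr(data, function(d) {
    tibble(stratum = d$stratum, n = length(d$dmu_ids),
           m = ncol(d$X), s = ncol(d$Y),
           required = 3L * (ncol(d$X) + ncol(d$Y)),
           ok = length(d$dmu_ids) >= 3L * (ncol(d$X) + ncol(d$Y)))
  })
  for (i in which(!rep$ok)) {
    warning("stratum ", rep$stratum[i], ": ", rep$n[i],
            " DMUs < 3 x (", rep$m[i], " inputs + ", rep$s[i],
            " outputs) = ", rep$required[i], call. = FALSE)
  }
  rep
}
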