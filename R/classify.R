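# round half away from zero, the convention of the published tables
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

dea_categories <- function() {
  c("inefficient", "efficient_self_only", "efficient_multi_reference")
}

#' Classify DMUs by frontier status and reference role
#'
#' A DMU is `inefficient` when it is not radially efficient;
#' `efficient_self_only` when it is efficient but a reference only for
#' itself (a peculiar input/product mix, unlikely to transfer); and
#' `efficient_multi_reference` when at least one other DMU carries it in
#' its reference set — the benchmark municipalities whose practice can be
#' reproduced.
#'
#' @param frontier a [dea_frontier()] or a list of them (one per stratum).
#' @return An object of class `dea_classification` holding `per_dmu`
#'   (tibble: `dmu_id`, `stratum`, `category`) and `per_stratum`
#'   (counts and percentages per category).
#' @export
classify_dmus <- function(frontier) {
  if (inherits(frontier, "dea_frontier")) frontier <- list(frontier)
  per_dmu <- purrr::map_dfr(frontier, function(fr) {
    td <- tidy(fr)
    dplyr::mutate(
      td[, c("dmu_id", "stratum")],
      category = dplyr::case_when(
        !td$is_efficient ~ "inefficient",
        td$reference_count >= 2L ~ "efficient_multi_reference",
        TRUE ~ "efficient_self_only"))
  })
  per_dmu$category <- factor(per_dmu$category, levels = dea_categories())
  structure(list(per_dmu = per_dmu,
                 per_stratum = category_percentages(per_dmu)),
            class = "dea_classification")
}

#' Category counts and percentages by stratum
#'
#' The reporting stage shared by single-model and cross-model tables:
#' turns per-DMU categories into per-stratum (plus `"total"`) counts and
#' percentages, rounded to one decimal, half away from zero.
#'
#' @param per_dmu tibble with columns `stratum` and `category`.
#' @return Tibble with `stratum`, `category`, `n`, `pct`.
#' @export
category_percentages <- function(per_dmu) {
  levs <- if (is.factor(per_dmu$category)) levels(per_dmu$category) else
    unique(per_dmu$category)
  by_str <- per_dmu |>
    dplyr::mutate(stratum = as.character(.data$stratum)) |>
    dplyr::count(.data$stratum, .data$category, .drop = FALSE)
  tot <- per_dmu |>
    dplyr::count(.data$category, .drop = FALSE) |>
    dplyr::mutate(stratum = "total")
  dplyr::bind_rows(by_str, tot) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::mutate(category = as.character(.data$category)) |>
    dplyr::select("stratum", "category", "n", "pct")
}

#' @export
print.dea_classification <- function(x, ...) {
  cat("<dea_classification> ", nrow(x$per_dmu), " DMUs\n", sep = "")
  print(x$per_stratum, n = Inf)
  invisible(x)
}

cross_category_levels <- function() {
  c("inefficient_both",
    "inefficient_one_multi_other",
    "self_only_exactly_one",
    "self_only_both",
    "self_one_multi_other",
    "multi_both")
}

joint_category <- function(c1, c2) {
  key <- paste(pmin(as.character(c1), as.character(c2)),
               pmax(as.character(c1), as.character(c2)))
  # unordered pairs over {inefficient, self_only, multi}
  map <- c(
    "inefficient inefficient" = "inefficient_both",
    "efficient_multi_reference inefficient" = "inefficient_one_multi_other",
    "efficient_self_only inefficient" = "self_only_exactly_one",
    "efficient_self_only efficient_self_only" = "self_only_both",
    "efficient_multi_reference efficient_self_only" =
      "self_one_multi_other",
    "efficient_multi_reference efficient_multi_reference" = "multi_both")
  unname(map[key])
}

#' Cross-model efficiency classification
#'
#' Joins the per-DMU categories of the two companion models on the
#' municipalities retained in both, and assigns each to one of six joint
#' categories: inefficient in both; inefficient in one and a
#' multi-reference benchmark in the other; efficient only for itself in
#' exactly one; efficient only for itself in both; self-only in one and
#' multi-reference in the other; multi-reference benchmark in both.
#'
#' @param class1,class2 `dea_classification` objects for the two models.
#' @return A list of class `dea_cross_classification`: `per_dmu` (tibble
#'   `dmu_id`, `stratum`, `category_model1`, `category_model2`, `joint`)
#'   and `table` (per-stratum and total counts with one-decimal
#'   percentages).
#' @export
cross_classify <- function(class1, class2) {
  a <- class1$per_dmu
  b <- class2$per_dmu
  both <- dplyr::inner_join(
    dplyr::rename(a, category_model1 = "category"),
    dplyr::rename(b[, c("dmu_id", "category")], category_model2 = "category"),
    by = "dmu_id")
  if (nrow(both) == 0) {
    stop("no municipality is present in both models; ",
         "cross-classification undefined", call. = FALSE)
  }
  both$joint <- factor(
    joint_category(both$category_model1, both$category_model2),
    levels = cross_category_levels())
  tab <- category_percentages(
    dplyr::transmute(both, stratum = .data$stratum,
                     category = .data$joint))
  structure(list(per_dmu = both, table = tab),
            class = "dea_cross_classification")
}

#' @export
print.dea_cross_classification <- function(x, ...) {
  cat("<dea_cross_classification> ", nrow(x$per_dmu),
      " municipalities in both models\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' Aggregate equiproportional product-expansion targets
#'
#' For each raw product (controls excluded), the absolute shortfall is the
#' extra production the inefficient DMUs would deliver at their radial
#' targets, `sum((phi - 1) * y)` over inefficient DMUs; the percentage
#' divides by the total observed production, by default over ALL retained
#' DMUs (`denominator = "all"`), alternatively over the inefficient ones
#' only. Slack shortfalls (output slack beyond the radial target) are
#' reported in a separate column, never folded into the headline
#' equiproportional figure.
#'
#' @param frontier a [dea_frontier()] or list of them.
#' @param denominator `"all"` (default) or `"inefficient"`.
#' @return Tibble with `stratum` (including a pooled `"total"` row set),
#'   `product`, `shortfall`, `slack_shortfall`, `observed_total`, `pct`
#'   (`NA` when the denominator is zero).
#' @export
aggregate_expansion <- function(frontier,
                                denominator = c("all", "inefficient")) {
  denominator <- match.arg(denominator)
  if (inherits(frontier, "dea_frontier")) frontier <- list(frontier)
  per <- purrr::map_dfr(frontier, function(fr) {
    d <- fr$data
    prods <- seq_len(d$n_products)
    phi <- purrr::map_dbl(fr$results, "phi")
    ineff <- !purrr::map_lgl(fr$results, "is_efficient")
    Yp <- d$Y[, prods, drop = FALSE]
    slacks <- do.call(rbind,
                      purrr::map(fr$results,
                                 ~ .x$output_slacks[prods]))
    short <- colSums(((phi - 1) * Yp)[ineff, , drop = FALSE])
    slack_short <- colSums(slacks[ineff, , drop = FALSE])
    denom <- if (denominator == "all") colSums(Yp) else
      colSums(Yp[ineff, , drop = FALSE])
    tibble(stratum = as.character(d$stratum),
           product = colnames(d$Y)[prods],
           shortfall = unname(short),
           slack_shortfall = unname(slack_short),
           observed_total = unname(denom))
  })
  pooled <- per |>
    dplyr::group_by(.data$product) |>
    dplyr::summarise(dplyr::across(c("shortfall", "slack_shortfall",
                                     "observed_total"), sum),
                     .groups = "drop") |>
    dplyr::mutate(stratum = "total")
  dplyr::bind_rows(per, pooled) |>
    dplyr::mutate(pct = ifelse(.data$observed_total > 0,
                               100 * .data$shortfall /
                                 .data$observed_total, NA_real_)) |>
    dplyr::select("stratum", "product", "shortfall", "slack_shortfall",
                  "observed_total", "pct")
}

#' Descriptive statistics of model variables by stratum
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of every input and output column, per stratum.
#'
#' @param strata named list of [stratum_data()] objects.
#' @return Tibble with `stratum`, `variable`, `role`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
descriptive_stats <- function(strata) {
  if (inherits(strata, "stratum_data")) strata <- list(strata)
  purrr::map_dfr(strata, function(d) {
    vars <- cbind(d$X, d$Y)
    role <- c(rep("input", ncol(d$X)),
              rep("product", d$n_products),
              rep("control", ncol(d$Y) - d$n_products))
    tibble(stratum = d$stratum,
           variable = colnames(vars),
           role = role,
           mean = unname(colMeans(vars)),
           sd = unname(apply(vars, 2, stats::sd)),
           min = unname(apply(vars, 2, min)),
           max = unname(apply(vars, 2, max)))
  })
}

#' Input-product correlation screen
#'
#' Spearman rank correlation between every input and every output column,
#' with a two-sided p-value; counts are heavily right-skewed, so a rank
#' method is the defensible default. A pair involving a constant column is
#' reported as undefined (`NA`). The summary attribute flags whether every
#' pair is positive and significant at the 5% level, the precondition for
#' a meaningful production frontier.
#'
#' @param data a [stratum_data()] object.
#' @return Tibble with `input`, `output`, `rho`, `p_value`,
#'   `positive_significant`; attribute `all_positive` carries the summary
#'   flag.
#' @export
correlation_screen <- function(data) {
  stopifnot(inherits(data, "stratum_data"))
  if (nrow(data$X) < 3) stop("need at least 3 DMUs", call. = FALSE)
  grid <- tidyr::expand_grid(input = colnames(data$X),
                             output = colnames(data$Y))
  res <- purrr::pmap_dfr(grid, function(input, output) {
    x <- data$X[, input]
    y <- data$Y[, output]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble(input = input, output = output, rho = NA_real_,
                    p_value = NA_real_, positive_significant = NA))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(input = input, output = output,
           rho = unname(ct$estimate), p_value = ct$p.value,
           positive_significant = unname(ct$estimate) > 0 &
             ct$p.value < 0.05)
  })
  attr(res, "all_positive") <- all(res$positive_significant %in% TRUE)
  res
}
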