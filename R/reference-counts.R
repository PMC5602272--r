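#' Published classification counts from the 2012 national evaluation
#'
#' Aggregate counts published by the 2012 nationwide efficiency evaluation
#' of Brazilian municipal primary care that this package operationalizes.
#' The underlying municipal microdata have no public accession, but the
#' published per-stratum counts are sufficient to exercise the reporting
#' stage on real magnitudes: `single_model` holds, per model and
#' population-size stratum, the number of municipalities classified
#' inefficient, efficient only for themselves, and efficient reference
#' for more than one DMU; `cross_model` holds the six-category joint
#' classification of the 1,880 municipalities retained in both models.
#'
#' @return List with tibbles `single_model` (`model`, `stratum`,
#'   `inefficient`, `efficient_self_only`, `efficient_multi_reference`)
#'   and `cross_model` (`stratum`, one column per joint category).
#' @export
reference_classification_counts <- function() {
  single_model <- dplyr::bind_rows(
    tibble(model = "model1", stratum = 1:5,
           inefficient = c(378L, 282L, 384L, 221L, 19L),
           efficient_self_only = c(16L, 93L, 142L, 84L, 27L),
           efficient_multi_reference = c(25L, 101L, 122L, 97L, 20L)),
    tibble(model = "model2", stratum = 1:5,
           inefficient = c(613L, 540L, 729L, 403L, 40L),
           efficient_self_only = c(3L, 23L, 38L, 29L, 17L),
           efficient_multi_reference = c(10L, 49L, 59L, 32L, 10L)))
  cross_model <- tibble(
    stratum = 1:5,
    inefficient_both = c(332L, 238L, 362L, 211L, 13L),
    inefficient_one_multi_other = c(30L, 81L, 90L, 65L, 11L),
    self_only_exactly_one = c(15L, 72L, 120L, 79L, 16L),
    self_only_both = c(0L, 3L, 5L, 4L, 7L),
    self_one_multi_other = c(0L, 14L, 27L, 19L, 12L),
    multi_both = c(0L, 14L, 20L, 18L, 2L))
  list(single_model = single_model, cross_model = cross_model)
}

#' Expand published per-category counts into per-DMU classification tables
#'
#' Reconstructs synthetic per-DMU category assignments that realize given
#' per-stratum counts, so published aggregate tables can be fed through
#' the same reporting stage ([category_percentages()], [cross_classify()])
#' as freshly computed frontiers. For joint categories that pair two
#' different single-model categories, the first-named category is
#' assigned to model 1 (percentages are invariant to that choice).
#'
#' @param cross_model tibble in the layout of
#'   `reference_classification_counts()$cross_model`.
#' @return List of two `dea_classification` objects (`model1`, `model2`)
#'   whose cross-classification reproduces the given counts.
#' @export
expand_cross_counts <- function(cross_model) {
  pair <- list(
    inefficient_both = c("inefficient", "inefficient"),
    inefficient_one_multi_other = c("inefficient",
                                    "efficient_multi_reference"),
    self_only_exactly_one = c("efficient_self_only", "inefficient"),
    self_only_both = c("efficient_self_only", "efficient_self_only"),
    self_one_multi_other = c("efficient_self_only",
                             "efficient_multi_reference"),
    multi_both = c("efficient_multi_reference",
                   "efficient_multi_reference"))
  rows <- list()
  for (i in seq_len(nrow(cross_model))) {
    for (cat in names(pair)) {
      k <- cross_model[[cat]][i]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          stratum = cross_model$stratum[i],
          category_model1 = pair[[cat]][1],
          category_model2 = pair[[cat]][2],
          n = k)
      }
    }
  }
  long <- dplyr::bind_rows(rows) |> tidyr::uncount(.data$n)
  long$dmu_id <- sprintf("R%05d", seq_len(nrow(long)))
  as_class <- function(categories, stratum, ids) {
    per_dmu <- tibble(dmu_id = ids, stratum = stratum,
                      category = factor(categories,
                                        levels = dea_categories()))
    structure(list(per_dmu = per_dmu,
                   per_stratum = category_percentages(per_dmu)),
              class = "dea_classification")
  }
  list(model1 = as_class(long$category_model1, long$stratum, long$dmu_id),
       model2 = as_class(long$category_model2, long$stratum, long$dmu_id))
}
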