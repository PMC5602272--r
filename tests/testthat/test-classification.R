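# Reference-role classification, cross-model categories, expansion
# targets, descriptive statistics, correlation screen.

test_that("classification partitions the DMU set", {
  d <- stratum_data(1, c("A", "B"), matrix(c(1, 1)), matrix(c(1, 2)))
  cls <- classify_dmus(dea_frontier(d))
  expect_equal(
    as.character(cls$per_dmu$category[cls$per_dmu$dmu_id == "A"]),
    "inefficient")
  expect_equal(
    as.character(cls$per_dmu$category[cls$per_dmu$dmu_id == "B"]),
    "efficient_multi_reference")

  # an efficient DMU referenced by nobody else is efficient_self_only:
  # C is efficient but no other DMU uses it as a peer
  d3 <- stratum_data(1, c("A", "B", "C"),
                     matrix(c(1, 1, 5)), matrix(c(1, 2, 2.01)))
  cls3 <- classify_dmus(dea_frontier(d3))
  expect_equal(
    as.character(cls3$per_dmu$category[cls3$per_dmu$dmu_id == "C"]),
    "efficient_self_only")

  set.seed(808)
  inst <- random_instance(50, 2, 2)
  cls50 <- classify_dmus(dea_frontier(make_stratum(inst$X, inst$Y)))
  expect_equal(sum(cls50$per_stratum$n[cls50$per_stratum$stratum == "1"]),
               50)
  # percentages sum to 100 up to rounding
  sums <- tapply(cls50$per_stratum$pct, cls50$per_stratum$stratum, sum)
  expect_true(all(abs(sums - 100) <= 0.2))
})

test_that("cross-model joint categories follow the six-way definition", {
  mk <- function(ids, strata, cats) {
    per <- tibble::tibble(dmu_id = ids, stratum = strata,
                          category = factor(cats,
                                            levels = pcdea:::dea_categories()))
    structure(list(per_dmu = per,
                   per_stratum = category_percentages(per)),
              class = "dea_classification")
  }
  c1 <- mk(c("a", "b", "c", "d"), 1,
           c("inefficient", "inefficient", "efficient_self_only",
             "efficient_multi_reference"))
  c2 <- mk(c("a", "b", "c", "d"), 1,
           c("inefficient", "efficient_multi_reference",
             "efficient_self_only", "efficient_self_only"))
  x <- cross_classify(c1, c2)
  joint <- setNames(as.character(x$per_dmu$joint), x$per_dmu$dmu_id)
  expect_equal(unname(joint["a"]), "inefficient_both")
  expect_equal(unname(joint["b"]), "inefficient_one_multi_other")
  expect_equal(unname(joint["c"]), "self_only_both")
  expect_equal(unname(joint["d"]), "self_one_multi_other")

  # marginals restricted to the intersection match each model's counts
  expect_equal(sum(x$table$n[x$table$stratum == "1"]), 4)

  # empty intersection errors explicitly
  c3 <- mk("zzz", 1, "inefficient")
  expect_error(cross_classify(c1, c3), "both models")
})

test_that("published cross-model counts reproduce the printed shares", {
  rc <- reference_classification_counts()
  # the printed table pools 1,880 municipalities present in both models
  expect_equal(sum(colSums(rc$cross_model[, -1])), 1880)
  cls <- expand_cross_counts(rc$cross_model)
  x <- cross_classify(cls$model1, cls$model2)
  tab <- x$table
  pick <- function(stratum, category) {
    tab$pct[tab$stratum == stratum & tab$category == category]
  }
  expect_equal(pick("1", "inefficient_both"), 88.1)
  expect_equal(pick("total", "multi_both"), 2.9)
  eff_both <- sum(tab$n[tab$stratum == "total" &
                          tab$category %in% c("self_only_both",
                                              "self_one_multi_other",
                                              "multi_both")])
  expect_equal(pcdea:::round_half_up(100 * eff_both / 1880, 1), 7.7)
})

test_that("aggregate expansion matches hand arithmetic and a re-aggregation oracle", {
  d <- stratum_data(1, c("A", "B"), matrix(c(1, 1)), matrix(c(1, 2)))
  fr <- dea_frontier(d)
  exp_tab <- aggregate_expansion(fr)
  row <- exp_tab[exp_tab$stratum == "1", ]
  # A expands from 1 to 2: shortfall 1 over total production 3
  expect_equal(row$shortfall, 1, tolerance = 1e-6)
  expect_equal(row$observed_total, 3)
  expect_equal(row$pct, 100 / 3, tolerance = 1e-4)

  # all-efficient stratum: zero shortfall everywhere
  d_eff <- stratum_data(1, c("A", "B"), matrix(c(1, 2)), matrix(c(1, 2)))
  exp_eff <- aggregate_expansion(dea_frontier(d_eff))
  expect_true(all(exp_eff$shortfall == 0))
  expect_true(all(exp_eff$pct == 0))

  # synthetic stratum: independent re-aggregation sum((phi-1) y)/sum(y)
  set.seed(909)
  inst <- random_instance(40, 2, 2)
  ds <- make_stratum(inst$X, inst$Y)
  frs <- dea_frontier(ds)
  tab <- aggregate_expansion(frs)
  phi <- purrr::map_dbl(frs$results, "phi")
  ineff <- phi > 1 + 1e-6
  for (j in 1:2) {
    ref <- sum((phi[ineff] - 1) * inst$Y[ineff, j]) / sum(inst$Y[, j]) * 100
    expect_equal(tab$pct[tab$stratum == "1"][j], ref, tolerance = 1e-8)
  }
  # the alternative denominator restricts to inefficient DMUs
  tab_i <- aggregate_expansion(frs, denominator = "inefficient")
  expect_equal(tab_i$observed_total[tab_i$stratum == "1"],
               colSums(inst$Y[ineff, , drop = FALSE]))

  # expansion report is invariant to DMU ordering
  perm <- sample(40)
  dp <- make_stratum(inst$X[perm, ], inst$Y[perm, ])
  tabp <- aggregate_expansion(dea_frontier(dp))
  expect_equal(tabp$pct, tab$pct, tolerance = 1e-8)
})

test_that("controls are excluded from expansion targets", {
  gen <- generate_municipalities(synthetic_config(
    n_per_stratum = c(`3` = 40), seed = 17))
  spec <- builtin_model_specs()$model1
  pre <- preprocess_model(gen$table, spec)
  fr <- dea_frontier(pre$strata[["3"]])
  tab <- aggregate_expansion(fr)
  expect_setequal(unique(tab$product), spec$product_vars)
})

test_that("descriptive statistics use the sample SD", {
  d <- stratum_data(1, c("A", "B", "C"),
                    X = matrix(c(1, 2, 3), dimnames = list(NULL, "x")),
                    Y = matrix(c(5, 5, 5), dimnames = list(NULL, "y")))
  st <- descriptive_stats(list(d))
  xrow <- st[st$variable == "x", ]
  expect_equal(xrow$mean, 2)
  expect_equal(xrow$sd, 1)   # n-1 denominator
  expect_equal(c(xrow$min, xrow$max), c(1, 3))
  yrow <- st[st$variable == "y", ]
  expect_equal(yrow$sd, 0)
  expect_equal(yrow$min, yrow$max)

  set.seed(123)
  inst <- random_instance(30, 2, 2)
  ds <- make_stratum(inst$X, inst$Y)
  st2 <- descriptive_stats(list(ds))
  expect_equal(st2$mean, unname(colMeans(cbind(inst$X, inst$Y))))
})

test_that("correlation screen detects monotone, null and anti-monotone pairs", {
  x <- 1:50
  d <- stratum_data(1, sprintf("D%02d", 1:50),
                    X = matrix(x, dimnames = list(NULL, "inp")),
                    Y = cbind(prop = 3 * x, anti = 51 - x))
  cs <- correlation_screen(d)
  expect_equal(cs$rho[cs$output == "prop"], 1)
  expect_equal(cs$rho[cs$output == "anti"], -1)
  expect_false(cs$positive_significant[cs$output == "anti"])
  expect_false(attr(cs, "all_positive"))

  set.seed(2024)
  xr <- runif(200, 1, 2)
  d2 <- stratum_data(1, sprintf("D%03d", 1:200),
                     X = matrix(xr, dimnames = list(NULL, "inp")),
                     Y = matrix(sample(xr), dimnames = list(NULL, "perm")))
  cs2 <- correlation_screen(d2)
  expect_lt(abs(cs2$rho), 0.2)
  expect_gt(cs2$p_value, 0.05)

  # constant column reported as undefined
  d3 <- stratum_data(1, c("A", "B", "C"),
                     X = matrix(c(1, 1, 1), dimnames = list(NULL, "inp")),
                     Y = matrix(1:3, dimnames = list(NULL, "out")))
  expect_true(is.na(correlation_screen(d3)$rho))
})
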