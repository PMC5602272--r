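# Exclusion stages, derived products, percentile trimming, stratification.

specs <- builtin_model_specs()

test_that("exclusion stages fire in order and log each record once", {
  toy <- make_toy_fixture()
  res <- apply_exclusions(toy, specs$model1)
  log <- res$log

  expect_equal(log$stage[log$id == "T03"], "non_pmaq")
  expect_equal(log$stage[log$id == "T04"], "low_coverage")
  expect_equal(log$stage[log$id == "T06"], "inconsistent")
  expect_equal(log$stage[log$id == "T05"], "zero_input")
  expect_equal(nrow(log), 4)
  expect_equal(nrow(res$retained), nrow(toy) - 4)
  expect_length(intersect(res$retained$id, log$id), 0)

  # conservation at the stage level
  expect_equal(nrow(res$retained) + nrow(log), nrow(toy))
})

test_that("coverage threshold is strict: exactly 80 percent is retained", {
  toy <- make_toy_fixture()
  toy$pc_coverage[toy$id == "T01"] <- 80.0
  res <- apply_exclusions(toy, specs$model1)
  expect_true("T01" %in% res$retained$id)
  toy$pc_coverage[toy$id == "T01"] <- 79.999
  res <- apply_exclusions(toy, specs$model1)
  expect_equal(res$log$stage[res$log$id == "T01"], "low_coverage")
})

test_that("zero-input rule is ANY for model 1 and ALL for model 2", {
  toy <- make_toy_fixture()
  r1 <- apply_exclusions(toy, specs$model1)
  expect_equal(r1$log$stage[r1$log$id == "T05"], "zero_input")
  r2 <- apply_exclusions(toy, specs$model2)
  expect_false("T05" %in% r2$log$id)

  toy$nurses[toy$id == "T05"] <- 0
  toy$bhu_total[toy$id == "T05"] <- 0
  toy$bhu_vaccination_room[toy$id == "T05"] <- 0
  toy$bhu_sonar_pinard[toy$id == "T05"] <- 0
  r2 <- apply_exclusions(toy, specs$model2)
  expect_equal(r2$log$stage[r2$log$id == "T05"], "zero_input")
})

test_that("excluding everything raises an explicit empty-sample error", {
  toy <- make_toy_fixture()
  toy$pmaq_participant <- FALSE
  expect_error(apply_exclusions(toy, specs$model1), "empty sample")
})

test_that("derived products follow the published formulas", {
  toy <- make_toy_fixture()[1:2, ]
  toy$physicians <- c(2, 3)
  toy$population <- c(4000, 3000)
  toy$hospitalizations_total <- c(100, 200)
  toy$hospitalizations_pcsc <- c(10, 50)
  der <- derive_products(toy, specs$model2)
  expect_equal(der$physicians_per_1000, c(0.5, 1))
  expect_equal(der$pct_non_pcsc, c(90, 75))

  der1 <- derive_products(make_toy_fixture(), specs$model1)
  # every unit equipped -> 100%
  expect_equal(der1$pct_bhu_vaccination_room,
               rep(100, nrow(der1)))
})

test_that("percentile trim matches an independent brute-force scan", {
  set.seed(7)
  tbl <- make_toy_fixture()[rep(1, 100), ]
  tbl$id <- sprintf("S%03d", 1:100)
  tbl$rate_a <- sample(1:100)
  tbl$rate_b <- runif(100)
  res <- trim_percentiles(tbl, c("rate_a", "rate_b"))

  lo_a <- quantile(tbl$rate_a, 0.05, type = 7)
  hi_a <- quantile(tbl$rate_a, 0.95, type = 7)
  lo_b <- quantile(tbl$rate_b, 0.05, type = 7)
  hi_b <- quantile(tbl$rate_b, 0.95, type = 7)
  out <- tbl$rate_a < lo_a | tbl$rate_a > hi_a |
    tbl$rate_b < lo_b | tbl$rate_b > hi_b
  expect_setequal(res$log$id, tbl$id[out])
  expect_setequal(res$retained$id, tbl$id[!out])
  # conservation and boundary retention
  expect_equal(nrow(res$retained) + nrow(res$log), nrow(tbl))
  kept <- res$retained
  expect_true(all(kept$rate_a >= lo_a & kept$rate_a <= hi_a))
})

test_that("degenerate and ANY-rule trim cases behave", {
  tbl <- make_toy_fixture()[rep(1, 10), ]
  tbl$id <- sprintf("S%02d", 1:10)
  tbl$rate_a <- 5
  res <- trim_percentiles(tbl, "rate_a")
  expect_equal(nrow(res$log), 0)

  # extreme in the second variable only still eliminates
  tbl$rate_b <- c(rep(1, 9), 1000)
  res <- trim_percentiles(tbl, c("rate_a", "rate_b"))
  expect_equal(res$log$id, "S10")

  expect_error(trim_percentiles(tbl, "absent_var"), "absent_var")
})

test_that("stratification uses the published size boundaries", {
  toy <- make_toy_fixture()
  toy <- toy[toy$id %in% c("T01", "T02", "T07"), ]
  toy$population <- c(5000, 5001, 150000)
  der <- derive_products(toy, specs$model1)
  strata <- suppressMessages(stratify(der, specs$model1))
  expect_equal(strata[["1"]]$dmu_ids, "T01")
  expect_equal(strata[["2"]]$dmu_ids, "T02")
  expect_false("T07" %in% unlist(purrr::map(strata, "dmu_ids")))
  expect_message(stratify(der, specs$model1), "100,000")

  # controls omitted in stratum 1 only: 4 vs 8 output columns
  expect_equal(ncol(strata[["1"]]$Y), 4)
  expect_equal(ncol(strata[["2"]]$Y), 8)
  expect_equal(strata[["2"]]$n_products, 4)
})

test_that("DMU adequacy rule flags under-sized strata", {
  d <- stratum_data(1, sprintf("D%02d", 1:30),
                    matrix(runif(30 * 4, 1, 2), 30),
                    matrix(runif(30 * 8, 1, 2), 30))
  expect_warning(rep30 <- check_dmu_rule(d), "30 DMUs")
  expect_false(rep30$ok)

  d36 <- stratum_data(1, sprintf("D%02d", 1:36),
                      matrix(runif(36 * 4, 1, 2), 36),
                      matrix(runif(36 * 8, 1, 2), 36))
  expect_silent(rep36 <- check_dmu_rule(d36))
  expect_true(rep36$ok)

  gen <- generate_municipalities(synthetic_config(
    n_per_stratum = c(`3` = 200), seed = 5))
  strata <- stratify(derive_products(gen$table, specs$model2),
                     specs$model2)
  expect_true(all(check_dmu_rule(strata)$ok))
})

test_that("the preprocessing chain is idempotent on clean output", {
  gen <- generate_municipalities(synthetic_config(
    n_per_stratum = c(`2` = 60, `4` = 60), seed = 31))
  pre <- preprocess_model(gen$table, specs$model1)
  again <- apply_exclusions(pre$retained, specs$model1)
  expect_equal(nrow(again$log), 0)
  expect_setequal(again$retained$id, pre$retained$id)
  # records inside [P5, P95] on every trim variable are never removed;
  # re-trimming narrows only via freshly computed thresholds, so verify
  # the no-op on an already uniform-rate table instead
  toy <- make_toy_fixture()
  p1 <- preprocess_model(toy, specs$model1)
  p2 <- preprocess_model(p1$retained[, pcdea:::municipality_columns()],
                         specs$model1)
  expect_equal(nrow(p2$log), 0)
  expect_setequal(p2$retained$id, p1$retained$id)
})
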