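test_that("product-limit estimator matches hand-computed examples", {
  ## all censored: S identically 1, median undefined
  all_cens <- kaplan_meier(c(3, 5, 9), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(all_cens), 0L)
  expect_equal(km_survival_at(all_cens, c(0, 10)), c(1, 1))
  expect_true(is.na(attr(all_cens, "median")))

  ## events at 1 and 2, n = 2: S = 0.5 then 0
  two <- kaplan_meier(c(1, 2), c(TRUE, TRUE))
  expect_equal(two$survival, c(0.5, 0))
  expect_equal(two$at_risk, c(2, 1))
  expect_equal(attr(two, "median"), 1)

  ## tie rule: censored at an event time stays at risk through it
  ## {1 event, 1 censored at 1, 1 censored at 2}: d1=1, n1=3 -> S(1)=2/3
  tie <- kaplan_meier(c(1, 1, 2), c(TRUE, FALSE, FALSE))
  expect_equal(tie$survival, 2 / 3)
  expect_equal(tie$at_risk, 3)
  expect_equal(tie$events, 1)
})

test_that("without censoring S equals the empirical survival function", {
  set.seed(41)
  t <- sample(1:50, 30, replace = TRUE)
  km <- kaplan_meier(t, rep(TRUE, 30))
  for (tt in c(0, sort(unique(t))))
    expect_equal(km_survival_at(km, tt), mean(t > tt))
})

test_that("estimator agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    t <- sample(1:40, n, replace = TRUE)
    ev <- runif(n) < 0.6
    if (!any(ev)) ev[1] <- TRUE
    km <- kaplan_meier(t, ev)
    sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
    ref <- summary(sf, times = km$time)
    expect_equal(km$survival, ref$surv, tolerance = 1e-12)
    expect_equal(km$at_risk, ref$n.risk)
  }
})

test_that("greenwood errors and log-rank match the reference", {
  skip_if_not_installed("survival")
  set.seed(43)
  t <- sample(1:30, 40, replace = TRUE)
  ev <- runif(40) < 0.5
  if (!any(ev)) ev[1] <- TRUE
  km <- kaplan_meier(t, ev, conf = TRUE)
  ref <- summary(survival::survfit(survival::Surv(t, ev) ~ 1,
                                   conf.type = "plain"), times = km$time)
  expect_equal(km$std_err, ref$std.err, tolerance = 1e-8)

  g <- rep(c("a", "b"), 20)
  lr <- log_rank_test(t, ev, g)
  sd <- survival::survdiff(survival::Surv(t, ev) ~ g)
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-8)
  expect_equal(unname(lr$observed), unname(sd$obs))
  expect_equal(unname(lr$expected), unname(sd$exp), tolerance = 1e-8)
})

test_that("negative times are rejected", {
  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)),
               class = "dw_validation_error")
})

test_that("warehouse survival records mirror the generator's ground truth", {
  pipe <- run_pipeline(80, seed = 44)
  rec <- survival_records(pipe$warehouse)
  truth <- pipe$sim$truth$survival
  ## map warehouse pseudonyms back to source ids through the lookup
  map <- setNames(pipe$lookup$pseudonyms$pu_patient_id,
                  pipe$lookup$pseudonyms$warehouse_id)
  rec$pu <- unname(map[rec$patient_id])
  expect_setequal(rec$pu, truth$pu_patient_id)
  m <- match(rec$pu, truth$pu_patient_id)
  expect_equal(rec$time, truth$time[m])
  expect_equal(rec$event, truth$event[m])
})

test_that("biobank_info equals a brute-force three-way join", {
  pipe <- run_pipeline(200, seed = 45)
  wh <- pipe$warehouse
  ps <- run_query(query_definition(query_panel("\\Biobank\\")), wh)
  rows <- biobank_info(ps, "tissue", pipe$sync$biobank, pipe$lookup,
                       authorized = TRUE)
  ## independent join over the raw stores
  map <- setNames(pipe$lookup$pseudonyms$warehouse_id,
                  pipe$lookup$pseudonyms$pu_patient_id)
  bmap <- setNames(pipe$lookup$barcodes$pu_patient_id,
                   pipe$lookup$barcodes$payload)
  bb <- pipe$sync$biobank
  want <- bb$payload[bb$material_type == "tissue" &
                       unname(map[bmap[bb$payload]]) %in% ps$patient_ids]
  expect_setequal(rows$payload, want)
  expect_false("patient_id" %in% names(rows))
  expect_false(any(grepl("MRN-", unlist(rows), fixed = TRUE)))

  expect_error(biobank_info(ps, "tissue", pipe$sync$biobank, pipe$lookup,
                            authorized = FALSE),
               class = "dw_authorization_error")
  none <- biobank_info(ps, "RNA", pipe$sync$biobank, pipe$lookup,
                       authorized = TRUE)
  expect_true(nrow(none) == 0L ||
                all(none$material_type == "RNA"))
  empty_set <- structure(list(patient_ids = character(0),
                              provenance = ps$provenance),
                         class = "patient_set")
  expect_equal(nrow(biobank_info(empty_set, "tissue", pipe$sync$biobank,
                                 pipe$lookup, authorized = TRUE)), 0L)
})

test_that("km curve export and evaluation are consistent", {
  pipe <- run_pipeline(60, seed = 46)
  rec <- survival_records(pipe$warehouse)
  km <- kaplan_meier(rec$time, rec$event)
  expect_true(all(diff(km$time) > 0))
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_km_curve(km, f)
  back <- dw_read_table(f, numeric_cols = c("time", "at_risk", "events",
                                            "survival"))
  expect_equal(back$survival, km$survival)
})
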