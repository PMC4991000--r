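test_that("Kaplan-Meier curve matches hand product-limit computations", {
  # all censored: survival stays at 1
  km <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km$surv == 1))

  # three events at 1, 2, 3: S = 2/3, 1/3, 0
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # 10-subject mixed fixture vs the hand-worked oracle
  time <- c(3, 5, 5, 7, 8, 10, 12, 12, 14, 15)
  event <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0)
  km <- km_curve(time, event)
  hand <- oracle_km(time, event)
  expect_equal(km$surv[match(hand$time, km$time)], hand$surv,
               tolerance = 1e-12)
  # non-increasing, starts at/below 1
  expect_true(all(diff(km$surv) <= 0))
  expect_lte(km$surv[1], 1)

  expect_error(km_curve(numeric(0), numeric(0)), "empty")
  expect_error(km_curve(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("KM equals 1 - ECDF when no one is censored", {
  set.seed(55)
  for (i in 1:5) {
    t <- round(rexp(40, 0.1), 1)
    km <- km_curve(t, rep(1, 40))
    ec <- ecdf(t)
    expect_equal(km$surv, 1 - ec(km$time), tolerance = 1e-12)
  }
})

test_that("log-rank test matches term-by-term accumulation", {
  # 8-subject fixture with ties and censoring
  time <- c(2, 2, 4, 5, 6, 8, 8, 11)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- c(1, 2, 1, 2, 1, 2, 1, 2)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi2, oracle_logrank_chi2(time, event, group),
               tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))

  # identical data in both groups: chi2 = 0, p = 1
  lr0 <- logrank_test(rep(c(1, 3, 7), 2), rep(c(1, 1, 0), 2),
                      rep(1:2, each = 3))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # invariant to relabelling groups
  set.seed(70)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.7); g2 <- rep(1:2, 15)
  a <- logrank_test(t2, e2, g2)
  b <- logrank_test(t2, e2, 3 - g2)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(1, 2)), "no events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "2 groups")
})

test_that("k-means stratification separates distant clouds perfectly", {
  set.seed(12)
  n <- 40
  x <- rbind(matrix(rnorm(n / 2 * 3, -5), ncol = 3),
             matrix(rnorm(n / 2 * 3, 5), ncol = 3))
  rownames(x) <- sprintf("p%02d", 1:n)
  colnames(x) <- c("f1", "f2", "f3")
  co <- survival_cohort(rexp(n), rbinom(n, 1, 0.5), x)
  grp <- kmeans_stratify(co, c("f1", "f2", "f3"), k = 2, seed = 3)
  expect_length(unique(grp[1:(n / 2)]), 1)
  expect_length(unique(grp[(n / 2 + 1):n]), 1)
  expect_equal(length(unique(grp)), 2)

  expect_error(kmeans_stratify(co, "missing_gene"), "not in cohort")
  expect_error(kmeans_stratify(co, "f1", k = 100), "exceeds")
})

test_that("k-means attains the exhaustive-search optimum at small n", {
  set.seed(9)
  n <- 12
  x <- matrix(rnorm(n * 2), ncol = 2,
              dimnames = list(sprintf("p%02d", 1:n), c("a", "b")))
  co <- survival_cohort(rexp(n), rbinom(n, 1, 0.5), x)
  grp <- kmeans_stratify(co, c("a", "b"), k = 2, seed = 5,
                         n_restarts = 25)
  z <- scale(x)
  wss <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      xx <- z[assign == g, , drop = FALSE]
      sum(sweep(xx, 2, colMeans(xx))^2)
    }, numeric(1)))
  }
  # enumerate all 2-partitions (fix patient 1 in group 1)
  best <- Inf
  for (code in 0:(2^(n - 1) - 1)) {
    assign <- c(1, as.integer(intToBits(code))[1:(n - 1)] + 1)
    if (length(unique(assign)) == 2) best <- min(best, wss(assign))
  }
  expect_equal(wss(unname(grp)), best, tolerance = 1e-8)
})

test_that("RF-RFE finds a perfectly separating feature among noise", {
  found <- 0
  for (s in 1:3) {
    set.seed(s)
    n <- 200
    y <- rep(0:1, each = n / 2)
    x <- matrix(rnorm(n * 11), nrow = n,
                dimnames = list(sprintf("p%03d", 1:n),
                                c("signal", sprintf("noise%02d", 1:10))))
    x[, "signal"] <- y * 4 + rnorm(n, sd = 0.2)
    co <- survival_cohort(rexp(n), y, x)
    rfe <- rf_rfe(co, label = y, n_folds = 5, n_repeats = 1,
                  seed = s, num_trees = 100)
    found <- found + ("signal" %in% rfe$selected)
    expect_gt(max(rfe$accuracy_by_size), 0.95)
  }
  expect_equal(found, 3)
})

test_that("RFE result structure obeys its invariants", {
  co <- generate_cohort(generator_config(
    n_patients = 60, n_candidates = 8, n_informative = 2, seed = 14))
  rfe <- rf_rfe(co$cohort, n_folds = 3, n_repeats = 1, seed = 2,
                num_trees = 80)
  expect_length(rfe$accuracy_by_size, 8)
  expect_true(all(rfe$accuracy_by_size >= 0 &
                    rfe$accuracy_by_size <= 1))
  expect_equal(length(rfe$selected), rfe$best_size)
  expect_equal(unname(rfe$accuracy_by_size[rfe$best_size]),
               max(rfe$accuracy_by_size))
  expect_true(all(rfe$selected %in% colnames(co$cohort$features)))
  expect_setequal(rfe$elimination_order,
                  colnames(co$cohort$features))
  # deterministic given the seed
  rfe2 <- rf_rfe(co$cohort, n_folds = 3, n_repeats = 1, seed = 2,
                 num_trees = 80)
  expect_identical(rfe$accuracy_by_size, rfe2$accuracy_by_size)
  expect_identical(rfe$selected, rfe2$selected)

  expect_error(rf_rfe(co$cohort, label = rep(1, 60)), "2 classes")
  expect_error(rf_rfe(co$cohort, n_folds = 100), "class size")
})

test_that("stratification labels the higher-event-rate group poor", {
  co <- generate_cohort(generator_config(seed = 31))
  strat <- stratify_and_test(co$cohort, co$truth$informative, seed = 31)
  expect_equal(sort(unique(unname(strat$group_of))), c(1, 2))
  rates <- vapply(1:2, function(g)
    mean(co$cohort$event[strat$group_of == g]), numeric(1))
  poor <- unname(which(strat$prognosis_of == "poor"))
  expect_equal(poor, which.max(rates))
  expect_true(all(vapply(strat$km_curves,
                         function(cv) all(diff(cv$surv) <= 0),
                         logical(1))))
})

test_that("stratification on hazard-independent features is calibrated", {
  # clustering on pure-noise features is independent of survival, so the
  # log-rank p across replicates should be uniform
  ps <- vapply(1:100, function(s) {
    co <- generate_cohort(generator_config(
      n_patients = 80, n_candidates = 5, n_informative = 0,
      hazard_ratio = 1, seed = 4000 + s))
    stratify_and_test(co$cohort, colnames(co$cohort$features),
                      seed = s, n_restarts = 5)$logrank_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("full prognostic stage is reproducible given the seed", {
  co <- generate_cohort(generator_config(
    n_patients = 80, n_candidates = 10, n_informative = 3, seed = 8))
  a <- prognostic_pipeline(co$cohort, seed = 6, n_repeats = 1,
                           num_trees = 80, n_restarts = 10)
  b <- prognostic_pipeline(co$cohort, seed = 6, n_repeats = 1,
                           num_trees = 80, n_restarts = 10)
  expect_identical(a$rfe$selected, b$rfe$selected)
  expect_identical(a$stratification$group_of, b$stratification$group_of)
  expect_identical(a$stratification$logrank_p, b$stratification$logrank_p)
})
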