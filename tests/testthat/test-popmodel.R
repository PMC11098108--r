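test_that("trajectories are seed-reproducible and conserve cell flows", {
  p <- population_model_params(r = 1, arrest_a = 0.05, arrest_b = 0.3,
                               lysis_rate = 0.5, initial_n = 20, t_max = 5,
                               seed = 7)
  tr1 <- simulate_population(p)
  tr2 <- simulate_population(p)
  expect_identical(tr1, tr2)

  # flow bookkeeping at every recorded time
  init <- attr(tr1, "initial_n")
  expect_true(all(tr1$cum_births - (tr1$n_proliferating - init) -
                    tr1$cum_arrests == 0))
  expect_true(all(tr1$cum_arrests - tr1$n_postreplicative -
                    tr1$n_lysed == 0))
  expect_true(all(diff(tr1$n_lysed) >= 0))
  expect_true(all(tr1$total_viable ==
                    tr1$n_proliferating + tr1$n_postreplicative))
})

test_that("without arrest the model is a pure birth process", {
  r <- 1
  counts <- matrix(0, nrow = 50, ncol = 21)
  for (i in 1:50) {
    p <- population_model_params(r = r, arrest_a = 0, arrest_b = 0,
                                 lysis_rate = 0, initial_n = 30, t_max = 2,
                                 record_dt = 0.1, seed = 100 + i)
    counts[i, ] <- simulate_population(p)$total_viable
  }
  tt <- seq(0, 2, by = 0.1)
  slope <- .lm.fit(cbind(1, tt), log(colMeans(counts)))$coefficients[2]
  expect_equal(slope, r, tolerance = 0.05 * r)
  # mean count within 3 SE of the branching-process mean at the endpoint
  mu <- 30 * exp(r * 2)
  se <- sd(counts[, 21]) / sqrt(50)
  expect_lt(abs(mean(counts[, 21]) - mu), 3 * se + 1e-9)
})

test_that("without division the model is a Gompertz cohort", {
  p <- population_model_params(r = 0, arrest_a = 0.01, arrest_b = 0.2,
                               lysis_rate = 1, initial_n = 3000, t_max = 50,
                               record_dt = 0.5, seed = 8)
  tr <- simulate_population(p)
  at <- sort(attr(tr, "arrest_times"))
  ks <- max(abs(seq_along(at) / length(at) -
                  (1 - gompertz_survival(at, 0.01, 0.2))))
  expect_lt(ks, 0.03)
})

test_that("the apparent growth curve is the log viable count", {
  p <- population_model_params(r = 1.2, arrest_a = 0, arrest_b = 0,
                               lysis_rate = 0, initial_n = 50, t_max = 3,
                               record_dt = 0.25, seed = 9)
  g <- apparent_growth_curve(simulate_population(p))
  expect_s3_class(g, "growth_curve")
  sl <- ls_slope(g$times, attr(g, "log_ratio"))
  expect_equal(sl, 1.2, tolerance = 0.15)
  gp <- extract_growth_params(g, window = 5)
  expect_equal(gp$mgr, 1.2, tolerance = 0.3)

  # extinction truncates and flags the series
  pe <- population_model_params(r = 0, arrest_a = 2, arrest_b = 0,
                                lysis_rate = 5, initial_n = 40, t_max = 30,
                                record_dt = 0.2, seed = 10)
  ge <- apparent_growth_curve(simulate_population(pe))
  expect_true(attr(ge, "extinct"))
  expect_lt(attr(ge, "extinction_time"), 30)
  expect_true(all(ge$od > 0))
})

test_that("exceeding the cell cap errors unless subsampling is enabled", {
  p <- population_model_params(r = 2, arrest_a = 0, arrest_b = 0,
                               lysis_rate = 0, initial_n = 10, t_max = 6,
                               max_cells = 200, subsample = FALSE, seed = 11)
  expect_error(simulate_population(p), "max_cells")
  p$subsample <- TRUE
  tr <- simulate_population(p)
  expect_gt(attr(tr, "n_dropped"), 0)
  expect_lte(max(tr$cum_births) + attr(tr, "initial_n"), 200)
})

test_that("extinction fraction behaves at the trivial corners", {
  # no arrest, no lysis: nothing can go extinct
  p0 <- population_model_params(r = 0.5, arrest_a = 0, arrest_b = 0,
                                lysis_rate = 0, initial_n = 2, t_max = 4,
                                subsample = TRUE, max_cells = 500, seed = 12)
  ep0 <- extinction_probe(p0, b_grid = 0, n_replicates = 10, seed = 13)
  expect_equal(ep0$extinction_fraction, 0)

  # no division, positive hazard and lysis: the cohort must die out
  p1 <- population_model_params(r = 0, arrest_a = 0.5, arrest_b = 0,
                                lysis_rate = 2, initial_n = 10, t_max = 60,
                                seed = 14)
  ep1 <- extinction_probe(p1, b_grid = 0, n_replicates = 10, seed = 15)
  expect_equal(ep1$extinction_fraction, 1)
  expect_error(extinction_probe(p1, b_grid = numeric(0)), "non-empty")
})

test_that("faster aging lowers the apparent culture growth rate", {
  mean_mgr <- vapply(c(0, 0.8), function(b) {
    sl <- vapply(1:15, function(i) {
      p <- population_model_params(r = 1.2, arrest_a = 0.2, arrest_b = b,
                                   lysis_rate = 1, initial_n = 40, t_max = 3,
                                   record_dt = 0.1, subsample = TRUE,
                                   max_cells = 5000, seed = 200 + i)
      g <- apparent_growth_curve(simulate_population(p))
      extract_growth_params(g, window = 5)$mgr
    }, numeric(1))
    mean(sl)
  }, numeric(1))
  expect_gt(mean_mgr[1], mean_mgr[2])
})
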