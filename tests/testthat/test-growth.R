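test_that("log transform maps OD to ln(N/N0)", {
  g <- growth_curve(0:11, rep(0.3, 12))
  expect_equal(as.numeric(log_transform(g)), rep(0, 12))
  # doubling each step gives ln 2 increments regardless of the N0 estimate
  g2 <- growth_curve(0:11, 0.01 * 2^(0:11))
  expect_equal(diff(as.numeric(log_transform(g2))), rep(log(2), 11))
  # exponential curve becomes a straight line of slope r
  tt <- seq(0, 5, by = 0.1)
  r <- 0.8
  g3 <- growth_curve(tt, 0.02 * exp(r * tt))
  y <- as.numeric(log_transform(g3))
  expect_equal(max(abs(diff(y) / diff(tt) - r)), 0, tolerance = 1e-10)
  # sub-floor readings are clipped and counted
  g4 <- growth_curve(0:11, c(rep(1e-6, 3), rep(0.5, 9)))
  expect_identical(attr(log_transform(g4), "n_floored"), 3L)
})

test_that("growth parameters match closed forms on noiseless curves", {
  r <- log(2) / 0.5  # 30-min doubling
  tt <- seq(0, 3, by = 0.05)
  gp <- extract_growth_params(growth_curve(tt, 0.01 * exp(r * tt)))
  expect_equal(gp$mgr, r, tolerance = 1e-6)
  expect_equal(gp$texp, diff(range(tt)))  # exponential throughout

  # logistic: SPG -> ln(K/N0), AUC -> analytic integral
  tt <- seq(0, 15, by = 0.01)
  K <- 1; N0 <- 0.01; rl <- 1
  gl <- growth_curve(tt, K * N0 / (N0 + (K - N0) * exp(-rl * tt)))
  gpl <- extract_growth_params(gl)
  expect_equal(gpl$spg, log(K / N0), tolerance = 0.01 * log(K / N0))
  auc_oracle <- stats::integrate(function(t) {
    log((N0 + (K - N0) * exp(-rl * t))^-1 * K * N0 / N0) - log(1)
  }, 0, 15, subdivisions = 2000L)$value
  expect_equal(gpl$auc, auc_oracle, tolerance = 0.01 * auc_oracle)
  # max of the analytic log-slope r(1 - N/K) is at t = 0
  expect_equal(gpl$mgr, rl * (1 - N0 / K), tolerance = 0.01)

  gp0 <- extract_growth_params(growth_curve(0:19, rep(0.4, 20)))
  expect_equal(unlist(gp0[c("mgr", "spg", "auc", "texp")], use.names = FALSE),
               rep(0, 4))
})

test_that("AUC is additive over a split and MGR is scale-invariant", {
  set.seed(41)
  for (i in 1:10) {
    tt <- sort(runif(40, 0, 10))
    od <- 0.01 * exp(cumsum(abs(rnorm(40, 0.2, 0.1))))
    g <- growth_curve(tt, od)
    y <- as.numeric(log_transform(g))
    k <- sample(5:35, 1)
    left <- pracma::trapz(tt[1:k], y[1:k])
    right <- pracma::trapz(tt[k:40], y[k:40])
    expect_equal(extract_growth_params(g)$auc, left + right,
                 tolerance = 1e-10)
    g_scaled <- growth_curve(tt, od * 7.3)
    expect_equal(extract_growth_params(g_scaled)$mgr,
                 extract_growth_params(g)$mgr, tolerance = 1e-10)
  }
})

test_that("panel assembly z-scores features and rejects degenerate input", {
  params <- expand.grid(strain = c("s1", "s2", "s3"),
                        medium = c("LB", "M9G"), stringsAsFactors = FALSE)
  set.seed(42)
  params$mgr <- rnorm(6, 1); params$spg <- rnorm(6, 4)
  params$auc <- rnorm(6, 20); params$texp <- rnorm(6, 2)
  pm <- panel_matrix(params)
  expect_equal(colMeans(pm$matrix), rep(0, 8), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(apply(pm$matrix, 2, sd), rep(1, 8), ignore_attr = TRUE,
               tolerance = 1e-12)
  # single strain: z-scoring degenerate
  expect_error(panel_matrix(params[params$strain == "s1", ]), "two strains")
  # identical strains: all-zero after centring
  p2 <- params[params$strain %in% c("s1", "s2"), ]
  p2[p2$strain == "s2", c("mgr", "spg", "auc", "texp")] <-
    p2[p2$strain == "s1", c("mgr", "spg", "auc", "texp")]
  expect_equal(max(abs(panel_matrix(p2)$matrix)), 0)
  # duplicated feature column -> correlation 1
  p3 <- params; p3$texp <- p3$mgr
  expect_equal(panel_matrix(p3)$correlation["mgr-LB", "texp-LB"], 1)
  # missing strain x medium cell -> explicit error
  expect_error(panel_matrix(params[-1, ]), "missing")
})

test_that("decomposition reconstructs the matrix and respects structure", {
  set.seed(43)
  # rank-1 matrix: first component captures everything
  u <- rnorm(12); v <- rnorm(6)
  m1 <- outer(u, v)
  rownames(m1) <- sprintf("s%02d", 1:12)
  d1 <- decompose_and_cluster(m1, n_clusters = 2)
  expect_gte(d1$variance_explained[1], 0.999)
  expect_true(all(diff(d1$variance_explained) <= 1e-12))
  # orthonormal loadings
  gram <- crossprod(d1$loadings)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # full reconstruction
  rec <- d1$scores %*% t(d1$loadings)
  rec <- sweep(rec, 2, d1$center, "+")
  expect_lt(max(abs(rec - m1)), 1e-8)

  # two blobs 10 SD apart are recovered exactly
  blob <- rbind(matrix(rnorm(10 * 4), 10), matrix(rnorm(10 * 4, mean = 10), 10))
  rownames(blob) <- sprintf("s%02d", 1:20)
  d2 <- decompose_and_cluster(blob, n_clusters = 2)
  truth <- rep(1:2, each = 10)
  agree <- max(mean(d2$cluster_labels == truth),
               mean(d2$cluster_labels == 3 - truth))
  expect_equal(agree, 1)

  # clustering is invariant to strain ordering
  perm <- sample(20)
  d3 <- decompose_and_cluster(blob[perm, ], n_clusters = 2)
  same <- outer(d2$cluster_labels[perm], d2$cluster_labels[perm], "==")
  same3 <- outer(d3$cluster_labels, d3$cluster_labels, "==")
  expect_identical(same, same3)

  expect_error(decompose_and_cluster(blob, n_clusters = 21), "exceed")
})

test_that("isotropic noise spreads variance over all components", {
  set.seed(44)
  m <- matrix(rnorm(100 * 12), 100, 12)
  rownames(m) <- sprintf("s%03d", 1:100)
  d <- decompose_and_cluster(m, n_clusters = 2)
  expect_lt(max(d$variance_explained), 0.35)
})
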