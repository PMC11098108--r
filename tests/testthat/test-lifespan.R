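make_pi_trace <- function(step_at = NA, level = 300, n = 601, dt = 0.05,
                          base = 100, noise = 0, seed = 1) {
  set.seed(seed)
  tt <- seq(0, by = dt, length.out = n)
  p <- rep(base, n)
  if (!is.na(step_at)) p[tt >= step_at] <- base + level
  if (noise > 0) p <- p + rnorm(n, 0, noise)
  lineage_trace(tt, rep(2.5, n), pi_au = p, gfp_au = rep(1000, n))
}

test_that("dye-entry detection finds sustained steps and censors flat traces", {
  flat <- make_pi_trace(NA, noise = 5)
  expect_true(detect_pi_entry(flat)$censored)

  # +20 sigma step at t = 20 h, sustained
  stepped <- make_pi_trace(step_at = 20, level = 200, noise = 10)
  res <- detect_pi_entry(stepped, k_sigma = 5, sustain_frames = 2)
  expect_false(res$censored)
  expect_equal(res$time, 20, tolerance = 1e-12)

  # a single-frame speckle is ignored when sustain_frames = 2
  speck <- make_pi_trace(NA, noise = 0)
  speck$pi_au[100] <- 1e4
  expect_true(detect_pi_entry(speck, sustain_frames = 2)$censored)

  no_pi <- lineage_trace(1:20, rep(2, 20))
  expect_error(detect_pi_entry(no_pi), "pi_au")
})

test_that("lifespan segmentation splits aRL and PRL at the last division", {
  # divisions every 0.5 h until 15 h, lysis at 20 h
  tt <- seq(0, 25, by = 0.05)
  phase <- tt %% 0.5
  L <- ifelse(tt < 15, 2.5 * 2^(phase / 0.5), 2.5)
  tr <- lineage_trace(tt, L, pi_au = ifelse(tt >= 20, 500, 100))
  div <- detect_divisions(tr)
  lys <- detect_pi_entry(tr)
  rec <- segment_lifespan(tr, div, lys)
  expect_equal(rec$arl_h, 15)
  expect_equal(rec$prl_h, 5)
  expect_equal(rec$arl_h + rec$prl_h, rec$lysis_time)
  expect_identical(rec$arl_generations, length(div))

  # censored: PRL is the observed lower bound to the movie end
  tr2 <- lineage_trace(tt, L, pi_au = rep(100, length(tt)))
  rec2 <- segment_lifespan(tr2, div, detect_pi_entry(tr2))
  expect_true(rec2$censored)
  expect_equal(rec2$prl_h, 25 - 15)
  expect_error(segment_lifespan(tr, div, list(time = -1, censored = FALSE)),
               "before the first frame")
})

test_that("phenotype rules fire in the specified order", {
  n <- 601
  dt <- 0.05
  tt <- seq(0, by = dt, length.out = n)
  base_len <- 2.5 * 2^((tt %% 0.5) / 0.5)
  mk <- function(len, gfp) {
    lineage_trace(tt, len, gfp_au = gfp,
                  pi_au = ifelse(tt >= 28, 600, 100))
  }
  arl_end <- 20
  len <- ifelse(tt < arl_end, base_len, 2.5)
  gfp_flat <- rep(1000, n)

  # filament: length grows past 3x the cohort mean in the terminal segment
  len_fil <- ifelse(tt < arl_end, base_len,
                    pmin(2.5 * exp(0.9 * (tt - arl_end)), 14))
  tr_ii <- mk(len_fil, gfp_flat)
  rec <- segment_lifespan(tr_ii, detect_divisions(tr_ii),
                          detect_pi_entry(tr_ii))
  expect_identical(classify_phenotype(tr_ii, rec, mean_length = 3.6), "II")

  # sudden chromosome loss at the last division -> Ia
  gfp_ia <- ifelse(tt >= arl_end, 50, 1000)
  tr_ia <- mk(len, gfp_ia)
  rec_ia <- segment_lifespan(tr_ia, detect_divisions(tr_ia),
                             detect_pi_entry(tr_ia))
  expect_identical(classify_phenotype(tr_ia, rec_ia, mean_length = 3.6), "Ia")

  # retained chromosome decaying during PRL -> Ib
  gfp_ib <- ifelse(tt >= arl_end, 1000 * 2^(-(tt - arl_end) / 2), 1000)
  tr_ib <- mk(len, gfp_ib)
  rec_ib <- segment_lifespan(tr_ib, detect_divisions(tr_ib),
                             detect_pi_entry(tr_ib))
  expect_identical(classify_phenotype(tr_ib, rec_ib, mean_length = 3.6), "Ib")

  # chromosome-label loss long before the final cycle -> excluded, even if
  # the cell later looks like Ia
  gfp_ex <- ifelse(tt >= 5, 50, 1000)
  tr_ex <- mk(len, gfp_ex)
  rec_ex <- segment_lifespan(tr_ex, detect_divisions(tr_ex),
                             detect_pi_entry(tr_ex))
  expect_identical(classify_phenotype(tr_ex, rec_ex, mean_length = 3.6),
                   "excluded")

  # no chromosome channel: only filamentation is resolvable
  tr_nogfp <- lineage_trace(tt, len, pi_au = ifelse(tt >= 28, 600, 100))
  rec_ng <- segment_lifespan(tr_nogfp, detect_divisions(tr_nogfp),
                             detect_pi_entry(tr_nogfp))
  expect_identical(classify_phenotype(tr_nogfp, rec_ng, mean_length = 3.6),
                   "I-unresolved")

  # classification is deterministic
  expect_identical(classify_phenotype(tr_ia, rec_ia, mean_length = 3.6),
                   classify_phenotype(tr_ia, rec_ia, mean_length = 3.6))
})

test_that("raising the filament threshold never increases the II fraction", {
  cfg <- lineage_sim_config()
  co <- simulate_cohort(cfg, 60, seed = 61)
  counts <- vapply(c(3, 4, 5, 8), function(ff) {
    res <- analyze_cohort(co$traces, filament_factor = ff)
    sum(res$records$phenotype == "II")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("aRL + PRL equals the lysis time for uncensored cells", {
  cfg <- lineage_sim_config()
  co <- simulate_cohort(cfg, 30, seed = 62)
  res <- analyze_cohort(co$traces)
  unc <- res$records[!res$records$censored, ]
  expect_equal(unc$arl_h + unc$prl_h, unc$lysis_time)
})

test_that("phenotype fractions sum to one over non-excluded records", {
  rec <- data.frame(
    cell_id = sprintf("c%d", 1:6), strain = "wt", medium = "LB",
    phenotype = c("II", "II", "II", "excluded", "II", "II"),
    stringsAsFactors = FALSE
  )
  fr <- phenotype_fractions(rec)
  expect_equal(fr$frac_II, 1)
  expect_equal(fr$frac_Ia + fr$frac_Ib + fr$frac_II, 1)
  expect_identical(fr$n_excluded, 1L)

  only_excl <- data.frame(cell_id = "c1", strain = "wt", medium = "M9G",
                          phenotype = "excluded", stringsAsFactors = FALSE)
  fr2 <- phenotype_fractions(only_excl)
  expect_true(is.na(fr2$frac_Ia))
  expect_identical(fr2$n_excluded, 1L)
})
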