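#' Configuration for the single-cell lineage simulator
#'
#' Defines the study conditions emulated by the synthetic mother-machine
#' generator: exponential per-cycle elongation with division resets at a
#' medium-dependent mean doubling time, a Gompertz-distributed replicative
#' lifespan, a truncated-normal post-replicative lifespan ending in a
#' viability-dye step, and one of three death phenotypes per cell (Ia: sudden
#' chromosome-signal loss at the last division; Ib: chromosome signal retained,
#' decaying gradually; II: filamentation in the final cycle).
#'
#' Defaults describe a fast-growth (LB-like) condition: 0.5 h mean doubling
#' time, frames every 3 min. Doubling times of roughly 31 and 100 min emulate
#' the moderate (M9CG) and poor (M9G) media.
#'
#' @param mean_doubling_time Mean doubling time (h).
#' @param elongation_noise_sd SD of the multiplicative lognormal noise on the
#'   per-cycle elongation rate (dimensionless fraction).
#' @param birth_length_mean Birth length (um).
#' @param division_ratio Fraction of length retained by the tracked (mother)
#'   cell at division, in (0, 1).
#' @param sampling_interval Frame interval (h); must not exceed
#'   `mean_doubling_time / 3` or division events become unresolvable.
#' @param gompertz_a,gompertz_b Initial hazard and aging rate (1/h) of the
#'   Gompertz law generating replicative lifespans.
#' @param prl_duration_mean,prl_duration_sd Mean and SD (h) of the
#'   truncated-normal (non-negative) post-replicative lifespan.
#' @param phenotype_probs Probabilities of phenotypes Ia, Ib, II; must sum to 1.
#' @param filament_factor Target excess-length factor (relative to the cell's
#'   running mean length) reached by filamenting phenotype II cells; must
#'   exceed 3, the conventional filamentation threshold.
#' @param gfp_baseline,pi_baseline Baseline fluorescence levels (a.u.).
#' @param signal_noise_sd Additive Gaussian noise SD on both channels (a.u.).
#' @param gfp_decay_halflife Half-life (h) of the gradual chromosome-signal
#'   decay during the post-replicative phase of phenotype Ib cells.
#' @param movie_length Movie duration (h); cells still alive at the end are
#'   right-censored.
#' @param seed Default integer seed used by [simulate_lineage()] when no seed
#'   is passed explicitly.
#' @return A validated list of class `lineage_sim_config`.
#' @export
lineage_sim_config <- function(mean_doubling_time = 0.5,
                               elongation_noise_sd = 0.05,
                               birth_length_mean = 2.5,
                               division_ratio = 0.5,
                               sampling_interval = 0.05,
                               gompertz_a = 0.01,
                               gompertz_b = 0.1,
                               prl_duration_mean = 8,
                               prl_duration_sd = 3,
                               phenotype_probs = c(Ia = 0.4, Ib = 0.3, II = 0.3),
                               filament_factor = 3.5,
                               gfp_baseline = 1000,
                               pi_baseline = 100,
                               signal_noise_sd = 10,
                               gfp_decay_halflife = 2,
                               movie_length = 72,
                               seed = 1L) {
  cfg <- list(
    mean_doubling_time = mean_doubling_time,
    elongation_noise_sd = elongation_noise_sd,
    birth_length_mean = birth_length_mean,
    division_ratio = division_ratio,
    sampling_interval = sampling_interval,
    gompertz_a = gompertz_a, gompertz_b = gompertz_b,
    prl_duration_mean = prl_duration_mean, prl_duration_sd = prl_duration_sd,
    phenotype_probs = phenotype_probs, filament_factor = filament_factor,
    gfp_baseline = gfp_baseline, pi_baseline = pi_baseline,
    signal_noise_sd = signal_noise_sd,
    gfp_decay_halflife = gfp_decay_halflife,
    movie_length = movie_length, seed = as.integer(seed)
  )
  pos <- c("mean_doubling_time", "birth_length_mean", "sampling_interval",
           "gompertz_a", "prl_duration_mean", "prl_duration_sd",
           "gfp_baseline", "pi_baseline", "gfp_decay_halflife", "movie_length")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("`%s` must be strictly positive", nm), call. = FALSE)
    }
  }
  for (nm in c("elongation_noise_sd", "gompertz_b", "signal_noise_sd")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  if (length(phenotype_probs) != 3L || any(phenotype_probs < 0) ||
      abs(sum(phenotype_probs) - 1) > 1e-9) {
    stop("`phenotype_probs` must be three non-negative values summing to 1",
         call. = FALSE)
  }
  names(cfg$phenotype_probs) <- c("Ia", "Ib", "II")
  if (division_ratio <= 0 || division_ratio >= 1) {
    stop("`division_ratio` must lie in (0, 1)", call. = FALSE)
  }
  if (sampling_interval > mean_doubling_time / 3) {
    stop("`sampling_interval` must be <= mean_doubling_time / 3; ",
         "division events would be unresolvable", call. = FALSE)
  }
  if (filament_factor <= 3) {
    stop("`filament_factor` must exceed 3 (the filamentation threshold)",
         call. = FALSE)
  }
  structure(cfg, class = "lineage_sim_config")
}

#' Simulate one mother-machine lineage with ground truth
#'
#' Generates a [lineage_trace()] and its `lineage_truth`: length grows
#' exponentially within each cycle at rate `ln(2)/doubling_time` times
#' lognormal noise (unit mean); at each division the length is multiplied by
#' `division_ratio`; once the sampled Gompertz lifespan is exhausted the cell
#' stops dividing (the realized apparent replicative lifespan ends at the last
#' division) and enters its post-replicative phase, which ends with a step in
#' the viability-dye channel at lysis. The planted phenotype drives the
#' chromosome channel: Ia drops to near zero in a single frame at the last
#' division, Ib decays exponentially during the post-replicative phase, II
#' elongates without dividing until its length exceeds
#' `filament_factor` times its running mean length. Lineages whose lysis falls
#' beyond `movie_length` are truncated and flagged censored.
#'
#' @param config A [lineage_sim_config()].
#' @param seed Integer seed (defaults to `config$seed`); runs are
#'   bit-reproducible given the seed.
#' @param cell_id,strain,medium Metadata labels attached to the trace.
#' @param phenotype Optional forced phenotype (`"Ia"`, `"Ib"` or `"II"`);
#'   by default drawn from `config$phenotype_probs`.
#' @return A list with elements `trace` ([lineage_trace()]) and `truth`, a
#'   `lineage_truth` list carrying `lifespan` (aRL, h), `n_generations`,
#'   `phenotype`, `prl_duration`, `lysis_time`, `division_times`,
#'   `per_cycle_eer` and `censored`. Internally consistent:
#'   `lysis_time == lifespan + prl_duration` and `n_generations` equals the
#'   number of completed divisions.
#' @export
simulate_lineage <- function(config, seed = config$seed, cell_id = "cell",
                             strain = "wt", medium = "LB", phenotype = NULL) {
  stopifnot(inherits(config, "lineage_sim_config"))
  if (config$movie_length < config$sampling_interval) {
    stop("movie shorter than one sampling interval", call. = FALSE)
  }
  set.seed(as.integer(seed))
  phen <- if (is.null(phenotype)) {
    sample(c("Ia", "Ib", "II"), 1L, prob = config$phenotype_probs)
  } else {
    match.arg(phenotype, c("Ia", "Ib", "II"))
  }

  alpha0 <- log(2) / config$mean_doubling_time
  log_growth <- -log(config$division_ratio)  # ln-length gained per cycle
  sdl <- config$elongation_noise_sd

  ## replicative phase: draw a target aRL, then fill it with cycles whose
  ## durations follow from the noisy elongation rate. The lineage is
  ## conditioned on completing at least one division (a trapped mother is by
  ## construction observed dividing), by redrawing the target when needed.
  repeat {
    arl_target <- .rgompertz_wait(1L, config$gompertz_a, config$gompertz_b)
    eers <- numeric(0)
    div_times <- numeric(0)
    t_now <- 0
    repeat {
      eer <- if (sdl > 0) {
        alpha0 * stats::rlnorm(1L, meanlog = -sdl^2 / 2, sdlog = sdl)
      } else {
        alpha0
      }
      dur <- log_growth / eer
      if (t_now + dur > arl_target) break
      t_now <- t_now + dur
      div_times <- c(div_times, t_now)
      eers <- c(eers, eer)
    }
    if (length(div_times) >= 1L) break
  }
  arl <- div_times[length(div_times)]
  n_gen <- length(div_times)

  prl <- max(0, stats::rnorm(1L, config$prl_duration_mean, config$prl_duration_sd))

  ## II cells must have time to filament: growth at a reduced rate until the
  ## excess-length target, then plateau until lysis.
  filament_rate <- 0.7 * alpha0
  if (phen == "II") {
    # running mean length over the replicative phase; computed analytically
    # below once frame lengths exist, approximated here by the cycle mean
    approx_mean_len <- config$birth_length_mean *
      (exp(log_growth) - 1) / log_growth
    target_len <- 1.3 * config$filament_factor * approx_mean_len
    t_reach <- log(target_len / config$birth_length_mean) / filament_rate
    prl <- max(prl, t_reach + 2 * config$sampling_interval)
  }
  lysis <- arl + prl
  censored <- lysis > config$movie_length

  end_t <- min(config$movie_length, lysis + 1)
  times <- seq(0, end_t, by = config$sampling_interval)
  nf <- length(times)

  ## piecewise-exponential length profile
  starts <- c(0, div_times)
  cyc <- findInterval(times, starts, rightmost.closed = FALSE)  # >=1
  len <- numeric(nf)
  in_arl <- cyc <= n_gen
  if (any(in_arl)) {
    k <- cyc[in_arl]
    len[in_arl] <- config$birth_length_mean *
      exp(eers[k] * (times[in_arl] - starts[k]))
  }
  term <- which(!in_arl)  # frames at/after the last division
  if (length(term)) {
    dt_term <- times[term] - arl
    if (phen == "II") {
      mean_len_arl <- if (any(in_arl)) mean(len[in_arl]) else config$birth_length_mean
      target_len <- 1.3 * config$filament_factor * mean_len_arl
      grown <- config$birth_length_mean * exp(filament_rate * dt_term)
      len[term] <- pmin(grown, target_len)
    } else {
      len[term] <- config$birth_length_mean
    }
  }

  ## fluorescence channels
  noise <- function() if (config$signal_noise_sd > 0) {
    stats::rnorm(nf, 0, config$signal_noise_sd)
  } else rep(0, nf)
  gfp <- rep(config$gfp_baseline, nf)
  if (phen == "Ia") {
    gfp[times >= arl] <- 0.05 * config$gfp_baseline
  } else if (phen == "Ib") {
    post <- times >= arl
    gfp[post] <- config$gfp_baseline *
      2^(-(times[post] - arl) / config$gfp_decay_halflife)
  }
  gfp <- gfp + noise()
  pi_ch <- rep(config$pi_baseline, nf)
  pi_ch[times >= lysis] <- config$pi_baseline + 0.5 * config$gfp_baseline
  pi_ch <- pi_ch + noise()
  width <- rep(1, nf)
  if (config$signal_noise_sd > 0) width <- width + stats::rnorm(nf, 0, 0.02)

  trace <- lineage_trace(
    time_h = times, length_um = len, width_um = pmax(width, 0.5),
    gfp_au = gfp, pi_au = pi_ch,
    cell_id = cell_id, strain = strain, medium = medium
  )
  truth <- structure(
    list(
      cell_id = as.character(cell_id), lifespan = arl, n_generations = n_gen,
      phenotype = phen, prl_duration = prl, lysis_time = lysis,
      division_times = div_times, per_cycle_eer = eers, censored = censored
    ),
    class = "lineage_truth"
  )
  list(trace = trace, truth = truth)
}

#' Simulate a cohort of independent lineages
#'
#' Runs [simulate_lineage()] for `n_cells` cells with per-cell seeds derived
#' deterministically from `seed`. Empirical phenotype fractions converge to
#' `config$phenotype_probs` as the cohort grows.
#'
#' @inheritParams simulate_lineage
#' @param n_cells Number of cells (>= 1).
#' @param seed Master integer seed.
#' @return A list with `traces` (list of [lineage_trace()]) and `truths`
#'   (list of `lineage_truth`).
#' @export
simulate_cohort <- function(config, n_cells, seed = config$seed,
                            strain = "wt", medium = "LB") {
  stopifnot(inherits(config, "lineage_sim_config"))
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells < 1) {
    stop("`n_cells` must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n_cells)
  ids <- sprintf("cell_%05d", seq_len(n_cells))
  out <- lapply(seq_len(n_cells), function(i) {
    simulate_lineage(config, seed = seeds[i], cell_id = ids[i],
                     strain = strain, medium = medium)
  })
  list(
    traces = lapply(out, `[[`, "trace"),
    truths = lapply(out, `[[`, "truth")
  )
}

#' Flatten ground-truth records to a table
#'
#' @param truths List of `lineage_truth` objects from [simulate_cohort()].
#' @return A data frame with one row per cell (list-valued fields
#'   `division_times` and `per_cycle_eer` are dropped).
#' @export
truth_table <- function(truths) {
  do.call(rbind, lapply(truths, function(tr) {
    data.frame(
      cell_id = tr$cell_id, lifespan = tr$lifespan,
      n_generations = tr$n_generations, phenotype = tr$phenotype,
      prl_duration = tr$prl_duration, lysis_time = tr$lysis_time,
      censored = tr$censored, stringsAsFactors = FALSE
    )
  }))
}

#' Simulate a population growth curve
#'
#' Logistic growth delayed by a lag phase, with additive Gaussian measurement
#' noise floored at a small positive optical density:
#' \eqn{N(t) = K N_0 / (N_0 + (K - N_0) e^{-r (t - lag)})} for `t > lag`,
#' `N_0` before.
#'
#' @param r Maximum specific growth rate (1/h), positive.
#' @param K Carrying capacity (OD600).
#' @param N0 Initial density (OD600), `0 < N0 < K`.
#' @param lag Lag-phase duration (h).
#' @param noise_sd SD of additive Gaussian noise (OD600).
#' @param t_grid Measurement times (h), strictly increasing.
#' @param seed Optional integer seed.
#' @param strain,medium,replicate Metadata labels.
#' @param floor Lower clip applied after adding noise (OD600).
#' @return A [growth_curve()].
#' @export
simulate_growth_curve <- function(r, K, N0, lag = 0, noise_sd = 0,
                                  t_grid = seq(0, 16, by = 1 / 12),
                                  seed = NULL, strain = "wt", medium = "LB",
                                  replicate = "r1", floor = 1e-4) {
  if (!is.finite(r) || r <= 0) stop("`r` must be positive", call. = FALSE)
  if (!is.finite(N0) || !is.finite(K) || N0 <= 0 || N0 >= K) {
    stop("need 0 < N0 < K", call. = FALSE)
  }
  if (any(diff(t_grid) <= 0)) stop("`t_grid` must be increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tt <- pmax(t_grid - lag, 0)
  od <- K * N0 / (N0 + (K - N0) * exp(-r * tt))
  if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  od <- pmax(od, floor)
  growth_curve(times = t_grid, od = od, strain = strain, medium = medium,
               replicate = replicate)
}
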