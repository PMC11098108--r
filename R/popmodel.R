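#' Parameters for the age-structured population model
#'
#' A minimal three-compartment reconstruction of culture-level growth from
#' single-cell fates: proliferating cells divide at rate `r`; each cell
#' transitions to the post-replicative compartment at the age-dependent
#' Gompertz hazard \eqn{a e^{b \cdot age}}; post-replicative cells lyse at
#' rate `lysis_rate`. Under the `"lineage"` age clock a division leaves the
#' aged mother's clock running and starts the daughter at age zero (the
#' mother-machine mother-cell reading); under the `"cell"` clock both
#' post-division cells inherit the mother's age.
#'
#' @param r Division rate (1/h), positive.
#' @param arrest_a Initial arrest hazard (1/h), non-negative (0 disables
#'   arrest).
#' @param arrest_b Aging rate of the arrest hazard (1/h), non-negative.
#' @param lysis_rate Lysis rate of post-replicative cells (1/h),
#'   non-negative.
#' @param initial_n Starting number of proliferating cells, >= 1.
#' @param t_max Simulated horizon (h).
#' @param max_cells Cap on the number of simulated cells.
#' @param age_clock `"lineage"` or `"cell"` (see above).
#' @param subsample If `TRUE`, daughters born beyond `max_cells` are dropped
#'   (uniformly over births) and counted; if `FALSE`, exceeding the cap is an
#'   error.
#' @param record_dt Grid spacing (h) of the recorded trajectory.
#' @param seed Integer seed.
#' @return Validated list of class `population_model_params`.
#' @export
population_model_params <- function(r, arrest_a, arrest_b, lysis_rate,
                                    initial_n = 1L, t_max = 10,
                                    max_cells = 1e5,
                                    age_clock = c("lineage", "cell"),
                                    subsample = FALSE, record_dt = 0.1,
                                    seed = 1L) {
  age_clock <- match.arg(age_clock)
  if (!is.finite(r) || r < 0) stop("`r` must be >= 0", call. = FALSE)
  for (v in c(arrest_a = arrest_a, arrest_b = arrest_b,
              lysis_rate = lysis_rate)) {
    if (!is.finite(v) || v < 0) {
      stop("rates must be finite and non-negative", call. = FALSE)
    }
  }
  if (initial_n < 1L) stop("`initial_n` must be >= 1", call. = FALSE)
  if (t_max <= 0 || record_dt <= 0) {
    stop("`t_max` and `record_dt` must be positive", call. = FALSE)
  }
  structure(
    list(r = r, arrest_a = arrest_a, arrest_b = arrest_b,
         lysis_rate = lysis_rate, initial_n = as.integer(initial_n),
         t_max = t_max, max_cells = max_cells, age_clock = age_clock,
         subsample = isTRUE(subsample), record_dt = record_dt,
         seed = as.integer(seed)),
    class = "population_model_params"
  )
}

#' Simulate the age-structured population model
#'
#' Stochastic agent simulation with exact event times: per-cell exponential
#' waiting times for division and lysis, and exact inverse-CDF draws of the
#' residual Gompertz waiting time to replicative arrest given the cell's
#' current age. Cells are processed depth-first from a stack, so runtime is
#' linear in the number of events; trajectories are seed-reproducible.
#'
#' @param params A [population_model_params()].
#' @return Object of class `population_trajectory`: data frame on the
#'   recording grid with columns `time`, `n_proliferating`,
#'   `n_postreplicative`, `n_lysed`, `total_viable`, `cum_births`,
#'   `cum_arrests`, `cum_lyses`. Attributes carry the event times
#'   (`birth_times`, `arrest_times`, `lysis_times`), `initial_n`,
#'   `n_dropped` (daughters discarded under subsampling) and the parameters.
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "population_model_params"))
  set.seed(params$seed)
  r <- params$r
  a <- params$arrest_a
  b <- params$arrest_b
  mu <- params$lysis_rate
  t_max <- params$t_max
  lineage_clock <- params$age_clock == "lineage"

  cap <- 4096L
  births <- arrests <- lyses <- numeric(cap)
  nb <- na <- nl <- 0L
  grow <- function(v, need) {
    if (need > length(v)) c(v, numeric(length(v))) else v
  }

  ## stack of unprocessed cells (birth time, age at birth)
  st_t <- numeric(1024L)
  st_a <- numeric(1024L)
  sp <- params$initial_n
  if (sp > length(st_t)) {
    st_t <- numeric(sp * 2L); st_a <- numeric(sp * 2L)
  }
  st_t[seq_len(sp)] <- 0
  st_a[seq_len(sp)] <- 0
  n_created <- params$initial_n
  n_dropped <- 0L
  if (n_created > params$max_cells) {
    stop("`initial_n` exceeds `max_cells`", call. = FALSE)
  }

  while (sp > 0L) {
    t_now <- st_t[sp]
    age <- st_a[sp]
    sp <- sp - 1L
    repeat {
      w_div <- if (r > 0) stats::rexp(1L, r) else Inf
      w_arr <- .rgompertz_wait(1L, a, b, age)
      w <- min(w_div, w_arr)
      if (!is.finite(w) || t_now + w > t_max) break  # survives proliferating
      t_now <- t_now + w
      age <- age + w
      if (w_div <= w_arr) {
        if (n_created >= params$max_cells) {
          if (!params$subsample) {
            stop("population exceeded `max_cells`; enable `subsample` ",
                 "or raise the cap", call. = FALSE)
          }
          n_dropped <- n_dropped + 1L
        } else {
          n_created <- n_created + 1L
          nb <- nb + 1L
          births <- grow(births, nb)
          births[nb] <- t_now
          if (sp + 1L > length(st_t)) {
            st_t <- c(st_t, numeric(length(st_t)))
            st_a <- c(st_a, numeric(length(st_a)))
          }
          sp <- sp + 1L
          st_t[sp] <- t_now
          st_a[sp] <- if (lineage_clock) 0 else age
          ## mother continues with her age (lineage clock) or, under the
          ## cell clock, both post-division cells inherit the age: the
          ## continuing branch keeps `age` in either case
        }
      } else {
        na <- na + 1L
        arrests <- grow(arrests, na)
        arrests[na] <- t_now
        w_lys <- if (mu > 0) stats::rexp(1L, mu) else Inf
        if (is.finite(w_lys) && t_now + w_lys <= t_max) {
          nl <- nl + 1L
          lyses <- grow(lyses, nl)
          lyses[nl] <- t_now + w_lys
        }
        break
      }
    }
  }

  births <- sort(births[seq_len(nb)])
  arrests <- sort(arrests[seq_len(na)])
  lyses <- sort(lyses[seq_len(nl)])

  grid <- seq(0, t_max, by = params$record_dt)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  cb <- findInterval(grid, births)
  ca <- findInterval(grid, arrests)
  cl <- findInterval(grid, lyses)
  n_prolif <- params$initial_n + cb - ca
  n_post <- ca - cl
  traj <- data.frame(
    time = grid, n_proliferating = n_prolif, n_postreplicative = n_post,
    n_lysed = cl, total_viable = n_prolif + n_post,
    cum_births = cb, cum_arrests = ca, cum_lyses = cl
  )
  attr(traj, "birth_times") <- births
  attr(traj, "arrest_times") <- arrests
  attr(traj, "lysis_times") <- lyses
  attr(traj, "initial_n") <- params$initial_n
  attr(traj, "n_dropped") <- n_dropped
  attr(traj, "params") <- params
  class(traj) <- c("population_trajectory", "data.frame")
  traj
}

#' Apparent culture-level growth curve of a simulated population
#'
#' The log viable count \eqn{\ln(viable(t)/initial)}: what a plate reader
#' would see of the simulated culture. Returned as a [growth_curve()] (counts
#' standing in for optical density) so it can be fed directly to
#' [extract_growth_params()]; the log series is attached as the `log_ratio`
#' attribute. If the population goes extinct the series is truncated at the
#' last positive count and flagged.
#'
#' @param traj A [simulate_population()] trajectory.
#' @return A [growth_curve()] with attributes `log_ratio`, `extinct` and
#'   `extinction_time` (`NA` when the population persists).
#' @export
apparent_growth_curve <- function(traj) {
  stopifnot(inherits(traj, "population_trajectory"))
  init <- attr(traj, "initial_n")
  if (init <= 0) stop("trajectory has no initial cells", call. = FALSE)
  v <- traj$total_viable
  ext_idx <- which(v == 0L)
  extinct <- length(ext_idx) > 0L
  keep <- if (extinct) seq_len(ext_idx[1L] - 1L) else seq_along(v)
  if (length(keep) < 2L) stop("population extinct within one recording step",
                              call. = FALSE)
  gc <- growth_curve(times = traj$time[keep], od = v[keep],
                     strain = "model", medium = "model", replicate = "sim")
  attr(gc, "log_ratio") <- log(v[keep] / init)
  attr(gc, "extinct") <- extinct
  attr(gc, "extinction_time") <- if (extinct) traj$time[ext_idx[1L]] else NA_real_
  gc
}

#' Extinction fraction as a function of the aging rate
#'
#' Runs `n_replicates` populations per value of the aging rate `b` and
#' reports the fraction extinct (no viable cells) by `t_max`. Monotone
#' non-decreasing in `b` up to Monte-Carlo error: the faster the arrest
#' hazard accumulates, the likelier the culture collapses.
#'
#' @param params A [population_model_params()]; its `arrest_b` is overridden
#'   by each grid value.
#' @param b_grid Non-negative aging rates (1/h) to probe.
#' @param n_replicates Populations per grid value.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @return Data frame with `b`, `extinction_fraction`, `n_replicates`.
#' @export
extinction_probe <- function(params, b_grid, n_replicates = 50L, seed = 1L) {
  stopifnot(inherits(params, "population_model_params"))
  if (!length(b_grid)) stop("`b_grid` must be non-empty", call. = FALSE)
  if (any(b_grid < 0)) stop("`b_grid` must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max, length(b_grid) * n_replicates),
                  nrow = length(b_grid))
  frac <- vapply(seq_along(b_grid), function(i) {
    ext <- vapply(seq_len(n_replicates), function(j) {
      p <- params
      p$arrest_b <- b_grid[i]
      p$seed <- seeds[i, j]
      traj <- simulate_population(p)
      traj$total_viable[nrow(traj)] == 0L
    }, logical(1))
    mean(ext)
  }, numeric(1))
  data.frame(b = b_grid, extinction_fraction = frac,
             n_replicates = n_replicates)
}
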