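# fixtures built in code; no data files

ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

# brute-force product-limit oracle: explicit loop over distinct death times,
# counting the risk set from scratch each time
km_brute <- function(time, status) {
  dt <- sort(unique(time[status == 1L]))
  s <- numeric(length(dt))
  cur <- 1
  for (i in seq_along(dt)) {
    ni <- sum(time >= dt[i])
    di <- sum(time == dt[i] & status == 1L)
    cur <- cur * (1 - di / ni)
    s[i] <- cur
  }
  data.frame(time = dt, survival = s)
}

# random small event table with ties and optional censoring
random_event_table <- function(n, censor = TRUE) {
  time <- sample(c(1:8, round(runif(4, 0.5, 12), 2)), n, replace = TRUE)
  status <- if (censor) rbinom(n, 1L, 0.7) else rep(1L, n)
  if (!any(status == 1L)) status[sample.int(n, 1L)] <- 1L
  event_table(time, status)
}

# exact sawtooth lineage: `n_cyc` cycles of `frames_per` frames, doubling then
# halving; divisions land exactly on frame boundaries
sawtooth_trace <- function(n_cyc = 3, frames_per = 10, dt = 0.05, L0 = 2.5,
                           tail_frames = 0L, cell_id = "saw") {
  n <- n_cyc * frames_per + 1L
  tt <- seq(0, by = dt, length.out = n + tail_frames)
  phase <- (seq_len(n) - 1L) %% frames_per
  L <- c(L0 * 2^(phase / frames_per), rep(L0, tail_frames))
  lineage_trace(tt, L, cell_id = cell_id)
}

# hand-built cycle table: `n_cyc` complete cycles per cell, constant BL/EER/DR
# with an optional birth-length boost in the last cycle
planted_cycles <- function(n_cells = 40, n_cyc = 12, bl = 2.5, eer = 1.386,
                           dur = 0.5, last_bl_factor = 1) {
  rows <- lapply(seq_len(n_cells), function(i) {
    k <- seq_len(n_cyc)
    data.frame(
      cell_id = sprintf("c%03d", i), strain = "wt", medium = "LB",
      cycle_index = k, segment = "complete",
      birth_time = (k - 1) * dur, division_time = k * dur,
      birth_length = ifelse(k == n_cyc, bl * last_bl_factor, bl),
      final_length = 2 * bl, duration = dur, eer = eer, dr = 1 / dur,
      mean_width = 1, n_frames = 10L, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cell_cycles", "data.frame")
  out
}

noiseless_config <- function(...) {
  lineage_sim_config(elongation_noise_sd = 0, signal_noise_sd = 0, ...)
}
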