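#' Detect division events in a length trace
#'
#' A division is any frame-to-frame relative length decrease of at least
#' `drop_fraction`. With symmetric division a cell loses about half its length
#' in one frame, while elongation between frames is small, so the default
#' threshold of 0.25 separates the two cleanly.
#'
#' @param trace A [lineage_trace()].
#' @param drop_fraction Minimum relative single-frame length drop, in (0, 1).
#' @return Strictly increasing integer vector of post-division frame indices
#'   (possibly empty).
#' @export
detect_divisions <- function(trace, drop_fraction = 0.25) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (length(trace$time_h) < 2L) {
    stop("need at least two frames", call. = FALSE)
  }
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop("`drop_fraction` must lie in (0, 1)", call. = FALSE)
  }
  L <- trace$length_um
  rel_drop <- 1 - L[-1] / L[-length(L)]
  which(rel_drop >= drop_fraction) + 1L
}

#' Extract cell cycles from a lineage trace
#'
#' Splits a trace at its division events into birth-to-division intervals and
#' computes per cycle: birth length (BL, the first length of the cycle), the
#' exponential elongation rate (EER, least-squares slope of ln(length) vs time
#' over the cycle's frames) and the doubling rate (DR, the inverse of the
#' cycle duration). The segment before the first detected division is flagged
#' `"partial_first"` (the cell's age at trap entry is unknowable) and the
#' non-dividing segment after the last division is retained as `"terminal"`;
#' only `"complete"` cycles should enter population statistics. Segments with
#' fewer than `min_frames` frames are dropped and counted in the `n_dropped`
#' attribute.
#'
#' @param trace A [lineage_trace()].
#' @param divisions Post-division frame indices from [detect_divisions()].
#' @param min_frames Minimum frames per retained segment.
#' @return Data frame (class `cell_cycles`) with columns `cell_id`, `strain`,
#'   `medium`, `cycle_index`, `segment`, `birth_time`, `division_time`,
#'   `birth_length`, `final_length`, `duration`, `eer`, `dr`, `mean_width`,
#'   `n_frames`; attribute `n_dropped`. Empty (with a warning) if the trace
#'   has no divisions and no growing terminal segment.
#' @export
extract_cycles <- function(trace, divisions, min_frames = 4L) {
  stopifnot(inherits(trace, "lineage_trace"))
  tt <- trace$time_h
  L <- trace$length_um
  n <- length(tt)
  divisions <- as.integer(divisions)
  if (any(divisions < 2L | divisions > n) || is.unsorted(divisions, strictly = TRUE)) {
    stop("`divisions` must be strictly increasing frame indices in the trace",
         call. = FALSE)
  }

  ## segment boundaries: starts of segments and the division index closing them
  starts <- c(1L, divisions)
  closes <- c(divisions, NA_integer_)  # NA: terminal segment, no closing division
  seg_type <- c(
    if (length(divisions) > 0L) "partial_first" else "terminal",
    if (length(divisions) > 1L) rep("complete", length(divisions) - 1L),
    if (length(divisions) > 0L) "terminal"
  )

  n_dropped <- 0L
  rows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    e <- if (is.na(closes[k])) n else closes[k] - 1L  # frames within the cycle
    nf <- e - s + 1L
    if (nf < min_frames) {
      n_dropped <- n_dropped + 1L
      next
    }
    idx <- s:e
    div_t <- if (is.na(closes[k])) NA_real_ else tt[closes[k]]
    dur <- if (is.na(div_t)) NA_real_ else div_t - tt[s]
    rows[[k]] <- data.frame(
      cell_id = trace$cell_id, strain = trace$strain, medium = trace$medium,
      cycle_index = k, segment = seg_type[k],
      birth_time = tt[s], division_time = div_t,
      birth_length = L[s], final_length = L[e],
      duration = dur,
      eer = .ls_slope(tt[idx], log(L[idx])),
      dr = if (is.na(dur)) NA_real_ else 1 / dur,
      mean_width = if (is.null(trace$width_um)) NA_real_ else mean(trace$width_um[idx]),
      n_frames = nf, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(
      cell_id = character(0), strain = character(0), medium = character(0),
      cycle_index = integer(0), segment = character(0),
      birth_time = numeric(0), division_time = numeric(0),
      birth_length = numeric(0), final_length = numeric(0),
      duration = numeric(0), eer = numeric(0), dr = numeric(0),
      mean_width = numeric(0), n_frames = integer(0), stringsAsFactors = FALSE
    )
  }
  if (length(divisions) == 0L &&
      (nrow(out) == 0L || all(out$eer <= 0))) {
    warning("trace has no divisions and no growing terminal segment",
            call. = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("cell_cycles", class(out))
  out
}

#' Extract cycles for a whole cohort
#'
#' Convenience wrapper running [detect_divisions()] and [extract_cycles()] on
#' each trace and row-binding the results.
#'
#' @param traces List of [lineage_trace()] objects.
#' @inheritParams detect_divisions
#' @inheritParams extract_cycles
#' @return Combined `cell_cycles` data frame.
#' @export
cohort_cycles <- function(traces, drop_fraction = 0.25, min_frames = 4L) {
  out <- lapply(traces, function(tr) {
    extract_cycles(tr, detect_divisions(tr, drop_fraction), min_frames)
  })
  res <- do.call(rbind, out)
  attr(res, "n_dropped") <- sum(vapply(out, attr, integer(1), "n_dropped"))
  class(res) <- c("cell_cycles", "data.frame")
  res
}

#' Align cell cycles to the last replicative cycle
#'
#' Cells enter the traps at unknown ages, so per-generation statistics are
#' aligned to the end of replicative life: generation 0 is each cell's last
#' complete cycle with elongation rate above `eps_growth`, earlier cycles are
#' indexed -1, -2, ... . Returns per-index aggregates (mean, SD, n) of birth
#' length, elongation rate and doubling rate, together with a reference mean
#' computed over all generations except the last three (indices <= -3), the
#' baseline against which end-of-life deviations are judged.
#'
#' @param cycles A `cell_cycles` data frame covering one or more cells; only
#'   `"complete"` segments are used.
#' @param eps_growth Minimum elongation rate (1/h) counting as growth.
#' @return A list with `aligned` (the complete cycles plus a
#'   `generation_index` column), `summary` (per-index mean/SD/n for
#'   `birth_length`, `eer`, `dr`), `reference` (named means over indices
#'   <= -3) and `n_excluded_cells` (cells with no growing cycle).
#' @export
align_to_last_replicative <- function(cycles, eps_growth = 0.01) {
  stopifnot(is.data.frame(cycles))
  if (eps_growth < 0) stop("`eps_growth` must be >= 0", call. = FALSE)
  cc <- cycles[cycles$segment == "complete", , drop = FALSE]
  n_excluded <- 0L
  parts <- list()
  for (id in unique(cc$cell_id)) {
    ci <- cc[cc$cell_id == id, , drop = FALSE]
    ci <- ci[order(ci$birth_time), , drop = FALSE]
    grow <- which(ci$eer > eps_growth)
    if (!length(grow)) {
      n_excluded <- n_excluded + 1L
      next
    }
    last <- grow[length(grow)]
    ci <- ci[seq_len(last), , drop = FALSE]
    ci$generation_index <- seq_len(last) - last
    parts[[id]] <- ci
  }
  aligned <- do.call(rbind, parts)
  if (is.null(aligned)) {
    stop("no cell has a cycle with elongation rate above `eps_growth`",
         call. = FALSE)
  }
  rownames(aligned) <- NULL

  stat_cols <- c("birth_length", "eer", "dr")
  idx <- sort(unique(aligned$generation_index), decreasing = TRUE)
  summ <- do.call(rbind, lapply(idx, function(g) {
    sub <- aligned[aligned$generation_index == g, stat_cols, drop = FALSE]
    data.frame(
      generation_index = g, n = nrow(sub),
      t(vapply(sub, mean, numeric(1))),
      setNames(as.data.frame(t(vapply(sub, stats::sd, numeric(1)))),
               paste0(stat_cols, "_sd"))
    )
  }))
  ref_rows <- aligned[aligned$generation_index <= -3L, stat_cols, drop = FALSE]
  reference <- if (nrow(ref_rows)) vapply(ref_rows, mean, numeric(1)) else
    setNames(rep(NA_real_, 3), stat_cols)
  list(aligned = aligned, summary = summ, reference = reference,
       n_excluded_cells = n_excluded)
}

#' Population summary statistics of cycle parameters
#'
#' Mean, SD and coefficient of variation (CV = SD/mean, population SD with the
#' n denominator) of doubling rate, birth length and width, grouped by strain
#' and medium. The CV of the doubling-rate distribution is the dispersion
#' statistic used to compare growth-rate heterogeneity across conditions.
#'
#' @param cycles A `cell_cycles` data frame; only `"complete"` segments enter.
#' @return Data frame with one row per strain x medium x statistic
#'   (`dr`, `birth_length`, `mean_width`) carrying `mean`, `sd`, `cv`, `n`.
#'   `cv` is `NA` where the mean is zero.
#' @export
population_summary <- function(cycles) {
  stopifnot(is.data.frame(cycles))
  cc <- cycles[cycles$segment == "complete", , drop = FALSE]
  if (nrow(cc) < 2L) stop("need at least two complete cycles", call. = FALSE)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  groups <- unique(cc[c("strain", "medium")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- cc[cc$strain == groups$strain[i] & cc$medium == groups$medium[i], ]
    for (col in c("dr", "birth_length", "mean_width")) {
      x <- sub[[col]]
      x <- x[is.finite(x)]
      if (length(x) < 2L) next
      m <- mean(x)
      s <- sd_pop(x)
      out[[length(out) + 1L]] <- data.frame(
        strain = groups$strain[i], medium = groups$medium[i], statistic = col,
        mean = m, sd = s, cv = if (m == 0) NA_real_ else s / m,
        n = length(x), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
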