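#' Run the full single-cell aging pipeline on a cohort
#'
#' For each trace: detect divisions, extract cell cycles, detect
#' viability-dye entry, decompose the lifespan into replicative and
#' post-replicative phases, then classify death phenotypes against the
#' cohort mean cell length of each strain x medium group.
#'
#' @param traces List of [lineage_trace()] objects.
#' @param drop_fraction Division-detection threshold, see [detect_divisions()].
#' @param min_frames Minimum frames per retained cycle, see [extract_cycles()].
#' @param eps_growth Growth threshold (1/h), see [segment_lifespan()].
#' @param k_sigma,sustain_frames,baseline_frames Dye-entry detection settings,
#'   see [detect_pi_entry()].
#' @param filament_factor,gfp_drop_fraction Classification thresholds, see
#'   [classify_phenotype()].
#' @return A list with `cycles` (combined `cell_cycles` data frame),
#'   `records` (classified lifespan table: one row per cell) and
#'   `mean_length` (named per-group cohort means).
#' @export
analyze_cohort <- function(traces, drop_fraction = 0.25, min_frames = 4L,
                           eps_growth = 0.01, k_sigma = 5,
                           sustain_frames = 2L, baseline_frames = 10L,
                           filament_factor = 3, gfp_drop_fraction = 0.5) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  divs <- lapply(traces, detect_divisions, drop_fraction = drop_fraction)
  cycles <- do.call(rbind, lapply(seq_along(traces), function(i) {
    extract_cycles(traces[[i]], divs[[i]], min_frames = min_frames)
  }))
  class(cycles) <- c("cell_cycles", "data.frame")
  records <- do.call(rbind, lapply(seq_along(traces), function(i) {
    lys <- detect_pi_entry(traces[[i]], k_sigma = k_sigma,
                           sustain_frames = sustain_frames,
                           baseline_frames = baseline_frames)
    segment_lifespan(traces[[i]], divs[[i]], lys, eps_growth = eps_growth)
  }))
  mean_len <- cohort_mean_length(traces, records)
  records$phenotype <- vapply(seq_along(traces), function(i) {
    key <- paste(traces[[i]]$strain, traces[[i]]$medium, sep = ".")
    classify_phenotype(traces[[i]], records[i, , drop = FALSE],
                       mean_length = mean_len[[key]],
                       filament_factor = filament_factor,
                       gfp_drop_fraction = gfp_drop_fraction,
                       divisions = divs[[i]])
  }, character(1))
  list(cycles = cycles, records = records, mean_length = mean_len)
}

#' Build a survival event table from lifespan records
#'
#' Converts classified lifespan records into an [event_table()] for survival
#' estimation and Gompertz fitting. The death event can be lysis (dye entry,
#' the whole-lifespan clock) or the end of replication (entry into the
#' post-replicative phase); the clock can run in hours or in completed
#' generations during the replicative phase.
#'
#' @param records Lifespan table from [analyze_cohort()] /
#'   [segment_lifespan()].
#' @param event `"lysis"` (death = dye entry; censored cells enter with their
#'   observed lower bound `arl_h + prl_h`) or `"arrest"` (death = end of
#'   replication; always observed here).
#' @param clock `"hours"` or `"generations"` (generation counts during the
#'   replicative phase; only meaningful with `event = "arrest"`).
#' @param group_by Record columns pasted into the group label.
#' @return An [event_table()].
#' @export
lifespan_events <- function(records, event = c("lysis", "arrest"),
                            clock = c("hours", "generations"),
                            group_by = c("strain", "medium")) {
  event <- match.arg(event)
  clock <- match.arg(clock)
  stopifnot(is.data.frame(records))
  grp <- if (length(group_by)) {
    do.call(paste, c(records[group_by], sep = "."))
  } else "all"
  if (event == "lysis") {
    time <- ifelse(records$censored, records$arl_h + records$prl_h,
                   records$lysis_time)
    status <- as.integer(!records$censored)
    if (clock == "generations") {
      stop('clock = "generations" applies to the replicative phase; ',
           'use event = "arrest"', call. = FALSE)
    }
  } else {
    time <- if (clock == "generations") records$arl_generations else
      records$arl_h
    status <- rep(1L, nrow(records))
  }
  event_table(time = time, status = status, group = grp)
}
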