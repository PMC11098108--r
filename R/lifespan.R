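#' Detect viability-dye entry (lysis)
#'
#' The viability dye (propidium iodide) is excluded by an intact membrane, so
#' a sustained rise of its signal marks imminent lysis. Lysis time is the
#' first time the dye channel exceeds `baseline mean + k_sigma * baseline SD`
#' for at least `sustain_frames` consecutive frames; the baseline is estimated
#' from the cell's own first `baseline_frames` frames. Cells whose dye channel
#' never crosses the threshold are censored.
#'
#' @param trace A [lineage_trace()] with a `pi_au` channel and at least
#'   `baseline_frames` frames.
#' @param k_sigma Threshold in baseline SD units.
#' @param sustain_frames Consecutive frames the signal must stay above
#'   threshold (guards against single-frame speckle).
#' @param baseline_frames Frames used for the baseline estimate.
#' @return A list with `time` (lysis time, `NA` if censored), `index` (frame
#'   index) and `censored` (logical).
#' @export
detect_pi_entry <- function(trace, k_sigma = 5, sustain_frames = 2L,
                            baseline_frames = 10L) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (is.null(trace$pi_au)) stop("trace has no `pi_au` channel", call. = FALSE)
  p <- trace$pi_au
  if (length(p) < baseline_frames) {
    stop(sprintf("need at least %d baseline frames", baseline_frames),
         call. = FALSE)
  }
  base <- p[seq_len(baseline_frames)]
  thr <- mean(base) + k_sigma * stats::sd(base)
  above <- p > thr
  ## first index opening a run of >= sustain_frames above-threshold frames.
  ## Dye entry is absorbing, so a candidate must also persist: the median of
  ## the following ~20 frames has to stay above threshold, which rejects
  ## brief noise excursions that a short baseline sample can let through.
  n <- length(p)
  run <- 0L
  hit <- NA_integer_
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain_frames) {
      cand <- i - sustain_frames + 1L
      persist <- p[cand:min(cand + 19L, n)]
      if (stats::median(persist) > thr) {
        hit <- cand
        break
      }
      run <- 0L
    }
  }
  if (is.na(hit)) {
    list(time = NA_real_, index = NA_integer_, censored = TRUE)
  } else {
    list(time = trace$time_h[hit], index = hit, censored = FALSE)
  }
}

#' Decompose a trace into replicative and post-replicative lifespans
#'
#' The apparent replicative lifespan (aRL) runs from the start of the record
#' to the last detected division (or, if the cell never divides on record, to
#' the last frame with a local elongation rate above `eps_growth`); the
#' post-replicative lifespan (PRL) runs from there to dye entry. For censored
#' cells the PRL is the lower bound `movie end - aRL end`. For uncensored
#' records `arl_h + prl_h` equals the lysis time exactly (times are relative
#' to the first frame).
#'
#' @param trace A [lineage_trace()].
#' @param divisions Post-division frame indices from [detect_divisions()].
#' @param lysis Result of [detect_pi_entry()] (or a list with `time` and
#'   `censored`).
#' @param eps_growth Minimum local elongation rate (1/h) counting as growth
#'   when no division is observed.
#' @return A one-row data frame (class `lifespan_record`) with `cell_id`,
#'   `strain`, `medium`, `arl_h`, `arl_generations`, `prl_h`, `lysis_time`,
#'   `censored`, `phenotype` (`NA`, set by [classify_phenotype()]).
#' @export
segment_lifespan <- function(trace, divisions, lysis, eps_growth = 0.01) {
  stopifnot(inherits(trace, "lineage_trace"))
  tt <- trace$time_h
  t0 <- tt[1L]
  if (!lysis$censored && lysis$time < t0) {
    stop("lysis before the first frame", call. = FALSE)
  }
  if (length(divisions)) {
    arl_end <- tt[divisions[length(divisions)]]
  } else {
    ## frame-wise log-length slope; last frame still growing
    sl <- diff(log(trace$length_um)) / diff(tt)
    grow <- which(sl > eps_growth)
    arl_end <- if (length(grow)) tt[grow[length(grow)] + 1L] else t0
  }
  arl_h <- arl_end - t0
  if (lysis$censored) {
    prl_h <- tt[length(tt)] - arl_end
    lysis_time <- NA_real_
  } else {
    prl_h <- lysis$time - arl_end
    lysis_time <- lysis$time - t0
  }
  out <- data.frame(
    cell_id = trace$cell_id, strain = trace$strain, medium = trace$medium,
    arl_h = arl_h, arl_generations = length(divisions),
    prl_h = prl_h, lysis_time = lysis_time, censored = lysis$censored,
    phenotype = NA_character_, stringsAsFactors = FALSE
  )
  class(out) <- c("lifespan_record", class(out))
  out
}

#' Mean cell length of a cohort during replicative life
#'
#' Pooled mean of all length readings recorded before each cell's aRL end,
#' per strain x medium group. This is the "average cell length in the tested
#' medium" against which filamentation (length > 3x the average) is judged;
#' post-replicative frames are excluded so filamented corpses do not inflate
#' the baseline.
#'
#' @param traces List of [lineage_trace()] objects.
#' @param records Data frame of [segment_lifespan()] rows for the same cells.
#' @return Named numeric vector of mean lengths, names `strain.medium`.
#' @export
cohort_mean_length <- function(traces, records) {
  acc <- list()
  for (tr in traces) {
    rec <- records[records$cell_id == tr$cell_id, , drop = FALSE]
    if (!nrow(rec)) next
    key <- paste(tr$strain, tr$medium, sep = ".")
    keep <- tr$time_h - tr$time_h[1L] <= rec$arl_h[1L]
    acc[[key]] <- c(acc[[key]], tr$length_um[keep])
  }
  vapply(acc, mean, numeric(1))
}

#' Classify the death phenotype of a cell
#'
#' Applies the morphology/chromosome-signal decision rules, in order:
#' 1. `excluded` — the chromosome signal shows a sudden loss during the aRL
#'    before the final cycle while the cell keeps dividing: plasmid loss of
#'    the chromosome label, not a death phenotype;
#' 2. `II` — the maximum length during the final cycle or the
#'    post-replicative phase exceeds `filament_factor` times the cohort mean
#'    length (filamentation, replicative crisis in the last generation);
#' 3. `Ia` — the chromosome signal drops by at least `gfp_drop_fraction` of
#'    its replicative-phase level within one frame, coincident (within one
#'    frame) with the last division: chromosome lost at the final division;
#' 4. `Ib` — otherwise: the chromosome is retained, typically decaying
#'    gradually during the post-replicative phase.
#'
#' Censored cells that are not filamented are labelled `I-unresolved`, as are
#' non-filamented cells of traces lacking a chromosome channel. A sudden drop
#' is measured relative to the median chromosome signal during the aRL, so
#' fluctuations around a near-zero signal never register as drops.
#'
#' @param trace A [lineage_trace()].
#' @param record The cell's [segment_lifespan()] row.
#' @param mean_length Cohort mean cell length for the cell's strain x medium
#'   group (see [cohort_mean_length()]).
#' @param filament_factor Filamentation threshold (default 3: a cell longer
#'   than 3x the average cell length is filamented).
#' @param gfp_drop_fraction Single-frame chromosome-signal drop fraction that
#'   counts as sudden loss.
#' @param divisions Optional division indices (recomputed with defaults when
#'   omitted).
#' @param drop_fraction Length-drop threshold used when recomputing divisions.
#' @return One of `"Ia"`, `"Ib"`, `"II"`, `"excluded"`, `"I-unresolved"`.
#' @export
classify_phenotype <- function(trace, record, mean_length,
                               filament_factor = 3, gfp_drop_fraction = 0.5,
                               divisions = NULL, drop_fraction = 0.25) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (!is.finite(mean_length) || mean_length <= 0) {
    stop("`mean_length` must be positive", call. = FALSE)
  }
  if (is.null(divisions)) divisions <- detect_divisions(trace, drop_fraction)
  n_div <- length(divisions)
  last_div <- if (n_div) divisions[n_div] else NA_integer_
  final_start <- if (n_div >= 2L) divisions[n_div - 1L] else 1L

  ## filamentation assessed over the final cycle and the post-replicative
  ## frames only: mid-life transient filaments that resume division do not
  ## count
  max_late_len <- max(trace$length_um[final_start:length(trace$length_um)])
  filamented <- max_late_len > filament_factor * mean_length

  gfp <- trace$gfp_au
  if (is.null(gfp)) {
    return(if (filamented) "II" else "I-unresolved")
  }

  arl_end_t <- trace$time_h[1L] + record$arl_h[1L]
  ref <- stats::median(gfp[trace$time_h <= arl_end_t])
  drops <- which(-diff(gfp) >= gfp_drop_fraction * ref) + 1L

  if (any(drops < final_start)) return("excluded")
  if (filamented) return("II")
  if (isTRUE(record$censored[1L])) return("I-unresolved")
  if (n_div && any(abs(drops - last_div) <= 1L)) return("Ia")
  "Ib"
}

#' Phenotype fractions per strain and medium
#'
#' Fractions of the death phenotypes over non-excluded records in each
#' strain x medium group (summing to 1 per group); excluded (plasmid-loss)
#' cells are counted separately. Groups containing only excluded cells get
#' `NA` fractions with their counts.
#'
#' @param records Data frame of classified [segment_lifespan()] rows.
#' @return Data frame with `strain`, `medium`, `n`, `n_excluded` and one
#'   `frac_*` column per observed phenotype label.
#' @export
phenotype_fractions <- function(records) {
  stopifnot(is.data.frame(records), "phenotype" %in% names(records))
  groups <- unique(records[c("strain", "medium")])
  labs <- setdiff(unique(records$phenotype), c(NA, "excluded"))
  labs <- union(c("Ia", "Ib", "II"), labs)
  out <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- records[records$strain == groups$strain[i] &
                     records$medium == groups$medium[i], ]
    excl <- sum(sub$phenotype == "excluded", na.rm = TRUE)
    kept <- sub[!is.na(sub$phenotype) & sub$phenotype != "excluded", ]
    fr <- if (nrow(kept)) {
      vapply(labs, function(l) mean(kept$phenotype == l), numeric(1))
    } else {
      setNames(rep(NA_real_, length(labs)), labs)
    }
    row <- data.frame(strain = groups$strain[i], medium = groups$medium[i],
                      n = nrow(kept), n_excluded = excl,
                      stringsAsFactors = FALSE)
    for (l in labs) row[[paste0("frac_", l)]] <- fr[[l]]
    out[[i]] <- row
  }
  do.call(rbind, out)
}
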