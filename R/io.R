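#' Write lineage traces to a tidy delimited table
#'
#' Long-format CSV with columns `cell_id`, `strain`, `medium`, `time_h`,
#' `length_um`, `width_um`, `gfp_au`, `pi_au` (missing channels written as
#' empty fields).
#'
#' @param traces List of [lineage_trace()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read lineage traces from a tidy delimited table
#'
#' Inverse of [write_lineage_traces()]; one [lineage_trace()] per `cell_id`
#' (channels that are entirely missing are dropped).
#'
#' @param path Input file path.
#' @return Named list of [lineage_trace()] objects.
#' @export
read_lineage_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_h", "length_um")
  if (!all(need %in% names(df))) {
    stop("trace table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(df$cell_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    ch <- function(nm) {
      if (!nm %in% names(sub) || all(is.na(sub[[nm]]))) NULL else sub[[nm]]
    }
    lineage_trace(
      time_h = sub$time_h, length_um = sub$length_um,
      width_um = ch("width_um"), gfp_au = ch("gfp_au"), pi_au = ch("pi_au"),
      cell_id = id,
      strain = if ("strain" %in% names(sub)) sub$strain[1L] else "wt",
      medium = if ("medium" %in% names(sub)) sub$medium[1L] else "LB"
    )
  })
  names(out) <- ids
  out
}

#' Write / read ground-truth tables
#'
#' Companion table for the synthetic generator's ground truth. List-valued
#' fields (`division_times`, `per_cycle_eer`) are serialised as
#' semicolon-joined strings.
#'
#' @param truths List of `lineage_truth` objects.
#' @param path File path.
#' @return `path` invisibly (write); list of `lineage_truth` objects (read).
#' @export
write_ground_truth <- function(truths, path) {
  df <- truth_table(truths)
  df$division_times <- vapply(truths, function(x)
    paste(format(x$division_times, digits = 15), collapse = ";"), character(1))
  df$per_cycle_eer <- vapply(truths, function(x)
    paste(format(x$per_cycle_eer, digits = 15), collapse = ";"), character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure(
      list(
        cell_id = df$cell_id[i], lifespan = df$lifespan[i],
        n_generations = df$n_generations[i], phenotype = df$phenotype[i],
        prl_duration = df$prl_duration[i], lysis_time = df$lysis_time[i],
        division_times = as.numeric(strsplit(df$division_times[i], ";")[[1L]]),
        per_cycle_eer = as.numeric(strsplit(df$per_cycle_eer[i], ";")[[1L]]),
        censored = df$censored[i]
      ),
      class = "lineage_truth"
    )
  })
}

#' Write / read growth curves as a long-format table
#'
#' Columns `strain`, `medium`, `replicate`, `time_h`, `od600`.
#'
#' @param curves List of [growth_curve()] objects.
#' @param path File path.
#' @return `path` invisibly (write); list of [growth_curve()] objects (read).
#' @export
write_growth_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(g) {
    data.frame(strain = g$strain, medium = g$medium, replicate = g$replicate,
               time_h = g$times, od600 = g$od, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_curves
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "medium", "replicate", "time_h", "od600")
  if (!all(need %in% names(df))) {
    stop("growth table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$strain, df$medium, df$replicate, sep = "\r")
  lapply(split(df, key), function(sub) {
    sub <- sub[order(sub$time_h), , drop = FALSE]
    growth_curve(times = sub$time_h, od = sub$od600, strain = sub$strain[1L],
                 medium = sub$medium[1L], replicate = sub$replicate[1L])
  })
}
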