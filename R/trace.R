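#' Single-cell lineage trace
#'
#' Container for one mother cell's multi-channel time series as recorded in a
#' mother-machine movie: cell length, optionally width, a chromosome-label
#' fluorescence channel (constitutive DNA-binding GFP) and a viability-dye
#' channel (propidium iodide, which enters the cell when the membrane becomes
#' permeable).
#'
#' @param time_h Acquisition times in hours, strictly increasing.
#' @param length_um Cell length in micrometres, strictly positive.
#' @param width_um Optional cell width in micrometres.
#' @param gfp_au Optional chromosome-label fluorescence (a.u.).
#' @param pi_au Optional viability-dye fluorescence (a.u.).
#' @param cell_id,strain,medium Metadata labels.
#' @return An object of class `lineage_trace`.
#' @export
lineage_trace <- function(time_h, length_um, width_um = NULL, gfp_au = NULL,
                          pi_au = NULL, cell_id = "cell", strain = "wt",
                          medium = "LB") {
  n <- length(time_h)
  if (n < 1L) stop("trace must contain at least one frame", call. = FALSE)
  if (any(diff(time_h) <= 0)) {
    stop("`time_h` must be strictly increasing", call. = FALSE)
  }
  if (length(length_um) != n || any(!is.finite(length_um)) || any(length_um <= 0)) {
    stop("`length_um` must be positive and match `time_h` in length", call. = FALSE)
  }
  for (ch in list(width_um = width_um, gfp_au = gfp_au, pi_au = pi_au)) NULL
  chk <- function(x, nm) {
    if (!is.null(x) && length(x) != n) {
      stop(sprintf("channel `%s` must match `time_h` in length", nm), call. = FALSE)
    }
    x
  }
  structure(
    list(
      cell_id = as.character(cell_id), strain = as.character(strain),
      medium = as.character(medium),
      time_h = as.numeric(time_h), length_um = as.numeric(length_um),
      width_um = chk(width_um, "width_um"), gfp_au = chk(gfp_au, "gfp_au"),
      pi_au = chk(pi_au, "pi_au")
    ),
    class = "lineage_trace"
  )
}

#' @export
print.lineage_trace <- function(x, ...) {
  cat(sprintf(
    "<lineage_trace> %s (%s, %s): %d frames over %.2f h; channels: %s\n",
    x$cell_id, x$strain, x$medium, length(x$time_h),
    diff(range(x$time_h)),
    paste(c("length", if (!is.null(x$width_um)) "width",
            if (!is.null(x$gfp_au)) "gfp", if (!is.null(x$pi_au)) "pi"),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
as.data.frame.lineage_trace <- function(x, ...) {
  n <- length(x$time_h)
  data.frame(
    cell_id = rep(x$cell_id, n), strain = rep(x$strain, n),
    medium = rep(x$medium, n), time_h = x$time_h, length_um = x$length_um,
    width_um = if (is.null(x$width_um)) rep(NA_real_, n) else x$width_um,
    gfp_au = if (is.null(x$gfp_au)) rep(NA_real_, n) else x$gfp_au,
    pi_au = if (is.null(x$pi_au)) rep(NA_real_, n) else x$pi_au,
    stringsAsFactors = FALSE
  )
}
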