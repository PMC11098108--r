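#' Population growth curve
#'
#' OD600 time series for one strain in one medium (one replicate well).
#'
#' @param times Times (h), strictly increasing.
#' @param od OD600 readings, non-negative, same length as `times`.
#' @param strain,medium,replicate Metadata labels.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, strain = "strain", medium = "medium",
                         replicate = "r1") {
  if (length(times) != length(od)) {
    stop("`times` and `od` must have equal length", call. = FALSE)
  }
  if (length(times) < 2L) stop("need at least two readings", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(od)) || any(od < 0)) {
    stop("`od` must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), od = as.numeric(od),
         strain = as.character(strain), medium = as.character(medium),
         replicate = as.character(replicate)),
    class = "growth_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s / %s / %s: %d readings over %.1f h\n",
              x$strain, x$medium, x$replicate, length(x$times),
              diff(range(x$times))))
  invisible(x)
}

#' Log-transform a growth curve
#'
#' Returns \eqn{\ln(N / N_0)}, the scale on which all growth parameters are
#' defined. `N0` is the mean of the first three OD readings (robust to
#' first-read noise); readings below `floor` are clipped before the log and
#' counted in the `n_floored` attribute.
#'
#' @param curve A [growth_curve()].
#' @param floor OD clip applied before taking logs.
#' @return Numeric vector of log-ratios, with attributes `n0` and `n_floored`.
#' @export
log_transform <- function(curve, floor = 1e-4) {
  stopifnot(inherits(curve, "growth_curve"))
  od <- curve$od
  n_floored <- sum(od < floor)
  od <- pmax(od, floor)
  if (any(od <= 0)) stop("non-positive OD after flooring", call. = FALSE)
  n0 <- mean(od[seq_len(min(3L, length(od)))])
  structure(log(od / n0), n0 = n0, n_floored = n_floored)
}

#' Extract growth parameters from a growth curve
#'
#' Computes the four standard population growth parameters from
#' \eqn{y = \ln(N/N_0)}:
#' * `mgr` — maximum growth rate: the largest least-squares slope of `y` vs
#'   time over sliding windows of `window` consecutive points (1/h);
#' * `spg` — saturation point of growth: the maximum of a 3-point running
#'   median of `y` (dimensionless);
#' * `auc` — area under the log-growth curve: trapezoidal integral of `y` over
#'   the full record (h);
#' * `texp` — duration of the exponential phase: total time during which the
#'   local slope is at least `exp_fraction * mgr` (h).
#'
#' @param curve A [growth_curve()] with at least 10 readings.
#' @param window Sliding-window width in points (`3 <= window <= n/2`).
#' @param exp_fraction Fraction of `mgr` defining the exponential phase,
#'   in (0, 1).
#' @param floor OD clip passed to [log_transform()].
#' @return A one-row data frame (class `growth_params`) with columns `strain`,
#'   `medium`, `replicate`, `mgr`, `spg`, `auc`, `texp`, `n_floored`.
#' @export
extract_growth_params <- function(curve, window = 5, exp_fraction = 0.5,
                                  floor = 1e-4) {
  stopifnot(inherits(curve, "growth_curve"))
  n <- length(curve$times)
  if (n < 10L) stop("need at least 10 readings for parameter extraction",
                    call. = FALSE)
  if (window < 3 || window > n / 2) {
    stop("`window` must satisfy 3 <= window <= n/2", call. = FALSE)
  }
  if (exp_fraction <= 0 || exp_fraction >= 1) {
    stop("`exp_fraction` must lie in (0, 1)", call. = FALSE)
  }
  y <- log_transform(curve, floor = floor)
  tt <- curve$times
  w <- as.integer(window)

  nw <- n - w + 1L
  slopes <- vapply(seq_len(nw), function(j) {
    idx <- j:(j + w - 1L)
    .ls_slope(tt[idx], y[idx])
  }, numeric(1))
  mgr <- max(slopes)

  spg <- max(stats::runmed(y, 3L))
  auc <- pracma::trapz(tt, as.numeric(y))

  texp <- 0
  if (mgr > 1e-12) {
    ## local slope for the interval (t_i, t_{i+1}]: slope of the window whose
    ## centre is nearest the interval midpoint
    centres <- seq_len(nw) + (w - 1) / 2
    mids <- seq_len(n - 1L) + 0.5
    jj <- pmin(pmax(round(mids - (w - 1) / 2), 1L), nw)
    local <- slopes[jj]
    texp <- sum(diff(tt)[local >= exp_fraction * mgr])
  }

  out <- data.frame(
    strain = curve$strain, medium = curve$medium, replicate = curve$replicate,
    mgr = mgr, spg = spg, auc = auc, texp = texp,
    n_floored = attr(y, "n_floored"), stringsAsFactors = FALSE
  )
  class(out) <- c("growth_params", class(out))
  out
}

## least-squares slope of y on x without lm() overhead
.ls_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Assemble the strain-by-feature panel matrix
#'
#' Averages replicates per strain-by-medium cell, spreads the four growth
#' parameters across media into feature columns (e.g. `auc-M9CG`) and z-scores
#' each column (mean 0, SD 1; columns that are constant across strains are
#' centred but left unscaled). Every strain must be measured in every medium;
#' missing cells raise an error rather than being silently imputed.
#'
#' @param params Data frame of [extract_growth_params()] rows (one or more
#'   replicates per strain and medium).
#' @param features Parameter columns to spread.
#' @return A list with `matrix` (strains x features, z-scored), `correlation`
#'   (feature correlation matrix) and `raw` (the unscaled wide matrix).
#' @export
panel_matrix <- function(params, features = c("mgr", "spg", "auc", "texp")) {
  stopifnot(is.data.frame(params),
            all(c("strain", "medium", features) %in% names(params)))
  agg <- stats::aggregate(params[features],
                          by = list(strain = params$strain,
                                    medium = params$medium),
                          FUN = mean)
  strains <- sort(unique(agg$strain))
  media <- sort(unique(agg$medium))
  if (length(strains) < 2L) {
    stop("panel needs at least two strains (z-scoring is degenerate)",
         call. = FALSE)
  }
  cols <- as.vector(outer(features, media, paste, sep = "-"))
  raw <- matrix(NA_real_, nrow = length(strains), ncol = length(cols),
                dimnames = list(strains, cols))
  for (i in seq_len(nrow(agg))) {
    raw[agg$strain[i], paste(features, agg$medium[i], sep = "-")] <-
      as.numeric(agg[i, features])
  }
  if (anyNA(raw)) {
    miss <- which(is.na(raw), arr.ind = TRUE)
    stop(sprintf("missing strain x medium cells (e.g. %s / %s)",
                 rownames(raw)[miss[1, 1]], colnames(raw)[miss[1, 2]]),
         call. = FALSE)
  }
  ctr <- sweep(raw, 2, colMeans(raw))
  sds <- apply(raw, 2, stats::sd)
  z <- sweep(ctr, 2, ifelse(sds > 0, sds, 1), "/")
  corr <- suppressWarnings(stats::cor(raw))
  list(matrix = z, correlation = corr, raw = raw)
}

#' Principal-component decomposition and hierarchical clustering of a panel
#'
#' Singular-value decomposition of the column-centred strain-by-feature matrix
#' followed by agglomerative clustering (average linkage on Euclidean
#' distances over the retained component scores) cut to `n_clusters`. This is
#' the workflow that groups mutant strains by their population growth
#' profiles on the first two principal components.
#'
#' @param mat Strain-by-feature matrix (or the list returned by
#'   [panel_matrix()]), finite, at least 3 strains.
#' @param n_clusters Number of clusters to cut the dendrogram into.
#' @param n_retain Number of leading component scores used for clustering.
#' @return An object of class `panel_decomposition`: list with `scores`,
#'   `loadings` (orthonormal columns), `variance_explained` (non-increasing,
#'   sums to 1), `cluster_labels`, and the `hclust` tree.
#' @export
decompose_and_cluster <- function(mat, n_clusters = 2, n_retain = 2) {
  if (is.list(mat) && !is.null(mat$matrix)) mat <- mat$matrix
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L) stop("need at least 3 strains", call. = FALSE)
  if (any(!is.finite(mat))) stop("matrix must be finite", call. = FALSE)
  if (n_clusters > nrow(mat)) {
    stop("`n_clusters` cannot exceed the number of strains", call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_retain, ncol(pc$x))
  hc <- stats::hclust(stats::dist(pc$x[, seq_len(k), drop = FALSE]),
                      method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  structure(
    list(scores = pc$x, loadings = pc$rotation, variance_explained = ve,
         cluster_labels = labels, center = pc$center, tree = hc),
    class = "panel_decomposition"
  )
}

#' @export
print.panel_decomposition <- function(x, ...) {
  cat(sprintf(
    "<panel_decomposition> %d strains, %d features; PC1+PC2 explain %.1f%%; %d clusters\n",
    nrow(x$scores), nrow(x$loadings),
    100 * sum(x$variance_explained[seq_len(min(2, length(x$variance_explained)))]),
    length(unique(x$cluster_labels))
  ))
  invisible(x)
}
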