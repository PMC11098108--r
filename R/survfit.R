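#' Event table for survival analysis
#'
#' @param time Event or censoring times (h or generations), non-negative.
#' @param status Event indicator: `1`/`TRUE`/`"died"` for deaths,
#'   `0`/`FALSE`/`"censored"` for right-censored records.
#' @param group Optional group label per record.
#' @return Data frame (class `event_table`) with columns `time`, `status`
#'   (integer 0/1) and `group`.
#' @export
event_table <- function(time, status, group = "all") {
  if (is.character(status) || is.factor(status)) {
    status <- as.character(status)
    if (!all(status %in% c("died", "censored"))) {
      stop('character `status` must be "died" or "censored"', call. = FALSE)
    }
    status <- as.integer(status == "died")
  }
  status <- as.integer(status)
  if (length(status) == 1L) status <- rep(status, length(time))
  if (length(time) != length(status) || !all(status %in% c(0L, 1L))) {
    stop("`status` must be 0/1 and match `time` in length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("`time` must be finite and non-negative", call. = FALSE)
  }
  out <- data.frame(time = as.numeric(time), status = status,
                    group = rep_len(as.character(group), length(time)),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", class(out))
  out
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Nonparametric survival estimate
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}, where at each distinct
#' death time \eqn{t_i}, \eqn{d_i} cells die out of the \eqn{n_i} still at
#' risk. Censored records leave the risk set without producing a step;
#' records censored at a death time are counted as still at risk at that time.
#' Without censoring the estimate equals the empirical survival function.
#'
#' @param events An [event_table()] (or data frame with `time` and `status`).
#' @return Object of class `survival_curve`: data frame with `time` (distinct
#'   death times), `survival` (non-increasing step values, S before the first
#'   death is 1), `at_risk` and `deaths`; attributes `n` and `n_censored`.
#' @export
kaplan_meier <- function(events) {
  stopifnot(is.data.frame(events), all(c("time", "status") %in% names(events)))
  if (!nrow(events)) stop("empty event table", call. = FALSE)
  km <- .km(events$time, events$status)
  if (!nrow(km)) warning("all records censored: survival stays at 1",
                         call. = FALSE)
  attr(km, "n") <- nrow(events)
  attr(km, "n_censored") <- sum(events$status == 0L)
  class(km) <- c("survival_curve", "data.frame")
  km
}

## O(n log n) product-limit core
.km <- function(time, status) {
  n <- length(time)
  o <- order(time)
  ts <- time[o]
  st <- status[o]
  r <- rle(ts)
  ut <- r$values
  first <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  at_risk <- n - first + 1L
  deaths <- as.vector(rowsum(st, ts))
  surv <- cumprod(1 - deaths / at_risk)
  keep <- deaths > 0L
  data.frame(time = ut[keep], survival = surv[keep],
             at_risk = at_risk[keep], deaths = deaths[keep])
}

#' Evaluate a survival curve at arbitrary times
#'
#' Right-continuous step-function evaluation of a `survival_curve`.
#'
#' @param curve A [kaplan_meier()] result.
#' @param t Times at which to evaluate.
#' @return Survival probabilities at `t`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (!nrow(curve)) return(rep(1, length(t)))
  idx <- findInterval(t, curve$time)
  c(1, curve$survival)[idx + 1L]
}

#' Fit the Gompertz mortality law to event data
#'
#' Estimates the initial hazard `a` and the aging rate `b` of
#' \eqn{S(t) = \exp\{-(a/b)(e^{bt}-1)\}} from possibly censored event times,
#' with 95% confidence bounds from a nonparametric bootstrap over cells.
#'
#' Two estimation routes are provided. `"nls_on_km"` (default) fits the
#' Gompertz survival function to the Kaplan-Meier curve by nonlinear least
#' squares, mirroring the usual practice of fitting the plotted survival
#' curve. `"mle"` maximises the censoring-aware likelihood
#' \eqn{\prod_d \lambda(t_i) \prod_i S(t_i)} by profiling: for fixed `b` the
#' maximising `a` is available in closed form, leaving a one-dimensional
#' search over `b`. Both constrain `b >= 0`; fits pinned at the boundary are
#' flagged (`boundary_b`), never allowed to report negative aging.
#'
#' @param events An [event_table()]; needs at least one death (ten or more
#'   recommended for a stable fit).
#' @param method `"nls_on_km"` or `"mle"`.
#' @param n_boot Bootstrap replicates for the confidence bounds (0 skips the
#'   bootstrap).
#' @param seed Integer seed for the bootstrap resampling.
#' @param clock Label naming the time units of `events` (`"hours"` or
#'   `"generations"`); `a` and `b` are in the inverse of this unit.
#' @return Object of class `gompertz_fit`: list with `a`, `b`, `ci95_a`,
#'   `ci95_b`, `method`, `clock`, `n`, `n_deaths`, `gof` (RMSE of the fitted
#'   survival against the KM curve), `boundary_b` and the bootstrap draws.
#' @export
fit_gompertz <- function(events, method = c("nls_on_km", "mle"),
                         n_boot = 1000L, seed = 1L,
                         clock = c("hours", "generations")) {
  method <- match.arg(method)
  clock <- match.arg(clock)
  stopifnot(is.data.frame(events), all(c("time", "status") %in% names(events)))
  time <- events$time
  status <- as.integer(events$status)
  n_deaths <- sum(status == 1L)
  if (n_deaths < 1L) stop("need at least one death to fit", call. = FALSE)
  if (length(unique(time[status == 1L])) < 2L) {
    stop("degenerate event data: all deaths at the same time", call. = FALSE)
  }
  if (n_deaths < 10L) {
    warning("fewer than 10 deaths: Gompertz fit will be unstable", call. = FALSE)
  }

  pt <- .fit_gompertz_point(time, status, method)

  boot <- NULL
  ci_a <- ci_b <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    n <- length(time)
    ab <- matrix(NA_real_, nrow = n_boot, ncol = 2L,
                 dimnames = list(NULL, c("a", "b")))
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit_i <- tryCatch(.fit_gompertz_point(time[idx], status[idx], method),
                        error = function(e) NULL)
      if (!is.null(fit_i)) ab[i, ] <- c(fit_i$a, fit_i$b)
    }
    boot <- ab[stats::complete.cases(ab), , drop = FALSE]
    if (nrow(boot) >= 10L) {
      ci_a <- unname(stats::quantile(boot[, "a"], c(0.025, 0.975)))
      ci_b <- unname(stats::quantile(boot[, "b"], c(0.025, 0.975)))
    }
  }

  structure(
    list(a = pt$a, b = pt$b, ci95_a = ci_a, ci95_b = ci_b, method = method,
         clock = clock, n = length(time), n_deaths = n_deaths, gof = pt$gof,
         boundary_b = pt$b <= 1e-10, boot = boot),
    class = "gompertz_fit"
  )
}

.fit_gompertz_point <- function(time, status, method) {
  km <- .km(time, status)
  if (method == "mle") {
    d <- sum(status == 1L)
    sum_td <- sum(time[status == 1L])
    nll <- function(b) {
      g <- if (b < 1e-12) time else expm1(b * time) / b
      sg <- sum(g)
      ahat <- d / sg
      -(d * log(ahat) + b * sum_td - ahat * sg)
    }
    bmax <- max(100 / max(time), 1)
    opt <- stats::optimize(nll, c(0, bmax))
    b <- if (nll(0) <= opt$objective) 0 else opt$minimum
    g <- if (b < 1e-12) time else expm1(b * time) / b
    a <- d / sum(g)
  } else {
    if (nrow(km) < 2L) stop("too few distinct death times", call. = FALSE)
    fit <- fit_gompertz_curve(km$time, km$survival)
    a <- fit$a
    b <- fit$b
  }
  gof <- if (nrow(km)) {
    sqrt(mean((km$survival - gompertz_survival(km$time, a, b))^2))
  } else NA_real_
  list(a = a, b = b, gof = gof)
}

#' Least-squares Gompertz fit to survival-curve points
#'
#' Fits \eqn{S(t) = \exp\{-(a/b)(e^{bt}-1)\}} to `(times, survival)` pairs by
#' nonlinear least squares with `b` constrained non-negative (L-BFGS-B on
#' `(log a, b)`, with starts taken from the exponential rate and from the
#' slope of the log cumulative hazard). This is the curve-fitting core behind
#' `fit_gompertz(method = "nls_on_km")`; on noiseless survival values it
#' recovers the generating parameters to numerical precision.
#'
#' @param times Times of the survival-curve points, non-negative.
#' @param survival Survival values in `(0, 1]` at `times`.
#' @return List with `a`, `b` and `sse` (residual sum of squares).
#' @export
fit_gompertz_curve <- function(times, survival) {
  if (length(times) != length(survival) || length(times) < 2L) {
    stop("need matching `times` and `survival` of length >= 2", call. = FALSE)
  }
  ts <- as.numeric(times)
  s <- as.numeric(survival)
  sse <- function(p) sum((s - gompertz_survival(ts, exp(p[1L]), p[2L]))^2)
  H <- -log(pmax(s, 1e-12))
  a0 <- max(H[length(H)] / ts[length(ts)], 1e-10)  # exponential-rate scale
  b_lh <- .ls_slope(ts, log(pmax(H, 1e-12)))
  b0s <- unique(pmax(c(0.01, if (is.finite(b_lh)) b_lh), 0))
  best <- NULL
  for (b0 in b0s) {
    a0b <- if (b0 > 1e-8) {
      max(b0 * H[length(H)] / expm1(b0 * ts[length(ts)]), 1e-12)
    } else a0
    o <- stats::optim(c(log(a0b), b0), sse, method = "L-BFGS-B",
                      lower = c(-30, 0), upper = c(10, 100),
                      control = list(factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- best$par
  val <- best$value
  ## Levenberg-Marquardt polish for sharp convergence near the optimum
  polish <- tryCatch({
    df <- data.frame(ts = ts, s = s)
    fit <- minpack.lm::nlsLM(
      s ~ gompertz_survival(ts, exp(la), b), data = df,
      start = list(la = par[1L], b = par[2L]),
      lower = c(-30, 0), upper = c(10, 100),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    )
    cf <- stats::coef(fit)
    list(par = c(cf[["la"]], cf[["b"]]),
         value = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
  if (!is.null(polish) && polish$value <= val) {
    par <- polish$par
    val <- polish$value
  }
  list(a = exp(par[1L]), b = par[2L], sse = val)
}

#' @export
print.gompertz_fit <- function(x, ...) {
  unit <- if (x$clock == "hours") "1/h" else "1/gen"
  cat(sprintf(
    "<gompertz_fit> (%s, %s clock)\n  a = %.4g %s (95%% CI %.4g-%.4g)\n  b = %.4g %s (95%% CI %.4g-%.4g)%s\n  n = %d (%d deaths), KM RMSE = %.3g\n",
    x$method, x$clock, x$a, unit, x$ci95_a[1], x$ci95_a[2],
    x$b, unit, x$ci95_b[1], x$ci95_b[2],
    if (x$boundary_b) " [pinned at b = 0]" else "",
    x$n, x$n_deaths, x$gof
  ))
  invisible(x)
}

#' Compare aging rates across groups
#'
#' Tabulates Gompertz fits per group, orders them by aging rate and flags
#' pairs of groups whose 95% confidence intervals for `b` do not overlap
#' (evidence for genuinely different aging rates).
#'
#' @param fits Named list of [fit_gompertz()] results (entries may be `NULL`
#'   for unfittable groups, which are reported with `NA`).
#' @return A list with `table` (one row per group, ordered by `b`) and
#'   `nonoverlapping` (data frame of flagged group pairs; zero rows when all
#'   intervals overlap).
#' @export
compare_groups <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (is.null(names(fits))) names(fits) <- paste0("group", seq_along(fits))
  rows <- lapply(names(fits), function(g) {
    f <- fits[[g]]
    if (is.null(f)) {
      data.frame(group = g, a = NA_real_, b = NA_real_,
                 b_lo = NA_real_, b_hi = NA_real_, clock = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, a = f$a, b = f$b,
                 b_lo = f$ci95_b[1], b_hi = f$ci95_b[2], clock = f$clock,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$b), , drop = FALSE]
  rownames(tab) <- NULL

  pairs <- list()
  ok <- which(!is.na(tab$b_lo))
  if (length(ok) >= 2L) {
    cmb <- utils::combn(ok, 2L)
    for (j in seq_len(ncol(cmb))) {
      i1 <- cmb[1L, j]; i2 <- cmb[2L, j]
      disjoint <- tab$b_lo[i1] > tab$b_hi[i2] || tab$b_lo[i2] > tab$b_hi[i1]
      if (disjoint) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          group1 = tab$group[i1], group2 = tab$group[i2],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  nonover <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(group1 = character(0), group2 = character(0))
  list(table = tab, nonoverlapping = nonover)
}
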