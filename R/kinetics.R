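# Residence-time kinetics: survival time correlation function sigma(t),
# biexponential fit, koff = slower rate, tau = 1/koff, bootstrap spread.

#' Survival time correlation function
#'
#' From a set of contact events, the normalized probability that a contact
#' present at time nu persists to nu + t, summed over contacts and window
#' starts. For an event of duration d frames, the number of lag-k windows it
#' keeps alive is `max(0, d - k)`; raw counts are normalized by the lag-0
#' value so `sigma(0) = 1`.
#'
#' @param events Event tibble (needs `start_frame`, `end_frame`) or a
#'   numeric vector of durations in ns.
#' @param T_total Trajectory length in ns (lag grid upper end). For pooled
#'   repeats use the longest repeat.
#' @param dt Time per frame (ns).
#' @param lag_stride Evaluate every `lag_stride`-th frame lag (1 = every
#'   frame step).
#' @return A `survival_curve`: tibble `t` (ns), `sigma`, with attributes
#'   `T_total`, `dt`, `n_events`.
#' @export
survival_function <- function(events, T_total, dt, lag_stride = 1L) {
  durations <- if (is.data.frame(events)) {
    (events$end_frame - events$start_frame + 1L)
  } else {
    d <- round(events / dt)
    d[d < 1] <- 1
    d
  }
  if (length(durations) == 0L) stop_ls("no contacts sampled")
  if (T_total <= 0) stop_ls("T_total must be positive")

  # lag grid in frames: 0 .. T-1 (at lag T no window fits the trajectory)
  max_lag <- max(1L, floor(T_total / dt) - 1L)
  lags <- seq(0L, max_lag, by = as.integer(lag_stride))
  # raw window count at lag k: sum over events of max(0, d - k), computed
  # from tail sums of the duration histogram in O(max duration); each lag is
  # then normalized by the number of windows of that lag the trajectory
  # holds, so a contact spanning the whole trajectory gives sigma identical
  # to 1 at every lag.
  dmax <- max(durations)
  hist_d <- tabulate(durations, nbins = dmax)
  cnt_ge <- rev(cumsum(rev(hist_d))) # cnt_ge[j] = #events with d >= j
  sum_ge <- rev(cumsum(rev(hist_d * seq_len(dmax)))) # sum of d over d >= j
  t_frames <- floor(T_total / dt)
  counts <- vapply(lags, function(k) {
    if (k >= dmax) {
      return(0)
    }
    sum_ge[k + 1L] - k * cnt_ge[k + 1L]
  }, numeric(1))
  sigma_raw <- counts / (t_frames - lags)
  curve <- tibble::tibble(t = lags * dt, sigma = sigma_raw / sigma_raw[1])
  structure(curve,
    class = c("survival_curve", class(curve)),
    T_total = T_total, dt = dt, n_events = length(durations),
    counts = counts
  )
}

# log-linear slope of sigma over a lag window; used to initialize the fit.
loglin_rate <- function(t, sigma) {
  keep <- sigma > 0
  if (sum(keep) < 2L) {
    return(NA_real_)
  }
  fit <- stats::lm(log(sigma[keep]) ~ t[keep])
  max(1e-8, -unname(coef(fit)[2]))
}

#' Fit a biexponential to a survival curve
#'
#' Least-squares fit of `sigma(t) ~ A exp(-k1 t) + B exp(-k2 t)` with all
#' parameters constrained non-negative. The slower rate is reported as
#' `koff` and the residence time as `1/koff`; a component whose amplitude is
#' below `amp_tol` of the total (default 10%) is not interpreted as a bound
#' population and is skipped when choosing the slow rate, so a
#' single-exponential decay whose two-component fit parks a sliver of
#' amplitude on a spurious slow rate still reports the real rate.
#'
#' @param curve A `survival_curve` (or tibble with `t`, `sigma`).
#' @param constrain_sum Constrain `A + B = 1` (off by default).
#' @param amp_tol Relative amplitude below which a component is treated as
#'   absent when selecting `koff`.
#' @return A `koff_fit` object; see [tidy.koff_fit()] and
#'   [glance.koff_fit()].
#' @export
fit_biexponential <- function(curve, constrain_sum = FALSE, amp_tol = 0.1) {
  t <- curve$t
  y <- curve$sigma
  n_half <- max(2L, floor(length(t) / 4))
  k_fast0 <- loglin_rate(t[seq_len(n_half)], y[seq_len(n_half)])
  tail_ix <- seq(max(1L, length(t) - 4L * n_half), length(t))
  k_slow0 <- loglin_rate(t[tail_ix], y[tail_ix])
  if (is.na(k_fast0)) k_fast0 <- 1
  if (is.na(k_slow0) || k_slow0 > k_fast0) k_slow0 <- k_fast0

  # Each sigma(t) value is estimated from a finite number of observation
  # windows; its sampling sd scales like the square root of that count
  # (Poisson-like), so residuals are weighted by sqrt(count) with a floor of
  # one window. Empty-tail lags then still anchor the fit at zero without
  # letting tail noise capture the slow component. Curves built outside
  # survival_function() carry no counts and are fitted unweighted.
  counts <- attr(curve, "counts")
  w <- if (is.null(counts)) rep(1, length(t)) else sqrt(pmax(counts, 1))
  w <- w / mean(w)

  # Levenberg-Marquardt on the weighted residuals (box-constrained);
  # coinciding start rates make the components collinear, so starts are
  # spread around the log-linear estimates and widened on failure
  resid_fun <- if (constrain_sum) {
    function(p) w * (p[1] * exp(-p[2] * t) + (1 - p[1]) * exp(-p[3] * t) - y)
  } else {
    function(p) w * (p[1] * exp(-p[3] * t) + p[2] * exp(-p[4] * t) - y)
  }
  starts <- list(c(0.5, 2), c(1, 4), c(0.1, 10))
  fit <- NULL
  for (st in starts) {
    par0 <- if (constrain_sum) {
      c(0.5, k_slow0 * st[1], k_fast0 * st[2])
    } else {
      c(0.5, 0.5, k_slow0 * st[1], k_fast0 * st[2])
    }
    lower <- if (constrain_sum) c(0, 0, 0) else c(0, 0, 0, 0)
    upper <- if (constrain_sum) c(1, Inf, Inf) else rep(Inf, 4)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, fn = resid_fun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$info %in% 1:4) break
    fit <- NULL
  }

  if (is.null(fit)) {
    return(new_koff_fit(
      k1 = NA_real_, k2 = NA_real_, A = NA_real_, B = NA_real_,
      r_squared = NA_real_, curve = curve, converged = FALSE
    ))
  }

  p <- fit$par
  if (constrain_sum) {
    amps <- c(p[1], 1 - p[1])
    rates <- c(p[2], p[3])
  } else {
    amps <- c(p[1], p[2])
    rates <- c(p[3], p[4])
  }
  ord <- order(rates) # slow first
  rates <- rates[ord]
  amps <- amps[ord]

  yhat <- amps[1] * exp(-rates[1] * t) + amps[2] * exp(-rates[2] * t)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  # select koff: slowest component with non-negligible amplitude
  total_amp <- sum(amps)
  real <- if (total_amp > 0) amps / total_amp >= amp_tol else c(TRUE, TRUE)
  koff <- if (any(real)) rates[which(real)[1]] else rates[1]

  new_koff_fit(
    k1 = rates[1], k2 = rates[2], A = amps[1], B = amps[2],
    koff = koff, r_squared = r2, curve = curve, converged = TRUE
  )
}

new_koff_fit <- function(k1, k2, A, B, r_squared, curve,
                         koff = k1, converged = TRUE,
                         bootstrap_koffs = numeric()) {
  no_decay <- is.finite(koff) && koff < 1e-8
  structure(
    list(
      k1 = k1, k2 = k2, A = A, B = B,
      koff = koff,
      residence_time = if (isTRUE(no_decay)) Inf else 1 / koff,
      no_decay = isTRUE(no_decay),
      r_squared = r_squared,
      n_events = attr(curve, "n_events") %||% NA_integer_,
      curve = curve,
      converged = converged,
      bootstrap_koffs = bootstrap_koffs
    ),
    class = "koff_fit"
  )
}

#' @export
print.koff_fit <- function(x, ...) {
  cat(sprintf(
    "<koff_fit> koff = %.4g ns^-1, tau = %.4g ns, r^2 = %.4f (%s, %s events)\n",
    x$koff, x$residence_time, x$r_squared,
    if (x$converged) "converged" else "NOT converged", x$n_events
  ))
  invisible(x)
}

#' Tidy a kinetics fit
#'
#' @param x A `koff_fit`.
#' @param ... Unused.
#' @return One row per biexponential component: `term`, `rate` (ns^-1),
#'   `amplitude`.
#' @method tidy koff_fit
#' @export
tidy.koff_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slow", "fast"),
    rate = c(x$k1, x$k2),
    amplitude = c(x$A, x$B)
  )
}

#' One-row kinetics fit summary
#'
#' @param x A `koff_fit`.
#' @param ... Unused.
#' @return Tibble with `koff`, `residence_time`, `r_squared`, `n_events`,
#'   `converged`, and the bootstrap mean/sd when bootstraps were run.
#' @method glance koff_fit
#' @export
glance.koff_fit <- function(x, ...) {
  tibble::tibble(
    koff = x$koff, residence_time = x$residence_time,
    r_squared = x$r_squared, n_events = x$n_events,
    converged = x$converged,
    boot_koff_mean = if (length(x$bootstrap_koffs)) {
      mean(x$bootstrap_koffs, na.rm = TRUE)
    } else {
      NA_real_
    },
    boot_koff_sd = if (length(x$bootstrap_koffs)) {
      sd(x$bootstrap_koffs, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' Bootstrap koff over contact events
#'
#' Resamples the events with replacement (same count), rebuilds the survival
#' curve and refits. Deterministic for a given seed.
#'
#' @inheritParams survival_function
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param lag_stride Passed to [survival_function()].
#' @return Numeric vector of `n_boot` koff values (NaN where a refit failed).
#' @export
bootstrap_koff <- function(events, T_total, dt, n_boot = 10L, seed = 1L,
                           lag_stride = 1L) {
  durations <- if (is.data.frame(events)) {
    (events$end_frame - events$start_frame + 1L) * dt
  } else {
    events
  }
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      resampled <- sample(durations, length(durations), replace = TRUE)
      fit <- fit_biexponential(
        survival_function(resampled, T_total, dt, lag_stride = lag_stride)
      )
      if (fit$converged) fit$koff else NaN
    }, numeric(1))
  })
}

#' Residence-time kinetics for pooled events
#'
#' Pools contact events (typically all repeats of one residue or one binding
#' site), builds the survival curve, fits the biexponential and attaches
#' bootstrap koffs. `T_total` defaults to the longest repeat length.
#'
#' @param events Event tibble.
#' @param T_total Trajectory length (ns).
#' @param dt Frame time (ns).
#' @param n_boot Bootstrap replicates (0 to skip).
#' @param seed Seed for the bootstrap.
#' @param lag_stride Survival lag stride.
#' @return A `koff_fit` with `bootstrap_koffs` filled in.
#' @export
compute_koff <- function(events, T_total, dt, n_boot = 10L, seed = 1L,
                         lag_stride = 1L) {
  curve <- survival_function(events, T_total, dt, lag_stride = lag_stride)
  fit <- fit_biexponential(curve)
  if (n_boot > 0L) {
    fit$bootstrap_koffs <- bootstrap_koff(
      events, T_total, dt,
      n_boot = n_boot, seed = seed, lag_stride = lag_stride
    )
  }
  fit
}

#' @rdname compute_koff
#' @param residue Residue serial whose events to pool.
#' @export
residue_koff <- function(events, residue, T_total, dt, n_boot = 10L,
                         seed = 1L, lag_stride = 1L) {
  ev <- events[events$residue == residue, , drop = FALSE]
  if (nrow(ev) == 0L) stop_ls("no contacts sampled for residue %s", residue)
  compute_koff(ev, T_total, dt, n_boot = n_boot, seed = seed, lag_stride = lag_stride)
}

#' Plot data for a kinetics fit
#'
#' Left panel: sorted contact durations; right panel: normalized survival
#' function with the fitted biexponential overlaid.
#'
#' @param object A `koff_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot koff_fit
#' @export
autoplot.koff_fit <- function(object, ...) {
  curve <- object$curve
  yhat <- object$A * exp(-object$k1 * curve$t) +
    object$B * exp(-object$k2 * curve$t)
  df <- dplyr::bind_rows(
    tibble::tibble(t = curve$t, value = curve$sigma, kind = "survival"),
    tibble::tibble(t = curve$t, value = yhat, kind = "biexponential fit")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value, colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "lag t (ns)", y = expression(sigma(t)),
      title = sprintf(
        "koff = %.3g ns^-1, tau = %.3g ns, r^2 = %.3f",
        object$koff, object$residence_time, object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}
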