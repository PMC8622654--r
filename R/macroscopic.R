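#' Construct a macroscopic (multichannel) record
#'
#' A current trace together with the moment at which the membrane modifier
#' was added. The spans before and after the addition must each be long
#' enough to hold a steady-state window.
#'
#' @param trace A `current_trace`.
#' @param addition_time_s Time of modifier addition, in s from the start of
#'   the record; must lie strictly inside the record.
#' @return An object of class `macroscopic_record`.
#' @export
macroscopic_record <- function(trace, addition_time_s) {
  dur <- length(trace$samples) / trace$sampling_rate_Hz
  stopifnot(is.finite(addition_time_s), addition_time_s > 0,
            addition_time_s < dur)
  structure(list(trace = trace, addition_time_s = addition_time_s,
                 duration_s = dur),
            class = "macroscopic_record")
}

#' Steady-state current over a time window
#'
#' Mean and sd of the current over `[t_start, t_end]`, with a drift check:
#' if the fitted linear trend changes the current by more than 5% of its
#' mean across the window, a warning is emitted (the window is probably not
#' at steady state yet).
#'
#' @param trace A `current_trace`.
#' @param window Numeric `c(t_start_s, t_end_s)`; must lie inside the record
#'   and contain at least 100 samples.
#' @return List with `mean_pA`, `sd_pA`, `n`.
#' @export
steady_state_current <- function(trace, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  fs <- trace$sampling_rate_Hz
  dur <- length(trace$samples) / fs
  if (window[1] < 0 || window[2] > dur + 0.5 / fs)
    stop(sprintf("window [%g, %g] s outside the record (0-%g s)",
                 window[1], window[2], dur))
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(trace$samples), ceiling(window[2] * fs))
  if (i1 - i0 + 1L < 100L) stop("steady-state window must contain >= 100 samples")
  y <- trace$samples[i0:i1]
  t <- (seq_along(y) - 1) / fs
  slope <- stats::coef(stats::lm(y ~ t))[[2]]
  m <- mean(y)
  if (is.finite(slope) && m != 0 &&
      abs(slope) * (window[2] - window[1]) > 0.05 * abs(m))
    warning("current drifts by more than 5% of its mean across the window; ",
            "steady state may not be reached", call. = FALSE)
  list(mean_pA = m, sd_pA = stats::sd(y), n = length(y))
}

# default steady-state window: final 20% of the phase, capped at 60 s
.phase_window <- function(t_lo, t_hi) {
  w <- min(0.2 * (t_hi - t_lo), 60)
  c(t_hi - w, t_hi)
}

#' Steady-state activity ratio before/after modifier addition
#'
#' Estimates the steady-state current before the addition (final 20% of the
#' pre-addition span, capped at 60 s) and after it (same rule applied to the
#' post-addition span, with the window constrained to start no earlier than
#' `addition + settle_time_s`), and returns the activity ratio
#' I_inf / I_inf0 with a delta-method standard error.
#'
#' @param record A `macroscopic_record`.
#' @param settle_time_s Time allowed for the current to re-equilibrate after
#'   the addition before the steady-state window may start, in s.
#' @return A `steady_state_ratio`: list with `i_inf_0_pA`, `i_inf_pA`,
#'   `ratio`, `se_ratio`.
#' @export
activity_ratio <- function(record, settle_time_s = 100) {
  tr <- record$trace
  add <- record$addition_time_s
  dur <- record$duration_s
  if (dur - add < settle_time_s + 100 / tr$sampling_rate_Hz)
    stop("post-addition span too short for settle time plus a steady-state window")

  w_pre <- .phase_window(0, add)
  w_post <- .phase_window(add, dur)
  w_post[1] <- max(w_post[1], add + settle_time_s)
  if (w_post[1] >= w_post[2])
    stop("settle time leaves no room for the post-addition window")

  pre <- steady_state_current(tr, w_pre)
  post <- steady_state_current(tr, w_post)
  if (pre$mean_pA <= 0) stop("pre-addition steady-state current must be > 0")
  ratio <- post$mean_pA / pre$mean_pA
  # delta method on the ratio of two window means
  se <- abs(ratio) * sqrt((pre$sd_pA / pre$mean_pA)^2 / pre$n +
                          (post$sd_pA / post$mean_pA)^2 / post$n)
  structure(list(i_inf_0_pA = pre$mean_pA, i_inf_pA = post$mean_pA,
                 ratio = ratio, se_ratio = se),
            class = "steady_state_ratio")
}

#' @export
print.steady_state_ratio <- function(x, ...) {
  cat(sprintf("Steady-state activity ratio: %.3f +/- %.3f (I = %.2f -> %.2f pA)\n",
              x$ratio, x$se_ratio, x$i_inf_0_pA, x$i_inf_pA))
  invisible(x)
}

#' Aggregate per-record activity ratios across bilayers
#'
#' @param ratios List of `steady_state_ratio` objects (one per bilayer).
#' @return List with `mean`, `sd`, `n`.
#' @export
aggregate_activity_ratios <- function(ratios) {
  r <- vapply(ratios, `[[`, 0, "ratio")
  list(mean = mean(r), sd = if (length(r) > 1) stats::sd(r) else 0,
       n = length(r))
}
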