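#' Detect binding events on a single-molecule intensity trace
#'
#' Two-state segmentation by hysteresis thresholding: a binding event is
#' entered when the intensity rises above the high threshold and exited when
#' it falls below the low threshold, which suppresses chatter from noise
#' around a single threshold. Default thresholds sit `k_high` (default 3)
#' and `k_low` (default 2) noise SDs above the unbound baseline. Baseline
#' and noise SD are estimated from the 5th/25th intensity quantiles (the
#' unbound level is the lower mode of the trace), which stays correct even
#' when the particle is bound most of the time — up to ~75% occupancy;
#' supply explicit thresholds beyond that.
#'
#' Frames are 0-based and events are half-open `[start, end)`; an event
#' still bound at the final frame is flagged censored. Events shorter than
#' `min_frames` are discarded as unresolvable.
#'
#' @param intensity per-frame intensity (arbitrary units), >= 10 frames.
#' @param frame_interval_s frame interval (s), > 0.
#' @param high,low explicit thresholds; both or neither.
#' @param k_high,k_low MAD multiples for the default thresholds.
#' @param min_frames minimum event duration in frames.
#' @return Data frame with columns `start_frame`, `end_frame`,
#'   `duration_s`, `censored`.
#' @export
detect_events <- function(intensity, frame_interval_s, high = NULL,
                          low = NULL, k_high = 3, k_low = 2,
                          min_frames = 2) {
  if (!is.numeric(intensity) || length(intensity) < 10) {
    stop("'intensity' must be numeric with at least 10 frames")
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  .check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  if (is.null(high) != is.null(low)) {
    stop("supply both 'high' and 'low' thresholds, or neither")
  }
  if (is.null(high)) {
    q <- quantile(intensity, c(0.05, 0.25), names = FALSE)
    s <- (q[2] - q[1]) / 0.9709        # N(0,1): z_.25 - z_.05
    if (s <= 0) s <- mad(intensity)
    m <- q[2] + 0.6745 * s             # back to the baseline centre
    high <- m + k_high * s
    low <- m + k_low * s
  }
  if (high <= low) stop("thresholds inverted: 'high' must exceed 'low'")

  n <- length(intensity)
  bound <- FALSE
  start <- NA_integer_
  ev <- list()
  for (i in seq_len(n)) {
    if (!bound && intensity[i] > high) {
      bound <- TRUE
      start <- i - 1L                      # 0-based
    } else if (bound && intensity[i] < low) {
      ev[[length(ev) + 1L]] <- c(start, i - 1L, 0L)
      bound <- FALSE
    }
  }
  if (bound) ev[[length(ev) + 1L]] <- c(start, n, 1L)
  if (!length(ev)) {
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      duration_s = numeric(), censored = logical()))
  }
  m <- do.call(rbind, ev)
  keep <- (m[, 2] - m[, 1]) >= min_frames
  m <- m[keep, , drop = FALSE]
  data.frame(start_frame = m[, 1], end_frame = m[, 2],
             duration_s = (m[, 2] - m[, 1]) * frame_interval_s,
             censored = m[, 3] == 1L)
}

#' Truncated-exponential maximum likelihood for dwell times
#'
#' Single-molecule residence times below the minimum resolvable dwell
#' `t_min` are unobservable, so the observed distribution is a left-truncated
#' exponential, whose rate MLE has the closed form
#' \deqn{\hat k_{off} = n / \sum_i (t_i - t_{min})}
#' over the n uncensored dwells (exponential memorylessness makes the
#' estimate unbiased for any truncation point). Dwells censored by the end
#' of a trace are excluded by default, matching naive probability-density
#' regression; with `include_censored = TRUE` they contribute exponential
#' survival terms, i.e. their `(t - t_min)` enters the denominator only.
#'
#' @param durations_s dwell durations (s), all >= `t_min`.
#' @param t_min minimum resolvable dwell (s).
#' @param censored logical vector marking dwells that ran off the trace end.
#' @param include_censored add survival contributions of censored dwells.
#' @param min_n minimum number of uncensored dwells required.
#' @return Object of class `dwell_fit`: `koff` (s^-1), `se`, `n`,
#'   `n_censored`, `t_min`.
#' @export
fit_dwell_exponential <- function(durations_s, t_min = 0, censored = NULL,
                                  include_censored = FALSE, min_n = 20) {
  if (!is.numeric(durations_s) || !length(durations_s)) {
    stop("'durations_s' must be a nonempty numeric vector")
  }
  if (is.null(censored)) censored <- rep(FALSE, length(durations_s))
  if (length(censored) != length(durations_s)) {
    stop("'censored' must match 'durations_s' in length")
  }
  if (any(!is.finite(durations_s)) || any(durations_s < t_min - 1e-12)) {
    stop("all durations must be finite and >= t_min")
  }
  n <- sum(!censored)
  if (n < min_n) {
    stop(sprintf("need at least %d uncensored dwells (got %d)", min_n, n))
  }
  denom <- if (include_censored) sum(durations_s - t_min)
           else sum(durations_s[!censored] - t_min)
  if (denom <= 0) {
    stop("degenerate dwell set: all durations at the truncation point")
  }
  koff <- n / denom
  structure(list(koff = koff, se = koff / sqrt(n), n = n,
                 n_censored = sum(censored), t_min = t_min,
                 include_censored = include_censored),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Dwell-time fit: koff = %.4g +/- %.2g /s (n = %d, %d censored)\n",
              x$koff, x$se, x$n, x$n_censored))
  invisible(x)
}

#' Rate constants from apparent off-rates at two competitor concentrations
#'
#' Under the linear relation \eqn{k_{off}^{obs}(D) = k_{-1} + k_\theta D},
#' the zero-competitor condition gives the intrinsic dissociation rate and
#' the chase condition gives the transfer constant by the difference
#' quotient. A negative difference is clamped to zero with a warning.
#'
#' @param koff_zero apparent off-rate at zero competitor (s^-1).
#' @param koff_D apparent off-rate at competitor concentration `D` (s^-1).
#' @param D competitor concentration (M), > 0.
#' @return List with `k_neg1` (s^-1), `k_theta` (M^-1 s^-1) and their ratio
#'   `ratio_M` (M^-1).
#' @export
estimate_rate_constants <- function(koff_zero, koff_D, D) {
  .check_scalar(koff_zero, "koff_zero")
  .check_scalar(koff_D, "koff_D")
  .check_scalar(D, "D", positive = TRUE)
  k_theta <- (koff_D - koff_zero) / D
  if (k_theta < 0) {
    warning("negative transfer rate clamped to 0", call. = FALSE)
    k_theta <- 0
  }
  list(k_neg1 = koff_zero, k_theta = k_theta,
       ratio_M = if (koff_zero > 0) k_theta / koff_zero else Inf)
}

#' Correct apparent off-rates for photobleaching
#'
#' Photobleaching terminates fluorescence as a competing exponential, so
#' apparent off-rates are inflated additively by the bleach rate and the
#' correction is a subtraction: `koff - k_b`. The fraction of apparent
#' dissociation events attributable to bleaching, `k_b / koff`, is reported
#' per condition.
#'
#' @param koff_obs apparent off-rate(s) (s^-1); vectorised.
#' @param k_b photobleaching rate (s^-1), `0 <= k_b < min(koff_obs)`.
#' @return List with `koff_corrected` and `bleach_fraction`.
#' @export
photobleach_correct <- function(koff_obs, k_b) {
  .check_scalar(k_b, "k_b")
  if (any(!is.finite(koff_obs)) || any(koff_obs < 0)) {
    stop("'koff_obs' must be finite and >= 0")
  }
  if (any(k_b >= koff_obs)) {
    stop("bleach rate cannot equal or exceed the apparent off-rate")
  }
  list(koff_corrected = koff_obs - k_b,
       bleach_fraction = ifelse(koff_obs > 0, k_b / koff_obs, 0))
}

#' Dwell-time analysis across competitor conditions
#'
#' Fits a truncated-exponential rate per condition, applies photobleach
#' correction, and derives the dissociation and transfer rate constants from
#' the zero-competitor and chase conditions.
#'
#' @param dwells data frame with columns `competitor_M`, `duration_s` and
#'   optionally `censored`.
#' @param t_min minimum resolvable dwell (s).
#' @param k_b photobleaching rate (s^-1) to subtract; 0 disables.
#' @inheritParams fit_dwell_exponential
#' @return Object of class `sm_rate_estimate`: per-condition table and
#'   `k_neg1`, `k_theta`, `k_b`.
#' @export
analyze_sm_dwells <- function(dwells, t_min = 0, k_b = 0,
                              include_censored = FALSE, min_n = 20) {
  need <- c("competitor_M", "duration_s")
  if (!all(need %in% names(dwells))) {
    stop("dwells must have columns 'competitor_M' and 'duration_s'")
  }
  cens <- if ("censored" %in% names(dwells)) as.logical(dwells$censored)
          else rep(FALSE, nrow(dwells))
  conds <- sort(unique(dwells$competitor_M))
  if (!0 %in% conds) stop("a zero-competitor condition is required")
  rows <- lapply(conds, function(D) {
    sel <- dwells$competitor_M == D
    f <- fit_dwell_exponential(dwells$duration_s[sel], t_min = t_min,
                               censored = cens[sel],
                               include_censored = include_censored,
                               min_n = min_n)
    koff <- f$koff
    bf <- 0
    if (k_b > 0) {
      pc <- photobleach_correct(koff, k_b)
      koff <- pc$koff_corrected
      bf <- pc$bleach_fraction
    }
    data.frame(competitor_M = D, koff_obs = f$koff, koff_corrected = koff,
               se = f$se, n = f$n, bleach_fraction = bf)
  })
  tab <- do.call(rbind, rows)
  k_neg1 <- tab$koff_corrected[tab$competitor_M == 0]
  chase <- tab[tab$competitor_M > 0, , drop = FALSE]
  k_theta <- if (nrow(chase)) {
    mean(vapply(seq_len(nrow(chase)), function(i) {
      estimate_rate_constants(k_neg1, chase$koff_corrected[i],
                              chase$competitor_M[i])$k_theta
    }, numeric(1)))
  } else NA_real_
  structure(list(per_condition = tab, k_neg1 = k_neg1, k_theta = k_theta,
                 k_b = k_b),
            class = "sm_rate_estimate")
}

#' @export
print.sm_rate_estimate <- function(x, ...) {
  cat("Single-molecule rate estimate:\n")
  print(x$per_condition, digits = 4)
  cat(sprintf("  k_neg1 = %.4g /s, k_theta = %.4g /M/s (k_b = %.3g /s)\n",
              x$k_neg1, x$k_theta, x$k_b))
  invisible(x)
}

#' Classify two-colour direct-transfer events
#'
#' In dual-colour experiments a direct transfer appears as one channel's
#' binding event ending while an event in the other channel begins at the
#' same particle within a short ternary window (the intermediate lives
#' < ~150 ms). An arrival is matched to a departure when
#' `|arrival_start - departure_end| <= window_s`; longer simultaneous
#' double-occupancy or longer gaps are independent binding, not transfer.
#' Detection is symmetric under swapping the two channels.
#'
#' Event tables may carry continuous `start_s`/`end_s` times (as generator
#' ground truth does); these are preferred over frame indices, because a
#' frame interval comparable to the ternary window quantizes the gap and
#' drops genuine sub-frame transfers.
#'
#' @param events_red,events_green event tables (as from [detect_events()])
#'   with columns `particle_id`, `start_frame`, `end_frame` (and optionally
#'   `start_s`, `end_s`).
#' @param frame_interval_s frame interval (s).
#' @param window_s ternary window (s), default 0.15.
#' @return Data frame with one row per transfer: `particle_id`,
#'   `from_channel`, `depart_s`, `to_channel`, `arrive_s`, `gap_s`,
#'   `confidence` (1 at zero gap, 0 at the window edge).
#' @export
detect_transfer_events <- function(events_red, events_green,
                                   frame_interval_s, window_s = 0.15) {
  .check_scalar(frame_interval_s, "frame_interval_s", positive = TRUE)
  .check_scalar(window_s, "window_s", positive = TRUE)
  times <- function(df) {
    if (all(c("start_s", "end_s") %in% names(df))) {
      df[c("particle_id", "start_s", "end_s")]
    } else if (all(c("start_frame", "end_frame") %in% names(df))) {
      data.frame(particle_id = df$particle_id,
                 start_s = df$start_frame * frame_interval_s,
                 end_s = df$end_frame * frame_interval_s)
    } else {
      stop(paste("event tables need columns particle_id plus",
                 "start_frame/end_frame or start_s/end_s"))
    }
  }
  match_dir <- function(from, to, from_name, to_name) {
    out <- list()
    for (i in seq_len(nrow(from))) {
      pid <- from$particle_id[i]
      cand <- to[to$particle_id == pid, , drop = FALSE]
      if (!nrow(cand)) next
      gap <- cand$start_s - from$end_s[i]
      hit <- which(abs(gap) <= window_s)
      for (j in hit) {
        out[[length(out) + 1L]] <- data.frame(
          particle_id = pid, from_channel = from_name,
          depart_s = from$end_s[i], to_channel = to_name,
          arrive_s = cand$start_s[j], gap_s = gap[j],
          confidence = 1 - abs(gap[j]) / window_s,
          stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  events_red <- times(events_red)
  events_green <- times(events_green)
  res <- rbind(match_dir(events_red, events_green, "red", "green"),
               match_dir(events_green, events_red, "green", "red"))
  if (is.null(res)) {
    res <- data.frame(particle_id = character(), from_channel = character(),
                      depart_s = numeric(), to_channel = character(),
                      arrive_s = numeric(), gap_s = numeric(),
                      confidence = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Transfer-event percentage
#'
#' @param transfers number of classified transfer events.
#' @param total_binding_events total number of binding events observed.
#' @return Percentage `100 * transfers / total_binding_events`.
#' @export
transfer_event_fraction <- function(transfers, total_binding_events) {
  .check_scalar(transfers, "transfers")
  .check_scalar(total_binding_events, "total_binding_events")
  if (total_binding_events <= 0) {
    stop("'total_binding_events' must be > 0")
  }
  100 * transfers / total_binding_events
}
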