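#' Hand-off proficiency (HOP) score
#'
#' Normalized propensity for direct transfer: the log10 ratio of an
#' interaction's \eqn{k_\theta / k_{-1}} to a reference ratio, so that 0
#' means average propensity among the reference set, positive means
#' above-average and negative below-average. The natural reference is the
#' fitted zero-intercept slope of a compiled record set
#' ([theta_vs_k1_regression()]); a fixed 1e5 M^-1 preset is the typical
#' cross-study average.
#'
#' Interactions without detectable transfer (`k_theta = 0`, classic
#' competition selected) have no defined score and return `NA`.
#'
#' @param k_neg1 intrinsic dissociation rate constant(s) (s^-1), > 0.
#' @param k_theta direct-transfer rate constant(s) (M^-1 s^-1), >= 0.
#' @param reference_ratio reference \eqn{k_\theta/k_{-1}} (M^-1), > 0.
#' @return Dimensionless score(s); `NA` where `k_theta = 0`.
#' @export
hop_score <- function(k_neg1, k_theta, reference_ratio = 1e5) {
  if (any(k_neg1 <= 0)) stop("'k_neg1' must be > 0")
  if (any(k_theta < 0)) stop("'k_theta' must be >= 0")
  .check_scalar(reference_ratio, "reference_ratio", positive = TRUE)
  ifelse(k_theta > 0,
         log10((k_theta / k_neg1) / reference_ratio),
         NA_real_)
}

#' Zero-intercept regression of transfer versus dissociation rate constants
#'
#' Cross-study correlation of \eqn{k_\theta} against \eqn{k_{-1}} on linear
#' axes with a linear zero-intercept model. The slope is the closed-form
#' \eqn{\sum x y / \sum x^2}; R^2 uses the uncentered definition
#' \eqn{1 - RSS/\sum y^2} appropriate for through-origin regression (the
#' centered alternative is also reported). Records with `k_theta = 0`
#' (classic competition) are excluded.
#'
#' @param records data frame with columns `k_neg1` and `k_theta`.
#' @param r_squared `"uncentered"` (default) or `"centered"`.
#' @return List with `slope` (M^-1), `r_squared`, `n_used`, `n_excluded`.
#' @export
theta_vs_k1_regression <- function(records,
                                   r_squared = c("uncentered", "centered")) {
  r_squared <- match.arg(r_squared)
  if (!all(c("k_neg1", "k_theta") %in% names(records))) {
    stop("records must have columns 'k_neg1' and 'k_theta'")
  }
  use <- is.finite(records$k_neg1) & is.finite(records$k_theta) &
    records$k_neg1 > 0 & records$k_theta > 0
  x <- records$k_neg1[use]
  y <- records$k_theta[use]
  if (length(x) < 3) {
    stop("need at least 3 records with k_theta > 0")
  }
  slope <- sum(x * y) / sum(x * x)
  rss <- sum((y - slope * x)^2)
  r2 <- if (r_squared == "uncentered") 1 - rss / sum(y * y)
        else 1 - rss / sum((y - mean(y))^2)
  list(slope = slope, r_squared = r2, n_used = length(x),
       n_excluded = sum(!use))
}

#' Competitor concentration of equal pathway flux
#'
#' The concentration at which flux through the direct-transfer pathway
#' equals flux through classic dissociation, i.e. where
#' [flux_partition()] is exactly 0.5: \eqn{D_{1/2} = k_{-1}/k_\theta}.
#' With no transfer the crossover is never reached (`Inf`).
#'
#' @inheritParams hop_score
#' @return Concentration(s) (M); `Inf` where `k_theta = 0`.
#' @export
flux_crossover <- function(k_neg1, k_theta) {
  if (any(k_neg1 <= 0)) stop("'k_neg1' must be > 0")
  if (any(k_theta < 0)) stop("'k_theta' must be >= 0")
  ifelse(k_theta > 0, k_neg1 / k_theta, Inf)
}

#' Assemble a cross-interaction summary table
#'
#' Collects FP and/or single-molecule fit results into one row per
#' interaction with the apparent K_d, rate constants, HOP score and
#' model-selection footnotes. Replicate results under the same label are
#' aggregated as mean +/- SD. For classic-selected interactions the transfer
#' constant is 0 and the HOP score is `NA` (not applicable).
#'
#' @param results list of result entries; each entry is a list with elements
#'   `label` (character), one of `competition` (a `competition_fit`) or
#'   `sm` (an `sm_rate_estimate`) or explicit `k_neg1`/`k_theta`, and
#'   optionally `kd` (a `kd_fit`), `temperature_C`, `carrier`, `source`.
#' @param reference_ratio HOP reference (M^-1); `NULL` (default) fits the
#'   zero-intercept slope of the assembled records when at least three have
#'   `k_theta > 0`, else falls back to the fixed 1e5 M^-1 preset.
#' @return Data frame of class `synthesis_table`, one row per label.
#' @export
build_summary_table <- function(results, reference_ratio = NULL) {
  if (!length(results)) stop("need at least one result")
  one <- function(r) {
    if (!is.null(r$competition)) {
      stopifnot(inherits(r$competition, "competition_fit"))
      kn <- r$competition$k_neg1P
      kt <- r$competition$k_thetaD
      model <- r$competition$selected
      notes <- character()
      if (r$competition$indeterminate) notes <- c(notes, "BIC indeterminate")
      if (model == "classic") notes <- c(notes, "BIC favored classic")
    } else if (!is.null(r$sm)) {
      stopifnot(inherits(r$sm, "sm_rate_estimate"))
      kn <- r$sm$k_neg1; kt <- r$sm$k_theta
      model <- if (kt > 0) "direct_transfer" else "classic"
      notes <- "single-molecule"
    } else {
      kn <- r$k_neg1; kt <- r$k_theta
      model <- if (kt > 0) "direct_transfer" else "classic"
      notes <- character()
    }
    if (!is.null(r$carrier) && nzchar(r$carrier)) {
      notes <- c(notes, paste0("carrier: ", r$carrier))
    }
    data.frame(label = r$label,
               temperature_C = if (!is.null(r$temperature_C))
                 r$temperature_C else NA_real_,
               K_d_app_M = if (!is.null(r$kd)) r$kd$K_d else NA_real_,
               k_neg1 = kn, k_theta = kt, model = model,
               source = if (!is.null(r$source)) r$source else "this-study",
               footnotes = paste(notes, collapse = "; "),
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(results, one))
  agg <- do.call(rbind, lapply(split(rows, rows$label), function(g) {
    out <- g[1, ]
    out$K_d_app_M <- mean(g$K_d_app_M)
    out$k_neg1 <- mean(g$k_neg1)
    out$k_theta <- mean(g$k_theta)
    out$k_neg1_sd <- if (nrow(g) > 1) sd(g$k_neg1) else NA_real_
    out$k_theta_sd <- if (nrow(g) > 1) sd(g$k_theta) else NA_real_
    out$n_experiments <- nrow(g)
    out
  }))
  if (is.null(reference_ratio)) {
    usable <- sum(agg$k_theta > 0 & agg$k_neg1 > 0)
    reference_ratio <- if (usable >= 3) {
      theta_vs_k1_regression(agg)$slope
    } else 1e5
  }
  agg$HOP <- hop_score(agg$k_neg1, pmax(agg$k_theta, 0), reference_ratio)
  attr(agg, "reference_ratio") <- reference_ratio
  rownames(agg) <- NULL
  class(agg) <- c("synthesis_table", "data.frame")
  agg
}

#' @export
print.synthesis_table <- function(x, ...) {
  cat(sprintf("Synthesis table (%d interactions, HOP reference %.3g /M):\n",
              nrow(x), attr(x, "reference_ratio")))
  print.data.frame(x, digits = 3)
  invisible(x)
}
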