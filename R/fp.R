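#' Normalize FP chase time courses to fraction of initial complex
#'
#' Maps raw polarization readings onto \[0, 1\] using the global signal range
#' across all competitor concentrations and replicates of a plate, so that 1
#' corresponds to the fully bound starting complex and 0 to free labelled
#' ligand. Three anchor estimators are available:
#' \describe{
#'   \item{plateau (default)}{condition-structured means: the upper anchor
#'     is the mean signal over the earliest quarter of the highest-signal
#'     condition (the un-chased complex), the lower anchor the mean over the
#'     latest quarter of the lowest-signal condition (the fully chased
#'     plateau). Averaging makes the anchors unbiased under read noise.}
#'   \item{range}{exact global min/max. Simple, but the extremes of
#'     thousands of noisy reads sit several noise SDs outside the true
#'     signal range, which compresses every normalized amplitude (and hence
#'     every initial-slope off-rate) by a few percent.}
#'   \item{quantile}{1st/99th percentiles; resists isolated outlier wells
#'     but retains part of the extreme-value bias.}
#' }
#'
#' @param plate long-format data frame with columns `condition_id`,
#'   `competitor_M`, `replicate`, `time_s`, `polarization_mP`.
#' @param anchors anchor estimator, see above.
#' @param min_range_mP minimum acceptable global signal range; a flatter
#'   plate is degenerate data and raises an error.
#' @param probs quantile anchors used when `anchors = "quantile"`.
#' @return Data frame with the identifying columns of `plate` plus
#'   `fraction`; the anchors are recorded in attribute `"anchors"`.
#' @export
normalize_polarization <- function(plate,
                                   anchors = c("plateau", "range",
                                               "quantile"),
                                   min_range_mP = 5, probs = c(0.01, 0.99)) {
  anchors <- match.arg(anchors)
  .check_plate(plate)
  p <- plate$polarization_mP
  if (anchors == "range") {
    lo <- min(p); hi <- max(p)
  } else if (anchors == "quantile") {
    q <- quantile(p, probs, names = FALSE)
    lo <- q[1]; hi <- q[2]
  } else {
    cm <- vapply(split(p, plate$condition_id), mean, numeric(1))
    early_mean <- function(id, late = FALSE) {
      sel <- plate$condition_id == id
      tt <- plate$time_s[sel]
      qt <- quantile(tt, if (late) 0.75 else 0.25, names = FALSE)
      mean(p[sel][if (late) tt >= qt else tt <= qt])
    }
    hi <- early_mean(names(cm)[which.max(cm)])
    late <- vapply(names(cm), early_mean, numeric(1), late = TRUE)
    lo <- min(late)
  }
  if (hi - lo < min_range_mP) {
    stop(sprintf(
      "degenerate data: polarization range %.3g mP is below %.3g mP",
      hi - lo, min_range_mP))
  }
  out <- plate[c("condition_id", "competitor_M", "replicate", "time_s")]
  out$fraction <- (p - lo) / (hi - lo)
  attr(out, "anchors") <- c(P_min_mP = lo, P_max_mP = hi)
  out
}

.check_plate <- function(plate) {
  need <- c("condition_id", "competitor_M", "replicate", "time_s",
            "polarization_mP")
  miss <- setdiff(need, names(plate))
  if (length(miss)) {
    stop("plate is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(plate$polarization_mP))) {
    stop("polarization readings must be finite")
  }
  for (key in split(seq_len(nrow(plate)),
                    interaction(plate$condition_id, plate$replicate,
                                drop = TRUE))) {
    tt <- plate$time_s[key]
    if (any(diff(tt) <= 0)) {
      stop("times within a condition/replicate must be strictly increasing")
    }
  }
  invisible(TRUE)
}

#' One-phase exponential decay regression
#'
#' Least-squares fit of \eqn{F(t) = A e^{-kt} + c} to a normalized decay.
#' The model is separable: for fixed `k` the amplitude and plateau are exact
#' linear least-squares solutions, so the fit reduces to a one-dimensional
#' profiled optimisation over `k`, initialised on a deterministic grid of
#' `n_starts` log-spaced decay rates and refined by Brent search (no RNG is
#' involved in fitting).
#'
#' Fits whose decay is mostly complete before the first read (amplitude
#' < 0.2) or whose plateau is unresolved within the observation window
#' (`k * span < 1`) are flagged `partial` and should be reported with a
#' caveat rather than dropped.
#'
#' When the value of the decay at reaction initiation is known — in a chase
#' every condition starts from the same pre-equilibrated complex, which the
#' normalization maps to 1 — supplying it as `f0` constrains
#' \eqn{A + c = f_0}. This removes the strong k--A correlation that
#' otherwise arises when a dead time hides the early decay (the fit must
#' back-extrapolate through the delay), at the cost of assuming the anchor
#' is right.
#'
#' @param time_s,fraction numeric vectors (s, dimensionless).
#' @param min_points minimum number of timepoints required.
#' @param n_starts number of deterministic log-spaced initial rates.
#' @param f0 optional known value of the decay at t = 0; `NULL` (default)
#'   leaves the amplitude and plateau free.
#' @return Object of class `exp_fit` with elements `k` (s^-1), `amplitude`,
#'   `plateau`, `rss`, `n`, `converged`, `partial`.
#' @export
fit_exponential_decay <- function(time_s, fraction, min_points = 5,
                                  n_starts = 8, f0 = NULL) {
  if (length(time_s) != length(fraction)) {
    stop("'time_s' and 'fraction' must have equal length")
  }
  ok <- is.finite(time_s) & is.finite(fraction)
  t0 <- time_s[ok]; y <- fraction[ok]
  if (length(t0) < min_points) {
    stop(sprintf("need at least %d finite timepoints", min_points))
  }
  span <- diff(range(t0))
  if (span <= 0) stop("timepoints must span a nonzero interval")

  prof <- function(k) {
    x <- exp(-k * t0)
    if (is.null(f0)) {
      X <- cbind(x, 1)
      fit <- tryCatch(qr.solve(X, y), error = function(e) NULL)
      if (is.null(fit)) return(list(rss = Inf, A = NA_real_, c = NA_real_))
      r <- y - X %*% fit
      list(rss = sum(r * r), A = unname(fit[1]), c = unname(fit[2]))
    } else {
      # A + c = f0: F(t) = f0*x + c*(1 - x), linear in c alone
      u <- 1 - x
      cc <- sum((y - f0 * x) * u) / max(sum(u * u), 1e-300)
      r <- y - f0 * x - cc * u
      list(rss = sum(r * r), A = f0 - cc, c = cc)
    }
  }
  kgrid <- 10^seq(log10(0.05 / span), log10(50 / span), length.out = n_starts)
  rssg <- vapply(kgrid, function(k) prof(k)$rss, numeric(1))
  i <- which.min(rssg)
  lo <- log(kgrid[max(1L, i - 1L)])
  hi <- log(kgrid[min(length(kgrid), i + 1L)])
  opt <- optimize(function(lk) prof(exp(lk))$rss, c(lo, hi), tol = 1e-12)
  # one bisection polish pass: Brent's interval may sit on a grid shoulder
  opt2 <- optimize(function(lk) prof(exp(lk))$rss,
                   opt$minimum + c(-0.05, 0.05), tol = 1e-13)
  if (opt2$objective < opt$objective) opt <- opt2
  k <- exp(opt$minimum)
  # final linear-scale refinement: Brent's attainable accuracy is
  # sqrt(eps) * |x|, which is far tighter on k than on log k
  opt3 <- optimize(function(kk) prof(kk)$rss,
                   k * c(0.99, 1.01), tol = k * 1e-10)
  if (opt3$objective <= prof(k)$rss) k <- opt3$minimum
  best <- prof(k)
  converged <- is.finite(best$rss) && is.finite(best$A) && is.finite(best$c)
  structure(list(k = k, amplitude = best$A, plateau = best$c,
                 rss = best$rss, n = length(t0), converged = converged,
                 partial = converged &&
                   (abs(best$A) < 0.2 || k * span < 1)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit: k = %.4g /s, A = %.3g, plateau = %.3g (n = %d%s)\n",
    x$k, x$amplitude, x$plateau, x$n,
    if (isTRUE(x$partial)) ", partial" else ""))
  invisible(x)
}

#' Apparent off-rate from an exponential decay fit
#'
#' Default convention is the initial slope of the normalized decay,
#' \eqn{|dF/dt|_{t=0} = k \cdot A}, which equals the true initial
#' dissociation flux even when rebinding leaves a plateau. The alternative
#' convention reports the bare relaxation rate `k`; the two agree in the
#' full-dissociation limit (A = 1, c = 0).
#'
#' @param fit an `exp_fit` from [fit_exponential_decay()].
#' @param convention `"initial_slope"` (k*A, default) or `"rate"` (k).
#' @return Apparent off-rate (s^-1).
#' @export
koff_obs_from_fit <- function(fit, convention = c("initial_slope", "rate")) {
  stopifnot(inherits(fit, "exp_fit"))
  convention <- match.arg(convention)
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  if (convention == "initial_slope") fit$k * abs(fit$amplitude) else fit$k
}

#' Apparent off-rate profile of an FPCD plate
#'
#' Runs the plate-level chase analysis: global normalization, per-well
#' one-phase exponential regression, off-rate extraction, and aggregation to
#' mean +/- SD across replicates for each competitor concentration.
#'
#' Because every chase condition starts from the same pre-equilibrated
#' complex, whose normalized value is 1 by construction of the anchors, the
#' per-well fits are anchored at `F(0) = 1` by default (`f0 = 1`); set
#' `f0 = NULL` for fully free three-parameter fits.
#'
#' @inheritParams normalize_polarization
#' @inheritParams koff_obs_from_fit
#' @param min_points minimum timepoints per well.
#' @param f0 known normalized value at reaction initiation, or `NULL`.
#' @return Object of class `koff_profile`: list with `profile` (data frame
#'   `competitor_M`, `koff_obs`, `sd`, `n_rep`), `fits` (per-well fit table)
#'   and the conventions used.
#' @export
fpcd_koff_profile <- function(plate,
                              convention = c("initial_slope", "rate"),
                              anchors = c("plateau", "range", "quantile"),
                              min_range_mP = 5, min_points = 5, f0 = 1) {
  convention <- match.arg(convention)
  anchors <- match.arg(anchors)
  norm <- normalize_polarization(plate, anchors = anchors,
                                 min_range_mP = min_range_mP)
  keys <- unique(norm[c("condition_id", "competitor_M", "replicate")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- norm$condition_id == keys$condition_id[i] &
      norm$replicate == keys$replicate[i]
    f <- fit_exponential_decay(norm$time_s[sel], norm$fraction[sel],
                               min_points = min_points, f0 = f0)
    koff <- if (f$converged) koff_obs_from_fit(f, convention) else NA_real_
    if (!f$converged) {
      warning(sprintf("well %s/%s did not converge; excluded",
                      keys$condition_id[i], keys$replicate[i]),
              call. = FALSE)
    }
    rows[[i]] <- data.frame(
      condition_id = keys$condition_id[i],
      competitor_M = keys$competitor_M[i],
      replicate = keys$replicate[i],
      k = f$k, amplitude = f$amplitude, plateau = f$plateau, rss = f$rss,
      converged = f$converged, partial = f$partial, koff_obs = koff,
      stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, rows)
  okf <- fits[fits$converged & is.finite(fits$koff_obs), ]
  agg <- aggregate(koff_obs ~ competitor_M, data = okf, FUN = mean)
  agg$sd <- aggregate(koff_obs ~ competitor_M, data = okf, FUN = sd)$koff_obs
  agg$n_rep <- aggregate(koff_obs ~ competitor_M, data = okf,
                         FUN = length)$koff_obs
  agg <- agg[order(agg$competitor_M), ]
  rownames(agg) <- NULL
  structure(list(profile = agg, fits = fits, convention = convention,
                 anchors = attr(norm, "anchors")),
            class = "koff_profile")
}

#' @export
print.koff_profile <- function(x, ...) {
  cat(sprintf("Apparent off-rate profile: %d concentrations, convention %s\n",
              nrow(x$profile), x$convention))
  print(x$profile, digits = 4)
  invisible(x)
}

#' Classic-competition versus direct-transfer regression with BIC selection
#'
#' Weighted nonlinear least squares of the apparent off-rate profile against
#' the two chase models
#' \deqn{classic: k_{off}^{obs}(D) = k_{-1P} \frac{D}{D + K_c}, \qquad
#'   direct\ transfer: k_{off}^{obs}(D) = k_{-1P}\frac{D}{D + K_c}
#'     + k_{\theta D} D,}
#' where the capture constant \eqn{K_c} is a free parameter (the association
#' constants it is built from are not identifiable from chase data alone).
#' Both models are separable in their linear coefficients, so fitting is a
#' profiled search over \eqn{K_c} on a deterministic log grid with Brent
#' refinement; the linear coefficients are constrained nonnegative.
#'
#' Models are compared by \eqn{BIC = n \ln(RSS/n) + p \ln n} with p = 2
#' (classic) or 3 (direct transfer). A BIC difference within `tie_margin`
#' is reported as indeterminate and defaults to the simpler classic model.
#' When the classic model is selected the transfer constant is reported as 0.
#'
#' @param profile a `koff_profile` object or a data frame with columns
#'   `competitor_M`, `koff_obs` and optionally `sd`, `n_rep`.
#' @param weighting `"auto"` uses inverse-variance weights from replicate
#'   SDs when every concentration has >= 3 replicates, else unweighted;
#'   `"none"` forces unweighted.
#' @param tie_margin BIC difference below which the comparison is
#'   indeterminate.
#' @return Object of class `competition_fit` with elements `classic`,
#'   `direct_transfer` (each a list with parameters, `rss`, `bic`, `se`),
#'   `selected`, `indeterminate`, `delta_bic`, and the selected-model
#'   parameters `k_neg1P`, `K_c`, `k_thetaD`.
#' @export
fit_competition_models <- function(profile, weighting = c("auto", "none"),
                                   tie_margin = 2) {
  weighting <- match.arg(weighting)
  df <- if (inherits(profile, "koff_profile")) profile$profile else profile
  if (!all(c("competitor_M", "koff_obs") %in% names(df))) {
    stop("profile must have columns 'competitor_M' and 'koff_obs'")
  }
  df <- df[is.finite(df$koff_obs), ]
  D <- df$competitor_M
  y <- df$koff_obs
  n <- length(y)
  Dnz <- D[D > 0]
  if (length(unique(D)) < 4 || length(Dnz) < 2 ||
      max(Dnz) / min(Dnz) < 10) {
    stop(paste("competition fitting needs >= 4 competitor concentrations",
               "spanning a >= 10-fold range"))
  }
  w <- rep(1, n)
  if (weighting == "auto" && !is.null(df$sd) && !is.null(df$n_rep) &&
      all(df$n_rep >= 3) && all(is.finite(df$sd))) {
    s <- df$sd
    s[s <= 0] <- min(s[s > 0], na.rm = TRUE)
    if (all(is.finite(s)) && all(s > 0)) w <- 1 / s^2
  }

  nonneg_ls <- function(X, y, w) {
    # tiny exact nonnegative LS: try full solution, then each face
    sw <- sqrt(w)
    Xw <- X * sw; yw <- y * sw
    cand <- list()
    co <- tryCatch(qr.solve(Xw, yw), error = function(e) NULL)
    if (!is.null(co) && all(co >= 0)) cand <- c(cand, list(co))
    for (j in seq_len(ncol(X))) {
      cj <- numeric(ncol(X))
      xj <- Xw[, j]
      bj <- sum(xj * yw) / sum(xj * xj)
      cj[j] <- max(bj, 0)
      cand <- c(cand, list(cj))
    }
    cand <- c(cand, list(numeric(ncol(X))))
    rss <- vapply(cand, function(b) sum((yw - Xw %*% b)^2), numeric(1))
    b <- cand[[which.min(rss)]]
    list(coef = b, rss = min(rss))
  }

  fit_model <- function(transfer) {
    basis <- function(Kc) {
      x1 <- ifelse(D > 0, D / (D + Kc), 0)
      if (transfer) cbind(x1, D) else cbind(x1)
    }
    obj <- function(lKc) nonneg_ls(basis(exp(lKc)), y, w)$rss
    lgrid <- log(10^seq(log10(min(Dnz)) - 4, log10(max(D)) + 3,
                        length.out = 41))
    rg <- vapply(lgrid, obj, numeric(1))
    i <- which.min(rg)
    lo <- lgrid[max(1L, i - 1L)]; hi <- lgrid[min(length(lgrid), i + 1L)]
    opt <- optimize(obj, c(lo, hi), tol = 1e-10)
    Kc <- exp(opt$minimum)
    ls <- nonneg_ls(basis(Kc), y, w)
    p <- if (transfer) 3L else 2L
    pars <- c(k_neg1P = unname(ls$coef[1]), K_c = Kc,
              k_thetaD = if (transfer) unname(ls$coef[2]))
    model <- function(q) {
      x1 <- ifelse(D > 0, D / (D + q[2]), 0)
      q[1] * x1 + if (transfer) q[3] * D else 0
    }
    se <- .wls_se(model, unname(pars), y, w, ls$rss, p)
    # RSS below the floor is numerical noise (both models can reach it on
    # noiseless data); flooring keeps the BIC comparison meaningful there
    floor_rss <- n * (1e-8 * max(abs(y), 1e-30))^2
    bic <- n * log(max(ls$rss, floor_rss) / n) + p * log(n)
    list(pars = pars, rss = ls$rss, bic = bic, se = se, p = p)
  }

  cl <- fit_model(transfer = FALSE)
  dt <- fit_model(transfer = TRUE)
  if (dt$pars[["k_thetaD"]] == 0) {
    warning(paste("direct-transfer fit: k_thetaD hit its lower bound 0;",
                  "models are ambiguous"), call. = FALSE)
  }
  delta <- cl$bic - dt$bic   # > 0 favours direct transfer
  indeterminate <- abs(delta) < tie_margin
  selected <- if (delta > tie_margin) "direct_transfer" else "classic"
  sel <- if (selected == "direct_transfer") dt else cl
  structure(list(
    classic = list(k_neg1P = cl$pars[["k_neg1P"]], K_c = cl$pars[["K_c"]],
                   rss = cl$rss, bic = cl$bic, se = cl$se),
    direct_transfer = list(k_neg1P = dt$pars[["k_neg1P"]],
                           K_c = dt$pars[["K_c"]],
                           k_thetaD = dt$pars[["k_thetaD"]],
                           rss = dt$rss, bic = dt$bic, se = dt$se),
    selected = selected, indeterminate = indeterminate, delta_bic = delta,
    k_neg1P = sel$pars[["k_neg1P"]], K_c = sel$pars[["K_c"]],
    k_thetaD = if (selected == "direct_transfer")
      dt$pars[["k_thetaD"]] else 0,
    n = n, weighted = !all(w == w[1])),
    class = "competition_fit")
}

# parameter standard errors from the weighted Gauss-Newton approximation
.wls_se <- function(model, pars, y, w, rss, p) {
  n <- length(y)
  if (n <= p) return(rep(NA_real_, length(pars)))
  J <- matrix(NA_real_, n, length(pars))
  f0 <- model(pars)
  for (j in seq_along(pars)) {
    h <- max(abs(pars[j]), 1e-12) * 1e-6
    pj <- pars; pj[j] <- pj[j] + h
    J[, j] <- (model(pj) - f0) / h
  }
  JtWJ <- crossprod(J * sqrt(w))
  v <- tryCatch(diag(solve(JtWJ)) * rss / (n - p),
                error = function(e) rep(NA_real_, length(pars)))
  sqrt(pmax(v, 0))
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Competition model comparison (BIC):\n")
  cat(sprintf("  classic:         k_neg1P = %.4g /s, K_c = %.3g M, BIC = %.2f\n",
              x$classic$k_neg1P, x$classic$K_c, x$classic$bic))
  cat(sprintf(
    "  direct transfer: k_neg1P = %.4g /s, k_thetaD = %.4g /M/s, BIC = %.2f\n",
    x$direct_transfer$k_neg1P, x$direct_transfer$k_thetaD,
    x$direct_transfer$bic))
  cat(sprintf("  selected: %s (delta BIC = %.2f%s)\n", x$selected,
              x$delta_bic,
              if (x$indeterminate) ", indeterminate: defaulted to classic"
              else ""))
  invisible(x)
}

#' End-to-end FPCD plate analysis
#'
#' Convenience wrapper running [fpcd_koff_profile()] followed by
#' [fit_competition_models()]. Rerunning on identical input with identical
#' settings is bit-identical (no RNG is used anywhere in fitting).
#'
#' @inheritParams fpcd_koff_profile
#' @inheritParams fit_competition_models
#' @return List of class `fpcd_analysis` with elements `profile`
#'   (a `koff_profile`) and `competition` (a `competition_fit`).
#' @export
analyze_fpcd <- function(plate, convention = c("initial_slope", "rate"),
                         anchors = c("plateau", "range", "quantile"),
                         weighting = c("auto", "none"),
                         min_range_mP = 5, min_points = 5, tie_margin = 2,
                         f0 = 1) {
  prof <- fpcd_koff_profile(plate, convention = match.arg(convention),
                            anchors = match.arg(anchors),
                            min_range_mP = min_range_mP,
                            min_points = min_points, f0 = f0)
  comp <- fit_competition_models(prof, weighting = match.arg(weighting),
                                 tie_margin = tie_margin)
  structure(list(profile = prof, competition = comp),
            class = "fpcd_analysis")
}

#' @export
print.fpcd_analysis <- function(x, ...) {
  print(x$profile)
  print(x$competition)
  invisible(x)
}
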