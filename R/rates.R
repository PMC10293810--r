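#' Reaction-scheme rate constants
#'
#' Container for the rate constants of the protein (E) / labelled ligand (P) /
#' unlabelled competitor (D) competition scheme. The simplified scheme has
#' five species \{E, P, D, EP, ED\} and six rate constants: association and
#' intrinsic dissociation for each binary complex, plus two second-order
#' direct-transfer constants describing concerted exchange through a
#' transient ternary intermediate:
#' \deqn{EP + D \rightarrow ED + P \quad (k_{\theta D}), \qquad
#'       ED + P \rightarrow EP + D \quad (k_{\theta P}).}
#' Units are molar and seconds throughout.
#'
#' When `k_thetaP` is omitted it is derived from the thermodynamic cycle
#' \eqn{k_{\theta D}/k_{\theta P} = K_{dP}/K_{dD}}, so that transfer is a
#' kinetic shortcut which leaves all equilibria unchanged. Supplying an
#' inconsistent pair is allowed (experimentally fitted transfer constants
#' are not constrained this way) but triggers a warning, or an error when
#' `consistency = "error"`.
#'
#' @param k1P association rate constant of ligand P (M^-1 s^-1), > 0.
#' @param k_neg1P intrinsic dissociation rate constant of EP (s^-1).
#' @param k1D association rate constant of competitor D (M^-1 s^-1), > 0.
#' @param k_neg1D intrinsic dissociation rate constant of ED (s^-1).
#' @param k_thetaD direct-transfer rate constant EP + D -> ED + P (M^-1 s^-1).
#' @param k_thetaP direct-transfer rate constant ED + P -> EP + D (M^-1 s^-1),
#'   or `NULL` to derive the thermodynamically consistent value.
#' @param identical_species if `TRUE`, P and D are the same molecule apart
#'   from the fluorophore: the D-side constants are forced equal to the
#'   P-side ones and `k_thetaP = k_thetaD`.
#' @param consistency what to do when a supplied `k_thetaP` violates the
#'   thermodynamic cycle: warn (default), error, or skip the check.
#' @param tol relative tolerance of the consistency check.
#'
#' @return An object of class `rate_constants`: a named list with elements
#'   `k1P`, `k_neg1P`, `k1D`, `k_neg1D`, `k_thetaD`, `k_thetaP`.
#' @seealso [dissociation_constants()], [simulate_scheme()]
#' @examples
#' r <- rate_constants(k1P = 7.9e5, k_neg1P = 7e-3, k_thetaD = 1500,
#'                     identical_species = TRUE)
#' dissociation_constants(r)
#' @export
rate_constants <- function(k1P, k_neg1P, k1D = k1P, k_neg1D = k_neg1P,
                           k_thetaD = 0, k_thetaP = NULL,
                           identical_species = FALSE,
                           consistency = c("warn", "error", "none"),
                           tol = 0.01) {
  consistency <- match.arg(consistency)
  if (identical_species) {
    k1D <- k1P
    k_neg1D <- k_neg1P
    if (!is.null(k_thetaP) && !isTRUE(all.equal(k_thetaP, k_thetaD))) {
      stop("identical_species = TRUE requires k_thetaP = k_thetaD")
    }
    k_thetaP <- k_thetaD
  }
  .check_scalar(k1P, "k1P", positive = TRUE)
  .check_scalar(k1D, "k1D", positive = TRUE)
  .check_scalar(k_neg1P, "k_neg1P")
  .check_scalar(k_neg1D, "k_neg1D")
  .check_scalar(k_thetaD, "k_thetaD")
  KdP <- k_neg1P / k1P
  KdD <- k_neg1D / k1D
  if (is.null(k_thetaP)) {
    # detailed-balance completion of the transfer cycle
    k_thetaP <- if (k_thetaD > 0 && KdP > 0) k_thetaD * KdD / KdP else 0
  }
  .check_scalar(k_thetaP, "k_thetaP")
  if (consistency != "none" && k_thetaD > 0 && k_thetaP > 0 &&
      KdP > 0 && KdD > 0) {
    ratio <- (k_thetaD / k_thetaP) / (KdP / KdD)
    if (abs(ratio - 1) > tol) {
      msg <- sprintf(paste0(
        "transfer constants are thermodynamically inconsistent: ",
        "k_thetaD/k_thetaP = %.3g but K_dP/K_dD = %.3g"),
        k_thetaD / k_thetaP, KdP / KdD)
      if (consistency == "error") stop(msg) else warning(msg, call. = FALSE)
    }
  }
  structure(
    list(k1P = k1P, k_neg1P = k_neg1P, k1D = k1D, k_neg1D = k_neg1D,
         k_thetaD = k_thetaD, k_thetaP = k_thetaP),
    class = "rate_constants")
}

#' Equilibrium dissociation constants implied by a rate-constant set
#'
#' @param rates a [rate_constants()] object.
#' @return Named numeric vector `c(K_dP, K_dD)` in molar.
#' @export
dissociation_constants <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  c(K_dP = rates$k_neg1P / rates$k1P, K_dD = rates$k_neg1D / rates$k1D)
}

#' @export
print.rate_constants <- function(x, ...) {
  kd <- dissociation_constants(x)
  cat("Rate constants (M, s):\n")
  cat(sprintf("  k1P     = %-10.4g k_neg1P = %-10.4g (K_dP = %.4g M)\n",
              x$k1P, x$k_neg1P, kd[["K_dP"]]))
  cat(sprintf("  k1D     = %-10.4g k_neg1D = %-10.4g (K_dD = %.4g M)\n",
              x$k1D, x$k_neg1D, kd[["K_dD"]]))
  cat(sprintf("  k_thetaD = %-9.4g k_thetaP = %.4g\n", x$k_thetaD, x$k_thetaP))
  invisible(x)
}

#' Total species concentrations of a competition reaction
#'
#' @param E_total total protein functional units (M).
#' @param P_total total labelled ligand (M).
#' @param D_total total unlabelled competitor (M).
#' @return An object of class `reaction_totals`.
#' @export
reaction_totals <- function(E_total, P_total, D_total = 0) {
  .check_scalar(E_total, "E_total")
  .check_scalar(P_total, "P_total")
  .check_scalar(D_total, "D_total")
  structure(list(E_total = E_total, P_total = P_total, D_total = D_total),
            class = "reaction_totals")
}

#' @export
print.reaction_totals <- function(x, ...) {
  cat(sprintf("Totals (M): E = %.4g, P = %.4g, D = %.4g\n",
              x$E_total, x$P_total, x$D_total))
  invisible(x)
}

# scalar validation: finite, length 1, >= 0 (or > 0)
.check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (!positive && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(TRUE)
}
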