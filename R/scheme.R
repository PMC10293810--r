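#' Integrate the competition reaction scheme
#'
#' Deterministic mass-action integration of the protein/ligand/competitor
#' competition scheme. The `"simplified"` variant tracks the five species
#' \{E, P, D, EP, ED\} with direct transfer as a concerted bimolecular step.
#' The `"complete"` variant additionally resolves partially associated
#' complexes EP* and ED* and a transient two-polynucleotide ternary species T:
#' \preformatted{
#'   E + P <-> EP*        (k1P, 2 k_neg1P)
#'   EP  <-> EP*          (lambda, lambda)
#'   EP* + D <-> T        (4 k_thetaD, lambda)
#'   T  -> ED* + P        (lambda)
#'   ... and symmetrically for the D side.
#' }
#' The micro-rates are constructed so that in the fast-exchange limit
#' (`exchange_rate` much larger than every other first-order rate) the total
#' bound pools obey the simplified scheme with the supplied effective
#' constants; see the methods vignette for the derivation.
#'
#' @param rates a [rate_constants()] object (effective constants).
#' @param totals a [reaction_totals()] object.
#' @param times numeric vector of output times (s), nonnegative, nondecreasing.
#' @param variant `"simplified"` (default) or `"complete"`.
#' @param state0 optional named vector of initial concentrations (M). Must be
#'   consistent with `totals` to 1e-6 relative. Default: everything free.
#' @param exchange_rate opening/closing rate lambda (s^-1) of the partial
#'   states (complete variant only). Default: 100x the largest other
#'   (pseudo-)first-order rate in the system.
#' @param rtol,atol relative / absolute integrator tolerances. The default
#'   stiff-capable `lsoda` settings (1e-8, 1e-12 M) keep mass conservation
#'   below 1e-8 relative.
#'
#' @return An object of class `time_course`: list with `times`, `states`
#'   (matrix, one row per time, one column per species), `variant`, `rates`,
#'   `totals`. Use [bound_ligand()] for the labelled bound pool and
#'   [as.data.frame.time_course()] for a tidy table.
#' @export
simulate_scheme <- function(rates, totals, times,
                            variant = c("simplified", "complete"),
                            state0 = NULL, exchange_rate = NULL,
                            rtol = 1e-8, atol = 1e-12) {
  variant <- match.arg(variant)
  stopifnot(inherits(rates, "rate_constants"),
            inherits(totals, "reaction_totals"))
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop("'times' must be a nonempty numeric vector")
  }
  if (any(times < 0) || is.unsorted(times)) {
    stop("'times' must be nonnegative and nondecreasing")
  }

  species <- c("E", "P", "D", "EP", "ED")
  if (variant == "complete") species <- c(species, "EPs", "EDs", "T")

  y0 <- setNames(numeric(length(species)), species)
  if (is.null(state0)) {
    y0["E"] <- totals$E_total
    y0["P"] <- totals$P_total
    y0["D"] <- totals$D_total
  } else {
    if (is.null(names(state0)) || !all(names(state0) %in% species)) {
      stop("'state0' must be named with species of the chosen variant")
    }
    if (any(state0 < 0)) stop("'state0' concentrations must be >= 0")
    y0[names(state0)] <- state0
    tot <- .species_totals(y0, variant)
    for (nm in c("E_total", "P_total", "D_total")) {
      ref <- totals[[nm]]
      if (abs(tot[[nm]] - ref) > 1e-6 * max(ref, 1e-15)) {
        stop(sprintf("state0 is inconsistent with totals (%s)", nm))
      }
    }
  }

  parms <- unclass(rates)
  if (variant == "complete") {
    if (is.null(exchange_rate)) {
      fo <- c(2 * rates$k_neg1P, 2 * rates$k_neg1D,
              rates$k1P * max(totals$E_total, totals$P_total),
              rates$k1D * max(totals$E_total, totals$D_total),
              4 * rates$k_thetaD * totals$D_total,
              4 * rates$k_thetaP * totals$P_total)
      exchange_rate <- 100 * max(fo, 1e-9)
    }
    .check_scalar(exchange_rate, "exchange_rate", positive = TRUE)
    parms$lambda <- exchange_rate
  }

  tt <- sort(unique(c(0, times)))
  deriv <- if (variant == "simplified") .deriv_simplified else .deriv_complete
  out <- deSolve::ode(y = y0, times = tt, func = deriv, parms = parms,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  istate <- attributes(out)$istate
  if (!is.null(istate) && istate[1] < 0) {
    stop("ODE integration failed to converge (istate ", istate[1], ")")
  }
  states <- out[match(times, tt), species, drop = FALSE]
  if (anyNA(states) || any(!is.finite(states))) {
    stop("ODE integration produced non-finite concentrations")
  }
  rownames(states) <- NULL
  structure(list(times = times, states = states, variant = variant,
                 rates = rates, totals = totals,
                 exchange_rate = if (variant == "complete") exchange_rate),
            class = "time_course")
}

.deriv_simplified <- function(t, y, p) {
  E <- y[1]; P <- y[2]; D <- y[3]; EP <- y[4]; ED <- y[5]
  aP <- p$k1P * E * P; dP <- p$k_neg1P * EP
  aD <- p$k1D * E * D; dD <- p$k_neg1D * ED
  tPD <- p$k_thetaD * EP * D   # EP + D -> ED + P
  tDP <- p$k_thetaP * ED * P   # ED + P -> EP + D
  list(c(E  = -aP - aD + dP + dD,
         P  = -aP + dP + tPD - tDP,
         D  = -aD + dD - tPD + tDP,
         EP =  aP - dP - tPD + tDP,
         ED =  aD - dD + tPD - tDP))
}

.deriv_complete <- function(t, y, p) {
  E <- y[1]; P <- y[2]; D <- y[3]; EP <- y[4]; ED <- y[5]
  EPs <- y[6]; EDs <- y[7]; Tn <- y[8]
  lam <- p$lambda
  aP <- p$k1P * E * P;  dP <- 2 * p$k_neg1P * EPs
  aD <- p$k1D * E * D;  dD <- 2 * p$k_neg1D * EDs
  cP <- lam * EPs - lam * EP          # net closing flux EP* -> EP
  cD <- lam * EDs - lam * ED
  tfP <- 4 * p$k_thetaD * EPs * D     # EP* + D -> T
  tfD <- 4 * p$k_thetaP * EDs * P     # ED* + P -> T
  trP <- lam * Tn                     # T -> EP* + D
  trD <- lam * Tn                     # T -> ED* + P
  list(c(E   = -aP - aD + dP + dD,
         P   = -aP + dP - tfD + trD,
         D   = -aD + dD - tfP + trP,
         EP  =  cP,
         ED  =  cD,
         EPs =  aP - dP - cP - tfP + trP,
         EDs =  aD - dD - cD - tfD + trD,
         T   =  tfP + tfD - trP - trD))
}

.species_totals <- function(y, variant) {
  if (variant == "simplified") {
    list(E_total = y[["E"]] + y[["EP"]] + y[["ED"]],
         P_total = y[["P"]] + y[["EP"]],
         D_total = y[["D"]] + y[["ED"]])
  } else {
    list(E_total = y[["E"]] + y[["EP"]] + y[["ED"]] + y[["EPs"]] +
           y[["EDs"]] + y[["T"]],
         P_total = y[["P"]] + y[["EP"]] + y[["EPs"]] + y[["T"]],
         D_total = y[["D"]] + y[["ED"]] + y[["EDs"]] + y[["T"]])
  }
}

#' Labelled-ligand bound pool of a time course
#'
#' Total concentration of complexes containing the labelled ligand P: `EP`
#' for the simplified scheme, `EP + EP* + T` for the complete scheme. This is
#' the quantity a fluorescence-polarization readout reports.
#'
#' @param tc a `time_course` from [simulate_scheme()].
#' @return Numeric vector aligned to `tc$times` (M).
#' @export
bound_ligand <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  s <- tc$states
  if (tc$variant == "simplified") s[, "EP"]
  else s[, "EP"] + s[, "EPs"] + s[, "T"]
}

#' Maximum relative mass-conservation error of a time course
#'
#' @param tc a `time_course`.
#' @return Largest relative deviation of the E, P and D totals from their
#'   initial values across all timepoints.
#' @export
conservation_error <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  tots <- apply(tc$states, 1, function(y) {
    unlist(.species_totals(as.list(y), tc$variant))
  })
  ref <- unlist(tc$totals)[rownames(tots)]
  max(abs(sweep(tots, 1, ref) / pmax(ref, 1e-300)))
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  sp <- colnames(x$states)
  data.frame(time_s = rep(x$times, times = length(sp)),
             species = rep(sp, each = length(x$times)),
             concentration_M = as.vector(x$states),
             scheme = x$variant,
             stringsAsFactors = FALSE)
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course (%s scheme): %d timepoints, t in [%g, %g] s\n",
              x$variant, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  final bound ligand: %.4g M of %.4g M total\n",
              tail(bound_ligand(x), 1), x$totals$P_total))
  invisible(x)
}

#' Equilibrium species concentrations of the simplified scheme
#'
#' Closed-form / root-finding equilibrium used as the oracle for isotherm
#' fitting. With no competitor the two-state quadratic solution is returned.
#' With competitor present, the coupled binding equilibria are solved by
#' monotone root-finding on free protein; when the supplied transfer
#' constants break the thermodynamic cycle (so that the long-time state is a
#' kinetic steady state rather than a true equilibrium) the solution is
#' polished by damped Newton iteration on the full mass-action stationarity
#' conditions.
#'
#' @param rates a [rate_constants()] object.
#' @param totals a [reaction_totals()] object.
#' @param tol convergence tolerance on free-species root-finding.
#' @return Named numeric vector of concentrations (M) for E, P, D, EP, ED.
#' @export
equilibrium_state <- function(rates, totals, tol = 1e-12) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(totals, "reaction_totals"))
  E0 <- totals$E_total; P0 <- totals$P_total; D0 <- totals$D_total
  KdP <- rates$k_neg1P / rates$k1P
  KdD <- rates$k_neg1D / rates$k1D

  if (D0 == 0 || P0 == 0) {
    # single-ligand two-state binding: exact quadratic
    L0 <- if (D0 == 0) P0 else D0
    Kd <- if (D0 == 0) KdP else KdD
    b <- E0 + L0 + Kd
    EX <- if (L0 == 0) 0 else (b - sqrt(b * b - 4 * E0 * L0)) / 2
    out <- c(E = E0 - EX, P = P0, D = D0, EP = 0, ED = 0)
    if (D0 == 0) { out["EP"] <- EX; out["P"] <- P0 - EX }
    else { out["ED"] <- EX; out["D"] <- D0 - EX }
    return(out)
  }

  # coupled competitive binding: free E is the single unknown; the bound
  # amounts are monotone in free E so uniroot brackets cleanly
  g <- function(Ef) {
    Ef + P0 * Ef / (Ef + KdP) + D0 * Ef / (Ef + KdD) - E0
  }
  Ef <- stats::uniroot(g, c(0, E0), tol = tol * max(E0, 1e-15))$root
  P <- P0 * KdP / (Ef + KdP)
  D <- D0 * KdD / (Ef + KdD)
  y <- c(E = Ef, P = P, D = D, EP = P0 - P, ED = D0 - D)

  # transfer terms that violate detailed balance shift the stationary state;
  # polish (P, D) on the stationarity of dEP/dt and dED/dt
  consistent <- rates$k_thetaD == 0 && rates$k_thetaP == 0
  if (!consistent && rates$k_thetaP > 0) {
    consistent <- abs((rates$k_thetaD / rates$k_thetaP) / (KdP / KdD) - 1) < 1e-9
  }
  if (!consistent) y <- .polish_steady_state(y, rates, E0, P0, D0)
  y
}

.polish_steady_state <- function(y, r, E0, P0, D0) {
  f <- function(x) {
    P <- x[1]; D <- x[2]
    EP <- P0 - P; ED <- D0 - D; E <- E0 - EP - ED
    c(r$k1P * E * P - r$k_neg1P * EP - r$k_thetaD * EP * D + r$k_thetaP * ED * P,
      r$k1D * E * D - r$k_neg1D * ED + r$k_thetaD * EP * D - r$k_thetaP * ED * P)
  }
  x <- c(y[["P"]], y[["D"]])
  scale <- max(abs(f(c(P0, D0))), abs(f(x)), 1e-300)
  for (it in seq_len(100)) {
    fx <- f(x)
    if (max(abs(fx)) < 1e-12 * scale) break
    h <- pmax(abs(x), 1e-15) * 1e-7
    J <- cbind((f(x + c(h[1], 0)) - fx) / h[1],
               (f(x + c(0, h[2])) - fx) / h[2])
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x + lam * step
      ok <- all(xn > 0) && xn[1] <= P0 && xn[2] <= D0 &&
        (E0 - (P0 - xn[1]) - (D0 - xn[2])) >= 0
      if (ok && max(abs(f(xn))) <= max(abs(fx))) break
      lam <- lam / 2
      if (lam < 1e-8) { xn <- x; break }
    }
    if (all(xn == x)) break
    x <- xn
  }
  P <- x[1]; D <- x[2]
  c(E = E0 - (P0 - P) - (D0 - D), P = P, D = D, EP = P0 - P, ED = D0 - D)
}

#' Apparent off-rate of the labelled complex under chase conditions
#'
#' Analytic prediction of the one-phase decay rate of the labelled complex
#' EP when competitor D is chased into a preformed, trace-labelled reaction:
#' \deqn{k_{off}^{obs}(D) = k_{-1P}\frac{k_{1D} D}{k_{1D} D + k_{1P} P_{free}}
#'   + k_{\theta D} D.}
#' The first term is classic competition (dissociation followed by capture of
#' the free protein by competitor, in kinetic competition with rebinding of
#' the trace free ligand); the second is direct transfer. With no competitor
#' every dissociation is followed by rebinding, so the observable rate is 0.
#'
#' @param rates a [rate_constants()] object.
#' @param D_free free competitor concentration(s) (M); vectorised.
#' @param P_free free labelled-ligand concentration (M), the trace level that
#'   competes for recapture of free protein.
#' @return Apparent decay rate(s) (s^-1).
#' @export
predicted_koff <- function(rates, D_free, P_free = 0) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(D_free < 0) || any(P_free < 0)) {
    stop("'D_free' and 'P_free' must be >= 0")
  }
  Kc <- (rates$k1P / rates$k1D) * P_free
  capture <- ifelse(D_free > 0, D_free / (D_free + Kc), 0)
  rates$k_neg1P * capture + rates$k_thetaD * D_free
}

# parameterisations used by the competition regression
.koff_classic <- function(D, k_neg1P, K_c) {
  ifelse(D > 0, k_neg1P * D / (D + K_c), 0)
}
.koff_dt <- function(D, k_neg1P, K_c, k_thetaD) {
  .koff_classic(D, k_neg1P, K_c) + k_thetaD * D
}

#' Proportion of translocations proceeding by direct transfer
#'
#' Partition of the protein-translocation flux between the direct-transfer
#' pathway (rate \eqn{k_\theta D}) and the classic
#' dissociation-then-reassociation pathway (rate \eqn{k_{-1}}) at competitor
#' effective molarity D:
#' \deqn{\phi(D) = \frac{k_\theta D}{k_\theta D + k_{-1}}.}
#'
#' @param k_neg1 intrinsic dissociation rate constant (s^-1).
#' @param k_theta direct-transfer rate constant (M^-1 s^-1).
#' @param D competitor concentration(s) (M); vectorised.
#' @return Proportion(s) in \[0, 1\].
#' @seealso [flux_crossover()] for the concentration where the partition is
#'   exactly 0.5.
#' @export
flux_partition <- function(k_neg1, k_theta, D) {
  if (k_neg1 < 0 || k_theta < 0 || any(D < 0)) {
    stop("all arguments must be >= 0")
  }
  num <- k_theta * D
  if (k_neg1 == 0 && any(num == 0)) {
    stop("flux partition undefined: k_neg1 and k_theta*D are both zero")
  }
  num / (num + k_neg1)
}
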