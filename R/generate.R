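#' Design of a synthetic FPCD plate experiment
#'
#' Describes the layout and noise of a plate-reader competitive-dissociation
#' experiment. Defaults emulate the usual design of these assays: a
#' 12-condition competitor series (a zero-competitor control plus an
#' 11-step 2-fold dilution ladder, i.e. one plate row), 4 reaction
#' replicates, 30 s read interval over one hour, a ~90 s
#' initiation-measurement dead time before the first read, trace labelled
#' ligand at 5 nM with 100 nM protein (saturating for the panel's K_d
#' range), polarization endpoints 60 mP (free) / 200 mP (bound), and
#' Gaussian read noise of 2.8 mP (2% of the endpoint range).
#'
#' The default ladder runs geometrically from 0.3 to 4.2 uM. Both ends are
#' set by assay physics: a chase needs competitor in excess of the protein
#' (sub-stoichiometric competitor only shifts the equilibrium slightly,
#' giving a shallow sigmoidal foot that no chase regression model
#' describes), and with a ~90 s dead time apparent rates much above
#' ~0.01 s^-1 complete during the delay and become unmeasurable (the fate
#' of over-chased conditions in real plates). Use [fp_plate_design_for()]
#' to scale the ladder and read schedule to a specific preset.
#'
#' @param competitor_M competitor concentrations (M).
#' @param replicates reaction replicates per concentration.
#' @param read_interval_s,duration_s read schedule (s).
#' @param dead_time_s initiation-measurement delay (s); reads before it do
#'   not exist.
#' @param protein_M,ligand_M total protein and labelled ligand (M).
#' @param free_mP,bound_mP polarization endpoints (mP).
#' @param noise_sd_mP Gaussian read-noise SD (mP).
#' @param carrier name of a non-binding carrier polynucleotide used to keep
#'   total polynucleotide constant across the series, or `NULL` for none.
#'   The carrier changes no rates; it is experiment-design bookkeeping.
#' @return Object of class `fp_plate_design`.
#' @export
fp_plate_design <- function(competitor_M = c(0, 10^seq(log10(3e-7),
                                                       log10(4.2e-6),
                                                       length.out = 11)),
                            replicates = 4, read_interval_s = 30,
                            duration_s = 3600, dead_time_s = 90,
                            protein_M = 1e-7, ligand_M = 5e-9,
                            free_mP = 60, bound_mP = 200,
                            noise_sd_mP = 2.8, carrier = NULL) {
  if (duration_s <= dead_time_s) stop("duration must exceed the dead time")
  if (bound_mP == free_mP) stop("polarization endpoints must be distinct")
  if (any(competitor_M < 0)) stop("competitor concentrations must be >= 0")
  structure(list(competitor_M = sort(competitor_M), replicates = replicates,
                 read_interval_s = read_interval_s, duration_s = duration_s,
                 dead_time_s = dead_time_s, protein_M = protein_M,
                 ligand_M = ligand_M, free_mP = free_mP, bound_mP = bound_mP,
                 noise_sd_mP = noise_sd_mP, carrier = carrier),
            class = "fp_plate_design")
}

#' Plate design scaled to a kinetic preset
#'
#' Chooses a measurable competitor ladder and read schedule for a given
#' preset. The observation window is extended to ~8 intrinsic lifetimes for
#' slow dissociators (keeping ~120 reads). The ladder is geometric over 11
#' nonzero concentrations plus a zero-competitor control: the bottom sits at
#' 3x the protein concentration (a chase requires competitor excess over
#' protein), and for transfer-capable interactions the top is set so the
#' fastest apparent rate stays below what the dead time plus read cadence
#' can resolve (about 1.2 / dead time), capped at 20 uM of competitor.
#'
#' @param preset a [parameter_preset()].
#' @param dead_time_s initiation-measurement delay (s).
#' @param protein_M total protein (M).
#' @param ... further overrides passed to [fp_plate_design()].
#' @return An [fp_plate_design()].
#' @export
fp_plate_design_for <- function(preset, dead_time_s = 90, protein_M = 1e-7,
                                ...) {
  stopifnot(inherits(preset, "parameter_preset"))
  duration <- max(3600, 8 / preset$k_neg1)
  interval <- max(30, round(duration / 120 / 10) * 10)
  k_meas <- 1.2 / dead_time_s
  D_min <- 3 * protein_M
  D_max <- if (preset$k_theta > 0) {
    min(2e-5, max((k_meas - preset$k_neg1) / preset$k_theta,
                  preset$k_neg1 / preset$k_theta, 10 * D_min))
  } else 2e-5
  fp_plate_design(competitor_M = c(0, 10^seq(log10(D_min), log10(D_max),
                                             length.out = 11)),
                  read_interval_s = interval, duration_s = duration,
                  dead_time_s = dead_time_s, protein_M = protein_M, ...)
}

#' Generate a synthetic FPCD plate from a kinetic preset
#'
#' Simulates the simplified competition scheme for each competitor
#' concentration, starting from the pre-equilibrated protein-ligand complex
#' (competitor added at t = 0), maps the bound-ligand fraction linearly to
#' polarization, adds i.i.d. Gaussian read noise per replicate, and drops
#' all reads before the dead time. The generating ground truth (rates,
#' noiseless bound fractions) is returned alongside so any downstream stage
#' can be scored without re-derivation.
#'
#' @param preset a [parameter_preset()] naming the generating rate
#'   constants.
#' @param design an [fp_plate_design()].
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return Object of class `fpcd_dataset`: list with `plate` (long data
#'   frame: `condition_id`, `competitor_M`, `replicate`, `time_s`,
#'   `polarization_mP`) and `truth` (preset, rates, design, seed, noiseless
#'   bound-fraction matrix).
#' @export
generate_fpcd_dataset <- function(preset, design = fp_plate_design(),
                                  seed = 1) {
  stopifnot(inherits(preset, "parameter_preset"),
            inherits(design, "fp_plate_design"))
  set.seed(seed)
  rates <- preset_rates(preset)
  times <- seq(design$dead_time_s, design$duration_s,
               by = design$read_interval_s)
  eq0 <- equilibrium_state(rates, reaction_totals(design$protein_M,
                                                  design$ligand_M, 0))
  fb <- matrix(NA_real_, length(times), length(design$competitor_M))
  out <- vector("list", length(design$competitor_M))
  for (i in seq_along(design$competitor_M)) {
    D <- design$competitor_M[i]
    totals <- reaction_totals(design$protein_M, design$ligand_M, D)
    y0 <- eq0
    y0["D"] <- D
    tc <- simulate_scheme(rates, totals, times, state0 = y0)
    fb[, i] <- bound_ligand(tc) / design$ligand_M
    mp <- design$free_mP + (design$bound_mP - design$free_mP) * fb[, i]
    reps <- lapply(seq_len(design$replicates), function(r) {
      data.frame(condition_id = sprintf("D%02d", i),
                 competitor_M = D, replicate = r, time_s = times,
                 polarization_mP = mp + rnorm(length(mp),
                                              sd = design$noise_sd_mP),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, reps)
  }
  # the normalization assumption needs the saturating condition to reach
  # the free-ligand plateau within the observation window
  imax <- which.max(design$competitor_M)
  if (max(design$competitor_M) > 0 &&
      fb[nrow(fb), imax] / fb[1, 1] > 0.05) {
    warning(paste("saturating-competitor condition does not reach the",
                  "free-ligand plateau within the simulated duration"),
            call. = FALSE)
  }
  plate <- do.call(rbind, out)
  if (!is.null(design$carrier)) {
    plate$carrier <- design$carrier
    plate$carrier_M <- max(design$competitor_M) - plate$competitor_M
  }
  structure(list(plate = plate,
                 truth = list(preset = preset, rates = rates,
                              design = design, seed = seed,
                              times = times, bound_fraction = fb)),
            class = "fpcd_dataset")
}

#' Generate a synthetic equilibrium binding isotherm
#'
#' Hill-form bound fraction (reducing to standard 1:1 binding at
#' `n_H = 1`) mapped to polarization with Gaussian noise. With
#' `depletion = TRUE` the exact ligand-depletion equilibrium is used
#' instead, producing the ligand-limited curves seen for very tight binders
#' whose apparent midpoint is about half the ligand concentration rather
#' than the true K_d.
#'
#' @param K_d dissociation constant (M), > 0.
#' @param n_H Hill coefficient, > 0 (ignored with `depletion = TRUE`).
#' @param protein_M protein concentrations (M); default a 2-fold ladder
#'   spanning K_d by 64-fold each way.
#' @param ligand_M labelled ligand (M).
#' @param free_mP,bound_mP,noise_sd_mP signal mapping and noise as in
#'   [fp_plate_design()].
#' @param depletion use the exact two-state depletion equilibrium.
#' @param seed integer seed.
#' @return Object of class `isotherm_dataset`: list with `isotherm` (data
#'   frame `protein_M`, `polarization_mP`) and `truth`.
#' @export
generate_isotherm <- function(K_d, n_H = 1, protein_M = K_d * 2^(-6:6),
                              ligand_M = 5e-9, free_mP = 60, bound_mP = 200,
                              noise_sd_mP = 2.8, depletion = FALSE,
                              seed = 1) {
  .check_scalar(K_d, "K_d", positive = TRUE)
  .check_scalar(n_H, "n_H", positive = TRUE)
  set.seed(seed)
  E <- sort(protein_M)
  f <- if (depletion) {
    b <- E + ligand_M + K_d
    (b - sqrt(pmax(b * b - 4 * E * ligand_M, 0))) / (2 * ligand_M)
  } else {
    En <- ifelse(E > 0, E^n_H, 0)
    En / (En + K_d^n_H)
  }
  mp <- free_mP + (bound_mP - free_mP) * f
  iso <- data.frame(protein_M = E,
                    polarization_mP = mp + rnorm(length(mp),
                                                 sd = noise_sd_mP))
  structure(list(isotherm = iso,
                 truth = list(K_d = K_d, n_H = n_H, ligand_M = ligand_M,
                              depletion = depletion, bound_fraction = f,
                              seed = seed)),
            class = "isotherm_dataset")
}

#' Design of a synthetic single-molecule experiment
#'
#' Defaults emulate slide-conjugated protein with 1 nM labelled ligand:
#' 0.2 s frames, 1500-frame movies, the single-molecule rate constants of
#' the TREX1-ssDNA interaction, a photobleaching rate of 0.004 s^-1 (10% of
#' the zero-competitor apparent rate, inside the 5-20% band such controls
#' report), signal-to-noise 5, and an 8% per-departure transfer probability
#' in two-colour mode.
#'
#' @param n_traces number of particle traces.
#' @param frame_interval_s frame interval (s).
#' @param trace_frames frames per trace.
#' @param k_neg1,k_theta generating rate constants (s^-1, M^-1 s^-1).
#' @param competitor_M unlabelled competitor concentration (M).
#' @param k_b photobleaching rate (s^-1).
#' @param snr two-level signal amplitude over noise SD.
#' @param arrival_rate binding-event arrival rate per trace (s^-1).
#' @param transfer_prob probability that a departure is a direct transfer
#'   (two-colour mode).
#' @param ternary_gap_s half-width of the uniform arrival-gap distribution
#'   around a transfer departure (s); must stay inside the ternary window.
#' @return Object of class `sm_design`.
#' @export
sm_design <- function(n_traces = 50, frame_interval_s = 0.2,
                      trace_frames = 1500, k_neg1 = 4.0e-2, k_theta = 9800,
                      competitor_M = 0, k_b = 0.004, snr = 5,
                      arrival_rate = 0.02, transfer_prob = 0.08,
                      ternary_gap_s = 0.075) {
  .check_scalar(k_neg1, "k_neg1")
  .check_scalar(k_theta, "k_theta")
  .check_scalar(k_b, "k_b")
  .check_scalar(snr, "snr", positive = TRUE)
  structure(list(n_traces = n_traces, frame_interval_s = frame_interval_s,
                 trace_frames = trace_frames, k_neg1 = k_neg1,
                 k_theta = k_theta, competitor_M = competitor_M, k_b = k_b,
                 snr = snr, arrival_rate = arrival_rate,
                 transfer_prob = transfer_prob,
                 ternary_gap_s = ternary_gap_s),
            class = "sm_design")
}

#' Generate synthetic single-molecule data
#'
#' Dwell durations are drawn from the competing-risks exponential with total
#' rate \eqn{k_{-1} + k_\theta D + k_b}; each termination is labelled
#' dissociation, transfer or bleach in the ground truth with probabilities
#' proportional to the component rates. Three output modes:
#' \describe{
#'   \item{dwells}{a dwell-time list: dwells shorter than the minimum
#'     resolvable dwell (2 frames) are discarded as unobservable, dwells
#'     longer than the movie are censored at its end.}
#'   \item{traces}{per-frame two-level intensity traces (bound amplitude 1,
#'     Gaussian noise SD `1/snr`) with the generating event list.}
#'   \item{two_colour}{paired red/green event streams on shared particles
#'     where a transfer departure spawns an arrival in the other channel
#'     within the ternary window; other departures are followed by
#'     independent rebinding after an exponential gap.}
#' }
#'
#' @param design an [sm_design()].
#' @param mode output mode, see above.
#' @param n_events number of dwells drawn (dwells mode).
#' @param seed integer seed.
#' @return Object of class `sm_dataset`; contents depend on `mode`, always
#'   including a `truth` element with full generator bookkeeping
#'   (counts of dissociation + transfer + bleach + censored = total).
#' @export
generate_sm_dataset <- function(design = sm_design(),
                                mode = c("dwells", "traces", "two_colour"),
                                n_events = 500, seed = 1) {
  stopifnot(inherits(design, "sm_design"))
  mode <- match.arg(mode)
  set.seed(seed)
  D <- design$competitor_M
  rate_diss <- design$k_neg1
  rate_tran <- design$k_theta * D
  rate_bleach <- design$k_b
  rate_total <- rate_diss + rate_tran + rate_bleach
  t_min <- 2 * design$frame_interval_s
  t_max <- design$trace_frames * design$frame_interval_s

  if (mode == "dwells") {
    dur <- rexp(n_events, rate_total)
    cause <- sample(c("dissociation", "transfer", "bleach"), n_events,
                    replace = TRUE,
                    prob = c(rate_diss, rate_tran, rate_bleach) / rate_total)
    censored <- dur > t_max
    cause[censored] <- "censored"
    dur[censored] <- t_max
    observed <- dur >= t_min
    dwells <- data.frame(condition_id = sprintf("D_%.3g", D),
                         competitor_M = D, duration_s = dur[observed],
                         censored = censored[observed],
                         stringsAsFactors = FALSE)
    truth <- list(design = design, seed = seed, rate_total = rate_total,
                  t_min = t_min, n_total = n_events,
                  n_below_t_min = sum(!observed),
                  cause_counts = table(factor(cause,
                    levels = c("dissociation", "transfer", "bleach",
                               "censored"))),
                  cause = cause[observed])
    return(structure(list(dwells = dwells, truth = truth),
                     class = "sm_dataset"))
  }

  if (mode == "traces") {
    traces <- vector("list", design$n_traces)
    events <- vector("list", design$n_traces)
    noise_sd <- 1 / design$snr
    for (p in seq_len(design$n_traces)) {
      t <- rexp(1, design$arrival_rate)      # first arrival
      ev <- list()
      while (t < t_max) {
        d <- rexp(1, rate_total)
        ev[[length(ev) + 1L]] <- c(t, min(t + d, t_max))
        t <- t + d + rexp(1, design$arrival_rate)
      }
      x <- rnorm(design$trace_frames, sd = noise_sd)
      frame_t <- (seq_len(design$trace_frames) - 1) * design$frame_interval_s
      for (e in ev) {
        inside <- frame_t >= e[1] & frame_t < e[2]
        x[inside] <- x[inside] + 1
      }
      traces[[p]] <- data.frame(particle_id = p,
                                frame = seq_len(design$trace_frames) - 1L,
                                intensity = x)
      events[[p]] <- if (length(ev)) {
        m <- do.call(rbind, ev)
        data.frame(particle_id = p, start_s = m[, 1], end_s = m[, 2],
                   censored = m[, 2] >= t_max)
      }
    }
    return(structure(list(traces = do.call(rbind, traces),
                          truth = list(design = design, seed = seed,
                                       events = do.call(rbind, events))),
                     class = "sm_dataset"))
  }

  # two_colour: event streams per particle; departures transfer with
  # probability transfer_prob, spawning an arrival in the other channel
  red <- list(); green <- list()
  n_transfers <- 0L; n_binding <- 0L
  for (p in seq_len(design$n_traces)) {
    t <- rexp(1, design$arrival_rate)
    chan <- sample(c("red", "green"), 1)
    while (t < t_max) {
      d <- rexp(1, rate_diss + rate_bleach)
      end <- min(t + d, t_max)
      rec <- c(t, end)
      n_binding <- n_binding + 1L
      if (chan == "red") red[[length(red) + 1L]] <- c(p, rec)
      else green[[length(green) + 1L]] <- c(p, rec)
      if (end >= t_max) break
      if (runif(1) < design$transfer_prob) {
        n_transfers <- n_transfers + 1L
        gap <- runif(1, -design$ternary_gap_s, design$ternary_gap_s)
        t <- max(end + gap, 0)
        chan <- if (chan == "red") "green" else "red"
      } else {
        t <- end + rexp(1, design$arrival_rate)
        chan <- sample(c("red", "green"), 1)
      }
    }
  }
  to_df <- function(lst) {
    if (!length(lst)) {
      return(data.frame(particle_id = integer(), start_s = numeric(),
                        end_s = numeric()))
    }
    m <- do.call(rbind, lst)
    df <- data.frame(particle_id = m[, 1], start_s = m[, 2], end_s = m[, 3])
    df$start_frame <- round(df$start_s / design$frame_interval_s)
    df$end_frame <- round(df$end_s / design$frame_interval_s)
    df
  }
  structure(list(events_red = to_df(red), events_green = to_df(green),
                 truth = list(design = design, seed = seed,
                              n_transfers = n_transfers,
                              n_binding_events = n_binding)),
            class = "sm_dataset")
}

#' Generate a noisy apparent-off-rate profile from generating rates
#'
#' Draws replicate apparent off-rates directly at the profile level (the
#' quantity [fit_competition_models()] consumes) from the analytic chase
#' prediction [predicted_koff()] with multiplicative Gaussian noise,
#' bypassing the plate simulation. This is the fast generator for
#' model-recovery Monte Carlo.
#'
#' @param preset a [parameter_preset()].
#' @param competitor_M competitor concentrations (M).
#' @param replicates replicates per concentration.
#' @param noise_rel relative (multiplicative) noise SD per replicate.
#' @param P_free free labelled-ligand concentration during the chase (M);
#'   the trace level left unbound at pre-equilibrium.
#' @param seed integer seed.
#' @return A `koff_profile` object (as from [fpcd_koff_profile()]) with the
#'   generating truth in `$truth`.
#' @export
generate_koff_profile <- function(preset,
                                  competitor_M = c(0, 2e-5 / 2^(10:0)),
                                  replicates = 4, noise_rel = 0.05,
                                  P_free = 5e-10, seed = 1) {
  stopifnot(inherits(preset, "parameter_preset"))
  set.seed(seed)
  rates <- preset_rates(preset)
  truth <- predicted_koff(rates, competitor_M, P_free)
  reps <- matrix(pmax(truth * (1 + rnorm(length(truth) * replicates,
                                         sd = noise_rel)), 0),
                 nrow = length(truth))
  prof <- data.frame(competitor_M = competitor_M,
                     koff_obs = rowMeans(reps),
                     sd = apply(reps, 1, sd),
                     n_rep = replicates)
  prof <- prof[order(prof$competitor_M), ]
  rownames(prof) <- NULL
  structure(list(profile = prof, fits = NULL, convention = "generated",
                 truth = list(preset = preset, rates = rates,
                              koff_true = truth, P_free = P_free,
                              noise_rel = noise_rel, seed = seed)),
            class = "koff_profile")
}
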