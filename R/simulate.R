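#' Describe an analyte for the gradient-elution simulator
#'
#' Retention follows a linear-solvent-strength law on the organic
#' fraction phi: `log10 k(phi) = log10 kw_eff - S * phi`, with `kw_eff`
#' the Henderson-Hasselbalch-weighted mix of the neutral-form and
#' ionized-form aqueous retention factors. For an acid the ionized
#' fraction is `1 / (1 + 10^(pKa - pH))` (so high pH pushes acids to
#' their less-retained ionized form); for a base the exponent is
#' reversed; `pKa = NA` makes retention pH-insensitive.
#'
#' @param name Analyte code.
#' @param log_kw_neutral,log_kw_ionized log10 aqueous retention factors
#'   of the two forms; for an acid the ionized form must not be more
#'   retained than the neutral one.
#' @param S Solvent-strength slope per unit organic fraction (positive).
#' @param pKa Acid dissociation constant, or `NA` for pH-insensitive.
#' @param acid_or_base `"acid"`, `"base"` or `"neutral"`.
#' @param plate_count Column plate number N; Gaussian base width is
#'   `4 tR / sqrt(N)`.
#' @return An `analyte_sim` object.
#' @export
analyte_sim <- function(name, log_kw_neutral, log_kw_ionized = log_kw_neutral,
                        S = 5, pKa = NA_real_,
                        acid_or_base = c("acid", "base", "neutral"),
                        plate_count = 10000) {
  acid_or_base <- match.arg(acid_or_base)
  if (!is.numeric(S) || S <= 0) stop("analyte_sim: S must be positive", call. = FALSE)
  if (!is.numeric(plate_count) || plate_count <= 0) {
    stop("analyte_sim: plate_count must be positive", call. = FALSE)
  }
  if (!is.na(pKa) && acid_or_base == "acid" && log_kw_ionized > log_kw_neutral) {
    stop("analyte_sim: for an acid the ionized form cannot be more retained", call. = FALSE)
  }
  structure(list(name = name, log_kw_neutral = log_kw_neutral,
                 log_kw_ionized = log_kw_ionized, S = S, pKa = pKa,
                 acid_or_base = acid_or_base, plate_count = plate_count),
            class = "analyte_sim")
}

#' Built-in eight-analyte parameter set
#'
#' A synthetic parameter set for the eight drink additives (ACE, BEN,
#' SOR, SAC, TAR, CAF, SUN, ASP): aqueous retention factors spread over
#' about 1.4 log10 units, acid pKa values in the upper half of the pH
#' 3-7 working window (CAF pH-insensitive), a -0.6 log10 retention shift
#' on ionization, and plate counts near 10^4. The set is
#' phenomenological: chosen to produce smooth, strongly pH-dependent
#' separation surfaces on the realistic resolution scale (overlap to
#' about 10), including pH-driven order crossings of the SOR/SAC pair
#' with peak-merge (FOP) events in part of the factor cube. It is not a
#' model of any particular instrument or column. Names give the nominal
#' order used for resolution labels; the actual elution order at a given
#' setting can differ for the crossing pair.
#'
#' @return Named list of [analyte_sim()] objects.
#' @export
default_analytes <- function() {
  path <- system.file("extdata", "analytes_default.csv", package = "chromrsm")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
    analyte_sim(tab$name[i], tab$log_kw_neutral[i], tab$log_kw_ionized[i],
                S = tab$S[i], pKa = tab$pKa[i],
                acid_or_base = tab$acid_or_base[i],
                plate_count = tab$plate_count[i])
  }), tab$name)
}

#' Define a linear gradient program
#'
#' @param phi_initial,phi_end Organic fraction (0..1) at the start and
#'   end of the linear ramp; `phi_initial <= phi_end`. After `duration`
#'   the composition is held at `phi_end`.
#' @param duration Ramp duration, minutes.
#' @param t0 Column dead time, minutes.
#' @param hold Maximum post-gradient hold, minutes; an analyte not eluted
#'   by `duration + hold` is flagged as not eluted.
#' @return A `gradient_program` object.
#' @export
gradient_program <- function(phi_initial, phi_end, duration = 30, t0 = 1.5,
                             hold = 30) {
  if (phi_initial < 0 || phi_end > 1 || phi_initial > phi_end) {
    stop("gradient_program: need 0 <= phi_initial <= phi_end <= 1", call. = FALSE)
  }
  if (duration <= 0 || t0 <= 0 || hold < 0) {
    stop("gradient_program: duration and t0 must be positive", call. = FALSE)
  }
  structure(list(phi_initial = phi_initial, phi_end = phi_end,
                 duration = duration, t0 = t0, hold = hold),
            class = "gradient_program")
}

#' Retention factor at a given mobile-phase composition and pH
#'
#' @param analyte An [analyte_sim()].
#' @param phi Organic fraction in \[0, 1\] (vectorized).
#' @param pH Mobile-phase pH.
#' @return Retention factor k (dimensionless).
#' @export
retention_factor <- function(analyte, phi, pH) {
  stopifnot(inherits(analyte, "analyte_sim"), all(phi >= 0 & phi <= 1))
  f_ion <- if (is.na(analyte$pKa) || analyte$acid_or_base == "neutral") {
    0
  } else if (analyte$acid_or_base == "acid") {
    1 / (1 + 10^(analyte$pKa - pH))
  } else {
    1 / (1 + 10^(pH - analyte$pKa))
  }
  kw_eff <- (1 - f_ion) * 10^analyte$log_kw_neutral + f_ion * 10^analyte$log_kw_ionized
  kw_eff * 10^(-analyte$S * phi)
}

# retention time under the gradient by solving the general elution
# equation  integral_0^{tR - t0} dt / (t0 k(phi(t))) = 1  with a
# cumulative trapezoidal rule on a fixed time grid and linear
# interpolation of the unit crossing. Returns NA when the analyte does
# not elute within duration + hold.
elution_time <- function(analyte, gradient, pH, dt = 0.002) {
  g <- gradient
  t_max <- g$duration + g$hold
  tt <- seq(0, t_max, by = dt)
  phi <- pmin(g$phi_end, g$phi_initial + (g$phi_end - g$phi_initial) * tt / g$duration)
  u <- 1 / (g$t0 * retention_factor(analyte, phi, pH))
  cumint <- c(0, cumsum((u[-1] + u[-length(u)]) / 2 * dt))
  i <- which(cumint >= 1)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(g$t0)
  # linear interpolation within the crossing step
  tau <- tt[i - 1L] + dt * (1 - cumint[i - 1L]) / (cumint[i] - cumint[i - 1L])
  g$t0 + tau
}

#' Simulate one gradient-elution chromatogram
#'
#' Retention times are obtained by numerically integrating the general
#' gradient-elution equation for each analyte; base peak widths follow
#' the plate-count law `w = 4 tR / sqrt(N)`. Optional Gaussian jitter of
#' standard deviation `noise_sd` minutes is applied to the retention
#' times under a fixed seed. Peaks closer than `0.15 * (w1 + w2) / 2`
#' are merged into a single co-eluting peak whose analyte label joins
#' the members with `"+"` (reported downstream as FOP).
#'
#' @param analytes List of [analyte_sim()] objects.
#' @param gradient A [gradient_program()].
#' @param pH Mobile-phase pH.
#' @param noise_sd Retention-time jitter SD, minutes (0 = noise free).
#' @param seed Integer seed for the jitter.
#' @param dt Integration step, minutes.
#' @param run_id Run identifier stored in the chromatogram.
#' @return A [chromatogram()]; analytes that fail to elute within
#'   `duration + hold` are dropped and listed in the `not_eluted`
#'   attribute of the result.
#' @export
simulate_run <- function(analytes, gradient, pH, noise_sd = 0, seed = 1,
                         dt = 0.002, run_id = NA_integer_) {
  stopifnot(length(analytes) > 0, noise_sd >= 0)
  tr <- vapply(analytes, elution_time, numeric(1), gradient = gradient,
               pH = pH, dt = dt)
  names(tr) <- vapply(analytes, `[[`, character(1), "name")
  not_eluted <- names(tr)[is.na(tr)]
  tr <- tr[!is.na(tr)]
  if (noise_sd > 0) {
    jitter <- local({
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(as.integer(seed))
      stats::rnorm(length(tr), 0, noise_sd)
    })
    tr <- pmax(tr + jitter, gradient$t0)  # argument order keeps the names
  }
  N <- vapply(analytes, `[[`, numeric(1), "plate_count")
  names(N) <- vapply(analytes, `[[`, character(1), "name")
  ord <- order(tr)
  tr <- tr[ord]
  w <- 4 * tr / sqrt(N[names(tr)])
  if (length(tr) == 0L) {
    stop("simulate_run: no analyte eluted within duration + hold", call. = FALSE)
  }
  # merge peaks whose apex separation is below 15% of their mean width
  groups <- list(1L)
  for (i in seq_along(tr)[-1]) {
    g_idx <- groups[[length(groups)]]
    j <- g_idx[length(g_idx)]
    if (tr[i] - tr[j] < 0.15 * (w[i] + w[j]) / 2) {
      groups[[length(groups)]] <- c(g_idx, i)
    } else {
      groups[[length(groups) + 1L]] <- i
    }
  }
  peaks <- lapply(groups, function(ix) {
    peak(paste(names(tr)[ix], collapse = "+"),
         t = mean(tr[ix]),
         w = if (length(ix) == 1L) w[ix] else max(tr[ix] + w[ix] / 2) - min(tr[ix] - w[ix] / 2),
         area = length(ix),
         height = sum(length(ix) / (w[ix] / 4 * sqrt(2 * pi))))
  })
  out <- chromatogram(peaks, run_id = run_id,
                      metadata = list(phi_initial = gradient$phi_initial,
                                      phi_end = gradient$phi_end, pH = pH,
                                      noise_sd = noise_sd, seed = seed))
  attr(out, "not_eluted") <- not_eluted
  out
}

# map one uncoded design row (%B initial, %B end, pH) to a simulator run
run_at_setting <- function(setting, analytes, duration = 30, t0 = 1.5,
                           noise_sd = 0, seed = 1, dt = 0.002,
                           run_id = NA_integer_) {
  grad <- gradient_program(setting[1] / 100, setting[2] / 100,
                           duration = duration, t0 = t0)
  simulate_run(analytes, grad, pH = setting[3], noise_sd = noise_sd,
               seed = seed, dt = dt, run_id = run_id)
}

#' Simulate a full designed experiment
#'
#' Runs the gradient-elution simulator at every design point (uncoded via
#' the design's factors: %B initial, %B end, pH) and extracts the
#' response table (pairwise resolutions with FOP markers, analysis time)
#' with [response_row()].
#'
#' @param design A [build_bbd()] design carrying three factors
#'   interpreted as %B initial, %B end (percent) and pH.
#' @param analytes List of [analyte_sim()]; default [default_analytes()].
#' @param noise_sd Retention-time jitter SD, minutes.
#' @param seed Base seed; run r uses `seed + r`.
#' @param duration,t0,dt Passed to the simulator.
#' @param fop_threshold Resolution below which a pair is reported FOP.
#' @return Response table: data frame with `run`, one character Rs column
#'   per adjacent analyte pair, and numeric `time`.
#' @export
generate_study <- function(design, analytes = default_analytes(), noise_sd = 0,
                           seed = 1, duration = 30, t0 = 1.5, dt = 0.002,
                           fop_threshold = 0.2) {
  stopifnot(inherits(design, "bbd_design"))
  settings <- uncode(design_coded(design), design$factors)
  order_names <- vapply(analytes, `[[`, character(1), "name")
  rows <- lapply(seq_len(nrow(settings)), function(r) {
    chrom <- run_at_setting(settings[r, ], analytes, duration = duration,
                            t0 = t0, noise_sd = noise_sd, seed = seed + r,
                            dt = dt, run_id = r)
    response_row(chrom, fop_threshold = fop_threshold,
                 analyte_order = order_names)
  })
  out <- do.call(rbind, rows)
  cbind(run = design$points$run, out)
}

#' Ground-truth optimum of the simulator by dense search
#'
#' Evaluates the true (noise-free) simulated responses on a coded
#' lattice, applies the same desirability configuration as the modelling
#' pipeline (Rs maximize / time minimize, anchors taken from the observed
#' range over the lattice), and returns the lattice point of maximum
#' composite desirability. This is the oracle against which the fitted
#' pipeline's optimum is compared.
#'
#' @param factors List of three [factor_spec()] (%B initial, %B end, pH).
#' @param analytes List of [analyte_sim()].
#' @param grid_n Lattice points per axis (default 13; cost grows as
#'   `grid_n^3` simulator runs).
#' @param rs_impact,time_impact Impact coefficients.
#' @param rs_anchors Resolution anchor convention, see [default_goals()];
#'   `"observed"` is the sensible choice here because the simulated
#'   resolutions exceed the complete-separation threshold over most of
#'   the cube, which would leave the `"separation"` ramp saturated.
#' @param goals Optional named list of [desirability_goal()] to use as
#'   is (e.g. the goals of the fitted pipeline being checked, so both
#'   sides score the same objective); overrides `rs_anchors` and the
#'   impacts.
#' @param duration,t0,dt,fop_threshold Passed to the simulator.
#' @return List with `coded_optimum`, `composite_D` and the lattice
#'   responses (`responses`, coded points as attribute).
#' @export
simulator_true_optimum <- function(factors, analytes = default_analytes(),
                                   grid_n = 13, rs_impact = 3, time_impact = 1,
                                   rs_anchors = "observed", goals = NULL,
                                   duration = 30, t0 = 1.5, dt = 0.01,
                                   fop_threshold = 0.2) {
  g <- seq(-1, 1, length.out = grid_n)
  coded <- as.matrix(expand.grid(x3 = g, x2 = g, x1 = g))[, 3:1]
  settings <- uncode(coded, factors)
  order_names <- vapply(analytes, `[[`, character(1), "name")
  rows <- lapply(seq_len(nrow(settings)), function(r) {
    chrom <- run_at_setting(settings[r, ], analytes, duration = duration,
                            t0 = t0, noise_sd = 0, seed = 1, dt = dt, run_id = r)
    response_row(chrom, fop_threshold = fop_threshold,
                 analyte_order = order_names)
  })
  resp <- do.call(rbind, rows)
  y <- fop_encode(resp)
  if (is.null(goals)) {
    goals <- default_goals(resp, rs_impact = rs_impact,
                           time_impact = time_impact, rs_anchors = rs_anchors)
  } else {
    stopifnot(setequal(names(goals), colnames(y)))
    goals <- goals[colnames(y)]
  }
  d <- vapply(colnames(y), function(nm) d_individual(y[, nm], goals[[nm]]),
              numeric(nrow(y)))
  D <- composite_desirability(d, vapply(goals, `[[`, integer(1), "impact"))
  best <- which.max(D)
  list(coded_optimum = stats::setNames(coded[best, ], c("x1", "x2", "x3")),
       composite_D = D[best],
       responses = structure(resp, coded = coded))
}
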