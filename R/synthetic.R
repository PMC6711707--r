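# Seeded generators emulating every input the analysis modules consume.
# All generators are pure functions of (arguments, seed).

#' Adhesion-frequency experiment schedule
#'
#' Defaults reproduce the standard assay layout: contact times 0.1, 0.2,
#' 0.5, 1, 2 and 5 s, four cell pairs per contact time, fifty
#' contact-retraction cycles per pair. (The long end of the published
#' schedule is open-ended; 5 s is comfortably past the plateau for
#' off-rates near 8 per second.)
#'
#' @param tc_list Contact times in seconds, all > 0.
#' @param pairs_per_tc Cell pairs tested per contact time.
#' @param cycles_per_pair Contact-retraction cycles per cell pair.
#' @return An object of class `experiment_schedule`.
#' @export
experiment_schedule <- function(tc_list = c(0.1, 0.2, 0.5, 1, 2, 5),
                                pairs_per_tc = 4, cycles_per_pair = 50) {
  stopifnot(all(tc_list > 0), pairs_per_tc >= 1, cycles_per_pair >= 1)
  structure(list(tc_list = tc_list, pairs_per_tc = as.integer(pairs_per_tc),
                 cycles_per_pair = as.integer(cycles_per_pair)),
            class = "experiment_schedule")
}

#' Simulate adhesion contact-retraction cycles
#'
#' Generates a synthetic adhesion-frequency experiment. In `closed_form`
#' mode every cycle is an independent Bernoulli trial with success
#' probability [adhesion_probability()] at its contact time. In `gillespie`
#' mode each cycle runs the exact immigration-death bond process
#' ([simulate_bond_count()]) and scores adhesion when at least one bond is
#' present at the end of the contact; this mode is the stochastic oracle
#' for the closed form.
#'
#' @param params Generating [kinetic_params()].
#' @param densities [density_pair()].
#' @param schedule [experiment_schedule()].
#' @param mode `"closed_form"` or `"gillespie"`.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   cycle table.
#' @param label Curve label.
#' @return An [adhesion_curve()]; the per-cycle 0/1 outcomes are attached
#'   as attribute `"cycles"` (columns `cell_pair_id`, `tc_s`,
#'   `cycle_index`, `adhesion`) so the output round-trips through
#'   [write_adhesion_cycles()] / [read_adhesion_cycles()].
#' @examples
#' simulate_adhesion_cycles(kinetic_params(3.03e-7, 7.75),
#'                          density_pair(1500, 1500), seed = 7)
#' @export
simulate_adhesion_cycles <- function(params, densities,
                                     schedule = experiment_schedule(),
                                     mode = c("closed_form", "gillespie"),
                                     seed = 1L, label = "synthetic") {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "experiment_schedule"))
  set.seed(seed)
  lam <- densities$mr * densities$ml * params$Ackon
  mu <- params$koff
  rows <- list()
  for (tc in schedule$tc_list) {
    p <- adhesion_probability(tc, densities, params)
    for (pair in seq_len(schedule$pairs_per_tc)) {
      nc <- schedule$cycles_per_pair
      if (mode == "closed_form") {
        hits <- stats::rbinom(nc, 1, p)
      } else {
        hits <- vapply(seq_len(nc), function(i) {
          as.integer(.gillespie_one(lam, mu, tc) >= 1L)
        }, integer(1))
      }
      rows[[length(rows) + 1]] <- data.frame(
        cell_pair_id = sprintf("tc%g_p%d", tc, pair),
        tc_s = tc, cycle_index = seq_len(nc), adhesion = hits)
    }
  }
  cycles <- do.call(rbind, rows)
  obs <- stats::aggregate(adhesion ~ cell_pair_id + tc_s, cycles,
                          function(x) c(n = length(x), k = sum(x)))
  obs <- data.frame(cell_pair_id = obs$cell_pair_id, tc = obs$tc_s,
                    n_cycles = obs$adhesion[, "n"],
                    n_adhesions = obs$adhesion[, "k"])
  obs <- obs[order(obs$tc, obs$cell_pair_id), , drop = FALSE]
  rownames(obs) <- NULL
  curve <- adhesion_curve(obs, densities, label)
  attr(curve, "cycles") <- cycles
  attr(curve, "seed") <- seed
  curve
}

# One exact immigration-death trajectory from 0 bonds to time t; returns the
# bond count at t. Formation at constant rate lam, each bond dies at rate mu.
.gillespie_one <- function(lam, mu, t) {
  n <- 0L
  now <- 0
  repeat {
    rate <- lam + n * mu
    if (rate <= 0) return(n)
    now <- now + stats::rexp(1, rate)
    if (now > t) return(n)
    if (stats::runif(1) < lam / rate) n <- n + 1L else n <- n - 1L
  }
}

#' Exact immigration-death bond-count simulator
#'
#' Simulates the stochastic bond process underlying the adhesion model:
#' bonds form at constant rate `lam = mr*ml*Ackon` and each existing bond
#' dissociates at rate `mu = koff`. Started from zero bonds the marginal
#' count at time `t` is Poisson with mean `(lam/mu) * (1 - exp(-mu*t))`, so
#' `P(count >= 1)` equals the closed-form adhesion probability — this
#' simulator is the independent oracle for [adhesion_probability()].
#'
#' @param lam Bond formation rate (s^-1), >= 0.
#' @param mu Per-bond dissociation rate (s^-1), > 0.
#' @param t Observation time in seconds, >= 0.
#' @param n_draws Number of independent draws.
#' @param seed Integer seed.
#' @return Integer vector of `n_draws` bond counts at time `t`.
#' @examples
#' mean(simulate_bond_count(5.28, 7.75, 2, n_draws = 1000, seed = 1) >= 1)
#' @export
simulate_bond_count <- function(lam, mu, t, n_draws = 1, seed = 1L) {
  if (!is.finite(t) || t < 0) stop("`t` must be non-negative")
  stopifnot(lam >= 0, mu > 0, n_draws >= 1)
  set.seed(seed)
  vapply(seq_len(n_draws), function(i) .gillespie_one(lam, mu, t), integer(1))
}

#' Simulate per-cell de-quenching FRET intensities
#'
#' Each cell's de-quenched donor intensity `DQ` is the base intensity with
#' multiplicative lognormal noise of coefficient of variation `noise_cv`;
#' the quenched intensity is `Q = DQ * (1 - true_E)` with independent noise
#' of the same CV. The lognormal factors have mean exactly 1, so the mean
#' computed efficiency converges to `true_E` as the number of cells grows.
#'
#' @param true_E Generating FRET (quenching) efficiency, in `[0, 1)`.
#' @param n_cells Number of cells.
#' @param noise_cv Coefficient of variation of the intensity noise, >= 0.
#' @param base_intensity Mean de-quenched intensity (arbitrary units).
#' @param group Group label stamped on every cell.
#' @param seed Integer seed.
#' @return data.frame with columns `cell_id`, `group`, `Q`, `DQ`.
#' @examples
#' cells <- simulate_fret_cells(0.40, n_cells = 20, noise_cv = 0.1, seed = 3)
#' mean(fret_efficiency(cells$Q, cells$DQ))
#' @export
simulate_fret_cells <- function(true_E, n_cells = 20, noise_cv = 0.10,
                                base_intensity = 1000, group = "group",
                                seed = 1L) {
  if (!is.finite(true_E) || true_E < 0 || true_E >= 1) {
    stop("`true_E` must lie in [0, 1)")
  }
  stopifnot(noise_cv >= 0, n_cells >= 1, base_intensity > 0)
  set.seed(seed)
  ln_factor <- function(n) {
    if (noise_cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)  # mean exactly 1
  }
  DQ <- base_intensity * ln_factor(n_cells)
  Q <- DQ * (1 - true_E) * ln_factor(n_cells)
  data.frame(cell_id = sprintf("cell%03d", seq_len(n_cells)),
             group = group, Q = Q, DQ = DQ)
}

#' Simulate a case-control genotype cohort under a recessive odds model
#'
#' Controls carry the homozygous minor genotype (CC) with probability
#' `control_cc_freq`; the case CC probability is obtained by multiplying
#' the control odds by `or_recessive`:
#' `p_case = q*OR / (1 + q*(OR - 1))` with `q = control_cc_freq`.
#'
#' @param control_cc_freq CC genotype frequency among controls, in (0, 1).
#' @param or_recessive Generating recessive odds ratio, > 0.
#' @param n_cases,n_controls Cohort sizes (cases may be 0).
#' @param label Subphenotype label.
#' @param seed Integer seed.
#' @return A [recessive_table()].
#' @examples
#' simulate_genotype_cohort(0.038, 1.927, 711, 688, seed = 11)
#' @export
simulate_genotype_cohort <- function(control_cc_freq, or_recessive,
                                     n_cases, n_controls, label = "synthetic",
                                     seed = 1L) {
  if (!is.finite(control_cc_freq) || control_cc_freq <= 0 ||
      control_cc_freq >= 1) {
    stop("`control_cc_freq` must lie strictly between 0 and 1")
  }
  stopifnot(or_recessive > 0, n_cases >= 0, n_controls >= 1)
  set.seed(seed)
  q <- control_cc_freq
  p_case <- q * or_recessive / (1 + q * (or_recessive - 1))
  cases_cc <- if (n_cases > 0) stats::rbinom(1, n_cases, p_case) else 0L
  controls_cc <- stats::rbinom(1, n_controls, q)
  recessive_table(cases_cc = cases_cc,
                  cases_other = as.integer(n_cases) - cases_cc,
                  controls_cc = controls_cc,
                  controls_other = as.integer(n_controls) - controls_cc,
                  label = label)
}

#' Expected case CC frequency under a recessive odds model
#'
#' Odds-algebra helper used by [simulate_genotype_cohort()]:
#' the case-group CC probability implied by a control CC frequency and a
#' recessive odds ratio.
#'
#' @inheritParams simulate_genotype_cohort
#' @return Expected CC probability among cases.
#' @export
case_cc_frequency <- function(control_cc_freq, or_recessive) {
  q <- control_cc_freq
  q * or_recessive / (1 + q * (or_recessive - 1))
}
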