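#' Receptor/ligand surface density pair
#'
#' Bundles the two surface densities that scale the adhesion model. Both are
#' molecular densities per unit membrane area, typically calibrated by flow
#' cytometry and supplied by the user; the package never infers them.
#'
#' @param mr Receptor surface density (molecules per square micron), > 0.
#' @param ml Ligand surface density (molecules per square micron), > 0.
#' @return An object of class `density_pair`.
#' @examples
#' density_pair(mr = 1500, ml = 1500)
#' @export
density_pair <- function(mr, ml) {
  stopifnot(is.numeric(mr), is.numeric(ml), length(mr) == 1, length(ml) == 1)
  if (!is.finite(mr) || mr <= 0) stop("`mr` must be a positive finite density")
  if (!is.finite(ml) || ml <= 0) stop("`ml` must be a positive finite density")
  structure(list(mr = mr, ml = ml), class = "density_pair")
}

#' Two-dimensional kinetic parameters
#'
#' Effective 2D affinity `AcKa` (contact area times affinity, square microns
#' to the fourth power because both densities are per-area) and off-rate
#' `koff` (per second). The contact area and the intrinsic affinity are only
#' ever identifiable as a product, so they are never reported separately.
#' The effective on-rate is derived, `Ackon = AcKa * koff`.
#'
#' @param AcKa Effective 2D binding affinity (um^4), > 0.
#' @param koff Off-rate (s^-1), > 0.
#' @return An object of class `kinetic_params` with fields `AcKa`, `koff`
#'   and the derived `Ackon`.
#' @examples
#' kinetic_params(AcKa = 3.03e-7, koff = 7.75)
#' @export
kinetic_params <- function(AcKa, koff) {
  stopifnot(length(AcKa) == 1, length(koff) == 1)
  if (!is.finite(AcKa) || AcKa <= 0) stop("`AcKa` must be positive and finite")
  if (!is.finite(koff) || koff <= 0) stop("`koff` must be positive and finite")
  structure(list(AcKa = AcKa, koff = koff, Ackon = AcKa * koff),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("2D kinetic parameters: AcKa = %.4g um^4, koff = %.4g s^-1, Ackon = %.4g um^4 s^-1\n",
              x$AcKa, x$koff, x$Ackon))
  invisible(x)
}

#' Effective 2D on-rate from affinity and off-rate
#'
#' `Ackon = AcKa * koff`. Returns `NA` for a not-detectable parameter set.
#'
#' @param params A [kinetic_params()] object, or a list with `AcKa`, `koff`.
#' @return Effective on-rate (um^4 s^-1), or `NA_real_` when either input is
#'   missing/ND.
#' @examples
#' derive_on_rate(kinetic_params(3.03e-7, 7.75))
#' @export
derive_on_rate <- function(params) {
  if (is.null(params) || is.na(params$AcKa) || is.na(params$koff)) {
    return(NA_real_)
  }
  stopifnot(is.finite(params$AcKa), is.finite(params$koff),
            params$AcKa > 0, params$koff > 0)
  params$AcKa * params$koff
}

#' Mean bond number of the probabilistic adhesion model
#'
#' Expected number of receptor-ligand bonds after contact time `tc` under
#' the single-species immigration-death kinetic model:
#' `<n>(tc) = mr * ml * AcKa * (1 - exp(-koff * tc))`.
#' Monotone non-decreasing in `tc`, saturating at `mr * ml * AcKa`.
#'
#' @param tc Contact time in seconds, >= 0 (vectorised).
#' @param densities A [density_pair()].
#' @param params A [kinetic_params()].
#' @return Dimensionless mean bond count, same length as `tc`.
#' @examples
#' mean_bond_number(0.1, density_pair(1500, 1500), kinetic_params(3.03e-7, 7.75))
#' @export
mean_bond_number <- function(tc, densities, params) {
  if (any(!is.finite(tc)) || any(tc < 0)) {
    stop("contact time `tc` must be finite and non-negative")
  }
  densities$mr * densities$ml * params$AcKa * (1 - exp(-params$koff * tc))
}

#' Adhesion probability versus contact time
#'
#' Probability that at least one bond is present at the end of a contact of
#' duration `tc`, given Poisson-distributed bond counts:
#' `Pa = 1 - exp(-<n>)`, with plateau `1 - exp(-mr*ml*AcKa)`.
#'
#' @inheritParams mean_bond_number
#' @return Adhesion probability in `[0, 1)`, same length as `tc`.
#' @examples
#' adhesion_probability(2, density_pair(1500, 1500), kinetic_params(3.03e-7, 7.75))
#' @export
adhesion_probability <- function(tc, densities, params) {
  1 - exp(-mean_bond_number(tc, densities, params))
}

#' Assemble an adhesion-frequency curve
#'
#' An adhesion curve is the unit the fitter consumes: one observation per
#' cell pair per contact time, carrying the number of contact-retraction
#' cycles tested and the number that produced adhesion, plus the shared
#' surface densities.
#'
#' @param observations data.frame with columns `cell_pair_id`, `tc`
#'   (seconds), `n_cycles`, `n_adhesions`.
#' @param densities A [density_pair()] shared by all observations.
#' @param label Free-text label (e.g. receptor/ligand names).
#' @return An object of class `adhesion_curve`.
#' @export
adhesion_curve <- function(observations, densities, label = "") {
  req <- c("cell_pair_id", "tc", "n_cycles", "n_adhesions")
  if (!is.data.frame(observations) || !all(req %in% names(observations))) {
    stop("`observations` must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  obs <- observations[req]
  if (any(obs$tc <= 0)) stop("all contact times must be positive")
  if (any(obs$n_cycles < 1)) stop("each observation needs at least one cycle")
  if (any(obs$n_adhesions < 0 | obs$n_adhesions > obs$n_cycles)) {
    stop("`n_adhesions` must lie in [0, n_cycles]")
  }
  if (!inherits(densities, "density_pair")) densities <- do.call(density_pair, as.list(densities))
  structure(list(observations = obs, densities = densities, label = label),
            class = "adhesion_curve")
}

#' @export
print.adhesion_curve <- function(x, ...) {
  p <- pool_adhesion(x)
  cat(sprintf("Adhesion-frequency curve%s: %d observations, %d contact times\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$observations), nrow(p)))
  cat(sprintf("  densities: mr = %g, ml = %g per um^2\n",
              x$densities$mr, x$densities$ml))
  print(p, row.names = FALSE)
  invisible(x)
}

# Pool observations per contact time: total cycles, adhesions, observed Pa.
pool_adhesion <- function(curve) {
  obs <- curve$observations
  tc <- sort(unique(obs$tc))
  n <- vapply(tc, function(t) sum(obs$n_cycles[obs$tc == t]), numeric(1))
  k <- vapply(tc, function(t) sum(obs$n_adhesions[obs$tc == t]), numeric(1))
  data.frame(tc = tc, n_cycles = n, n_adhesions = k, Pa = k / n)
}

# Objective factories over log-parameters (log AcKa, log koff).
# WLS: binomial variance weights with the Bernoulli variance floored at
# 1/(4n) so observed Pa of 0 or 1 keeps a finite weight.
.wls_objective <- function(pool, dens) {
  w <- pool$n_cycles / pmax(pool$Pa * (1 - pool$Pa), 1 / (4 * pool$n_cycles))
  function(par) {
    p <- 1 - exp(-dens$mr * dens$ml * exp(par[1]) * (1 - exp(-exp(par[2]) * pool$tc)))
    sum(w * (pool$Pa - p)^2)
  }
}

.mle_objective <- function(pool, dens) {
  function(par) {
    p <- 1 - exp(-dens$mr * dens$ml * exp(par[1]) * (1 - exp(-exp(par[2]) * pool$tc)))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(pool$n_adhesions * log(p) + (pool$n_cycles - pool$n_adhesions) * log(1 - p))
  }
}

# Deterministic multi-start minimisation in log space; returns best optim
# fit. The search is confined to a physically sensible box (AcKa in
# [1e-12, 1e-2] um^4, koff in [1e-3, 1e3] s^-1): outside it the objective
# goes flat (e.g. koff beyond the shortest contact time's resolution) and
# unbounded resampled refits would wander off to arbitrary values.
.fit_box <- cbind(logA = log(c(1e-12, 1e-2)), logk = log(c(1e-3, 1e3)))

.fit_kernel <- function(pool, dens, objective, init = NULL) {
  lower <- .fit_box[1, ]
  upper <- .fit_box[2, ]
  clamp <- function(p) pmin(pmax(p, lower), upper)
  pa_max <- min(max(max(pool$Pa), 1 / (2 * max(pool$n_cycles))), 0.999)
  AcKa0 <- -log(1 - pa_max) / (dens$mr * dens$ml)
  starts <- expand.grid(logA = log(AcKa0 * c(0.5, 1, 2)),
                        logk = log(c(0.1, 1, 10)))
  if (!is.null(init)) {
    starts <- rbind(c(log(init$AcKa), log(init$koff)), starts)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f0 <- stats::optim(clamp(as.numeric(starts[i, ])), objective,
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-12))
    f0$par <- clamp(f0$par)
    f0$value <- objective(f0$par)
    f1 <- tryCatch(
      stats::optim(f0$par, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e4)),
      error = function(e) f0)
    cand <- if (f1$value <= f0$value) f1 else f0
    # a failed line search while polishing an already-converged simplex
    # solution is still a converged fit
    if (f0$convergence == 0L) cand$convergence <- 0L
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  best
}

#' Fit the adhesion-frequency model
#'
#' Estimates the effective 2D affinity `AcKa` and off-rate `koff` from an
#' adhesion-frequency curve by minimising a binomial-weighted least-squares
#' objective on the per-contact-time pooled adhesion frequencies (default),
#' or by binomial maximum likelihood (`method = "mle"`). Optimisation runs
#' in log-parameter space from a deterministic multi-start grid, so
#' positivity is enforced and the fit is reproducible. The effective
#' on-rate `Ackon = AcKa * koff` is filled in afterwards.
#'
#' Curves with no adhesion at any contact time take the not-detectable (ND)
#' path: no numeric parameters are reported and `nd` is set, mirroring how
#' interactions below the assay's detection limit are reported.
#'
#' @param curve An [adhesion_curve()] (at least 2 distinct contact times).
#' @param init Optional [kinetic_params()] used as an extra start.
#' @param method `"wls"` (binomial-weighted least squares, default) or
#'   `"mle"` (binomial maximum likelihood).
#' @param background If `TRUE`, adds a constant nonspecific mean bond count
#'   `b >= 0` to the model (`Pa = 1 - exp(-(<n> + b))`). Off by default; no
#'   background subtraction is applied unless requested.
#' @param nd_limit Detection limit on `AcKa` (um^4) used by
#'   [detection_limit_check()]; stored on the fit. Default `1e-8`.
#' @param n_boot Number of bootstrap resamples for standard errors
#'   (see [bootstrap_errors()]); `0` skips the bootstrap.
#' @param seed Integer seed controlling the bootstrap resampling.
#' @return An object of class `adhesion_fit` with elements `params`
#'   ([kinetic_params()] or `NULL` on the ND path), `se` (named vector,
#'   `NA` until a bootstrap is run), `converged`, `nd`, `background`,
#'   `residuals` (per pooled tc, observed minus fitted Pa), `pool`,
#'   `objective_value`, `method`, `curve`.
#' @examples
#' cur <- simulate_adhesion_cycles(kinetic_params(3.03e-7, 7.75),
#'                                 density_pair(1500, 1500), seed = 1)
#' fit <- fit_adhesion(cur)
#' coef(fit)
#' @seealso [bootstrap_errors()], [detection_limit_check()], [compare_fits()]
#' @export
fit_adhesion <- function(curve, init = NULL, method = c("wls", "mle"),
                         background = FALSE, nd_limit = 1e-8,
                         n_boot = 0, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "adhesion_curve"))
  pool <- pool_adhesion(curve)
  if (nrow(pool) < 2) stop("need at least 2 distinct contact times to fit")
  dens <- curve$densities

  out <- structure(list(params = NULL, se = c(AcKa = NA_real_, koff = NA_real_,
                                              Ackon = NA_real_),
                        converged = FALSE, nd = FALSE, nd_limit = nd_limit,
                        background = NA_real_, residuals = NULL, pool = pool,
                        objective_value = NA_real_, method = method,
                        curve = curve),
                   class = "adhesion_fit")

  if (all(pool$n_adhesions == 0)) {
    # detection-limit path: nothing bound in any cycle
    out$nd <- TRUE
    out$converged <- TRUE
    return(out)
  }

  make_obj <- if (method == "wls") .wls_objective else .mle_objective
  if (!background) {
    obj <- make_obj(pool, dens)
    best <- .fit_kernel(pool, dens, obj, init)
    par <- best$par
    bg <- 0
  } else {
    # third log-parameter: constant nonspecific mean bond count
    base_obj <- make_obj(pool, dens)
    obj3 <- function(par3) {
      b <- exp(par3[3])
      p <- 1 - exp(-(dens$mr * dens$ml * exp(par3[1]) *
                       (1 - exp(-exp(par3[2]) * pool$tc)) + b))
      if (method == "wls") {
        w <- pool$n_cycles / pmax(pool$Pa * (1 - pool$Pa), 1 / (4 * pool$n_cycles))
        sum(w * (pool$Pa - p)^2)
      } else {
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -sum(pool$n_adhesions * log(p) +
               (pool$n_cycles - pool$n_adhesions) * log(1 - p))
      }
    }
    two <- .fit_kernel(pool, dens, base_obj, init)
    best <- stats::optim(c(two$par, log(1e-3)), obj3, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    par <- best$par[1:2]
    bg <- exp(best$par[3])
  }

  params <- kinetic_params(exp(par[1]), exp(par[2]))
  fitted <- 1 - exp(-(dens$mr * dens$ml * params$AcKa *
                        (1 - exp(-params$koff * pool$tc)) + bg))
  out$params <- params
  out$converged <- is.finite(best$value) && best$convergence %in% c(0L, 1L)
  out$background <- if (background) bg else NA_real_
  out$residuals <- stats::setNames(pool$Pa - fitted, format(pool$tc))
  out$objective_value <- best$value

  if (n_boot > 0) {
    out$se <- bootstrap_errors(curve, n_boot = n_boot, seed = seed,
                               method = method, background = background)
  }
  out
}

#' @export
print.adhesion_fit <- function(x, ...) {
  if (x$nd) {
    cat(sprintf("Adhesion-frequency fit: ND (no adhesion; AcKa below the %g um^4 detection limit)\n",
                x$nd_limit))
    return(invisible(x))
  }
  cat("Adhesion-frequency kinetic fit (", x$method, ")\n", sep = "")
  cat(sprintf("  AcKa  = %.4g um^4%s\n", x$params$AcKa,
              if (is.finite(x$se["AcKa"])) sprintf(" (SE %.2g)", x$se["AcKa"]) else ""))
  cat(sprintf("  koff  = %.4g s^-1%s\n", x$params$koff,
              if (is.finite(x$se["koff"])) sprintf(" (SE %.2g)", x$se["koff"]) else ""))
  cat(sprintf("  Ackon = %.4g um^4 s^-1%s\n", x$params$Ackon,
              if (is.finite(x$se["Ackon"])) sprintf(" (SE %.2g)", x$se["Ackon"]) else ""))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}

#' @export
coef.adhesion_fit <- function(object, ...) {
  if (object$nd) return(c(AcKa = NA_real_, koff = NA_real_, Ackon = NA_real_))
  c(AcKa = object$params$AcKa, koff = object$params$koff,
    Ackon = object$params$Ackon)
}

#' @export
residuals.adhesion_fit <- function(object, ...) object$residuals

#' Predicted adhesion probability at new contact times
#'
#' @param object An `adhesion_fit`.
#' @param tc Contact times (seconds); defaults to the fitted pooled times.
#' @param ... Unused.
#' @return Predicted Pa values (includes the fitted constant background if
#'   one was estimated).
#' @export
predict.adhesion_fit <- function(object, tc = NULL, ...) {
  if (object$nd) stop("ND fit: no parameters to predict from")
  if (is.null(tc)) tc <- object$pool$tc
  bg <- if (is.finite(object$background)) object$background else 0
  dens <- object$curve$densities
  1 - exp(-(mean_bond_number(tc, dens, object$params) + bg))
}

#' @export
fitted.adhesion_fit <- function(object, ...) predict(object)

#' @export
summary.adhesion_fit <- function(object, ...) {
  print(object)
  if (!object$nd) {
    cat("\nPer-contact-time fit:\n")
    tab <- object$pool
    tab$fitted <- predict(object)
    tab$residual <- object$residuals
    print(tab, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
plot.adhesion_fit <- function(x, ...) {
  pool <- x$pool
  graphics::plot(pool$tc, pool$Pa, xlab = "contact time (s)",
                 ylab = expression(P[a]), ylim = c(0, 1), pch = 19, ...)
  if (!x$nd) {
    tt <- seq(0, max(pool$tc) * 1.05, length.out = 200)
    graphics::lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' Simulate new adhesion curves from a fitted model
#'
#' @param object An `adhesion_fit` (not ND).
#' @param nsim Number of curves.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of [adhesion_curve()] objects drawn from the fitted
#'   parameters under the schedule of the original data.
#' @export
simulate.adhesion_fit <- function(object, nsim = 1, seed = 1L, ...) {
  if (object$nd) stop("ND fit: no parameters to simulate from")
  obs <- object$curve$observations
  tcs <- sort(unique(obs$tc))
  sched <- experiment_schedule(
    tc_list = tcs,
    pairs_per_tc = max(1, round(nrow(obs) / length(tcs))),
    cycles_per_pair = max(1, round(stats::median(obs$n_cycles))))
  lapply(seq_len(nsim), function(i) {
    simulate_adhesion_cycles(object$params, object$curve$densities, sched,
                             seed = seed + i - 1)
  })
}

#' Bootstrap standard errors for an adhesion fit
#'
#' Resamples cell pairs with replacement within each contact time (the cell
#' pair is the experimental replication unit), refits, and reports the
#' standard deviation of the estimates across resamples.
#'
#' @param curve An [adhesion_curve()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; the same seed reproduces the same SEs.
#' @param method,background Passed to the refits (see [fit_adhesion()]).
#' @return Named numeric vector of standard errors for `AcKa`, `koff`,
#'   `Ackon`, with attribute `n_used` (number of convergent, non-ND refits).
#' @export
bootstrap_errors <- function(curve, n_boot = 1000, seed = 1L,
                             method = "wls", background = FALSE) {
  stopifnot(inherits(curve, "adhesion_curve"), n_boot >= 100)
  obs <- curve$observations
  tcs <- unique(obs$tc)
  set.seed(seed)
  est <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(tcs, function(t) {
      rows <- which(obs$tc == t)
      sample(rows, length(rows), replace = TRUE)
    }))
    bcurve <- adhesion_curve(obs[idx, , drop = FALSE], curve$densities,
                             curve$label)
    fit <- tryCatch(fit_adhesion(bcurve, method = method,
                                 background = background),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$converged && !fit$nd) {
      est[b, ] <- coef(fit)
    }
  }
  ok <- stats::complete.cases(est)
  if (mean(ok) < 0.5) {
    stop(sprintf("bootstrap failed: only %d/%d resamples produced a convergent fit",
                 sum(ok), n_boot))
  }
  se <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  structure(stats::setNames(se, c("AcKa", "koff", "Ackon")), n_used = sum(ok))
}

#' Detection-limit verdict for a fit
#'
#' An interaction is reported as not detectable (ND) when the curve produced
#' no adhesion at all, or when the fitted effective affinity falls below the
#' assay's detection limit (default 1e-8 um^4).
#'
#' @param fit An `adhesion_fit`.
#' @param limit Detection limit on `AcKa` in um^4.
#' @return `TRUE` if the interaction should be reported ND.
#' @export
detection_limit_check <- function(fit, limit = 1e-8) {
  stopifnot(inherits(fit, "adhesion_fit"))
  if (fit$nd) return(TRUE)
  fit$params$AcKa < limit
}

#' Compare two adhesion fits
#'
#' Fold changes of `AcKa` and `Ackon` of fit `a` relative to fit `b`, with
#' normal-approximation z-tests on the log-parameters using bootstrap
#' standard errors (delta method: `se(log x) ~ se(x)/x`). Both fits must be
#' measurable; route ND fits through [detection_limit_check()] instead.
#'
#' @param a,b `adhesion_fit` objects (neither ND).
#' @return data.frame with one row per parameter (`AcKa`, `koff`, `Ackon`):
#'   `fold` (a over b), `z`, `p` (two-sided; `NA` without bootstrap SEs).
#' @export
compare_fits <- function(a, b) {
  stopifnot(inherits(a, "adhesion_fit"), inherits(b, "adhesion_fit"))
  if (a$nd || b$nd) {
    stop("ND fit supplied; use detection_limit_check() to report ND outcomes")
  }
  ca <- coef(a); cb <- coef(b)
  fold <- ca / cb
  se_log_a <- a$se / ca
  se_log_b <- b$se / cb
  z <- (log(ca) - log(cb)) / sqrt(se_log_a^2 + se_log_b^2)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(param = names(ca), fold = unname(fold), z = unname(z),
             p = unname(p), row.names = NULL)
}
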