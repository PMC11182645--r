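## pH-dependent protonation of the DxDxE triad and the two-mechanism
## activity model.
##
## The catalytic glutamate (E) must hold a proton to protonate the glycosidic
## oxygen. Two routes supply it: direct protonation from solution, dominant
## at acidic pH where D1 is also protonated (freeing D2 from its ionic anchor
## to D1), and proton shuttling across the triad (D1 -> D2 -> E), dominant
## near neutral pH. Each route is weighted by Henderson-Hasselbalch fractions
## evaluated with that route's own effective pKa pair: the triad's pKas are
## conformation-specific (the predictor assigns different values with D2 in
## the inactive vs active rotamer), and a single shared pair cannot produce
## a secondary activity optimum at all (see the methods vignette).

#' Henderson-Hasselbalch protonated fraction
#'
#' `1 / (1 + 10^(pH - pKa))`: the fraction of an ionizable group carrying its
#' proton at a given pH. Strictly decreasing in pH, 0.5 at `pH == pKa`, and
#' symmetric: `frac_protonated(pKa, pKa - x) + frac_protonated(pKa, pKa + x) == 1`.
#'
#' @param pKa acid dissociation constant (pH units).
#' @param pH solution pH (vectorised).
#' @return protonated fraction in (0, 1).
#' @export
frac_protonated <- function(pKa, pH) {
  stopifnot(all(is.finite(pKa)), all(is.finite(pH)))
  1 / (1 + 10^(pH - pKa))
}

#' Mechanism weights from one pKa pair
#'
#' For a pair (pKa_D1, pKa_E): the low-pH (direct-protonation) weight is the
#' joint fraction with E and D1 both protonated; the high-pH (shuttle) weight
#' is the fraction with E protonated and D1 deprotonated. The two weights sum
#' exactly to `frac_protonated(pKa_E, pH)`, and the shuttle weight is
#' unimodal with its maximum at `(pKa_D1 + pKa_E) / 2`.
#'
#' @param pH solution pH (vectorised).
#' @param pKa_D1,pKa_E the pair's pKa values.
#' @return data.frame with columns `pH`, `w_low`, `w_high`.
#' @export
mechanism_weights <- function(pH, pKa_D1, pKa_E) {
  fE <- frac_protonated(pKa_E, pH)
  fD1 <- frac_protonated(pKa_D1, pH)
  w_low <- fE * fD1
  ## the complement form keeps w_low + w_high == fE exact in floating point
  data.frame(pH = pH, w_low = w_low, w_high = fE - w_low)
}

#' Two-mechanism activity model parameters
#'
#' Amplitudes for the low- and high-pH mechanisms plus each mechanism's
#' effective pKa pair. D2's own pKa (12.4-13.0 in either conformation) never
#' titrates over pH 2-7.4 and therefore does not enter the weights.
#'
#' @param A_low,A_high mechanism amplitudes (kcat units, 1/s; must be >= 0).
#' @param pKa_D1_low,pKa_E_low pKa pair for the direct (low-pH) mechanism.
#' @param pKa_D1_high,pKa_E_high pKa pair for the shuttle (high-pH) mechanism.
#' @return object of class `MechanismParams`.
#' @export
mechanism_params <- function(A_low, A_high,
                             pKa_D1_low = 3.4, pKa_E_low = 7.7,
                             pKa_D1_high = 5.8, pKa_E_high = 7.2) {
  if (A_low < 0 || A_high < 0) stop("amplitudes must be non-negative")
  pk <- c(pKa_D1_low, pKa_E_low, pKa_D1_high, pKa_E_high)
  if (any(pk < 0 | pk > 16)) stop("pKa values must lie in [0, 16]")
  structure(list(A_low = A_low, A_high = A_high,
                 pKa_D1_low = pKa_D1_low, pKa_E_low = pKa_E_low,
                 pKa_D1_high = pKa_D1_high, pKa_E_high = pKa_E_high),
            class = "MechanismParams")
}

#' @export
print.MechanismParams <- function(x, ...) {
  cat(sprintf(paste0("MechanismParams: A_low %.4g, A_high %.4g /s\n",
                     "  low-pH pair:  pKa_D1 %.2f, pKa_E %.2f\n",
                     "  high-pH pair: pKa_D1 %.2f, pKa_E %.2f\n"),
              x$A_low, x$A_high, x$pKa_D1_low, x$pKa_E_low,
              x$pKa_D1_high, x$pKa_E_high))
  invisible(x)
}

mechanism_total <- function(params, pH) {
  wl <- mechanism_weights(pH, params$pKa_D1_low, params$pKa_E_low)$w_low
  wh <- mechanism_weights(pH, params$pKa_D1_high, params$pKa_E_high)$w_high
  params$A_low * wl + params$A_high * wh
}

#' pH-activity profile with optima
#'
#' Evaluates the two-mechanism model on a pH grid: `w_low` with the low-pH
#' pKa pair, `w_high` with the high-pH pair, and
#' `total = A_low * w_low + A_high * w_high` pointwise. Optima are local
#' maxima of `total` on the grid, with boundary points eligible, and the
#' global maximum flagged.
#'
#' @param params a [mechanism_params()].
#' @param pH_grid ascending pH grid (default `seq(2, 7.4, by = 0.1)`).
#' @return object of class `ActivityProfile`: list with `grid` (data.frame
#'   `pH`, `w_low`, `w_high`, `total`) and `optima` (data.frame `pH`,
#'   `value`, `global`).
#' @export
activity_profile <- function(params, pH_grid = seq(2, 7.4, by = 0.1)) {
  if (!length(pH_grid)) stop("empty pH grid")
  if (is.unsorted(pH_grid, strictly = TRUE)) stop("pH grid must be ascending")
  wl <- mechanism_weights(pH_grid, params$pKa_D1_low, params$pKa_E_low)$w_low
  wh <- mechanism_weights(pH_grid, params$pKa_D1_high, params$pKa_E_high)$w_high
  total <- params$A_low * wl + params$A_high * wh
  n <- length(total)
  is_max <- logical(n)
  if (n == 1) {
    is_max <- TRUE
  } else {
    is_max[1] <- total[1] > total[2]
    is_max[n] <- total[n] > total[n - 1]
    if (n > 2) for (i in 2:(n - 1))
      is_max[i] <- total[i] >= total[i - 1] && total[i] >= total[i + 1] &&
        (total[i] > total[i - 1] || total[i] > total[i + 1])
  }
  opt <- data.frame(pH = pH_grid[is_max], value = total[is_max])
  opt$global <- FALSE
  if (nrow(opt)) opt$global[which.max(opt$value)] <- TRUE
  structure(list(grid = data.frame(pH = pH_grid, w_low = wl, w_high = wh,
                                   total = total),
                 optima = opt, params = params),
            class = "ActivityProfile")
}

#' @export
print.ActivityProfile <- function(x, ...) {
  cat(sprintf("ActivityProfile over pH %.2f-%.2f (%d points)\n",
              min(x$grid$pH), max(x$grid$pH), nrow(x$grid)))
  print(x$optima, row.names = FALSE)
  invisible(x)
}

#' Calibrate mechanism amplitudes to a fold-change
#'
#' Solves the 2x2 linear system for (A_low, A_high) such that
#' `total(pH_lo) = fold * kcat_ref` and `total(pH_hi) = kcat_ref`, with the
#' pKa pairs held fixed.
#'
#' @param fold target `total(pH_lo) / total(pH_hi)` ratio.
#' @param kcat_ref total activity at `pH_hi` (1/s).
#' @param pH_lo,pH_hi anchor pH values.
#' @inheritParams mechanism_params
#' @return a [mechanism_params()].
#' @export
calibrate_mechanism <- function(fold = 6.3, kcat_ref = 0.1,
                                pH_lo = 2.0, pH_hi = 7.4,
                                pKa_D1_low = 3.4, pKa_E_low = 7.7,
                                pKa_D1_high = 5.8, pKa_E_high = 7.2) {
  wl <- mechanism_weights(c(pH_lo, pH_hi), pKa_D1_low, pKa_E_low)$w_low
  wh <- mechanism_weights(c(pH_lo, pH_hi), pKa_D1_high, pKa_E_high)$w_high
  M <- rbind(c(wl[1], wh[1]), c(wl[2], wh[2]))
  amp <- solve(M, c(fold * kcat_ref, kcat_ref))
  if (any(amp < 0))
    stop("calibration produced a negative amplitude; adjust the pKa pairs")
  mechanism_params(amp[1], amp[2], pKa_D1_low, pKa_E_low,
                   pKa_D1_high, pKa_E_high)
}

#' Fit the two-mechanism model to observed kcat vs pH
#'
#' Damped (Levenberg-Marquardt) nonlinear least squares with a seeded
#' multistart. The low-pH pair's pKa_E (the inactive-conformation glutamate,
#' ~7.7) multiplies a term that is already negligible wherever it titrates
#' and is therefore held fixed at its initial value; the remaining five
#' parameters are free. Non-convergence is flagged, not thrown.
#'
#' @param pH,kcat observed profile (>= 4 distinct pH points).
#' @param init optional [mechanism_params()] initial guess; by default
#'   amplitudes come from the data extremes and pKas from
#'   [mechanism_params()] defaults.
#' @param n_starts multistart count (default 5).
#' @param seed RNG seed for the start jitter.
#' @return list with `params` (MechanismParams), `converged`,
#'   `residual_norm`, `fitted` (total at the observed pH).
#' @export
fit_mechanism <- function(pH, kcat, init = NULL, n_starts = 5, seed = 1) {
  if (length(unique(pH)) < 4) stop("need >= 4 distinct pH points")
  if (all(kcat == 0)) {
    p <- mechanism_params(0, 0)
    return(list(params = p, converged = TRUE, residual_norm = 0,
                fitted = rep(0, length(pH))))
  }
  if (is.null(init)) {
    init <- mechanism_params(A_low = max(kcat), A_high = max(min(kcat), 1e-3))
  }
  pKa_E_low <- init$pKa_E_low
  model_fn <- function(A_low, A_high, pKa_D1_low, pKa_D1_high, pKa_E_high, pH) {
    p <- list(A_low = A_low, A_high = A_high, pKa_D1_low = pKa_D1_low,
              pKa_E_low = pKa_E_low, pKa_D1_high = pKa_D1_high,
              pKa_E_high = pKa_E_high)
    mechanism_total(p, pH)
  }
  dat <- data.frame(pH = pH, kcat = kcat)
  starts0 <- c(A_low = init$A_low, A_high = init$A_high,
               pKa_D1_low = init$pKa_D1_low, pKa_D1_high = init$pKa_D1_high,
               pKa_E_high = init$pKa_E_high)
  jit <- local({
    set.seed(seed)
    lapply(seq_len(max(0, n_starts - 1)), function(i)
      starts0 * exp(stats::rnorm(5, 0, 0.1)))
  })
  best <- NULL
  for (s in c(list(starts0), jit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        kcat ~ model_fn(A_low, A_high, pKa_D1_low, pKa_D1_high, pKa_E_high, pH),
        data = dat, start = as.list(s),
        lower = c(0, 0, 0, 0, 0), upper = c(Inf, Inf, 16, 16, 16),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best)) {
    return(list(params = init, converged = FALSE, residual_norm = NA_real_,
                fitted = mechanism_total(init, pH)))
  }
  cf <- stats::coef(best$fit)
  params <- mechanism_params(cf[["A_low"]], cf[["A_high"]],
                             pKa_D1_low = cf[["pKa_D1_low"]],
                             pKa_E_low = pKa_E_low,
                             pKa_D1_high = cf[["pKa_D1_high"]],
                             pKa_E_high = cf[["pKa_E_high"]])
  list(params = params, converged = TRUE, residual_norm = best$rn,
       fitted = mechanism_total(params, pH))
}

## ---- predictor output ingestion -----------------------------------------

#' Parse pKa-predictor summary files for the triad
#'
#' Reads files in the empirical predictor's `.pka` summary dialect (the
#' "SUMMARY OF THIS PREDICTION" table with `RES NUM CHAIN pKa` rows) and
#' extracts the triad residues' pKa values, keyed by conformation label.
#' The predictor itself is consumed via its output files, never re-run here.
#'
#' @param files character vector of `.pka` file paths.
#' @param conformations labels for each file (e.g. `c("inactive", "active")`).
#' @param triad a [triad_spec()].
#' @return named list of `PkaSet`s: each a list with `conformation`,
#'   `pKa_D1`, `pKa_D2`, `pKa_E`.
#' @export
ingest_pka_predictions <- function(files, conformations, triad = triad_spec()) {
  if (length(files) != length(conformations))
    stop("one conformation label per file required")
  out <- list()
  for (k in seq_along(files)) {
    lines <- readLines(files[k])
    start <- grep("SUMMARY OF THIS PREDICTION", lines)
    if (!length(start)) stop("no prediction summary section in ", files[k])
    tab <- lines[(start + 1):length(lines)]
    pick <- function(res, num) {
      pat <- sprintf("^\\s*%s\\s+%d\\s+%s\\s+(-?[0-9.]+)", res, num, triad$chain)
      hit <- regmatches(tab, regexec(pat, tab))
      hit <- Filter(length, hit)
      if (!length(hit))
        stop(sprintf("triad residue %s %d (chain %s) absent from %s",
                     res, num, triad$chain, files[k]))
      as.numeric(hit[[1]][2])
    }
    set <- structure(list(conformation = conformations[k],
                          pKa_D1 = pick("ASP", triad$d1),
                          pKa_D2 = pick("ASP", triad$d2),
                          pKa_E = pick("GLU", triad$e)),
                     class = "PkaSet")
    pk <- c(set$pKa_D1, set$pKa_D2, set$pKa_E)
    if (any(pk < 0 | pk > 16))
      stop("pKa outside [0, 16] in ", files[k])
    out[[conformations[k]]] <- set
  }
  out
}

#' @export
print.PkaSet <- function(x, ...) {
  cat(sprintf("PkaSet (%s): pKa D1 %.2f, D2 %.2f, E %.2f\n",
              x$conformation, x$pKa_D1, x$pKa_D2, x$pKa_E))
  invisible(x)
}

#' Triad protonation-state populations across pH
#'
#' Independent Henderson-Hasselbalch fractions for the three triad residues
#' of one conformation's pKa set.
#'
#' @param pka_set a `PkaSet` from [ingest_pka_predictions()].
#' @param pH_grid pH values.
#' @return data.frame with `pH`, `f_D1`, `f_D2`, `f_E` (protonated fractions).
#' @export
triad_protonation <- function(pka_set, pH_grid = seq(2, 7.4, by = 0.1)) {
  data.frame(pH = pH_grid,
             f_D1 = frac_protonated(pka_set$pKa_D1, pH_grid),
             f_D2 = frac_protonated(pka_set$pKa_D2, pH_grid),
             f_E = frac_protonated(pka_set$pKa_E, pH_grid))
}
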