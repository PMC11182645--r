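## Endpoint fluorogenic-substrate assay analysis: standard curves,
## fluorescence -> product conversion, initial rates, Michaelis-Menten fits
## per pH, and pH-profile fold changes.
##
## Plate schema (one row per well read):
##   pH, substrate_uM, time_s, replicate, rfu, well_type in
##   {"reaction", "standard", "blank"}. Standard wells carry the post-quench
##   fluorophore concentration in substrate_uM and have time_s = NA.

DEFAULT_TIMEPOINTS <- c(0, 15, 30, 45, 60, 90)
DEFAULT_ENZYME_UM <- 0.1

#' Validate a plate table
#' @param plate plate data.frame (see schema above).
#' @return the plate, invisibly.
#' @export
validate_plate <- function(plate) {
  need <- c("pH", "substrate_uM", "time_s", "replicate", "rfu", "well_type")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate lacks columns: ", paste(miss, collapse = ", "))
  if (any(plate$rfu < 0)) stop("negative RFU values")
  bad <- setdiff(unique(plate$well_type), c("reaction", "standard", "blank"))
  if (length(bad)) stop("unknown well_type: ", paste(bad, collapse = ", "))
  extra <- setdiff(unique(plate$time_s[plate$well_type == "reaction"]),
                   DEFAULT_TIMEPOINTS)
  if (length(extra))
    warning("non-standard timepoint(s): ", paste(extra, collapse = ", "), " s")
  invisible(plate)
}

#' Read / write a plate CSV
#' @param path CSV path.
#' @param enzyme_uM enzyme concentration annotation (default 0.1 uM).
#' @return plate data.frame with attribute `enzyme_uM`.
#' @export
read_plate <- function(path, enzyme_uM = DEFAULT_ENZYME_UM) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plate(plate)
  attr(plate, "enzyme_uM") <- enzyme_uM
  plate
}

#' @rdname read_plate
#' @param plate plate data.frame.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## through-origin least squares: slope = sum(xy) / sum(x^2)
origin_slope <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) stop("zero-variance predictor in through-origin regression")
  sum(x * y) / sxx
}

#' Fit a fluorophore standard curve for one pH
#'
#' Through-origin linear regression of RFU on post-quench fluorophore
#' concentration (the intercept is fixed at zero: zero fluorophore reads
#' zero above blank).
#'
#' @param plate plate table.
#' @param pH which pH's standards to use.
#' @return object of class `StandardCurve`: list with `pH`, `slope`
#'   (RFU per uM), `n`, `r_squared`.
#' @export
fit_standard_curve <- function(plate, pH) {
  std <- plate[plate$well_type == "standard" & plate$pH == pH, , drop = FALSE]
  if (length(unique(std$substrate_uM[std$substrate_uM > 0])) < 3)
    stop("need >= 3 nonzero standard concentrations at pH ", pH)
  slope <- origin_slope(std$substrate_uM, std$rfu)
  fitted <- slope * std$substrate_uM
  ss_res <- sum((std$rfu - fitted)^2)
  ss_tot <- sum(std$rfu^2)
  structure(list(pH = pH, slope = slope, n = nrow(std),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve pH %.2f: slope %.4g RFU/uM (n=%d, R2=%.4f)\n",
              x$pH, x$slope, x$n, x$r_squared))
  invisible(x)
}

#' Convert fluorescence to product concentration
#' @param rfu RFU values (vectorised).
#' @param curve a [fit_standard_curve()] result.
#' @return product concentration in uM.
#' @export
rfu_to_product <- function(rfu, curve) {
  if (curve$slope <= 0) stop("standard-curve slope must be positive")
  rfu / curve$slope
}

#' Initial rates per substrate concentration
#'
#' Per replicate, a through-origin regression of product concentration on
#' time gives the initial rate; the mean and sd across replicates are
#' reported per (pH, substrate) condition.
#'
#' @param plate plate table.
#' @param curves named list of standard curves keyed by `sprintf("%.2f", pH)`,
#'   or a single curve applied to every pH.
#' @return data.frame with `pH`, `substrate_uM`, `rate` (uM/s), `sd`, `n`.
#' @export
initial_rates <- function(plate, curves) {
  rx <- plate[plate$well_type == "reaction", , drop = FALSE]
  key <- paste(rx$pH, rx$substrate_uM, sep = "\r")
  out <- lapply(split(seq_len(nrow(rx)), key), function(i) {
    g <- rx[i, , drop = FALSE]
    curve <- if (inherits(curves, "StandardCurve")) curves
             else curves[[sprintf("%.2f", g$pH[1])]]
    if (is.null(curve)) stop("no standard curve for pH ", g$pH[1])
    reps <- split(seq_len(nrow(g)), g$replicate)
    rates <- vapply(reps, function(j) {
      h <- g[j, ]
      if (sum(h$time_s > 0) < 2)
        stop("fewer than 2 nonzero timepoints for pH ", h$pH[1],
             ", [S] ", h$substrate_uM[1])
      origin_slope(h$time_s, rfu_to_product(h$rfu, curve))
    }, numeric(1))
    data.frame(pH = g$pH[1], substrate_uM = g$substrate_uM[1],
               rate = mean(rates), sd = stats::sd(rates), n = length(rates))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$pH, out$substrate_uM), ]
  rownames(out) <- NULL
  out
}

#' Michaelis-Menten fit for one pH
#'
#' Unweighted nonlinear least squares of `v = Vmax [S] / (KM + [S])` (no
#' substrate-inhibition term), with `kcat = Vmax / [E]` and catalytic
#' efficiency `kcat / KM`. Wells above `s_ceiling` can be excluded to guard
#' against the product-inhibition regime seen at high substrate; the default
#' fits everything. A positive trend in the high-substrate residuals (rates
#' falling below the hyperbola) is reported as `high_s_residual_trend`.
#'
#' @param rates a [initial_rates()] table restricted to (or filtered for)
#'   one pH.
#' @param enzyme_uM enzyme concentration (uM, default 0.1).
#' @param exclude_above_uM optional substrate ceiling; wells above it are
#'   dropped before fitting (default `Inf` = fit all).
#' @param s_ceiling threshold defining "high substrate" for the residual
#'   diagnostic (default 80 uM).
#' @return object of class `MMFit`: list with `pH`, `Vmax`, `KM`, `kcat`,
#'   `CE`, `se` (named), `ci95` (2x2), `converged`, `poorly_determined`,
#'   `high_s_residual_trend`, `n`.
#' @export
fit_michaelis_menten <- function(rates, enzyme_uM = DEFAULT_ENZYME_UM,
                                 exclude_above_uM = Inf, s_ceiling = 80) {
  stopifnot(length(unique(rates$pH)) == 1)
  fitdat <- rates[rates$substrate_uM <= exclude_above_uM, , drop = FALSE]
  if (length(unique(fitdat$substrate_uM)) < 4)
    stop("need >= 4 substrate concentrations")
  v <- fitdat$rate; s <- fitdat$substrate_uM
  vmax0 <- max(v) * 1.2
  km0 <- s[which.min(abs(v - max(v) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ Vmax * substrate_uM / (KM + substrate_uM),
                      data = fitdat,
                      start = list(Vmax = vmax0, KM = max(km0, 1e-3)),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500,
                                                           ftol = 1e-14,
                                                           ptol = 1e-14)),
    error = function(e) NULL)
  converged <- !is.null(fit)
  if (converged) {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(Vmax = NA_real_, KM = NA_real_))
  } else {
    cf <- c(Vmax = vmax0, KM = km0)
    se <- c(Vmax = NA_real_, KM = NA_real_)
  }
  vmax <- unname(cf["Vmax"]); km <- unname(cf["KM"])
  tcrit <- stats::qt(0.975, max(1, nrow(fitdat) - 2))
  ci <- rbind(Vmax = vmax + c(-1, 1) * tcrit * se["Vmax"],
              KM = km + c(-1, 1) * tcrit * se["KM"])
  colnames(ci) <- c("lo", "hi")
  ## residual trend diagnostic over the full (unfiltered) rate table
  hi <- rates$substrate_uM > s_ceiling
  trend <- if (any(hi)) {
    pred <- vmax * rates$substrate_uM / (km + rates$substrate_uM)
    mean(pred[hi] - rates$rate[hi])
  } else NA_real_
  structure(list(pH = rates$pH[1], Vmax = vmax, KM = km,
                 kcat = vmax / enzyme_uM, CE = (vmax / enzyme_uM) / km,
                 se = se, ci95 = ci, converged = converged,
                 poorly_determined = km > 10 * max(s),
                 high_s_residual_trend = trend, n = nrow(fitdat)),
            class = "MMFit")
}

#' @export
print.MMFit <- function(x, ...) {
  cat(sprintf("MMFit pH %.2f: kcat %.4g /s, KM %.4g uM, kcat/KM %.4g /(uM s)%s\n",
              x$pH, x$kcat, x$KM, x$CE,
              if (!x$converged) " [NOT CONVERGED]"
              else if (x$poorly_determined) " [KM poorly determined]" else ""))
  invisible(x)
}

#' Full per-pH kinetics pipeline on one plate cohort
#'
#' Standard curve, initial rates, and Michaelis-Menten fit for every pH on
#' the plate.
#'
#' @param plate plate table.
#' @param enzyme_uM enzyme concentration (uM).
#' @param exclude_above_uM optional substrate ceiling for the MM fit.
#' @return named list of `MMFit`s keyed by `sprintf("%.2f", pH)`.
#' @export
fit_plate_kinetics <- function(plate, enzyme_uM = DEFAULT_ENZYME_UM,
                               exclude_above_uM = Inf) {
  validate_plate(plate)
  phs <- sort(unique(plate$pH[plate$well_type == "reaction"]))
  curves <- stats::setNames(lapply(phs, function(p) fit_standard_curve(plate, p)),
                            sprintf("%.2f", phs))
  rates <- initial_rates(plate, curves)
  stats::setNames(lapply(phs, function(p)
    fit_michaelis_menten(rates[rates$pH == p, , drop = FALSE],
                         enzyme_uM = enzyme_uM,
                         exclude_above_uM = exclude_above_uM)),
    sprintf("%.2f", phs))
}

#' pH profile and fold changes of the kinetic parameters
#'
#' @param fits list of `MMFit`s (one per pH).
#' @param folds data.frame with columns `parameter`, `pH_a`, `pH_b`; default
#'   requests the kcat, KM and kcat/KM fold changes between the pH extremes.
#' @return object of class `PHKineticProfile`: list with `table` (per-pH
#'   parameters) and `folds` (`parameter`, `pH_a`, `pH_b`, `ratio`).
#' @export
ph_profile_and_folds <- function(fits, folds = NULL) {
  if (length(fits) < 2) stop("need fits at >= 2 pH values")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(pH = f$pH, Vmax = f$Vmax, KM = f$KM, kcat = f$kcat, CE = f$CE,
               converged = f$converged)))
  tab <- tab[order(tab$pH), ]
  rownames(tab) <- NULL
  if (is.null(folds)) {
    a <- min(tab$pH); b <- max(tab$pH)
    folds <- data.frame(parameter = c("kcat", "KM", "CE"),
                        pH_a = a, pH_b = b, stringsAsFactors = FALSE)
  }
  folds$ratio <- NA_real_
  for (i in seq_len(nrow(folds))) {
    va <- tab[[folds$parameter[i]]][match(folds$pH_a[i], tab$pH)]
    vb <- tab[[folds$parameter[i]]][match(folds$pH_b[i], tab$pH)]
    if (is.na(va) || is.na(vb))
      stop(sprintf("fold %s(%g)/%s(%g): pH not present in the fits",
                   folds$parameter[i], folds$pH_a[i],
                   folds$parameter[i], folds$pH_b[i]))
    folds$ratio[i] <- va / vb
  }
  optimum <- tab$pH[which.max(tab$kcat)]
  structure(list(table = tab, folds = folds, kcat_optimum_pH = optimum),
            class = "PHKineticProfile")
}

#' @export
print.PHKineticProfile <- function(x, ...) {
  cat(sprintf("PHKineticProfile: %d pH points, kcat optimum at pH %.2f\n",
              nrow(x$table), x$kcat_optimum_pH))
  print(x$folds, row.names = FALSE)
  invisible(x)
}
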