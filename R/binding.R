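# Equilibrium single-site binding: hyperbolic and ligand-depletion
# (quadratic) isotherm fitting, and reporter repair-frequency normalisation.

#' Fraction bound under ligand depletion (quadratic isotherm)
#'
#' For a fixed labelled partner at total concentration `target_conc` (T)
#' titrated with ligand at total concentration L, the bound fraction is the
#' physical root of the single-site mass-balance quadratic:
#' f = ((T + L + Kd) - sqrt((T + L + Kd)^2 - 4 T L)) / (2 T),
#' evaluated in the cancellation-free form 2L / (b + sqrt(b^2 - 4TL)).
#' Required whenever T is comparable to Kd (ligand depletion regime).
#'
#' @param conc Total ligand concentrations (same units as `kd`), vectorised.
#' @param kd Dissociation constant.
#' @param target_conc Total fixed-partner concentration T (> 0).
#' @return Fraction bound in \[0, 1).
#' @export
fraction_bound_depletion <- function(conc, kd, target_conc) {
  stopifnot(target_conc > 0, kd > 0)
  b <- target_conc + conc + kd
  disc <- pmax(b^2 - 4 * target_conc * conc, 0)
  ifelse(conc > 0, 2 * conc / (b + sqrt(disc)), 0)
}

#' Fraction bound, hyperbolic (no-depletion) approximation
#'
#' f = L / (Kd + L); valid when the fixed partner is present at
#' concentrations well below Kd.
#'
#' @inheritParams fraction_bound_depletion
#' @return Fraction bound in \[0, 1).
#' @export
fraction_bound_hyperbolic <- function(conc, kd) {
  stopifnot(kd > 0)
  conc / (kd + conc)
}

#' Fit a single-site equilibrium binding model to a titration curve
#'
#' Fits `response = offset + rmax * f(conc; Kd)` by least squares, where f
#' is either the hyperbolic isotherm or the ligand-depletion quadratic
#' isotherm. Initialisation is a multi-start profile search: for each Kd on
#' a log-spaced grid spanning the concentration range (extended one decade
#' each side), `offset` and `rmax` are solved linearly; the best start
#' seeds a Gauss-Newton refinement (`nls`, port algorithm). Standard
#' errors come from the Jacobian at the optimum.
#'
#' @param conc Titrant concentrations (nM); >= 4 distinct values.
#' @param response Measured responses (same length as `conc`).
#' @param model `"depletion"` (default for MST-style data with the labelled
#'   target near Kd) or `"hyperbolic"` (SPR equilibrium default).
#' @param target_conc Fixed labelled-partner concentration (nM); required
#'   for the depletion model.
#' @param n_starts Number of Kd grid points (default 25).
#' @return List of class `fit_result`: `kd, rmax, offset, kd_se, rmax_se,
#'   offset_se, model, converged, rss, fitted`.
#' @export
fit_single_site <- function(conc, response, model = c("depletion", "hyperbolic"),
                            target_conc = NULL, n_starts = 25L) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(response), all(conc >= 0))
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations to fit")
  if (stats::sd(response) == 0)
    stop_degenerate("degenerate curve: responses are constant")
  if (model == "depletion") {
    if (is.null(target_conc) || target_conc <= 0)
      stop("depletion model requires target_conc > 0")
  }
  fb <- if (model == "depletion") {
    function(L, kd) fraction_bound_depletion(L, kd, target_conc)
  } else {
    function(L, kd) fraction_bound_hyperbolic(L, kd)
  }
  pos <- conc[conc > 0]
  grid <- exp(seq(log(min(pos) / 10), log(max(pos) * 10), length.out = n_starts))
  # profile the linear parameters (offset, rmax) on the Kd grid
  prof <- vapply(grid, function(kd) {
    f <- fb(conc, kd)
    co <- tryCatch(stats::lm.fit(cbind(1, f), response)$coefficients,
                   error = function(e) c(NA, NA))
    if (anyNA(co)) return(Inf)
    sum((response - co[[1]] - co[[2]] * f)^2)
  }, numeric(1))
  kd0 <- grid[[which.min(prof)]]
  f0 <- fb(conc, kd0)
  co0 <- stats::lm.fit(cbind(1, f0), response)$coefficients
  dat <- data.frame(conc = conc, response = response)
  fit <- tryCatch(
    stats::nls(response ~ offset + rmax * fb(conc, kd), data = dat,
               start = list(offset = co0[[1]], rmax = co0[[2]], kd = kd0),
               algorithm = "port",
               lower = c(offset = -Inf, rmax = -Inf, kd = min(pos) / 1e6),
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(offset = co0[[1]], rmax = co0[[2]], kd = kd0)
    se <- c(offset = NA_real_, rmax = NA_real_, kd = NA_real_)
    converged <- FALSE
    fitted_vals <- est[["offset"]] + est[["rmax"]] * fb(conc, est[["kd"]])
  } else {
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) stats::setNames(rep(NA_real_, 3), names(est)))
    converged <- fit$convInfo$isConv
    fitted_vals <- stats::fitted(fit)
  }
  structure(list(kd = unname(est[["kd"]]), rmax = unname(est[["rmax"]]),
                 offset = unname(est[["offset"]]),
                 kd_se = unname(se[["kd"]]), rmax_se = unname(se[["rmax"]]),
                 offset_se = unname(se[["offset"]]),
                 model = model, target_conc = target_conc,
                 converged = converged,
                 rss = sum((response - fitted_vals)^2),
                 fitted = fitted_vals),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model: Kd = %.4g +/- %.3g, Rmax = %.4g, offset = %.4g (converged: %s, RSS = %.4g)\n",
              x$model, x$kd, x$kd_se, x$rmax, x$offset, x$converged, x$rss))
  invisible(x)
}

#' Normalise reporter repair frequencies to transfection efficiency
#'
#' Divides the percentage of GFP-positive (repaired) cells by the parallel
#' transfection-efficiency fraction.
#'
#' @param gfp_pos_pct Percent GFP-positive cells, vectorised.
#' @param transfection_eff_pct Percent transfection efficiency (> 0), same
#'   length.
#' @return Normalised repair frequency in percent.
#' @export
normalize_repair <- function(gfp_pos_pct, transfection_eff_pct) {
  if (length(gfp_pos_pct) != length(transfection_eff_pct))
    stop("gfp_pos_pct and transfection_eff_pct must have the same length")
  if (any(transfection_eff_pct <= 0))
    stop("transfection efficiency must be > 0")
  gfp_pos_pct / (transfection_eff_pct / 100)
}
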