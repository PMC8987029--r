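# Steady-state kinetics: absorbance-to-rate conversion, Michaelis-Menten
# and substrate-inhibition fits (multi-start Levenberg-Marquardt), and
# on/off switching dynamic-range analysis.

#' Convert an absorbance slope to a molar rate (Beer-Lambert)
#'
#' rate (uM/s) = slope / (epsilon x path) x 1e6. The default extinction
#' coefficient is that of p-nitroaniline at 410 nm (7,126 M^-1 cm^-1),
#' the chromophore released from Z-Ala-Pro-pNA.
#'
#' @param slope absorbance slope in AU/s (vectorized).
#' @param path_length optical path in cm.
#' @param epsilon molar extinction coefficient in M^-1 cm^-1.
#' @return rate in uM/s.
#' @export
absorbance_to_rate <- function(slope, path_length = 1, epsilon = 7126) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (path_length <= 0) stop("path_length must be positive")
  slope / (epsilon * path_length) * 1e6
}

#' Michaelis-Menten rate law
#' @param S substrate concentration(s).
#' @param Vmax,Km parameters (Km in the units of S).
#' @return predicted rate(s).
#' @export
mm_rate <- function(S, Vmax, Km) Vmax * S / (Km + S)

#' Uncompetitive substrate-inhibition rate law
#'
#' v = Vmax * S / (Km + S * (1 + S / Ki)); reduces to Michaelis-Menten as
#' Ki -> Inf. Its maximum lies at S* = sqrt(Km * Ki).
#'
#' @param S substrate concentration(s).
#' @param Vmax,Km,Ki parameters (Km, Ki in the units of S).
#' @return predicted rate(s).
#' @export
si_rate <- function(S, Vmax, Km, Ki) Vmax * S / (Km + S * (1 + S / Ki))

# corrected Akaike information criterion for a least-squares fit
# (k = number of mean parameters + 1 for the error variance)
aicc_ls <- function(rss, n, n_par) {
  k <- n_par + 1
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

# interpolate the substrate concentration at half-maximal rate
half_sat_guess <- function(S, v) {
  vmax <- max(v)
  i <- which(v >= vmax / 2)[1]
  if (is.na(i) || i == 1) return(max(S[1], stats::median(S[S > 0]) / 2))
  s0 <- S[i - 1]; s1 <- S[i]; v0 <- v[i - 1]; v1 <- v[i]
  if (v1 == v0) return(s1)
  s0 + (vmax / 2 - v0) / (v1 - v0) * (s1 - s0)
}

# Levenberg-Marquardt (nls.lm) over deterministic multi-starts on
# sqrt-weight-folded residuals; keeps the lowest weighted RSS. Standard
# errors come from the converged Jacobian, sigma^2 (J'J)^-1; parameters
# pinned at a box bound get NA (the Wald approximation is invalid there).
multistart_nls <- function(model_fn, S, v, sw, starts, lower) {
  resid_fn <- function(p) sw * (v - model_fn(S, p))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(NULL)
  par <- unlist(best$fit$par)
  n <- length(v); p <- length(par)
  se <- rep(NA_real_, p)
  names(se) <- names(par)
  at_bound <- par <= lower + abs(lower) * 1e-8 + 1e-10
  vc <- tryCatch(chol2inv(chol(best$fit$hessian)) *
                   best$rss / max(n - p, 1),
                 error = function(e) NULL)
  if (!is.null(vc)) se[!at_bound] <- sqrt(pmax(diag(vc), 0))[!at_bound]
  list(par = par, se = se, rss = best$rss, fit = best$fit)
}

# resolve the weighting scheme to a weight vector normalized to mean 1
resolve_weights <- function(rate, sd, weighting) {
  w <- if (!is.null(sd)) {
    s <- pmax(sd, max(sd[sd > 0], 1e-12) * 1e-3)
    1 / s^2
  } else {
    switch(weighting,
           none = rep(1, length(rate)),
           # relative: constant-CV (multiplicative) error model
           relative = 1 / pmax(rate, max(rate) * 1e-3)^2,
           stop("weighting must be 'none' or 'relative'"))
  }
  w / mean(w)
}

#' Fit the Michaelis-Menten equation to a saturation curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialization: Vmax starts at the maximal observed rate, Km at the
#' interpolated half-saturation concentration, each perturbed over a
#' deterministic log-spaced grid. k_cat = Vmax / [E] is reported when the
#' enzyme concentration is supplied (rates in uM/s, enzyme in nM).
#'
#' Km is flagged indeterminate when the fitted value exceeds 10x the
#' highest tested concentration or its Wald confidence interval spans
#' more than two orders of magnitude (saturation not reached within the
#' soluble substrate range).
#'
#' @param conc substrate concentrations (>= 4 distinct values).
#' @param rate observed rates, non-negative, same length.
#' @param sd optional per-point standard deviations (weights 1/sd^2).
#' @param weighting when `sd` is absent: "none" (ordinary least squares)
#'   or "relative" (weights 1/rate^2, the constant-CV error model typical
#'   of optical assays).
#' @param enzyme_conc_nM optional enzyme concentration in nM.
#' @return an `mm_fit` list: K_M, V_max, k_cat, standard errors,
#'   `converged`, `km_indeterminate`, (weighted) residual sum of squares,
#'   AICc.
#' @export
fit_michaelis_menten <- function(conc, rate, sd = NULL, weighting = "none",
                                 enzyme_conc_nM = NULL) {
  stopifnot(length(conc) == length(rate))
  if (length(unique(conc)) < 4) stop("need >= 4 distinct concentrations")
  if (any(rate < 0)) stop("rates must be non-negative")
  sw <- sqrt(resolve_weights(rate, sd, weighting))
  ord <- order(conc)
  vmax0 <- max(rate)
  km0 <- half_sat_guess(conc[ord], rate[ord])
  starts <- lapply(c(1, 0.3, 3, 0.1, 10), function(f)
    c(Vmax = vmax0, Km = km0 * f))
  best <- multistart_nls(function(S, p) p[["Vmax"]] * S / (p[["Km"]] + S),
                         conc, rate, sw, starts,
                         lower = c(Vmax = 0, Km = 0))
  if (is.null(best)) {
    stop("Michaelis-Menten fit failed to converge from any start ",
         "(starts: Vmax ", signif(vmax0, 4), ", Km around ",
         signif(km0, 4), ")")
  }
  Km <- best$par[["Km"]]; Vmax <- best$par[["Vmax"]]
  se <- c(V_max = best$se[["Vmax"]], K_M = best$se[["Km"]])
  ci_lo <- Km - 1.96 * se[["K_M"]]; ci_hi <- Km + 1.96 * se[["K_M"]]
  indet <- Km > 10 * max(conc) ||
    (is.finite(ci_hi) && ci_hi / max(ci_lo, Km * 1e-6) > 100)
  out <- list(K_M = Km, V_max = Vmax, se = se,
              k_cat = if (!is.null(enzyme_conc_nM))
                Vmax / (enzyme_conc_nM * 1e-3) else NA_real_,
              enzyme_conc_nM = enzyme_conc_nM,
              converged = TRUE, km_indeterminate = indet,
              rss = best$rss, n = length(conc),
              aicc = aicc_ls(best$rss, length(conc), 2),
              model = "michaelis-menten", fit = best$fit)
  class(out) <- "mm_fit"
  out
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit: K_M =", signif(x$K_M, 4),
      if (x$km_indeterminate) "(indeterminate)" else "",
      " V_max =", signif(x$V_max, 4), "\n")
  if (!is.na(x$k_cat)) cat("  k_cat =", signif(x$k_cat, 4), "s^-1\n")
  invisible(x)
}

#' Fit the substrate-inhibition rate law (and compare with plain MM)
#'
#' Fits v = Vmax S / (Km + S (1 + S/Ki)) by multi-start
#' Levenberg-Marquardt, plus a plain Michaelis-Menten fit, and selects
#' between them by corrected AIC. Both fits are returned.
#'
#' @param conc substrate concentrations (>= 5 distinct values).
#' @param rate observed rates, same length.
#' @param sd optional per-point standard deviations.
#' @param weighting see [fit_michaelis_menten()]; both models are fitted
#'   and compared under the same weights.
#' @return an `si_fit` list: V_max, K_M, K_i with standard errors, the
#'   nested `mm` fit, AICc of both models and `selected` ("si" or "mm").
#' @export
fit_substrate_inhibition <- function(conc, rate, sd = NULL,
                                     weighting = "none") {
  stopifnot(length(conc) == length(rate))
  if (length(unique(conc)) < 5) stop("need >= 5 distinct concentrations")
  sw <- sqrt(resolve_weights(rate, sd, weighting))
  ord <- order(conc)
  vmax0 <- max(rate)
  km0 <- half_sat_guess(conc[ord], rate[ord])
  ki0 <- max(conc)
  starts <- list()
  for (fk in c(1, 0.3, 3)) for (fi in c(1, 0.2, 5)) {
    starts[[length(starts) + 1]] <-
      c(Vmax = vmax0 * 1.2, Km = km0 * fk, Ki = ki0 * fi)
  }
  best <- multistart_nls(
    function(S, p) p[["Vmax"]] * S /
      (p[["Km"]] + S * (1 + S / p[["Ki"]])),
    conc, rate, sw, starts,
    lower = c(Vmax = 0, Km = 0, Ki = 1e-9))
  if (is.null(best)) stop("substrate-inhibition fit failed to converge")
  mm <- fit_michaelis_menten(conc, rate, sd = sd, weighting = weighting)
  aicc_si <- aicc_ls(best$rss, length(conc), 3)
  out <- list(V_max = best$par[["Vmax"]], K_M = best$par[["Km"]],
              K_i = best$par[["Ki"]],
              se = c(V_max = best$se[["Vmax"]], K_M = best$se[["Km"]],
                     K_i = best$se[["Ki"]]),
              rss = best$rss, n = length(conc), aicc = aicc_si,
              mm = mm, aicc_mm = mm$aicc,
              selected = if (aicc_si < mm$aicc) "si" else "mm",
              converged = TRUE, model = "substrate-inhibition",
              fit = best$fit)
  class(out) <- "si_fit"
  out
}

#' @export
print.si_fit <- function(x, ...) {
  cat("Substrate-inhibition fit: V_max =", signif(x$V_max, 4),
      " K_M =", signif(x$K_M, 4), " K_i =", signif(x$K_i, 4), "\n")
  cat("  AICc (SI) =", signif(x$aicc, 5), " AICc (MM) =",
      signif(x$aicc_mm, 5), " selected:", x$selected, "\n")
  invisible(x)
}

#' Ratio of two rates (fold change)
#'
#' @param rate_a numerator rate.
#' @param rate_b denominator rate (> 0).
#' @return rate_a / rate_b.
#' @export
fold_change <- function(rate_a, rate_b) {
  if (any(rate_b <= 0)) {
    stop("denominator rate is zero or negative; report the fold change as ",
         "'> x-fold' using the assay detection floor instead")
  }
  rate_a / rate_b
}

#' Dynamic range and drift of an on/off switching series
#'
#' Rates are first normalized so that the highest relative rate is 1.
#' The dynamic range is the mean of the on-round (chelator-restored)
#' relative rates divided by the mean of the off-round (metal-bound)
#' ones; a zero off-mean gives an infinite dynamic range with a flag.
#' The trend slope (OLS of on-round relative rates on round index) checks
#' for activity degradation over cycles.
#'
#' @param series data.frame with columns `round` (integer), `state`
#'   ("on"/"off") and `rate`; optional `sd`.
#' @return list: mean_on, mean_off, dynamic_range, trend_slope,
#'   relative (full normalized series), `finite` flag.
#' @export
switching_dynamic_range <- function(series) {
  stopifnot(all(c("round", "state", "rate") %in% names(series)),
            all(series$state %in% c("on", "off")))
  if (!any(series$state == "on") || !any(series$state == "off")) {
    stop("series needs at least one 'on' and one 'off' round")
  }
  rel <- series$rate / max(series$rate)
  on <- rel[series$state == "on"]
  off <- rel[series$state == "off"]
  mean_on <- mean(on); mean_off <- mean(off)
  finite <- mean_off > 0
  dr <- if (finite) mean_on / mean_off else Inf
  rnd <- series$round[series$state == "on"]
  trend <- if (length(on) > 1) {
    unname(stats::coef(stats::lm(on ~ rnd))[2])
  } else NA_real_
  list(mean_on = mean_on, mean_off = mean_off, dynamic_range = dr,
       trend_slope = trend,
       relative = data.frame(round = series$round, state = series$state,
                             relative_rate = rel),
       finite = finite)
}
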