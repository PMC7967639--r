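#' Nisbet-LaGoy toxicity equivalency factors
#'
#' Per-congener carcinogenic potencies relative to benzo(a)pyrene, used to
#' collapse a 16-congener profile into a single BaP-equivalent concentration:
#' 0.001 for NAP, ACP, ACY, FLU, PHE, PYR; 0.01 for ANT, BgP, CYR; 0.1 for
#' BaA, BbF, BkF, IcP; 1 for BaP and DbA. FLA defaults to the Nisbet-LaGoy
#' value 0.001 and is exposed as an argument because TEQ schemes occasionally
#' omit it.
#'
#' @param fla TEF for fluoranthene (default 0.001).
#' @return Named numeric vector over the 16 congeners.
#' @export
tef_nisbet_lagoy <- function(fla = 0.001) {
  tef <- c(NAP = 0.001, ACP = 0.001, ACY = 0.001, FLU = 0.001,
           PHE = 0.001, PYR = 0.001,
           ANT = 0.01, BgP = 0.01, CYR = 0.01,
           BaA = 0.1, BbF = 0.1, BkF = 0.1, IcP = 0.1,
           BaP = 1, DbA = 1, FLA = fla)
  stopifnot(all(tef > 0 & tef <= 1), tef[["BaP"]] == 1)
  tef[pah_congeners()]
}

#' BaP-equivalent toxic concentration (TEQ)
#'
#' TEF-weighted sum of the congener concentrations; the result is in
#' benzo(a)pyrene-equivalent ng m^-3 and is linear and monotone in every
#' congener.
#'
#' @param profiles Imputed profile table (see [impute_below_mdl()]).
#' @param tef Named TEF vector, by default [tef_nisbet_lagoy()].
#' @return Numeric vector of TEQ values, one per sample.
#' @export
teq <- function(profiles, tef = tef_nisbet_lagoy()) {
  mat <- stop_if_missing_values(profiles, "teq")
  missing <- setdiff(colnames(mat), names(tef))
  if (length(missing))
    stop("TEF table lacks entries for: ", paste(missing, collapse = ", "))
  drop(mat %*% tef[colnames(mat)])
}

#' Per-congener share of the TEQ
#'
#' @inheritParams teq
#' @return Matrix (samples x congeners) of percentage contributions; each row
#'   sums to 100.
#' @export
teq_contributions <- function(profiles, tef = tef_nisbet_lagoy()) {
  mat <- stop_if_missing_values(profiles, "teq_contributions")
  weighted <- sweep(mat, 2, tef[colnames(mat)], `*`)
  tot <- rowSums(weighted)
  if (any(tot == 0))
    stop("TEQ is zero for at least one sample: contributions undefined")
  100 * weighted / tot
}

#' Exposure and dose-response parameters for the inhalation ILCR model
#'
#' Defaults are the childhood schooling scenario: inhalation rate 12 m^3
#' day^-1, exposure frequency 250 day year^-1 (school days), exposure
#' duration 6 years, averaging time 70 y x 365 d = 25,550 days, and the BaP
#' inhalation cancer slope factor 3.85 (mg kg^-1 day^-1)^-1 scaled between
#' body weights by a cube-root factor against the 70 kg reference adult.
#'
#' @param IR Inhalation rate, m^3 day^-1.
#' @param EF Exposure frequency, day year^-1.
#' @param ED Exposure duration, years.
#' @param AT Averaging time, days.
#' @param CSF Cancer slope factor for BaP, (mg kg^-1 day^-1)^-1.
#' @param BW_ref Reference adult body weight, kg.
#' @param unit_factor ng -> mg conversion (1e-6).
#' @return List of class `risk_params`.
#' @export
risk_params <- function(IR = 12, EF = 250, ED = 6, AT = 25550,
                        CSF = 3.85, BW_ref = 70, unit_factor = 1e-6) {
  vals <- c(IR = IR, EF = EF, ED = ED, AT = AT, CSF = CSF,
            BW_ref = BW_ref, unit_factor = unit_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all risk parameters must be positive and finite")
  structure(as.list(vals), class = "risk_params")
}

check_body_weight <- function(bw) {
  if (any(!is.finite(bw)) || any(bw <= 0))
    stop("body weight must be positive")
  if (any(bw < 10 | bw > 120))
    warning("body weight outside the physiologically plausible 10-120 kg range")
  bw
}

#' Deterministic incremental lifetime cancer risk from inhalation
#'
#' \deqn{ILCR = TEQ \times 10^{-6} \times CSF \times (BW/70)^{1/3}
#'   \times IR \times ED \times EF / (BW \times AT)}
#'
#' The cube-root factor extrapolates the BaP slope factor from the 70 kg
#' reference adult to the receptor's body weight; the net body-weight
#' dependence is \eqn{BW^{-2/3}}, so risk decreases with body weight.
#'
#' @param teq BaP-equivalent concentration, ng m^-3 (nonnegative).
#' @param bw Receptor body weight, kg.
#' @param params A [risk_params()] object.
#' @return Dimensionless lifetime risk (vectorised).
#' @examples
#' ilcr_point(1, 70)  # 3.875e-08
#' @export
ilcr_point <- function(teq, bw, params = risk_params()) {
  if (any(teq < 0, na.rm = TRUE)) stop("teq must be nonnegative")
  check_body_weight(bw)
  teq * params$unit_factor * params$CSF * (bw / params$BW_ref)^(1 / 3) *
    params$IR * params$ED * params$EF / (bw * params$AT)
}

#' Invert the ILCR model for body weight
#'
#' Solves `ilcr_point(teq, bw) = target` for `bw`. Since ILCR is proportional
#' to `bw^(-2/3)` the inversion is closed-form; it is used to calibrate a
#' group-representative child body weight from a reported group-mean risk.
#'
#' @param target Target ILCR (dimensionless, > 0).
#' @param teq TEQ at which the target was reported, ng m^-3 (> 0).
#' @inheritParams ilcr_point
#' @return Body weight in kg.
#' @export
calibrate_body_weight <- function(target, teq, params = risk_params()) {
  if (target <= 0 || teq <= 0) stop("target and teq must be positive")
  k <- teq * params$unit_factor * params$CSF * params$IR * params$ED *
    params$EF / (params$BW_ref^(1 / 3) * params$AT)
  bw <- (k / target)^(3 / 2)
  check_body_weight(bw)
}

#' Log-normal parameters from arithmetic moments
#'
#' Converts an arithmetic mean and standard deviation into the `(mu, sigma)`
#' of the underlying normal: `sigma^2 = log(1 + (sd/mean)^2)`,
#' `mu = log(mean) - sigma^2/2`. Round-tripping recovers the arithmetic
#' moments exactly.
#'
#' @param mean Arithmetic mean (> 0).
#' @param sd Arithmetic standard deviation (>= 0).
#' @return List with `mu` and `sigma`.
#' @export
lognormal_from_arithmetic <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (!is.finite(sd) || sd < 0) stop("sd must be nonnegative")
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Stochastic input specification
#'
#' Families:
#' * `constant(value)` — degenerate point mass.
#' * `logistic(mean, scale)` — location/scale logistic.
#' * `lognormal_arithmetic(mean, sd)` — log-normal parameterised by its
#'   arithmetic moments (see [lognormal_from_arithmetic()]).
#' * `negative_binomial(p, r)` — count distribution with success probability
#'   `p` and size `r` (mean `r(1-p)/p`); draws used for body weight are
#'   truncated below at 1 kg.
#'
#' @param family One of `"constant"`, `"logistic"`, `"lognormal_arithmetic"`,
#'   `"negative_binomial"`.
#' @param ... Family parameters (see above).
#' @return List of class `dist_spec`.
#' @export
dist_spec <- function(family = c("constant", "logistic",
                                 "lognormal_arithmetic", "negative_binomial"),
                      ...) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
    constant = "value",
    logistic = c("mean", "scale"),
    lognormal_arithmetic = c("mean", "sd"),
    negative_binomial = c("p", "r"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("dist_spec(", family, ") needs parameter(s): ",
         paste(missing, collapse = ", "))
  params <- params[need]
  if (family == "logistic" && params$scale <= 0)
    stop("logistic scale must be positive")
  if (family == "lognormal_arithmetic") {
    if (params$mean <= 0) stop("lognormal arithmetic mean must be positive")
    if (params$sd < 0) stop("lognormal arithmetic sd must be nonnegative")
  }
  if (family == "negative_binomial") {
    if (params$p <= 0 || params$p >= 1) stop("p must lie in (0, 1)")
    if (params$r <= 0) stop("r must be positive")
  }
  structure(list(family = family, params = params), class = "dist_spec")
}

#' Draw random variates from a `dist_spec`
#'
#' Uses the current RNG state; seed upstream (e.g. in [monte_carlo_ilcr()])
#' for reproducibility. A degenerate log-normal (sd = 0) returns the mean.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) stop("spec must be a dist_spec")
  p <- spec$params
  switch(spec$family,
    constant = rep(p$value, n),
    logistic = stats::rlogis(n, location = p$mean, scale = p$scale),
    lognormal_arithmetic = {
      if (p$sd == 0) rep(p$mean, n) else {
        ln <- lognormal_from_arithmetic(p$mean, p$sd)
        stats::rlnorm(n, ln$mu, ln$sigma)
      }
    },
    negative_binomial = stats::rnbinom(n, size = p$r, prob = p$p),
    stop("unknown distribution family: ", spec$family))
}

dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    constant = p$value,
    logistic = p$mean,
    lognormal_arithmetic = p$mean,
    negative_binomial = p$r * (1 - p$p) / p$p)
}

is_constant_spec <- function(spec) {
  spec$family == "constant" ||
    (spec$family == "lognormal_arithmetic" && spec$params$sd == 0)
}

#' Monte Carlo simulation of the inhalation ILCR
#'
#' Draws `n_iter` independent (TEQ, body-weight) pairs from their
#' distribution specifications and pushes each through [ilcr_point()].
#' TEQ draws are floored at 0 (a logistic tail can cross zero; the mass
#' involved is negligible at the default configurations) and body-weight
#' draws are floored at 1 kg. The per-draw inputs are retained so that
#' [sensitivity_analysis()] can attribute output variance to inputs.
#'
#' @param teq_spec,bw_spec [dist_spec()] objects for the TEQ (ng m^-3) and
#'   body weight (kg).
#' @param params A [risk_params()] object.
#' @param n_iter Number of iterations (default 10,000).
#' @param seed Integer seed for the single RNG stream of the run; recorded in
#'   the result. `NULL` uses the current RNG state.
#' @return Object of class `ilcr_mc` with elements `draws`, `inputs`
#'   (data.frame of per-draw `teq`, `bw`), `mean`, `percentiles` (5th, 50th,
#'   95th), `seed`, `params`, `teq_spec`, `bw_spec`.
#' @export
monte_carlo_ilcr <- function(teq_spec, bw_spec, params = risk_params(),
                             n_iter = 10000, seed = NULL) {
  if (!inherits(teq_spec, "dist_spec") || !inherits(bw_spec, "dist_spec"))
    stop("teq_spec and bw_spec must be dist_spec objects")
  if (n_iter < 1) stop("n_iter must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  teq_draws <- pmax(0, sample_dist(teq_spec, n_iter))
  bw_draws <- pmax(1, sample_dist(bw_spec, n_iter))
  draws <- suppressWarnings(ilcr_point(teq_draws, bw_draws, params))
  res <- list(
    draws = draws,
    inputs = data.frame(teq = teq_draws, bw = bw_draws),
    mean = mean(draws),
    percentiles = stats::quantile(draws, c(0.05, 0.5, 0.95), type = 7),
    seed = seed,
    params = params,
    teq_spec = teq_spec,
    bw_spec = bw_spec
  )
  structure(res, class = "ilcr_mc")
}

#' Empirical percentiles of a Monte Carlo run
#'
#' Quantiles use the linear-interpolation convention between order statistics
#' (R's default type 7).
#'
#' @param x An `ilcr_mc` object.
#' @param probs Probabilities in `[0, 1]`.
#' @param ... Unused.
#' @return Named numeric vector of quantiles.
#' @export
quantile.ilcr_mc <- function(x, probs = c(0.05, 0.5, 0.95), ...) {
  if (!length(x$draws)) stop("no draws to summarise")
  stats::quantile(x$draws, probs, type = 7)
}

#' @export
print.ilcr_mc <- function(x, ...) {
  cat("Monte Carlo incremental lifetime cancer risk\n")
  cat(sprintf("  iterations: %d%s\n", length(x$draws),
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  cat(sprintf("  TEQ ~ %s, BW ~ %s\n", x$teq_spec$family, x$bw_spec$family))
  cat(sprintf("  mean ILCR: %.3g\n", x$mean))
  p <- x$percentiles
  cat(sprintf("  5th / 50th / 95th percentile: %.3g / %.3g / %.3g\n",
              p[[1]], p[[2]], p[[3]]))
  invisible(x)
}

#' @export
summary.ilcr_mc <- function(object, ...) {
  out <- c(mean = object$mean,
           stats::quantile(object$draws, c(0.05, 0.25, 0.5, 0.75, 0.95),
                           type = 7))
  print(object)
  invisible(out)
}

#' @export
plot.ilcr_mc <- function(x, breaks = 50, ...) {
  graphics::hist(x$draws, breaks = breaks,
                 main = "Simulated incremental lifetime cancer risk",
                 xlab = "ILCR", ...)
  graphics::abline(v = x$mean, lty = 2)
  invisible(x)
}

#' Rank-correlation sensitivity analysis of a Monte Carlo run
#'
#' For each input that actually varies, computes the Spearman rank
#' correlation with the simulated ILCR and the normalised contribution to
#' variance (squared rank correlation rescaled to sum to 1 across varying
#' inputs — the convention used by risk-simulation spreadsheets). Body weight
#' carries a negative correlation whenever it varies, since ILCR falls as
#' body weight rises.
#'
#' @param mc An `ilcr_mc` object.
#' @return data.frame with columns `variable`, `rank_correlation`,
#'   `contribution`.
#' @export
sensitivity_analysis <- function(mc) {
  if (!inherits(mc, "ilcr_mc")) stop("mc must be an ilcr_mc object")
  varying <- vapply(mc$inputs, function(v) stats::sd(v) > 0, logical(1))
  if (!any(varying))
    stop("all inputs are constant: sensitivity undefined")
  if (sum(varying) == 1L)
    warning("only one varying input: its contribution is trivially 1")
  rho <- vapply(mc$inputs[varying], function(v)
    stats::cor(v, mc$draws, method = "spearman"), numeric(1))
  data.frame(variable = names(rho),
             rank_correlation = unname(rho),
             contribution = unname(rho^2 / sum(rho^2)),
             stringsAsFactors = FALSE)
}

#' Write risk-engine outputs
#'
#' `write_risk_csv` writes one row per scenario (`scenario, mean, p5, p50,
#' p95`); `write_sensitivity_csv` writes the [sensitivity_analysis()] table;
#' `write_draws_csv` dumps the per-draw audit trail (inputs and ILCR).
#'
#' @param runs Named list of `ilcr_mc` objects (names become scenarios).
#' @param path Output file path.
#' @export
write_risk_csv <- function(runs, path) {
  rows <- lapply(names(runs), function(nm) {
    q <- quantile.ilcr_mc(runs[[nm]], c(0.05, 0.5, 0.95))
    data.frame(scenario = nm, mean = runs[[nm]]$mean,
               p5 = q[[1]], p50 = q[[2]], p95 = q[[3]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_csv
#' @param sens Output of [sensitivity_analysis()].
#' @export
write_sensitivity_csv <- function(sens, path) {
  utils::write.csv(sens, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_risk_csv
#' @param mc An `ilcr_mc` object.
#' @export
write_draws_csv <- function(mc, path) {
  utils::write.csv(cbind(mc$inputs, ilcr = mc$draws), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a risk configuration (YAML)
#'
#' The configuration carries the risk parameters, the TEQ and body-weight
#' distribution specifications, the iteration count, seed and percentile
#' list, so a probabilistic run is fully reproducible from one file.
#'
#' @param config List with elements `params` (arguments to [risk_params()]),
#'   `teq_spec` / `bw_spec` (each `family` plus parameters), and optionally
#'   `n_iter`, `seed`, `percentiles`.
#' @param path File path.
#' @return `read_risk_config` returns a list with `params` ([risk_params()]),
#'   `teq_spec`/`bw_spec` ([dist_spec()]), `n_iter`, `seed`, `percentiles`.
#' @export
write_risk_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_risk_config
#' @export
read_risk_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_spec <- function(x) do.call(dist_spec, c(list(family = x$family),
                                              x[setdiff(names(x), "family")]))
  list(params = do.call(risk_params, as.list(raw$params %||% list())),
       teq_spec = as_spec(raw$teq_spec),
       bw_spec = as_spec(raw$bw_spec),
       n_iter = raw$n_iter %||% 10000,
       seed = raw$seed,
       percentiles = raw$percentiles %||% c(0.05, 0.5, 0.95))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
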