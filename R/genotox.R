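#' Comet-assay tail-moment group comparison
#'
#' Compares the tail moment (tail length x tail DNA fraction, dimensionless)
#' between the exposed and comparative groups with an independent t-test, and
#' across schools with a one-way ANOVA when a `school` column is present. A
#' Shapiro-Wilk normality gate (alpha = 0.05, per group) decides whether the
#' parametric result should be trusted; the non-parametric counterpart
#' (Mann-Whitney / Kruskal-Wallis) is always reported alongside rather than
#' silently swapped in.
#'
#' @param subjects data.frame with at least `group` (two levels, e.g.
#'   `exposed`/`comparative`) and `tail_moment`; optionally `school`.
#' @param var_equal Passed to [stats::t.test()]; defaults to `TRUE`
#'   (classical independent t-test).
#' @return List with `group_stats` (n, mean, sd per group), `t_test`,
#'   `wilcox`, `normal` (per-group Shapiro p-values and the gate verdict) and,
#'   if schools are present, `anova_schools` and `kruskal_schools`.
#' @export
compare_groups <- function(subjects, var_equal = TRUE) {
  if (!all(c("group", "tail_moment") %in% names(subjects)))
    stop("subjects need 'group' and 'tail_moment' columns")
  if (any(subjects$tail_moment < 0)) stop("tail moments must be nonnegative")
  groups <- split(subjects$tail_moment, subjects$group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 subjects")
  gs <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    mean = vapply(groups, mean, 1),
    sd = vapply(groups, stats::sd, 1),
    row.names = NULL
  )
  identical_groups <- all(vapply(groups, stats::sd, 1) == 0) &&
    abs(diff(vapply(groups, mean, 1))) == 0
  tt <- if (identical_groups) {
    list(statistic = c(t = 0), p.value = 1)  # degenerate: t.test errors here
  } else {
    stats::t.test(groups[[1]], groups[[2]], var.equal = var_equal)
  }
  wx <- if (identical_groups) list(p.value = 1) else
    suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
  shapiro_p <- vapply(groups, function(x) {
    if (stats::sd(x) == 0 || length(x) < 3) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  out <- list(
    group_stats = gs,
    t_test = tt,
    wilcox = wx,
    normal = list(shapiro_p = shapiro_p,
                  parametric_ok = all(is.na(shapiro_p) | shapiro_p >= 0.05))
  )
  if ("school" %in% names(subjects) &&
      length(unique(subjects$school)) > 1L &&
      stats::sd(subjects$tail_moment) > 0) {
    out$anova_schools <- stats::oneway.test(tail_moment ~ school,
                                            data = subjects, var.equal = TRUE)
    out$kruskal_schools <- stats::kruskal.test(tail_moment ~ school,
                                               data = subjects)
  }
  out
}

#' Stratified tail-moment comparison within each exposure group
#'
#' For a registered covariate (or age), summarises the tail moment per level
#' and tests the level effect separately inside the exposed and comparative
#' groups: an independent t-test for two levels, one-way ANOVA for more.
#' Levels with fewer than 2 subjects are flagged and excluded from the test.
#'
#' @param subjects Subject table (see [compare_groups()]); must also contain
#'   the stratification column.
#' @param factor Name of the column to stratify by (e.g. `"mosquito_coil"`,
#'   `"age"`).
#' @return data.frame with one row per group x level (`group`, `level`, `n`,
#'   `mean`, `sd`, `excluded`) and an attribute `tests`: per-group list with
#'   `method` and `p_value` (`NA` when fewer than two usable levels remain).
#' @export
stratified_comparison <- function(subjects, factor) {
  if (!factor %in% names(subjects))
    stop("unknown stratification factor: ", factor)
  if (length(unique(subjects[[factor]])) < 2L)
    stop("factor '", factor, "' has a single level: nothing to compare")
  rows <- list()
  tests <- list()
  for (g in unique(subjects$group)) {
    sub <- subjects[subjects$group == g, , drop = FALSE]
    lv <- split(sub$tail_moment, sub[[factor]])
    tab <- data.frame(
      group = g,
      level = names(lv),
      n = vapply(lv, length, 1L),
      mean = vapply(lv, mean, 1),
      sd = vapply(lv, stats::sd, 1),
      row.names = NULL
    )
    tab$excluded <- tab$n < 2L
    rows[[g]] <- tab
    usable <- lv[!tab$excluded]
    if (length(usable) < 2L) {
      tests[[g]] <- list(method = NA_character_, p_value = NA_real_)
    } else {
      y <- unlist(usable, use.names = FALSE)
      f <- factor(rep(names(usable), lengths(usable)))
      if (stats::sd(y) == 0) {
        # all outcomes equal across levels: no evidence of any effect
        tests[[g]] <- list(
          method = if (length(usable) == 2L) "t-test" else "anova",
          p_value = 1)
      } else if (length(usable) == 2L) {
        tests[[g]] <- list(method = "t-test",
                           p_value = stats::t.test(y ~ f,
                                                   var.equal = TRUE)$p.value)
      } else {
        tests[[g]] <- list(method = "anova",
                           p_value = stats::oneway.test(
                             y ~ f, var.equal = TRUE)$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}

#' Fit a tail-moment prediction model by backward elimination
#'
#' Ordinary least squares of the tail moment on the requested predictors,
#' followed by backward elimination: while any retained predictor has a
#' coefficient p-value of 0.05 or more, the worst one is dropped and the
#' model refit. Collinear predictor pairs are rejected up front (model-matrix
#' condition number above 1e8).
#'
#' @param subjects Subject table containing `tail_moment` and the predictors.
#' @param predictors Character vector of predictor column names.
#' @param p_remove Elimination threshold (default 0.05).
#' @return Object of class `tail_moment_fit`: `coefficients` (named, incl.
#'   `(Intercept)`), `adj_r2`, `f_stat`, `df`, `p_value`, `dropped`, and the
#'   underlying `lm` fit.
#' @export
fit_tail_moment_model <- function(subjects, predictors, p_remove = 0.05) {
  if (!"tail_moment" %in% names(subjects))
    stop("subjects need a 'tail_moment' column")
  missing <- setdiff(predictors, names(subjects))
  if (length(missing))
    stop("unknown predictors: ", paste(missing, collapse = ", "))
  if (nrow(subjects) <= length(predictors) + 1L)
    stop("need n > number of predictors + 1 for a residual degree of freedom")
  constant <- predictors[vapply(predictors, function(p)
    stats::sd(as.numeric(subjects[[p]])) == 0, logical(1))]
  if (length(constant))
    stop("constant predictor(s): ", paste(constant, collapse = ", "))
  mm <- stats::model.matrix(
    stats::reformulate(predictors), data = subjects)
  if (kappa(mm, exact = TRUE) > 1e8) {
    cors <- stats::cor(mm[, -1, drop = FALSE])
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("collinear predictors: ", colnames(cors)[worst[1]], " and ",
         colnames(cors)[worst[2]])
  }
  kept <- predictors
  dropped <- character()
  repeat {
    fit <- stats::lm(stats::reformulate(kept, response = "tail_moment"),
                     data = subjects)
    coefs <- summary(fit)$coefficients
    rows <- setdiff(rownames(coefs), "(Intercept)")
    pvals <- stats::setNames(coefs[rows, 4], rows)
    pvals[is.na(pvals)] <- 0  # zero residual variance: keep the predictor
    if (!length(pvals) || max(pvals) < p_remove) break
    worst <- names(which.max(pvals))
    # map a model-matrix column (e.g. factor dummies) back to its predictor
    victim <- kept[vapply(kept, function(p) startsWith(worst, p), logical(1))][1]
    if (is.na(victim)) victim <- worst
    kept <- setdiff(kept, victim)
    dropped <- c(dropped, victim)
    if (!length(kept)) {
      fit <- stats::lm(tail_moment ~ 1, data = subjects)
      break
    }
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = stats::coef(fit),
    adj_r2 = sm$adj.r.squared,
    f_stat = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
    df = if (!is.null(fstat)) unname(fstat[2:3]) else c(NA_real_, NA_real_),
    p_value = if (!is.null(fstat))
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
      else NA_real_,
    dropped = dropped,
    lm = fit
  ), class = "tail_moment_fit")
}

#' @export
print.tail_moment_fit <- function(x, digits = 4, ...) {
  cat("Tail-moment prediction model (OLS, backward elimination)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("adj R^2 = %.3f; F(%g, %g) = %.3f, p = %.3g\n",
              x$adj_r2, x$df[1], x$df[2], x$f_stat, x$p_value))
  if (length(x$dropped))
    cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Fixed-coefficient tail-moment prediction models
#'
#' The four published prediction equations for the comet tail moment after
#' confounder control. Each couples one PAH exposure metric with the
#' household open-burning indicator (1 = practice present):
#'
#' 1. `12.892 + 0.054 x total outdoor PAHs - 2.415 x open burning`
#'    (adj R^2 0.110)
#' 2. `14.120 + 0.170 x carcinogenic outdoor PAHs - 1.870 x open burning`
#'    (adj R^2 0.124)
#' 3. `13.345 + 0.076 x total indoor PAHs - 2.190 x open burning`
#'    (adj R^2 0.115)
#' 4. `15.468 + 0.187 x carcinogenic indoor PAHs - 2.328 x open burning`
#'    (adj R^2 0.127)
#'
#' Exposure units are ng m^-3. Note the published open-burning slopes are
#' negative even though the accompanying narrative describes open burning as
#' increasing DNA damage; the printed coefficients are reproduced as-is and
#' the contradiction is the caller's to interpret.
#'
#' @return Named list of `tail_moment_fit`-like fixed models, each with
#'   `coefficients` and `adj_r2`.
#' @export
tail_moment_models <- function() {
  fixed <- function(intercept, slopes, adj_r2) {
    structure(list(coefficients = c("(Intercept)" = intercept, slopes),
                   adj_r2 = adj_r2, f_stat = NA_real_,
                   df = c(NA_real_, NA_real_), p_value = NA_real_,
                   dropped = character(), lm = NULL),
              class = "tail_moment_fit")
  }
  list(
    model1 = fixed(12.892,
                   c(total_outdoor_pahs = 0.054, open_burning = -2.415),
                   0.110),
    model2 = fixed(14.120,
                   c(carcinogen_outdoor_pahs = 0.170, open_burning = -1.870),
                   0.124),
    model3 = fixed(13.345,
                   c(total_indoor_pahs = 0.076, open_burning = -2.190),
                   0.115),
    model4 = fixed(15.468,
                   c(carcinogen_indoor_pahs = 0.187, open_burning = -2.328),
                   0.127)
  )
}

#' Evaluate a tail-moment model on new covariates
#'
#' Affine evaluation of a fitted or fixed-coefficient model; every model
#' predictor must be supplied.
#'
#' @param model A `tail_moment_fit` (from [fit_tail_moment_model()] or
#'   [tail_moment_models()]).
#' @param covariates Named list / data.frame of predictor values.
#' @return Predicted tail moment (vectorised over covariate rows).
#' @export
predict_tail_moment <- function(model, covariates) {
  if (!inherits(model, "tail_moment_fit"))
    stop("model must be a tail_moment_fit")
  covariates <- as.data.frame(covariates)
  slopes <- model$coefficients[setdiff(names(model$coefficients),
                                       "(Intercept)")]
  missing <- setdiff(names(slopes), names(covariates))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  pred <- rep(model$coefficients[["(Intercept)"]], nrow(covariates))
  for (nm in names(slopes))
    pred <- pred + slopes[[nm]] * covariates[[nm]]
  pred
}

#' Read / write the subject table
#'
#' Columns: `subject_id, group, school, age, sex, bmi, body_weight_kg,
#' tail_moment, tobacco_smoke, grilled_food, supplement, mosquito_coil,
#' open_burning` plus any school-assigned exposure columns.
#'
#' @param path File path.
#' @export
read_subjects_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_subjects_csv
#' @param subjects Subject table to write.
#' @export
write_subjects_csv <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}
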