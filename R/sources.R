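#' Diagnostic-ratio rules for PAH source classification
#'
#' The six parent-PAH concentration ratios used to attribute samples to
#' pyrogenic/petrogenic origins and to specific combustion sources, with their
#' literature threshold taxonomy:
#'
#' * `LMW/HMW` — < 1 pyrogenic, otherwise petrogenic.
#' * `ANT/(ANT+PHE)` — < 0.1 petrogenic, otherwise pyrogenic.
#' * `IcP/(IcP+BgP)` — < 0.2 petrogenic, 0.2-0.5 fuel combustion, >= 0.5
#'   grass/wood/coal combustion.
#' * `BaA/CYR` — 0.2-0.35 coal combustion, >= 0.35 vehicular emission; below
#'   0.2 the literature assigns no source, labelled `unclassified`.
#' * `BaA/(BaA+CYR)` — < 0.2 petrogenic, 0.2-0.35 mixed, >= 0.35 combustion.
#' * `FLU/(FLU+PYR)` — < 0.5 gasoline, otherwise diesel.
#'
#' Intervals are half-open `[low, high)`: a value equal to a breakpoint takes
#' the label of the interval that starts there (e.g. BaA/(BaA+CYR) = 0.35 is
#' `combustion`).
#'
#' @return Named list of rules; each rule has `name`, `breakpoints`
#'   (strictly increasing) and `labels` (one more than breakpoints).
#' @export
diagnostic_rules <- function() {
  rule <- function(name, breakpoints, labels) {
    stopifnot(length(labels) == length(breakpoints) + 1L,
              !is.unsorted(breakpoints, strictly = TRUE))
    list(name = name, breakpoints = breakpoints, labels = labels)
  }
  list(
    "LMW/HMW" = rule("LMW/HMW", 1, c("pyrogenic", "petrogenic")),
    "ANT/(ANT+PHE)" = rule("ANT/(ANT+PHE)", 0.1, c("petrogenic", "pyrogenic")),
    "IcP/(IcP+BgP)" = rule("IcP/(IcP+BgP)", c(0.2, 0.5),
                           c("petrogenic", "fuel combustion",
                             "grass/wood/coal combustion")),
    "BaA/CYR" = rule("BaA/CYR", c(0.2, 0.35),
                     c("unclassified", "coal combustion", "vehicular emission")),
    "BaA/(BaA+CYR)" = rule("BaA/(BaA+CYR)", c(0.2, 0.35),
                           c("petrogenic", "mixed", "combustion")),
    "FLU/(FLU+PYR)" = rule("FLU/(FLU+PYR)", 0.5, c("gasoline", "diesel"))
  )
}

#' Compute the six diagnostic ratios for each sample
#'
#' A zero denominator yields `NA` with `defined = FALSE`; such samples are
#' excluded from that rule's tally rather than forced into a category.
#'
#' @param profiles Imputed profile table (see [impute_below_mdl()]).
#' @return Long data.frame with columns `sample_id`, `rule`, `value`,
#'   `defined`.
#' @export
compute_diagnostic_ratios <- function(profiles) {
  stop_if_missing_values(profiles, "compute_diagnostic_ratios")
  ids <- if ("sample_id" %in% names(profiles)) profiles$sample_id
         else seq_len(nrow(profiles))
  split <- lmw_hmw_split(profiles)
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  with_cols <- function(x) profiles[[x]]
  vals <- list(
    "LMW/HMW" = safe_ratio(split$lmw, split$hmw),
    "ANT/(ANT+PHE)" = safe_ratio(with_cols("ANT"),
                                 with_cols("ANT") + with_cols("PHE")),
    "IcP/(IcP+BgP)" = safe_ratio(with_cols("IcP"),
                                 with_cols("IcP") + with_cols("BgP")),
    "BaA/CYR" = safe_ratio(with_cols("BaA"), with_cols("CYR")),
    "BaA/(BaA+CYR)" = safe_ratio(with_cols("BaA"),
                                 with_cols("BaA") + with_cols("CYR")),
    "FLU/(FLU+PYR)" = safe_ratio(with_cols("FLU"),
                                 with_cols("FLU") + with_cols("PYR"))
  )
  out <- do.call(rbind, lapply(names(vals), function(rn) {
    data.frame(sample_id = ids, rule = rn, value = vals[[rn]],
               stringsAsFactors = FALSE)
  }))
  out$defined <- !is.na(out$value)
  rownames(out) <- NULL
  out
}

#' Classify a diagnostic-ratio value
#'
#' @param rule A rule name (see [diagnostic_rules()]) or a rule object.
#' @param value Nonnegative ratio value(s); `NA` propagates as `NA`.
#' @return Character vector of source labels.
#' @examples
#' classify_source("FLU/(FLU+PYR)", 0.25)  # "gasoline"
#' @export
classify_source <- function(rule, value) {
  if (is.character(rule)) {
    rules <- diagnostic_rules()
    if (!rule %in% names(rules)) stop("unknown diagnostic rule: ", rule)
    rule <- rules[[rule]]
  }
  if (any(value < 0, na.rm = TRUE))
    stop("diagnostic ratios are nonnegative")
  idx <- findInterval(value, rule$breakpoints) + 1L
  out <- rule$labels[idx]
  out[is.na(value)] <- NA_character_
  out
}

#' Ratio computation and classification in one pass
#'
#' @inheritParams compute_diagnostic_ratios
#' @return The [compute_diagnostic_ratios()] table with a `label` column.
#' @export
source_calls <- function(profiles) {
  ratios <- compute_diagnostic_ratios(profiles)
  ratios$label <- NA_character_
  for (rn in unique(ratios$rule)) {
    sel <- ratios$rule == rn
    ratios$label[sel] <- classify_source(rn, ratios$value[sel])
  }
  ratios
}

#' @rdname source_calls
#' @param calls Output of [source_calls()].
#' @param path File path for the ratio-call CSV.
#' @export
write_source_calls_csv <- function(calls, path) {
  utils::write.csv(calls[, c("sample_id", "rule", "value", "label")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 samples")
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant column: correlation matrix undefined")
  stats::cor(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO statistic comparing squared correlations with squared
#' anti-image (partial) correlations; values above 0.5 indicate the dataset
#' is suitable for factor extraction. Any two-variable dataset has KMO = 0.5
#' exactly, since the sole partial correlation equals the correlation.
#'
#' @param x Numeric matrix or data.frame, samples in rows, variables in
#'   columns.
#' @return KMO value in `[0, 1]`.
#' @export
kmo_statistic <- function(x) {
  r <- correlation_matrix(x)
  p <- ncol(r)
  rinv <- tryCatch(solve(r), error = function(e)
    stop("singular correlation matrix: KMO undefined"))
  d <- 1 / sqrt(diag(rinv))
  partial <- -rinv * tcrossprod(d)      # anti-image partial correlations
  off <- upper.tri(r)
  ssr <- sum(r[off]^2)
  ssp <- sum(partial[off]^2)
  if (ssr + ssp == 0)
    stop("all off-diagonal correlations are zero: KMO degenerate")
  ssr / (ssr + ssp)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity, i.e. whether the
#' variables are uncorrelated and factor extraction is pointless. The test
#' statistic is \eqn{-(n - 1 - (2p + 5)/6) \log|R|} on \eqn{p(p-1)/2}
#' degrees of freedom.
#'
#' @inheritParams kmo_statistic
#' @return List with `chi2`, `df` and `p_value`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (p < 2L) stop("Bartlett's test needs at least 2 variables")
  if (n <= p) stop("Bartlett's test needs more samples than variables")
  r <- correlation_matrix(x)
  detr <- det(r)
  if (detr <= 0) stop("correlation matrix not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detr)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Label factor-loading strength
#'
#' Conventional interpretation bands on the absolute loading: above 0.75
#' heavy, 0.50-0.75 moderate, 0.30-0.50 weak, below 0.30 none. Boundaries
#' follow the half-open convention used throughout (0.50 is moderate, 0.75 is
#' heavy).
#'
#' @param loadings Numeric vector/matrix of loadings in `[-1, 1]`.
#' @return Character labels with the same shape as `loadings`.
#' @export
interpret_loadings <- function(loadings) {
  a <- abs(loadings)
  if (any(a > 1 + 1e-6, na.rm = TRUE))
    stop("loadings must lie in [-1, 1]")
  lab <- ifelse(a >= 0.75, "heavy",
         ifelse(a >= 0.50, "moderate",
         ifelse(a >= 0.30, "weak", "none")))
  if (is.matrix(loadings)) {
    lab <- matrix(lab, nrow = nrow(loadings), dimnames = dimnames(loadings))
  }
  lab
}

#' Principal component analysis with varimax rotation
#'
#' Standardises the columns, extracts principal components of the correlation
#' matrix, retains those with eigenvalue above `eigen_threshold` (Kaiser
#' criterion) and varimax-rotates the retained loadings with Kaiser
#' normalisation. Adequacy is gated on KMO > 0.5 and a significant Bartlett
#' sphericity test; inadequate data produce a warning, not an error, so
#' exploratory runs still return the decomposition.
#'
#' @inheritParams kmo_statistic
#' @param eigen_threshold Minimum eigenvalue for a component to be retained
#'   (default 1).
#' @param alpha Significance level for the Bartlett gate.
#' @return Object of class `pah_pca`: `loadings` (rotated, variables x
#'   components), `eigenvalues` (retained), `variance_pct` (per rotated
#'   component, % of total variance), `communalities`, `kmo`, `bartlett`,
#'   `labels` (strength labels from [interpret_loadings()]), `n_retained`,
#'   `rotated` flag.
#' @export
run_pca_varimax <- function(x, eigen_threshold = 1, alpha = 0.05) {
  x <- as.matrix(x)
  kmo <- kmo_statistic(x)
  bart <- bartlett_sphericity(x)
  if (kmo <= 0.5)
    warning(sprintf("KMO = %.3f <= 0.5: sampling adequacy is poor", kmo))
  if (bart$p_value > alpha)
    warning("Bartlett's sphericity test is not significant")
  z <- scale(x)
  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  keep <- which(eig$values > eigen_threshold)
  n_keep <- length(keep)
  if (n_keep == 0L) stop("no component exceeds the eigenvalue threshold")
  load <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), n_keep)
  rownames(load) <- colnames(x)
  rotated <- n_keep >= 2L
  if (rotated) {
    rot <- stats::varimax(load, normalize = TRUE)  # Kaiser normalisation
    load <- unclass(rot$loadings)
  } else {
    warning("fewer than 2 retained components: rotation skipped")
  }
  # enforce the positive-orientation convention per component
  flip <- apply(load, 2, function(v) sum(v) < 0)
  load[, flip] <- -load[, flip]
  colnames(load) <- paste0("PC", seq_len(n_keep))
  variance_pct <- 100 * colSums(load^2) / ncol(x)
  structure(list(
    loadings = load,
    eigenvalues = eig$values[keep],
    all_eigenvalues = eig$values,
    variance_pct = variance_pct,
    communalities = rowSums(load^2),
    kmo = kmo,
    bartlett = bart,
    labels = interpret_loadings(load),
    n_retained = n_keep,
    rotated = rotated
  ), class = "pah_pca")
}

#' @export
print.pah_pca <- function(x, digits = 3, ...) {
  cat("Principal components analysis with varimax rotation\n")
  cat(sprintf("KMO = %.3f; Bartlett chi2 = %.2f (df = %d, p = %.3g)\n",
              x$kmo, x$bartlett$chi2, x$bartlett$df, x$bartlett$p_value))
  cat(sprintf("%d component(s) retained (eigenvalue > 1)%s\n",
              x$n_retained, if (x$rotated) ", varimax-rotated" else ""))
  tab <- rbind(Eigenvalue = round(x$eigenvalues, digits),
               `Variance %` = round(x$variance_pct, digits))
  colnames(tab) <- colnames(x$loadings)
  print(tab)
  cat("\nRotated loadings (|loading| >= 0.30 shown):\n")
  disp <- round(x$loadings, digits)
  disp[abs(x$loadings) < 0.30] <- NA
  print(disp, na.print = ".")
  invisible(x)
}

#' @rdname run_pca_varimax
#' @param pca A `pah_pca` object.
#' @param path File path for the PCA report CSV (per congener x component:
#'   loading, strength label; component eigenvalue and variance share).
#' @export
write_pca_report_csv <- function(pca, path) {
  long <- expand.grid(congener = rownames(pca$loadings),
                      component = colnames(pca$loadings),
                      stringsAsFactors = FALSE)
  long$loading <- mapply(function(cg, pc) pca$loadings[cg, pc],
                         long$congener, long$component)
  long$strength <- mapply(function(cg, pc) pca$labels[cg, pc],
                          long$congener, long$component)
  long$eigenvalue <- pca$eigenvalues[match(long$component,
                                           colnames(pca$loadings))]
  long$variance_pct <- pca$variance_pct[long$component]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
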