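# Independent oracles and small fixture builders used across test files.

# One-row profile table from named concentrations; unnamed congeners get 0.
make_profile <- function(..., sample_id = "s1") {
  conc <- c(...)
  all16 <- stats::setNames(rep(0, 16), pah_congeners())
  all16[names(conc)] <- conc
  out <- data.frame(sample_id = sample_id, school = "X", zone = "exposed",
                    site = "outdoor", stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(all16)))
}

# Random multi-sample profile table with strictly positive concentrations.
random_profiles <- function(n, seed) {
  set.seed(seed)
  mat <- matrix(stats::rlnorm(n * 16, 0, 1), n, 16,
                dimnames = list(NULL, pah_congeners()))
  out <- data.frame(sample_id = paste0("r", seq_len(n)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}

# Brute-force KMO: partial correlations obtained by residualising each pair
# of variables on all the others with lm(), never via the inverse
# correlation matrix the implementation uses.
brute_kmo <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  r <- stats::cor(x)
  partial <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- if (ncol(others)) stats::resid(stats::lm(x[, i] ~ others))
            else x[, i]
      rj <- if (ncol(others)) stats::resid(stats::lm(x[, j] ~ others))
            else x[, j]
      partial[i, j] <- partial[j, i] <- stats::cor(ri, rj)
    }
  }
  off <- upper.tri(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(partial[off]^2))
}

# Bartlett sphericity by direct evaluation: correlations assembled from
# covariances by hand, log-determinant through the eigenvalues.
brute_bartlett <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  cv <- stats::cov(x)
  r <- cv / sqrt(outer(diag(cv), diag(cv)))
  logdet <- sum(log(eigen(r, symmetric = TRUE, only.values = TRUE)$values))
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * logdet
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# Four exactly mutually uncorrelated, non-constant columns.
orthogonal_columns <- function() {
  cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1), c = c(1, -1, -1, 1))
}

# Subject table for regression tests: tail moment generated from a known
# affine model plus optional Gaussian noise.
model_subjects <- function(n, intercept, slopes, noise_sd = 0, seed = 1) {
  set.seed(seed)
  covs <- data.frame(
    total_outdoor_pahs = stats::runif(n, 5, 70),
    open_burning = stats::rbinom(n, 1, 0.4),
    carcinogen_indoor_pahs = stats::runif(n, 1, 40)
  )
  tm <- intercept
  for (nm in names(slopes)) tm <- tm + slopes[[nm]] * covs[[nm]]
  covs$tail_moment <- tm + stats::rnorm(n, 0, noise_sd)
  covs$group <- "exposed"
  covs
}
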