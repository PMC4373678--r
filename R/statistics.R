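# Statistical characterisation of the score distribution: moments with
# small-sample standard errors, the D'Agostino-Pearson omnibus normality
# test, integer-bin histograms with an amplitude-form Gaussian fit, and
# Spearman rank correlation with mean-rank ties.

#' Standard error of skewness
#'
#' Small-sample closed form
#' `sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))`.
#'
#' @param n Sample size (>= 3).
#' @return Numeric SES.
#' @examples
#' round(ses(86), 4)  # 0.2597
#' @export
ses <- function(n) {
  if (any(n < 3)) stop("ses() requires n >= 3", call. = FALSE)
  sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
}

#' Standard error of kurtosis
#'
#' Small-sample closed form
#' `2 * ses(n) * sqrt((n^2 - 1) / ((n-3)(n+5)))`.
#'
#' @param n Sample size (>= 4).
#' @return Numeric SEK.
#' @examples
#' round(sek(86), 4)  # 0.5139
#' @export
sek <- function(n) {
  if (any(n < 4)) stop("sek() requires n >= 4", call. = FALSE)
  2 * ses(n) * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
}

#' Describe a score distribution
#'
#' Computes sample mean and SD, the sample-adjusted skewness G1 and
#' excess kurtosis G2 with their small-sample standard errors ([ses()],
#' [sek()]), the D'Agostino-Pearson omnibus statistic
#' `K2 = Z1^2 + Z2^2` (skewness Z-transform after D'Agostino 1970,
#' kurtosis Z-transform after Anscombe & Glynn 1983, both applied to the
#' biased moment ratios) with its chi-square (2 df) p-value, and the
#' `|stat| > 2 SE` significance flags.
#'
#' @param values Numeric vector, `n >= 8`, non-constant.
#' @return Object of class `"score_distribution_summary"`: list with
#'   `n`, `mean`, `sd`, `skewness`, `ses`, `skew_significant`,
#'   `kurtosis`, `sek`, `kurt_significant`, `z_skew`, `z_kurt`, `k2`,
#'   `p_value`.
#' @export
describe_distribution <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 8L) stop("need n >= 8 for the omnibus normality test", call. = FALSE)
  m <- mean(values)
  dev <- values - m
  m2 <- mean(dev^2)
  if (m2 == 0) stop("constant input: moments undefined", call. = FALSE)
  m3 <- mean(dev^3)
  m4 <- mean(dev^4)
  b1 <- m3 / m2^1.5          # biased skewness
  b2 <- m4 / m2^2            # biased kurtosis (not excess)
  G1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  # D'Agostino (1970) transform of sqrt(b1)
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # Anscombe & Glynn (1983) transform of b2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xb2 <- (b2 - eb2) / sqrt(vb2)
  sb2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb2 * (2 / sb2 + sqrt(1 + 4 / sb2^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xb2 * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z1^2 + z2^2
  structure(list(
    n = n, mean = m, sd = sd(values),
    skewness = G1, ses = ses(n), skew_significant = abs(G1) > 2 * ses(n),
    kurtosis = G2, sek = sek(n), kurt_significant = abs(G2) > 2 * sek(n),
    z_skew = z1, z_kurt = z2, k2 = k2,
    p_value = pchisq(k2, df = 2, lower.tail = FALSE)),
    class = "score_distribution_summary")
}

#' @export
print.score_distribution_summary <- function(x, ...) {
  cat(sprintf("n = %d, mean %.4f, sd %.4f\n", x$n, x$mean, x$sd))
  cat(sprintf("skewness G1 %.4f (SES %.4f)%s; kurtosis G2 %.4f (SEK %.4f)%s\n",
              x$skewness, x$ses, if (x$skew_significant) " *" else "",
              x$kurtosis, x$sek, if (x$kurt_significant) " *" else ""))
  cat(sprintf("D'Agostino-Pearson K2 = %.4f, p = %.4f\n", x$k2, x$p_value))
  invisible(x)
}

#' Histogram of integer scores
#'
#' @param values Integer-valued scores, all within `[bin_lo, bin_hi]`.
#' @param bin_lo,bin_hi Inclusive integer bin range (bin centres).
#' @return data.frame with `center` and `count`; counts sum to
#'   `length(values)`.
#' @export
score_histogram <- function(values, bin_lo = 0L, bin_hi = 11L) {
  if (length(values) && any(values != round(values)))
    stop("scores must be integers", call. = FALSE)
  if (length(values) && (any(values < bin_lo) || any(values > bin_hi)))
    stop("score outside bin range", call. = FALSE)
  centers <- seq.int(bin_lo, bin_hi)
  counts <- vapply(centers, function(cc) sum(values == cc), integer(1))
  data.frame(center = centers, count = counts)
}

#' Fit an amplitude-form Gaussian to histogram counts
#'
#' Unweighted least squares of `y = A exp(-(x - mu)^2 / (2 sigma^2))`
#' via Levenberg-Marquardt, started at `A = max(count)`,
#' `mu` = count-weighted mean, `sigma` = count-weighted SD.  Goodness of
#' fit follows the usual nonlinear-regression conventions: ordinary
#' `R^2 = 1 - SS_res/SS_tot` about the mean count, asymptotic standard
#' errors, t-based 95% confidence intervals, `df = n_points - 3`, and
#' `sy.x = sqrt(SS_res / df)`.
#'
#' @param counts Numeric bin counts.
#' @param centers Bin centres (same length, >= 4 points).
#' @return Object of class `"gaussian_fit"`: list with `amplitude`,
#'   `mean`, `sd`, `se` (named vector), `ci95` (2x3 matrix), `df`,
#'   `r_squared`, `ss_res`, `sy_x`, and the `fitted` values.
#' @export
fit_gaussian <- function(counts, centers) {
  stopifnot(length(counts) == length(centers))
  if (length(counts) < 4L) stop("need at least 4 points", call. = FALSE)
  if (all(counts == 0)) stop("degenerate all-zero counts", call. = FALSE)
  ntot <- sum(counts)
  mu0 <- sum(centers * counts) / ntot
  s0 <- sqrt(sum(counts * (centers - mu0)^2) / ntot)
  if (s0 <= 0) s0 <- diff(range(centers)) / 6
  dat <- data.frame(x = centers, y = counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)), data = dat,
                      start = list(A = max(counts), mu = mu0, sigma = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- coef(fit)
  est["sigma"] <- abs(est[["sigma"]])
  se <- summary(fit)$coefficients[, "Std. Error"]
  df <- length(counts) - 3L
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  tq <- qt(0.975, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  structure(list(amplitude = est[["A"]], mean = est[["mu"]],
                 sd = est[["sigma"]],
                 se = c(amplitude = se[["A"]], mean = se[["mu"]],
                        sd = se[["sigma"]]),
                 ci95 = ci, df = df,
                 r_squared = 1 - ss_res / ss_tot,
                 ss_res = ss_res, sy_x = sqrt(ss_res / df),
                 fitted = as.numeric(fitted(fit))),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: A %.4f, mean %.4f, sd %.4f (df %d)\n",
              x$amplitude, x$mean, x$sd, x$df))
  cat(sprintf("R2 %.4f, SS_res %.4f, sy.x %.4f\n", x$r_squared, x$ss_res, x$sy_x))
  invisible(x)
}

#' Spearman rank correlation with mean-rank ties
#'
#' `rho` is the Pearson correlation of mean ranks.  The two-sided
#' p-value uses the t approximation on `n - 2` degrees of freedom; for
#' small samples (`n <= 8`) an exact permutation p-value is available.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param exact Use exact permutation enumeration (requires `n <= 8`).
#' @return Object of class `"spearman_result"`: list with `rho`,
#'   `p_value`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("zero rank variance: correlation undefined", call. = FALSE)
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 8L) stop("exact permutation supported for n <= 8", call. = FALSE)
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p_value <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_value <- 2 * pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p_value, n = n, method = method),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d), p = %.4g [%s]\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

# All n! permutations of 1..n as a matrix (rows); n is small by contract.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
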