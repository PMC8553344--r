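#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Pearson statistic without continuity correction (the convention used for
#' the prevalence comparisons), with the p-value from the upper tail of the
#' chi-squared distribution with 1 degree of freedom.
#'
#' @param table 2x2 numeric matrix of nonnegative counts, or the four counts
#'   `a, b, c, d` (row-wise).
#' @return List of class `chi2_test`: `statistic`, `p`, `df`, `expected`.
#' @export
chi2_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, nrow = 2L, byrow = TRUE)
  stopifnot(all(dim(table) == 2L), all(table >= 0), sum(table) >= 1)
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal")
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  structure(list(statistic = stat,
                 p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
                 df = 1L, expected = E),
            class = "chi2_test")
}

#' @export
print.chi2_test <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = 1, p = %.3g\n", x$statistic, x$p))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests a sample of phase angles against the uniform circular distribution.
#' R is the mean resultant length, Z = n R^2, and the p-value uses the
#' standard small-sample-corrected approximation
#' `exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param angles Numeric vector of angles (radians), n >= 2.
#' @return List of class `rayleigh_test`: `R`, `Z`, `p`, `n`, `mean_angle`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  stopifnot(n >= 2L, all(is.finite(angles)))
  C <- mean(cos(angles))
  S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  structure(list(R = R, Z = Z, p = min(p, 1), n = n,
                 mean_angle = atan2(S, C)),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh: R = %.3f, Z = %.3f, p = %.3g (n = %d)\n",
              x$R, x$Z, x$p, x$n))
  invisible(x)
}

# Fisher's approximation to the ML von Mises concentration for mean
# resultant length r (Fisher 1993, as used by the circular-statistics
# literature).
.kappa_est <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal circular means
#'
#' Circular one-way F test for two samples, with the standard concentration
#' correction factor K = 1 + 3/(8 kappa), kappa estimated from the pooled
#' mean resultant length (Berens/Zar formulation):
#' `F = K (N - 2) (R1 + R2 - RT) / (N - R1 - R2)`, referred to
#' F(1, N - 2). Assumes comparable, adequate concentrations; a warning is
#' attached when the pooled mean resultant length is below 0.45.
#'
#' @param a,b Numeric angle vectors (radians), each n >= 5.
#' @return List of class `ww_test`: `F`, `p`, `df1`, `df2`, `kappa`,
#'   `rbar`, `warning_low_concentration`.
#' @export
watson_williams_test <- function(a, b) {
  stopifnot(length(a) >= 5L, length(b) >= 5L)
  res <- function(x) {
    c(sum(cos(x)), sum(sin(x)))
  }
  ra <- res(a)
  rb <- res(b)
  R1 <- sqrt(sum(ra^2))
  R2 <- sqrt(sum(rb^2))
  rt <- ra + rb
  RT <- sqrt(sum(rt^2))
  N <- length(a) + length(b)
  rbar <- (R1 + R2) / N
  if (1 - rbar < 1e-12) {  # both samples perfectly concentrated
    same <- abs(atan2(ra[2L], ra[1L]) - atan2(rb[2L], rb[1L])) < 1e-8
    return(structure(list(F = if (same) 0 else Inf,
                          p = if (same) 1 else 0, df1 = 1L, df2 = N - 2L,
                          kappa = Inf, rbar = rbar,
                          warning_low_concentration = FALSE),
                     class = "ww_test"))
  }
  kappa <- .kappa_est(rbar)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * (N - 2L) * (R1 + R2 - RT) / (N - R1 - R2)
  Fstat <- max(Fstat, 0)
  structure(list(F = Fstat,
                 p = stats::pf(Fstat, 1L, N - 2L, lower.tail = FALSE),
                 df1 = 1L, df2 = N - 2L, kappa = kappa, rbar = rbar,
                 warning_low_concentration = rbar < 0.45),
            class = "ww_test")
}

#' @export
print.ww_test <- function(x, ...) {
  cat(sprintf("Watson-Williams: F(%d,%d) = %.3f, p = %.3g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$warning_low_concentration)
                " [low concentration: interpret with caution]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' mapped back to the input order. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
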