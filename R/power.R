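#' Analytic power to detect an F2 QTL
#'
#' Closed-form power for the single-marker additive test in an F2
#' intercross. The proportion of phenotypic variance the nearest marker
#' captures from a QTL of heritability \code{h2} is attenuated by
#' recombination: with average marker spacing \code{spacing} cM the QTL sits
#' on average half a spacing from the test marker, the additive association
#' decays by rho = (1 - 2r) with r the Haldane recombination fraction at
#' spacing/2, and the marker-level variance is h2 rho^2. The test statistic
#' is noncentral F(1, n - 2) with noncentrality
#' lambda = n h2 rho^2 / (1 - h2 rho^2), and power is the upper tail beyond
#' the alpha critical value. With \code{n_qtl} equal-effect loci the total
#' heritability is split evenly and the per-QTL power returned. An
#' additive-plus-dominance 2-df variant is available via \code{df2}.
#'
#' @param n F2 sample size.
#' @param h2 QTL heritability (total heritability when \code{n_qtl} > 1).
#' @param spacing Average marker spacing in cM.
#' @param alpha Type-I error rate.
#' @param n_qtl Number of equal-effect QTL sharing \code{h2}.
#' @param df2 Use the 2-df (additive + dominance) test instead of 1-df.
#' @param lambda_form "odds" uses h2m/(1 - h2m) (variance-ratio
#'   noncentrality, the default); "plain" uses h2m alone.
#' @return Power in [0, 1], with attributes \code{lambda} and
#'   \code{critical}.
#' @export
qtlDetectionPower <- function(n = 192, h2 = 0.097, spacing = 0.8,
                              alpha = 0.01, n_qtl = 1, df2 = FALSE,
                              lambda_form = c("odds", "plain")) {
  lambda_form <- match.arg(lambda_form)
  stopifnot(n >= 2, h2 >= 0, h2 < 1, alpha > 0, alpha < 1,
            spacing >= 0, n_qtl >= 1)
  h2q <- h2 / n_qtl
  if (h2q == 0) return(structure(alpha, lambda = 0, critical = NA_real_))
  r <- haldane(spacing / 2)
  rho2 <- (1 - 2 * r)^2
  h2m <- h2q * rho2
  lambda <- if (lambda_form == "odds") n * h2m / (1 - h2m) else n * h2m
  df1 <- if (df2) 2 else 1
  crit <- stats::qf(1 - alpha, df1, n - 2)
  pow <- stats::pf(crit, df1, n - 2, ncp = lambda, lower.tail = FALSE)
  structure(pow, lambda = lambda, critical = crit)
}

#' Power table across the study heritabilities
#'
#' Convenience wrapper producing the single-QTL and 10-equal-QTL powers for
#' a set of trait heritabilities.
#'
#' @param h2 Vector of total heritabilities.
#' @param n,spacing,alpha See \code{\link{qtlDetectionPower}}.
#' @param n_qtl Architectures to tabulate.
#' @return data.frame: h2, n_qtl, power.
#' @export
powerTable <- function(h2 = c(0.097, 0.299, 0.388, 0.148), n = 192,
                       spacing = 0.8, alpha = 0.01, n_qtl = c(1, 10)) {
  out <- expand.grid(h2 = h2, n_qtl = n_qtl)
  out$power <- mapply(function(h, q)
    as.numeric(qtlDetectionPower(n, h, spacing, alpha, q)), out$h2, out$n_qtl)
  out
}
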