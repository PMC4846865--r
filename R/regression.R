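#' Multilinear flexibility model: RMSF from surface accessibility and B-factor
#'
#' Ordinary least squares fit of
#' \code{RMSF = a * (relative SASA) + b * (B-factor) + c}, relating observed
#' per-residue fluctuations to crystallographic structure descriptors, plus
#' the Pearson correlation between fitted and observed RMSF.
#'
#' @param observed_rmsf Numeric vector of observed RMSF (Angstrom).
#' @param bfactors Numeric vector of crystallographic B-factors (Angstrom^2).
#' @param relative_sasa Numeric vector of relative SASA (fraction of the
#'   Ala-X-Ala reference).
#' @param max_condition Condition-number ceiling for the design matrix;
#'   collinear predictors beyond it are an error.
#' @return A \code{regression_model}: list with \code{a} (Angstrom per
#'   relative-SASA unit), \code{b} (Angstrom per Angstrom^2), \code{c}
#'   (Angstrom), \code{r} (Pearson R, fitted vs observed; NA with a warning if
#'   the observations have zero variance), \code{n}, \code{fitted} and the
#'   underlying \code{lm} fit.
#' @export
fit_rmsf_model <- function(observed_rmsf, bfactors, relative_sasa,
                           max_condition = 1e10) {
  n <- length(observed_rmsf)
  if (length(bfactors) != n || length(relative_sasa) != n) {
    stop("observed_rmsf, bfactors and relative_sasa must have equal length")
  }
  if (n < 4) stop("need at least 4 observations to fit 3 parameters")
  X <- cbind(1, relative_sasa, bfactors)
  kap <- kappa(X, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop("collinear predictors: design-matrix condition number ",
         format(kap, digits = 3), " exceeds ", format(max_condition))
  }
  fit <- lm(observed_rmsf ~ relative_sasa + bfactors)
  co <- coef(fit)
  r <- if (sd(observed_rmsf) < 1e-12 || sd(fitted(fit)) < 1e-12) {
    warning("zero variance in observed or fitted RMSF: R undefined")
    NA_real_
  } else {
    pearson_r(fitted(fit), observed_rmsf)
  }
  structure(list(a = unname(co["relative_sasa"]),
                 b = unname(co["bfactors"]),
                 c = unname(co["(Intercept)"]),
                 r = r, n = n, fitted = unname(fitted(fit)), fit = fit,
                 units = c(a = "Angstrom per relative-SASA unit",
                           b = "Angstrom per Angstrom^2", c = "Angstrom")),
            class = "regression_model")
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length.
#' @return Pearson R; NA with a warning if either input has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sd(x) < 1e-300 || sd(y) < 1e-300) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' @export
print.regression_model <- function(x, ...) {
  cat(sprintf(paste0("RMSF = %.4g * (relative SASA) + %.4g * (B-factor) ",
                     "+ %.4g   [R = %.3f, n = %d]\n"),
              x$a, x$b, x$c, x$r, x$n))
  invisible(x)
}

#' @importFrom stats fitted
NULL
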