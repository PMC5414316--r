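#' Variance components for genomic BLUP
#'
#' Collects the marker-effect variance \eqn{\sigma^2_\beta}, the residual
#' variance \eqn{\sigma^2_e}, their ratio
#' \eqn{\lambda = \sigma^2_e / \sigma^2_\beta} (the shrinkage parameter of
#' the mixed model equations) and the large variance \eqn{\sigma^2_L}
#' attached to the overall mean when it is treated as random (the
#' random-mean device of LOOCV strategy II).
#'
#' Any two of `sigma2_beta`, `sigma2_e`, `lambda` determine the third. If
#' only `lambda` is given, `sigma2_e` defaults to 1 (so
#' `sigma2_beta = 1/lambda`), matching the usual convention when only the
#' ratio is known.
#'
#' @param sigma2_beta marker-effect variance, > 0.
#' @param sigma2_e residual variance, > 0.
#' @param lambda variance ratio `sigma2_e / sigma2_beta`, > 0.
#' @param sigma2_L variance of the "random" overall mean; must satisfy
#'   `sigma2_L >= 100 * sigma2_e` so the mean is indistinguishable from a
#'   fixed effect. Default `1000 * sigma2_e`.
#' @return an object of class `"variance_components"`: a list with elements
#'   `sigma2_beta`, `sigma2_e`, `lambda`, `sigma2_L`.
#' @examples
#' variance_components(lambda = 10)             # sigma2_e = 1, sigma2_beta = 0.1
#' variance_components(sigma2_beta = 0.1, sigma2_e = 1)
#' @export
variance_components <- function(sigma2_beta = NULL, sigma2_e = NULL,
                                lambda = NULL, sigma2_L = NULL) {
  given <- c(beta = !is.null(sigma2_beta), e = !is.null(sigma2_e),
             lam = !is.null(lambda))
  if (!any(given))
    stop("supply sigma2_beta and sigma2_e, or lambda")
  if (is.null(lambda)) {
    if (is.null(sigma2_e)) sigma2_e <- 1
    if (is.null(sigma2_beta))
      stop("sigma2_beta (or lambda) is required")
    lambda <- sigma2_e / sigma2_beta
  } else {
    if (is.null(sigma2_e) && is.null(sigma2_beta)) sigma2_e <- 1
    if (is.null(sigma2_beta)) sigma2_beta <- sigma2_e / lambda
    if (is.null(sigma2_e)) sigma2_e <- lambda * sigma2_beta
    if (abs(lambda - sigma2_e / sigma2_beta) >
        1e-8 * max(1, abs(lambda)))
      stop("inconsistent variance components: lambda = ", lambda,
           " but sigma2_e/sigma2_beta = ", sigma2_e / sigma2_beta)
  }
  if (!is.finite(sigma2_beta) || sigma2_beta <= 0)
    stop("sigma2_beta must be a positive number")
  if (!is.finite(sigma2_e) || sigma2_e <= 0)
    stop("sigma2_e must be a positive number")
  if (is.null(sigma2_L)) sigma2_L <- 1000 * sigma2_e
  if (!is.finite(sigma2_L) || sigma2_L < 100 * sigma2_e)
    stop("sigma2_L must be large relative to sigma2_e ",
         "(require sigma2_L >= 100 * sigma2_e); got ", sigma2_L)
  structure(list(sigma2_beta = sigma2_beta, sigma2_e = sigma2_e,
                 lambda = sigma2_e / sigma2_beta, sigma2_L = sigma2_L),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components:\n")
  cat(sprintf("  sigma2_beta = %g\n  sigma2_e    = %g\n", x$sigma2_beta,
              x$sigma2_e))
  cat(sprintf("  lambda      = %g  (sigma2_e / sigma2_beta)\n", x$lambda))
  cat(sprintf("  sigma2_L    = %g  (random-mean device)\n", x$sigma2_L))
  invisible(x)
}

# Resolve loose arguments into a variance_components object.
as_variance_components <- function(vc = NULL, sigma2_beta = NULL,
                                   sigma2_e = NULL, lambda = NULL,
                                   sigma2_L = NULL) {
  if (!is.null(vc)) {
    if (!inherits(vc, "variance_components"))
      stop("vc must be a variance_components object")
    if (!is.null(sigma2_L))
      vc <- variance_components(vc$sigma2_beta, vc$sigma2_e,
                                sigma2_L = sigma2_L)
    return(vc)
  }
  variance_components(sigma2_beta, sigma2_e, lambda, sigma2_L)
}
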