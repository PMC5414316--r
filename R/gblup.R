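#' Fit genomic BLUP by the mixed model equations
#'
#' Fits the ridge-type genomic BLUP model
#' \deqn{y = 1\mu + X\beta + e,}
#' with marker effects \eqn{\beta} iid \eqn{(0, \sigma^2_\beta)} and
#' residuals iid \eqn{(0, \sigma^2_e)}, under one of two equivalent
#' parameterisations:
#'
#' * **MEM** (marker effect model): solve
#'   \eqn{(X^{*\prime}X^* + D\lambda)\hat\beta^* = X^{*\prime}y} with
#'   \eqn{X^* = [1\; X]}, \eqn{D = \mathrm{diag}(0, 1, \dots, 1)} and
#'   \eqn{\lambda = \sigma^2_e/\sigma^2_\beta}. System order `p + 1`.
#' * **BVM** (breeding value model, GBLUP): solve
#'   \eqn{(Z^{*\prime}Z^* + G\lambda)\hat u^* = Z^{*\prime}y} with
#'   \eqn{Z^* = [1\; I]} and \eqn{G} block-diagonal with 0 then
#'   \eqn{(XX')^{-1}}. System order `n + 1`. Requires \eqn{XX'}
#'   nonsingular (typical when `n < p`).
#'
#' The two models give identical predictions of any linear function; `"auto"`
#' picks MEM when `n >= p` and BVM otherwise, which minimises the order of
#' the system solved. Phenotypes are assumed pre-corrected for all fixed
#' effects other than the overall mean.
#'
#' Dosages enter raw (0/1/2) by default; `center = TRUE` subtracts column
#' means first, which changes \eqn{\hat\mu} but not predictions.
#'
#' @param genotypes n x p allele dosage matrix, see [genotype_matrix()].
#' @param phenotypes numeric vector of length n, pre-corrected trait values.
#' @param vc a [variance_components()] object; alternatively give
#'   `sigma2_beta`/`sigma2_e`/`lambda` directly.
#' @param model `"auto"`, `"mem"` or `"bvm"`.
#' @param sigma2_beta,sigma2_e,lambda variance components, used when `vc` is
#'   not supplied.
#' @param center centre marker columns before fitting. Default `FALSE`.
#' @param jitter if `TRUE`, a ridge of `1e-8 * mean(diag(XX'))` is added to
#'   a numerically singular `XX'` in the BVM (off by default; a singular
#'   `XX'` otherwise errors with advice to use the MEM).
#' @return an object of class `"gblup"`: a list with components `mu`
#'   (estimated overall mean), `effects` (p marker effects for MEM, n
#'   breeding values for BVM), `model` (`"MEM"` or `"BVM"`),
#'   `coefficient_inverse` (inverse of the MME coefficient matrix, kept for
#'   leverage extraction; order `p+1` or `n+1`), `fitted`, `X`, `y`, `vc`.
#' @seealso [loocv()], [leverage()], [genomic_covariance()]
#' @examples
#' g <- genotype_matrix(rbind(c(1, 2, 1, 2, 2),
#'                            c(2, 1, 0, 1, 1),
#'                            c(0, 0, 2, 1, 2)))
#' y <- c(1.97, 2.12, -0.62)
#' fit <- gblup(g, y, lambda = 10)
#' coef(fit)
#' @export
gblup <- function(genotypes, phenotypes, vc = NULL,
                  model = c("auto", "mem", "bvm"),
                  sigma2_beta = NULL, sigma2_e = NULL, lambda = NULL,
                  center = FALSE, jitter = FALSE) {
  model <- match.arg(model)
  X <- genotype_matrix(genotypes)
  y <- phenotype_vector(phenotypes, X)
  vc <- as_variance_components(vc, sigma2_beta, sigma2_e, lambda)
  n <- nrow(X)
  p <- ncol(X)
  if (model == "auto") model <- if (n >= p) "mem" else "bvm"

  centers <- NULL
  Xw <- X
  if (center) {
    centers <- colMeans(X)
    Xw <- sweep(X, 2L, centers)
  }

  if (model == "mem") {
    Xs <- cbind(`(Intercept)` = 1, Xw)
    C <- crossprod(Xs)
    idx <- seq(2L, p + 1L)
    C[cbind(idx, idx)] <- C[cbind(idx, idx)] + vc$lambda
    R <- tryCatch(chol(C), error = function(e)
      stop("MEM coefficient matrix X*'X* + D*lambda is numerically ",
           "singular; cannot fit"))
    Cinv <- chol2inv(R)
    sol <- drop(Cinv %*% crossprod(Xs, y))
    names(sol) <- colnames(Xs)
    mu <- sol[1L]
    effects <- sol[-1L]
    fitted <- drop(Xs %*% sol)
    kind <- "MEM"
  } else {
    XXt <- tcrossprod(Xw)
    # a chol() that merely survives rounding is not evidence of rank n:
    # duplicated genotype rows leave tiny positive pivots and a silently
    # wrong fit, so gate on the estimated reciprocal condition number
    Rg <- if (rcond(XXt) > 1e-10) tryCatch(chol(XXt),
                                           error = function(e) NULL)
    if (is.null(Rg)) {
      if (!jitter)
        stop("XX' is numerically singular (rank < n); the breeding-value ",
             "model is not identified. Use model = \"mem\" or jitter = TRUE")
      eps <- 1e-8 * mean(diag(XXt))
      Rg <- chol(XXt + diag(eps, n))
    }
    XXt_inv <- chol2inv(Rg)
    # Z* = [1 I] so Z*'Z* = [[n, 1'], [1, I]]
    C <- rbind(c(n, rep(1, n)), cbind(1, diag(n)))
    C[-1L, -1L] <- C[-1L, -1L] + XXt_inv * vc$lambda
    R <- tryCatch(chol(C), error = function(e)
      stop("BVM coefficient matrix Z*'Z* + G*lambda is numerically ",
           "singular; cannot fit"))
    Cinv <- chol2inv(R)
    Zs <- cbind(1, diag(n))
    sol <- drop(Cinv %*% crossprod(Zs, y))
    names(sol) <- c("(Intercept)", rownames(X))
    mu <- sol[1L]
    effects <- sol[-1L]
    fitted <- mu + effects
    kind <- "BVM"
  }
  names(fitted) <- rownames(X)
  structure(list(mu = unname(mu), effects = effects, model = kind,
                 coefficient_inverse = Cinv, fitted = fitted,
                 X = X, y = y, vc = vc, centers = centers,
                 call = match.call()),
            class = "gblup")
}

#' Genomic covariance matrix implied by marker dosages
#'
#' Returns \eqn{XX'\sigma^2_\beta}, the covariance matrix of the breeding
#' values \eqn{u = X\beta}, or \eqn{V = XX'\sigma^2_\beta + I\sigma^2_e},
#' the covariance matrix of the phenotypes, when `sigma2_e` is supplied.
#'
#' @param genotypes n x p allele dosage matrix.
#' @param sigma2_beta marker-effect variance.
#' @param sigma2_e residual variance; if given, `I * sigma2_e` is added.
#' @return symmetric n x n matrix.
#' @export
genomic_covariance <- function(genotypes, sigma2_beta, sigma2_e = NULL) {
  X <- as.matrix(genotypes)
  V <- tcrossprod(X) * sigma2_beta
  if (!is.null(sigma2_e)) V <- V + diag(sigma2_e, nrow(X))
  V
}

# Design matrix X* = [1 X] of the MEM.
mem_design <- function(X) cbind(`(Intercept)` = 1, X)

# Back-map breeding values to marker effects: beta = X'(XX')^{-1} u.
bvm_marker_effects <- function(object) {
  X <- object$X
  if (!is.null(object$centers)) X <- sweep(X, 2L, object$centers)
  drop(crossprod(X, solve(tcrossprod(X), object$effects)))
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("Genomic BLUP fit (%s), n = %d individuals, p = %d markers\n",
              x$model, nrow(x$X), ncol(x$X)))
  cat(sprintf("  lambda = %g (sigma2_e = %g, sigma2_beta = %g)\n",
              x$vc$lambda, x$vc$sigma2_e, x$vc$sigma2_beta))
  cat(sprintf("  overall mean: %.6g\n", x$mu))
  what <- if (x$model == "MEM") "marker effects" else "breeding values"
  cat(sprintf("  %d estimated %s (see coef())\n", length(x$effects), what))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) {
  c("(Intercept)" = object$mu, object$effects)
}

#' @export
fitted.gblup <- function(object, ...) object$fitted

#' @export
residuals.gblup <- function(object, ...) object$y - object$fitted

#' Predict genetic merit of (new) individuals from a gblup fit
#'
#' For a MEM fit predictions are \eqn{\hat\mu + x'\hat\beta}; for a BVM fit
#' marker effects are first recovered as
#' \eqn{\hat\beta = X'(XX')^{-1}\hat u}.
#'
#' @param object a `gblup` fit.
#' @param newdata dosage matrix with the same markers as the training data;
#'   defaults to the training genotypes.
#' @param ... unused.
#' @return named vector of predicted trait values.
#' @export
predict.gblup <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != ncol(object$X))
    stop("newdata has ", ncol(Xn), " markers; fit used ", ncol(object$X))
  if (!is.null(object$centers)) Xn <- sweep(Xn, 2L, object$centers)
  beta <- if (object$model == "MEM") object$effects
          else bvm_marker_effects(object)
  drop(object$mu + Xn %*% beta)
}

#' @export
summary.gblup <- function(object, ...) {
  r <- object$y - object$fitted
  structure(list(model = object$model, n = nrow(object$X),
                 p = ncol(object$X), mu = object$mu, vc = object$vc,
                 leverage = leverage(object),
                 rss = sum(r^2), fit_cor = stats::cor(object$y, object$fitted)),
            class = "summary.gblup")
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat(sprintf("Genomic BLUP (%s): n = %d, p = %d, lambda = %g\n",
              x$model, x$n, x$p, x$vc$lambda))
  cat(sprintf("  overall mean %.6g, in-sample RSS %.6g, cor(y, fitted) %.4f\n",
              x$mu, x$rss, x$fit_cor))
  cat("  leverage (diag of hat-type matrix):\n")
  print(summary(x$leverage))
  invisible(x)
}

#' Leverages (hat-type matrix diagonal) of a gblup fit
#'
#' Returns the diagonal of
#' \eqn{H = X^*(X^{*\prime}X^* + D\lambda)^{-1}X^{*\prime}} for a MEM fit or
#' \eqn{C = Z^*(Z^{*\prime}Z^* + G\lambda)^{-1}Z^{*\prime}} for a BVM fit.
#' By model equivalence the two diagonals are numerically identical. Each
#' leverage lies strictly in (0, 1) for \eqn{\lambda > 0}; these are the
#' denominators of the closed-form leave-one-out residuals.
#'
#' @param object a `gblup` fit.
#' @param ... unused.
#' @return named numeric vector of n leverages, with attribute `source`
#'   equal to `"MEM-H"` or `"BVM-C"`.
#' @export
leverage <- function(object, ...) UseMethod("leverage")

#' @export
leverage.gblup <- function(object, ...) {
  Cinv <- object$coefficient_inverse
  if (object$model == "MEM") {
    Xw <- object$X
    if (!is.null(object$centers)) Xw <- sweep(Xw, 2L, object$centers)
    M <- mem_design(Xw)
  } else {
    M <- cbind(1, diag(nrow(object$X)))
  }
  h <- rowSums((M %*% Cinv) * M)
  names(h) <- rownames(object$X)
  if (any(h >= 1 - 1e-12))
    stop("degenerate leverage: observation ",
         names(h)[which(h >= 1 - 1e-12)[1L]],
         " is self-predicting (leverage >= 1); leave-one-out residual ",
         "undefined")
  if (any(h <= 0))
    stop("leverage out of range (<= 0); coefficient matrix may be ",
         "numerically indefinite")
  attr(h, "source") <- if (object$model == "MEM") "MEM-H" else "BVM-C"
  h
}
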