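#' Leave-one-out cross-validation for a genomic BLUP fit
#'
#' Computes, for every individual j, the residual
#' \eqn{\hat e_j = y_j - \hat y_{(-j)}} of predicting its phenotype from a
#' model trained on the other n - 1 records, together with the PRESS
#' statistic \eqn{\sum_j \hat e_j^2} and the prediction accuracy
#' \eqn{\mathrm{cor}(y, \hat y)} -- without ever refitting, except under the
#' `"naive"` reference strategy.
#'
#' Available strategies:
#'
#' * `"mem"` -- hat-matrix identity for the marker effect model:
#'   \eqn{\hat e_j = (y_j - x_j^{*\prime}\hat\beta^*)/(1 - H_{jj})}, using
#'   only the full-data solution and the leverages.
#' * `"bvm1"` -- the same identity through the breeding value model:
#'   \eqn{\hat e_j = (y_j - z_j^{*\prime}\hat u^*)/(1 - C_{jj})}.
#' * `"bvm2"` -- augmented-covariance strategy: a single inverse of the
#'   (n+1) x (n+1) matrix `Q` (see [build_q()]) yields all residuals,
#'   plus per-individual prediction error variance (PEV) and reliability.
#'   The overall mean is handled by treating it as a random effect with
#'   large variance `sigma2_L`, so results approach the fixed-mean answer
#'   as `sigma2_L` grows.
#' * `"naive"` -- refits the mixed model equations n times; the exact
#'   reference the efficient strategies are tested against.
#' * `"auto"` -- the efficient identity matching the fitted model (`"mem"`
#'   for a MEM fit, `"bvm1"` for a BVM fit).
#'
#' Strategies `"mem"`/`"bvm1"`/`"naive"` give identical residuals (to
#' solver precision); `"bvm2"` agrees to within an \eqn{O(1/\sigma^2_L)}
#' discrepancy from the random-mean device.
#'
#' @param object a [gblup()] fit.
#' @param strategy one of `"auto"`, `"mem"`, `"bvm1"`, `"bvm2"`, `"naive"`.
#'   If the requested strategy needs the other model parameterisation than
#'   the one fitted, the model is resolved internally from the stored data.
#' @param sigma2_L variance of the random mean for `"bvm2"`; defaults to the
#'   value in the fit's variance components (1000 * sigma2_e unless set).
#' @param subset optional individual ids or indices: PRESS and accuracy are
#'   aggregated over this subgroup only (per-individual quantities are still
#'   returned for everyone). Useful e.g. to restrict validation to terminal
#'   offspring.
#' @param refit for `strategy = "naive"` only: ids or indices of the
#'   individuals to actually leave out and refit (default all). Residuals of
#'   the others are `NA`; handy for spot-checking the closed forms at scale,
#'   where n full refits would be prohibitive.
#' @param ... unused.
#' @return an object of class `"gblup_loocv"`: list with `ids`, `y`,
#'   `predictions`, `residuals`, `leverage` (strategies mem/bvm1/naive),
#'   `pev` and `reliability` (strategy bvm2 only), `press`, `accuracy`,
#'   `strategy`, `subset`. Always `predictions + residuals == y` exactly.
#' @examples
#' g <- genotype_matrix(rbind(c(1, 2, 1, 2, 2),
#'                            c(2, 1, 0, 1, 1),
#'                            c(0, 0, 2, 1, 2)))
#' fit <- gblup(g, c(1.97, 2.12, -0.62), lambda = 10)
#' cv <- loocv(fit)
#' round(cv$residuals, 2)   # 1.13  1.21 -2.66
#' @export
loocv <- function(object, ...) UseMethod("loocv")

#' @rdname loocv
#' @export
loocv.gblup <- function(object,
                        strategy = c("auto", "mem", "bvm1", "bvm2", "naive"),
                        sigma2_L = NULL, subset = NULL, refit = NULL, ...) {
  strategy <- match.arg(strategy)
  if (strategy == "auto")
    strategy <- if (object$model == "MEM") "mem" else "bvm1"
  y <- object$y
  ids <- rownames(object$X)

  if (strategy %in% c("mem", "bvm1")) {
    want <- if (strategy == "mem") "MEM" else "BVM"
    fit <- object
    if (fit$model != want)
      fit <- gblup(object$X, y, vc = object$vc,
                   model = tolower(if (want == "MEM") "mem" else "bvm"),
                   center = !is.null(object$centers))
    h <- leverage(fit)
    e <- (y - fit$fitted) / (1 - h)
    res <- new_loocv_result(ids, y, e, leverage = h, strategy = strategy)
  } else if (strategy == "bvm2") {
    qm <- build_q(object$X, y, object$vc, sigma2_L = sigma2_L,
                  centers = object$centers)
    res <- loocv_q(qm, strategy_label = "bvm2")
  } else {
    only <- if (is.null(refit)) NULL else resolve_subset(refit, ids)
    res <- naive_loocv(object, only = only)
    if (is.null(subset) && !is.null(only)) subset <- only
  }
  finish_loocv(res, subset)
}

# Assemble the common result skeleton; predictions are y - residuals by
# construction so the identity holds exactly.
new_loocv_result <- function(ids, y, residuals, leverage = NULL, pev = NULL,
                             reliability = NULL, strategy, sigma2_L = NULL) {
  residuals <- stats::setNames(as.numeric(residuals), ids)
  structure(list(ids = ids, y = stats::setNames(as.numeric(y), ids),
                 predictions = stats::setNames(y - residuals, ids),
                 residuals = residuals, leverage = leverage, pev = pev,
                 reliability = reliability, press = NA_real_,
                 accuracy = NA_real_, strategy = strategy,
                 sigma2_L = sigma2_L, subset = NULL),
            class = "gblup_loocv")
}

finish_loocv <- function(res, subset = NULL) {
  idx <- resolve_subset(subset, res$ids)
  res$subset <- idx
  s <- tryCatch(loo_summary(res, subset = idx),
                error = function(e) {
                  warning(conditionMessage(e), call. = FALSE)
                  list(press = sum(res$residuals[idx]^2), accuracy = NA_real_)
                })
  res$press <- s$press
  res$accuracy <- s$accuracy
  res
}

resolve_subset <- function(subset, ids) {
  if (is.null(subset)) return(seq_along(ids))
  if (is.character(subset)) {
    idx <- match(subset, ids)
    if (anyNA(idx))
      stop("subset ids not found: ",
           paste(subset[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > length(ids)))
      stop("subset indices out of range 1..", length(ids))
  }
  if (anyDuplicated(idx)) stop("subset contains duplicates")
  idx
}

#' PRESS and prediction accuracy over a subgroup
#'
#' Aggregates a LOOCV result: PRESS is the sum of squared prediction
#' residuals over the subgroup; accuracy is the Pearson correlation between
#' observed and predicted phenotypes over the subgroup.
#'
#' @param result a `gblup_loocv` object.
#' @param subset individual ids or indices (default: everyone).
#' @return list with elements `press` and `accuracy`.
#' @export
loo_summary <- function(result, subset = NULL) {
  stopifnot(inherits(result, "gblup_loocv"))
  idx <- resolve_subset(subset, result$ids)
  press <- sum(result$residuals[idx]^2)
  if (length(idx) < 2L)
    stop("accuracy undefined: subgroup has fewer than 2 individuals")
  yh <- result$predictions[idx]
  if (stats::sd(yh) == 0 || stats::sd(result$y[idx]) == 0)
    stop("accuracy undefined: constant predictions or phenotypes ",
         "in subgroup (correlation undefined)")
  list(press = press, accuracy = stats::cor(result$y[idx], yh))
}

#' Augmented covariance matrix Q for LOOCV strategy II
#'
#' Builds the (n+1) x (n+1) matrix
#' \deqn{Q = \begin{bmatrix} y'y & y' \\ y & V^* \end{bmatrix},
#'  \quad V^* = X^*\Sigma X^{*\prime} + I\sigma^2_e,}
#' where \eqn{X^* = [1\;X]} and
#' \eqn{\Sigma = \mathrm{diag}(\sigma^2_L, \sigma^2_\beta I)}: the overall
#' mean is treated as a random effect with large variance \eqn{\sigma^2_L}
#' so that the best linear predictor from `Q` is numerically
#' indistinguishable from the fixed-mean BLUP. A single inverse of `Q`
#' yields every leave-one-out residual and prediction error variance.
#'
#' @param genotypes n x p dosage matrix.
#' @param phenotypes length-n phenotype vector.
#' @param vc [variance_components()] object (or pass
#'   `sigma2_beta`/`sigma2_e`).
#' @param sigma2_L overrides the random-mean variance in `vc`.
#' @param sigma2_beta,sigma2_e used if `vc` is missing.
#' @param centers optional column centers to subtract from the dosages
#'   (used internally to match a centered fit).
#' @return object of class `"gblup_q"`: list with the matrix `q`, its
#'   inverse `q_inv`, `sigma2_L_used`, the phenotypes `y` and the diagonal
#'   of `V*` (`vstar_diag`, used for reliabilities).
#' @export
build_q <- function(genotypes, phenotypes, vc = NULL, sigma2_L = NULL,
                    sigma2_beta = NULL, sigma2_e = NULL, centers = NULL) {
  X <- genotype_matrix(genotypes)
  y <- phenotype_vector(phenotypes, X)
  vc <- as_variance_components(vc, sigma2_beta, sigma2_e,
                               sigma2_L = sigma2_L)
  if (!is.null(centers)) X <- sweep(X, 2L, centers)
  n <- nrow(X)
  # V* = X* Sigma X*' + I se2 = sL2 * 11' + XX' sb2 + I se2
  Vstar <- tcrossprod(X) * vc$sigma2_beta + vc$sigma2_L +
    diag(vc$sigma2_e, n)
  q <- rbind(c(sum(y * y), y), cbind(y, Vstar))
  dimnames(q) <- NULL
  q_inv <- tryCatch(solve(q), error = function(e)
    stop("augmented matrix Q is numerically singular; try a smaller ",
         "sigma2_L or check for duplicated phenotype/genotype rows"))
  structure(list(q = q, q_inv = q_inv, sigma2_L_used = vc$sigma2_L,
                 y = y, vstar_diag = diag(Vstar), ids = rownames(X)),
            class = "gblup_q")
}

#' @export
print.gblup_q <- function(x, ...) {
  cat(sprintf("Augmented Q matrix for LOOCV strategy II: %d x %d, sigma2_L = %g\n",
              nrow(x$q), ncol(x$q), x$sigma2_L_used))
  invisible(x)
}

# All leave-one-out residuals and PEVs from the inverse of Q. For
# individual j the 2x2 block of Q^{-1} on indices (1, 1+j) plays the role
# of W^11 after symmetric permutation; permutation is realised purely by
# index selection.
loocv_q <- function(qm, strategy_label = "bvm2") {
  stopifnot(inherits(qm, "gblup_q"))
  Qi <- qm$q_inv
  n <- length(qm$y)
  j1 <- seq_len(n) + 1L
  q11 <- Qi[1L, 1L]
  qjj <- Qi[cbind(j1, j1)]
  q1j <- Qi[1L, j1]
  qj1 <- Qi[j1, 1L]
  det2 <- q11 * qjj - q1j * qj1
  if (any(abs(det2) < 1e-12 * abs(q11)))
    stop("degenerate prediction for individual ",
         qm$ids[which(abs(det2) < 1e-12 * abs(q11))[1L]],
         ": 2x2 determinant in the Q-inverse identity is numerically zero")
  e <- -qj1 / det2
  pev <- q11 / det2   # (2,2) element of the inverse of W^11
  reliability <- 1 - pev / qm$vstar_diag
  new_loocv_result(qm$ids, qm$y, e, pev = stats::setNames(pev, qm$ids),
                   reliability = stats::setNames(reliability, qm$ids),
                   strategy = strategy_label, sigma2_L = qm$sigma2_L_used)
}

#' @describeIn loocv LOOCV strategy II directly from a prebuilt [build_q()]
#'   object.
#' @export
loocv.gblup_q <- function(object, subset = NULL, ...) {
  finish_loocv(loocv_q(object), subset)
}

# Naive reference: solve the mixed model equations of each n-1 subproblem
# from scratch, once per left-out individual. The only shortcut taken is in
# assembling the subproblem's cross-product/Gram matrix by subsetting the
# full-data one, which is exact arithmetic; every subproblem still gets its
# own independent factorisation. `only` restricts the refits to a subset of
# individuals (residuals of the rest are NA).
naive_loocv <- function(object, only = NULL) {
  X <- object$X
  if (!is.null(object$centers)) X <- sweep(X, 2L, object$centers)
  y <- object$y
  n <- nrow(X)
  p <- ncol(X)
  lam <- object$vc$lambda
  if (is.null(only)) only <- seq_len(n)
  e <- rep(NA_real_, n)
  if (object$model == "MEM") {
    Xs <- cbind(1, X)
    Cfull <- crossprod(Xs)
    rhs_full <- crossprod(Xs, y)
    Dl <- diag(c(0, rep(lam, p)))
  } else {
    XXt_full <- tcrossprod(X)
  }
  for (j in only) {
    pred <- tryCatch({
      if (object$model == "MEM") {
        # X*'_{-j} X*_{-j} = X*'X* - x*_j x*_j', assembled exactly
        Cj <- Cfull - tcrossprod(Xs[j, ]) + Dl
        b <- solve(Cj, rhs_full - Xs[j, ] * y[j])
        drop(Xs[j, ] %*% b)
      } else {
        m <- n - 1L
        XXm <- XXt_full[-j, -j, drop = FALSE]
        XXm_inv <- solve(XXm)
        C <- rbind(c(m, rep(1, m)), cbind(1, diag(m)))
        C[-1L, -1L] <- C[-1L, -1L] + XXm_inv * lam
        u <- drop(solve(C, crossprod(cbind(1, diag(m)), y[-j])))
        # predict the left-out individual from back-mapped marker effects
        beta <- drop(crossprod(X[-j, , drop = FALSE], XXm_inv %*% u[-1L]))
        u[1L] + drop(X[j, ] %*% beta)
      }
    }, error = function(err)
      stop("naive LOOCV: subproblem leaving out individual ",
           rownames(object$X)[j], " is singular: ", conditionMessage(err)))
    e[j] <- y[j] - pred
  }
  # full-data leverages reported alongside for reference
  h <- leverage(object)
  new_loocv_result(rownames(object$X), y, e, leverage = h,
                   strategy = "naive")
}

#' @export
print.gblup_loocv <- function(x, ...) {
  n <- length(x$residuals)
  cat(sprintf("Leave-one-out cross-validation (%s strategy), n = %d\n",
              x$strategy, n))
  if (!is.null(x$sigma2_L))
    cat(sprintf("  random-mean variance sigma2_L = %g\n", x$sigma2_L))
  m <- length(x$subset)
  cat(sprintf("  PRESS    = %.6g%s\n", x$press,
              if (m < n) sprintf(" (subgroup of %d)", m) else ""))
  cat(sprintf("  accuracy = %s  (cor of observed and predicted)\n",
              if (is.na(x$accuracy)) "NA" else sprintf("%.4f", x$accuracy)))
  invisible(x)
}

#' @export
summary.gblup_loocv <- function(object, ...) {
  d <- as.data.frame(object)
  print(object)
  cat("\nPer-individual results:\n")
  print(utils::head(d, 10L))
  if (nrow(d) > 10L) cat("  ... (", nrow(d) - 10L, " more rows)\n", sep = "")
  invisible(d)
}

#' @export
as.data.frame.gblup_loocv <- function(x, ...) {
  data.frame(id = x$ids, y = unname(x$y), y_hat = unname(x$predictions),
             e_hat = unname(x$residuals),
             leverage = if (is.null(x$leverage)) NA_real_
                        else unname(x$leverage),
             pev = if (is.null(x$pev)) NA_real_ else unname(x$pev),
             reliability = if (is.null(x$reliability)) NA_real_
                           else unname(x$reliability),
             stringsAsFactors = FALSE)
}

#' @export
plot.gblup_loocv <- function(x, ...) {
  graphics::plot(x$y, x$predictions,
                 xlab = "observed phenotype",
                 ylab = "leave-one-out prediction",
                 main = sprintf("LOOCV (%s): accuracy = %s", x$strategy,
                                if (is.na(x$accuracy)) "NA"
                                else sprintf("%.3f", x$accuracy)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
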