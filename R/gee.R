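#' @include utils.R
NULL

#' Gaussian GEE with exchangeable working correlation
#'
#' Fits the marginal linear model `y = X b` by generalized estimating
#' equations with identity link, exchangeable working correlation within
#' clusters, and robust (sandwich) standard errors.  This is the
#' estimator used for stage-conditional thickness means and treatment
#' window means on clustered eye/session data.  With one observation
#' per cluster the working correlation is irrelevant and the estimates
#' coincide with ordinary least squares.
#'
#' Moment estimators are used at each iteration: the dispersion is the
#' mean squared Pearson residual (with a `N - p` degrees-of-freedom
#' correction) and the exchangeable correlation is the cross-product of
#' residual pairs within clusters over `(n_pairs - p)`.
#'
#' @param y numeric response vector.
#' @param X design matrix (`length(y)` rows).
#' @param id cluster identifier (coerced to factor).
#' @param maxIter,tol iteration control.
#' @return a list with elements `coefficients`, `robust_se`,
#'   `naive_se`, `alpha` (working correlation), `phi` (dispersion),
#'   `vcov` (robust), `n_clusters`, `converged`.
#' @examples
#' set.seed(1)
#' id <- rep(1:20, each = 2)
#' x <- rnorm(40)
#' y <- 1 + 2 * x + rep(rnorm(20), each = 2) + rnorm(40, 0, 0.5)
#' fit <- geeFit(y, cbind(1, x), id)
#' fit$coefficients
#' @export
geeFit <- function(y, X, id, maxIter = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || length(id) != n)
    stop("y, X and id must have matching lengths", call. = FALSE)
  id <- factor(id)
  nClus <- nlevels(id)
  if (nClus < 2L)
    stop("GEE needs at least 2 clusters; fit an independent model instead",
      call. = FALSE)
  p <- ncol(X)
  idx <- split(seq_len(n), id)
  sizes <- lengths(idx)

  ## exchangeable R^{-1} applied to a matrix M (rows = cluster obs):
  ## R^{-1} = (I - a/(1+(m-1)a) J) / (1-a)
  rinv <- function(M, a) {
    m <- nrow(M)
    if (m == 1L || a == 0) return(M)
    (M - (a / (1 + (m - 1) * a)) * matrix(colSums(M), m, ncol(M),
      byrow = TRUE)) / (1 - a)
  }

  beta <- qr.solve(X, y) # OLS start
  alpha <- 0
  converged <- FALSE
  phi <- 1
  for (it in seq_len(maxIter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / max(1, n - p)
    nPairs <- sum(sizes * (sizes - 1) / 2)
    if (nPairs > p) {
      cross <- sum(vapply(idx, function(i) {
        ri <- r[i]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, numeric(1L)))
      alphaNew <- cross / phi / (nPairs - p)
      # keep the working correlation inside its positive-definite range
      maxM <- max(sizes)
      alphaNew <- min(0.999, max(-1 / (maxM - 1) + 1e-6, alphaNew))
    } else {
      alphaNew <- 0
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (i in idx) {
      Xi <- X[i, , drop = FALSE]
      WX <- rinv(Xi, alphaNew)
      A <- A + crossprod(Xi, WX)
      b <- b + crossprod(WX, y[i])
    }
    betaNew <- solve(A, b)
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    alpha <- alphaNew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  r <- y - X %*% beta
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (i in idx) {
    Xi <- X[i, , drop = FALSE]
    WX <- rinv(Xi, alpha)
    A <- A + crossprod(Xi, WX)
    u <- crossprod(WX, r[i])
    M <- M + tcrossprod(u)
  }
  Ainv <- solve(A)
  vcovRobust <- Ainv %*% M %*% t(Ainv)
  naive <- sqrt(pmax(0, diag(Ainv)) * phi)
  coef <- drop(beta)
  names(coef) <- colnames(X)
  se <- sqrt(pmax(0, diag(vcovRobust)))
  names(se) <- colnames(X)
  list(
    coefficients = coef,
    robust_se = se,
    naive_se = naive,
    alpha = alpha,
    phi = phi,
    vcov = vcovRobust,
    n_clusters = nClus,
    converged = converged
  )
}
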