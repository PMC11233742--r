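#' Gaussian-process regression with restarted hyperparameter optimization
#'
#' Exact GP regression with an isotropic RBF or Matern 3/2 covariance plus a
#' noise term. The three log-hyperparameters (length-scale, signal SD, noise
#' SD) are fitted by maximizing the log marginal likelihood with Nelder-Mead
#' from \code{restarts} seeded log-uniform starting points; the best objective
#' wins. The target is centered on its training mean.
#'
#' @param X training matrix (n x p).
#' @param y numeric target.
#' @param kernel \code{"rbf"} or \code{"matern32"}.
#' @param restarts number of seeded optimizer restarts (default 20).
#' @param seed integer seed controlling the restart draws.
#' @return object of class \code{gp_fit}.
#' @export
gp_fit <- function(X, y, kernel = c("rbf", "matern32"), restarts = 20L,
                   seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  n <- nrow(X)
  mu <- mean(y)
  yc <- y - mu
  D <- as.matrix(dist(X))
  kfun <- function(d, ell, sf) {
    if (kernel == "rbf") sf^2 * exp(-d^2 / (2 * ell^2))
    else { a <- sqrt(3) * d / ell; sf^2 * (1 + a) * exp(-a) }
  }
  nll <- function(theta) {
    ell <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
    K <- kfun(D, ell, sf) + diag(sn^2 + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    0.5 * sum(yc * alpha) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  }
  d_med <- median(D[upper.tri(D)])
  if (!is.finite(d_med) || d_med <= 0) d_med <- 1
  s_y <- max(sd(y), 1e-6)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(restarts)) {
    start <- c(log(d_med) + runif(1, log(0.1), log(10)),
               log(s_y) + runif(1, log(0.1), log(10)),
               log(s_y) + runif(1, log(0.01), log(1)))
    opt <- optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = 400))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  ell <- exp(best$par[1]); sf <- exp(best$par[2]); sn <- exp(best$par[3])
  K <- kfun(D, ell, sf) + diag(sn^2 + 1e-8, n)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(X = X, alpha = alpha, mu = mu, ell = ell, sf = sf, sn = sn,
                 kernel = kernel, nll = best$value, kfun = kfun),
            class = "gp_fit")
}

#' @rdname gp_fit
#' @param object a \code{gp_fit}.
#' @param newdata matrix of prediction points.
#' @param ... unused.
#' @export
predict.gp_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cross2 <- outer(rowSums(newdata^2), rowSums(object$X^2), "+") -
    2 * newdata %*% t(object$X)
  cross2[!is.finite(cross2) | cross2 < 0] <- 0 # numerical negatives
  cross <- sqrt(cross2)
  Ks <- object$kfun(cross, object$ell, object$sf)
  as.numeric(Ks %*% object$alpha) + object$mu
}
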