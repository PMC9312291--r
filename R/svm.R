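# Linear max-margin classifier: L2-regularized squared-hinge SVM
# (liblinear's default loss family), fixed cost C, unpenalized intercept,
# solved by BFGS with an analytic gradient. Deterministic given the data.

#' Fit a linear L2-SVM (squared hinge loss)
#'
#' Minimizes `0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (x_i w + b))^2`.
#'
#' @param X samples x features matrix.
#' @param y labels; any two-level vector (factor/character/numeric).
#' @param cost regularization constant C (fixed at 1 in the pipeline).
#' @return list of class `linear_svm`: `w`, `b`, `levels` (first level is
#'   coded -1, second +1), `converged`.
#' @export
linear_svm <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2) stopf("linear_svm: need exactly 2 classes, got %d", length(lev))
  yy <- ifelse(as.character(y) == lev[2], 1, -1)
  p <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- pmax(0, 1 - yy * (X %*% w + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- pmax(0, 1 - yy * (as.numeric(X %*% w) + b))
    gw <- w - 2 * cost * as.numeric(t(X) %*% (m * yy))
    gb <- -2 * cost * sum(m * yy)
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  structure(list(w = fit$par[seq_len(p)], b = fit$par[p + 1], levels = lev,
                 converged = fit$convergence == 0),
            class = "linear_svm")
}

#' Predict class labels from a fitted linear SVM
#' @param object a `linear_svm`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return character vector of predicted labels (ties go to the first level).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  score <- as.numeric(as.matrix(newdata) %*% object$w + object$b)
  ifelse(score > 0, object$levels[2], object$levels[1])
}
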