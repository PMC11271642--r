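# Primal L1-regularized linear SVM (squared hinge loss) solved by FISTA
# proximal gradient with an unpenalized intercept, and Platt's sigmoid
# calibration of decision values.

#' Fit an L1-regularized linear SVM (squared hinge loss)
#'
#' Minimizes `||w||_1 + C * sum_i s_i * max(0, 1 - y_i (x_i'w + b))^2`
#' where `s_i` are per-class weights and the intercept `b` is unpenalized.
#' Solved in the primal by accelerated proximal gradient (FISTA) with
#' soft-thresholding; the problem is convex and the solver is
#' deterministic. The L1 penalty drives redundant or degenerate features to
#' exactly zero weight.
#'
#' @param x Numeric matrix, instances x features.
#' @param y Labels: `"LRP"`/`"NoLRP"`, or a +1/-1 numeric vector (+1 = LRP).
#' @param C Complexity (loss) weight.
#' @param class_weights Named weights applied to the loss of each class
#'   (default `c(NoLRP = 1, LRP = 2)`).
#' @param max_iter,tol Solver iteration cap and relative convergence
#'   tolerance.
#' @return An `l1_svm` object: list with `w`, `b`, `C`, `class_weights`,
#'   `iterations`, `objective`.
#' @export
fit_l1_svm <- function(x, y, C = 1,
                       class_weights = c(NoLRP = 1, LRP = 2),
                       max_iter = 5000, tol = 1e-10) {
  x <- as.matrix(x)
  yv <- if (is.numeric(y)) {
    sign(y)
  } else {
    ifelse(as.character(y) == "LRP", 1, -1)
  }
  if (length(unique(yv)) < 2) {
    stop("both classes must be present to fit the SVM", call. = FALSE)
  }
  s <- ifelse(yv > 0, class_weights[["LRP"]], class_weights[["NoLRP"]])
  n <- nrow(x)
  p <- ncol(x)
  xa <- cbind(x, 1) # intercept as last column
  # Lipschitz constant of the smooth part: 2C * lambda_max(Xa' S Xa)
  L <- 2 * C * max(eigen(crossprod(xa * sqrt(s)), symmetric = TRUE,
                         only.values = TRUE)$values)
  L <- max(L, .Machine$double.eps)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  smooth_grad <- function(par) {
    h <- pmax(0, 1 - yv * drop(xa %*% par))
    -2 * C * drop(crossprod(xa, s * yv * h))
  }
  objective <- function(par) {
    h <- pmax(0, 1 - yv * drop(xa %*% par))
    sum(abs(par[seq_len(p)])) + C * sum(s * h^2)
  }
  par <- numeric(p + 1)
  par_prev <- par
  tk <- 1
  iters <- max_iter
  for (k in seq_len(max_iter)) {
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- par + ((tk - 1) / t_next) * (par - par_prev)
    g <- z - smooth_grad(z) / L
    new <- c(soft(g[seq_len(p)], 1 / L), g[p + 1])
    par_prev <- par
    par <- new
    tk <- t_next
    if (max(abs(par - par_prev)) <= tol * max(1, max(abs(par)))) {
      iters <- k
      break
    }
  }
  structure(
    list(w = par[seq_len(p)], b = par[p + 1], C = C,
         class_weights = class_weights, iterations = iters,
         objective = objective(par)),
    class = "l1_svm"
  )
}

#' Decision values of a fitted L1-SVM
#' @param object An `l1_svm`.
#' @param newdata Instances x features matrix.
#' @param ... Unused.
#' @return Numeric decision values (positive leans LRP).
#' @export
predict.l1_svm <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w) + object$b
}

#' Fit Platt's sigmoid calibration
#'
#' Maps decision values to probabilities `p = 1 / (1 + exp(-(A s + B)))` by
#' minimizing the cross-entropy against Platt's smoothed targets
#' `t+ = (N+ + 1) / (N+ + 2)` and `t- = 1 / (N- + 2)`.
#'
#' @param scores Decision values.
#' @param y Labels (`"LRP"` positive) or +1/-1.
#' @return A `platt_calibration`: list with `A`, `B`.
#' @export
fit_platt <- function(scores, y) {
  yv <- if (is.numeric(y)) y > 0 else as.character(y) == "LRP"
  n_pos <- sum(yv)
  n_neg <- sum(!yv)
  target <- ifelse(yv, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * scores + par[2]
    # numerically stable cross-entropy: log(1 + e^-z) via softplus
    sum((1 - target) * z + pmax(-z, 0) + log1p(exp(-abs(z))))
  }
  grad <- function(par) {
    p <- stats::plogis(par[1] * scores + par[2])
    d <- p - target
    c(sum(d * scores), sum(d))
  }
  fit <- stats::optim(c(1, 0), nll, grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  structure(list(A = fit$par[1], B = fit$par[2]), class = "platt_calibration")
}

platt_probability <- function(calibration, scores) {
  stats::plogis(calibration$A * scores + calibration$B)
}
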