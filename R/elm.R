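#' Initialise an extreme learning machine
#'
#' Single-hidden-layer feedforward network whose input weights and hidden
#' biases are drawn once at random and never trained: weights uniform on
#' [-1, 1], biases uniform on [0, 1]. Only the output weights are fitted, in
#' closed form, by [train_elm()].
#'
#' @param d Input dimension (number of features).
#' @param n_hidden Number of hidden neurons (the study default is 500).
#' @param m Number of output neurons (2 for peak / non-peak).
#' @param seed Integer seed; the draw is deterministic given the seed and
#'   leaves the global RNG state untouched.
#' @param activation Hidden activation: `"bipolar"` (tanh, range [-1, 1],
#'   the default) or `"unipolar"` (logistic, range [0, 1]).
#' @return An object of class `elm_model` with fields `a` (d x n_hidden
#'   input weights), `b` (length-n_hidden biases), `beta` (`NULL` until
#'   trained), `activation`, `d`, `n_hidden`, `m`, `seed`.
#' @export
init_elm <- function(d, n_hidden, m = 2L, seed,
                     activation = c("bipolar", "unipolar")) {
  activation <- match.arg(activation)
  d <- as.integer(d); n_hidden <- as.integer(n_hidden); m <- as.integer(m)
  if (any(c(d, n_hidden, m) < 1L)) {
    stop("dimensions 'd', 'n_hidden', 'm' must be positive", call. = FALSE)
  }
  draws <- with_rng_seed(seed, {
    list(a = matrix(stats::runif(d * n_hidden, -1, 1), nrow = d),
         b = stats::runif(n_hidden, 0, 1))
  })
  structure(list(a = draws$a, b = draws$b, beta = NULL,
                 activation = activation, d = d, n_hidden = n_hidden,
                 m = m, seed = as.integer(seed), scaler = NULL),
            class = "elm_model")
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d inputs -> %d hidden (%s) -> %d outputs; %s\n",
              x$d, x$n_hidden, x$activation, x$m,
              if (is.null(x$beta)) "untrained" else "trained"))
  invisible(x)
}

#' Hidden-layer output matrix
#'
#' `H[n, j] = g(sum_i a[i, j] x[n, i] + b[j])` with `g` the hidden
#' activation.
#'
#' @param X Numeric matrix, one row per sample, `d` columns.
#' @param model An `elm_model`.
#' @return `N x n_hidden` matrix.
#' @export
hidden_output <- function(X, model) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop("X has ", ncol(X), " columns; model expects ", model$d, call. = FALSE)
  }
  Z <- sweep(X %*% model$a, 2L, model$b, "+")
  switch(model$activation,
         bipolar = tanh(Z),
         unipolar = 1 / (1 + exp(-Z)))
}

#' Train the output weights in closed form
#'
#' Solves `H beta = T` for the output weights as `beta = pinv(H) T`, the
#' minimum-norm least-squares solution, using an SVD-based Moore-Penrose
#' pseudo-inverse (singular values below `1e-10` of the largest are treated
#' as zero). This remains well defined when `t(H) %*% H` is singular, where
#' the textbook normal-equations form would fail.
#'
#' @param model An `elm_model` from [init_elm()].
#' @param X `N x d` feature matrix.
#' @param targets `N x m` target matrix; for classification, one-hot rows
#'   built by [one_hot()].
#' @param weights Optional non-negative per-sample weights (weighted least
#'   squares, e.g. to counter class imbalance); default unweighted, as in the
#'   reference protocol.
#' @return The model with `beta` set.
#' @export
train_elm <- function(model, X, targets, weights = NULL) {
  X <- as.matrix(X); targets <- as.matrix(targets)
  if (nrow(X) != nrow(targets)) {
    stop("X and targets must have the same number of rows", call. = FALSE)
  }
  H <- hidden_output(X, model)
  if (!is.null(weights)) {
    if (length(weights) != nrow(X) || any(weights < 0)) {
      stop("'weights' must be non-negative, one per sample", call. = FALSE)
    }
    sw <- sqrt(weights)
    model$beta <- pseudo_inverse(sw * H) %*% (sw * targets)
  } else {
    model$beta <- pseudo_inverse(H) %*% targets
  }
  model
}

# SVD pseudo-inverse; relative tolerance on singular values
pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' One-hot target matrix for two-class peak labels
#'
#' Column 1 corresponds to class 0 (non-peak), column 2 to class 1 (peak).
#'
#' @param labels Logical or 0/1 vector, `TRUE`/1 = peak.
#' @return `N x 2` matrix of one-hot rows.
#' @export
one_hot <- function(labels) {
  lab <- as.integer(as.logical(labels))
  cbind(nonpeak = 1 - lab, peak = lab)
}

#' Predict class labels with a trained ELM
#'
#' Output neurons are linear, `f(x) = h(x) beta`; the predicted class is the
#' arg-max output neuron. Exact ties resolve to the lower class index
#' (non-peak), so prediction is deterministic.
#'
#' @param object A trained `elm_model`.
#' @param X `N x d` feature matrix.
#' @param ... Unused.
#' @return Integer vector of labels (1 = peak, 0 = non-peak), with the raw
#'   output scores as attribute `scores`.
#' @export
predict.elm_model <- function(object, X, ...) {
  if (is.null(object$beta)) stop("model is untrained; call train_elm() first",
                                 call. = FALSE)
  scores <- hidden_output(X, object) %*% object$beta
  labels <- as.integer(scores[, 2L] > scores[, 1L])  # tie -> non-peak
  attr(labels, "scores") <- scores
  labels
}

#' Fit min-max feature scaling on the training set
#'
#' Features are mapped to [0, 1] using the training-set minima and maxima;
#' at prediction time the same extrema are applied and values are clipped to
#' [0, 1]. A constant feature maps to 0.
#'
#' @param X Training feature matrix.
#' @return A list of class `minmax_scaler` with per-column `min` and `range`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2L, min)
  rg <- apply(X, 2L, max) - mn
  structure(list(min = mn, range = rg), class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A `minmax_scaler` from [fit_scaler()].
#' @param X Feature matrix with the same columns as the training set.
#' @return Scaled matrix with entries in [0, 1].
#' @export
apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)
  rg <- ifelse(scaler$range > 0, scaler$range, 1)
  S <- sweep(sweep(X, 2L, scaler$min, "-"), 2L, rg, "/")
  S[scaler$range == 0 | S < 0] <- 0  # constant columns and underflow clip to 0
  S[S > 1] <- 1
  S
}

#' Save / load a trained ELM as portable JSON
#'
#' Serialises weights, biases, output weights, activation tag, scaler and
#' seed to a JSON container readable anywhere.
#'
#' @param model An `elm_model`.
#' @param path Destination / source file path.
#' @return `save_elm` returns `path` invisibly; `load_elm` returns the model.
#' @export
save_elm <- function(model, path) {
  payload <- list(
    a = model$a, b = model$b,
    beta = if (is.null(model$beta)) NULL else model$beta,
    activation = model$activation, d = model$d, n_hidden = model$n_hidden,
    m = model$m, seed = model$seed,
    scaler = if (is.null(model$scaler)) NULL else
      list(min = as.numeric(model$scaler$min),
           range = as.numeric(model$scaler$range))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_elm
#' @export
load_elm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    a = matrix(p$a, nrow = p$d), b = as.numeric(p$b),
    beta = if (is.null(p$beta)) NULL else matrix(p$beta, ncol = p$m),
    activation = p$activation, d = as.integer(p$d),
    n_hidden = as.integer(p$n_hidden), m = as.integer(p$m),
    seed = as.integer(p$seed),
    scaler = if (is.null(p$scaler)) NULL else
      structure(list(min = p$scaler$min, range = p$scaler$range),
                class = "minmax_scaler")
  ), class = "elm_model")
  model
}

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
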