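# Random least-squares feed-forward network (extreme-learning-machine
# family): a fixed random hidden layer, sigmoid kernel, and a closed-form
# minimum-norm least-squares output layer. Orientation used throughout:
# X is n_s x n_f (subjects by features), W1 is n_f x n_h, ground vectors
# Y = sigmoid(X W1) are n_s x n_h, W2 is n_h x 2, outputs Z = sigmoid(Y W2)
# are n_s x 2 (column 1 = pathological membership, column 2 = normative).

#' Initialise the random hidden layer
#'
#' Draws the hidden-layer weight matrix with i.i.d. standard-normal
#' entries, reproducibly from the seed.
#'
#' @param n_f Feature dimension (input width).
#' @param n_h Number of hidden hyperplanes.
#' @param seed Integer seed.
#' @return `n_f x n_h` numeric matrix.
#' @export
init_hidden <- function(n_f, n_h, seed) {
  if (n_f < 1 || n_h < 1) stop_input("dimensions must be >= 1")
  with_seed(seed, matrix(stats::rnorm(n_f * n_h), n_f, n_h))
}

#' Hidden-layer mapping (ground vectors)
#'
#' Projects feature vectors through the random hyperplanes and the
#' sigmoid kernel: `Y = sigmoid(X W1)`, entries strictly in (0, 1).
#'
#' @param X Feature matrix, `n_s x n_f`.
#' @param W1 Hidden weights, `n_f x n_h`.
#' @param kernel List with `slope` and `offset` of the sigmoid.
#' @return Ground-vector matrix `n_s x n_h`.
#' @export
hidden_map <- function(X, W1, kernel = list(slope = 1, offset = 0)) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W1)) {
    stop_input("feature dimension of X (", ncol(X),
               ") does not match W1 (", nrow(W1), ")")
  }
  sigmoid(X %*% W1, kernel$slope, kernel$offset)
}

# Moore-Penrose pseudoinverse via SVD; singular values below
# max(dim) * eps * sigma_max are truncated.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' One-hot target coding
#'
#' Pathological subjects code as (1, 0), normative as (0, 1), matching
#' the two membership outputs of the network.
#'
#' @param labels Character vector of `"pathological"` / `"normative"`.
#' @return `n_s x 2` 0/1 matrix with columns `pathological`, `normative`.
#' @export
target_coding <- function(labels) {
  if (!all(labels %in% c("pathological", "normative"))) {
    stop_input("labels must be 'pathological' or 'normative'")
  }
  cbind(pathological = as.numeric(labels == "pathological"),
        normative = as.numeric(labels == "normative"))
}

#' Fit the output layer
#'
#' Minimum-norm least-squares solution of `Y W2 = T` via the SVD-based
#' Moore-Penrose pseudoinverse: among all `W2` minimising the residual
#' norm, the one of minimal Frobenius norm is returned (closed-form
#' "block" training — no iterative weight adjustment).
#'
#' @param Y Ground-vector matrix `n_s x n_h`.
#' @param T_mat Target matrix `n_s x 2` from [target_coding()].
#' @return Output weights `n_h x 2`.
#' @export
fit_output <- function(Y, T_mat) {
  Y <- as.matrix(Y)
  T_mat <- as.matrix(T_mat)
  if (nrow(Y) != nrow(T_mat)) stop_input("Y and targets must align by row")
  W2 <- pinv(Y) %*% T_mat
  dimnames(W2) <- NULL
  W2
}

#' Train a random least-squares network
#'
#' @param X Feature matrix `n_s x n_f` (rows are AKV probability
#'   distributions, entries in `[0, 1]`).
#' @param labels Class labels, `"pathological"` / `"normative"`.
#' @param n_h Hidden width.
#' @param seed Seed for the random hidden layer.
#' @param kernel1,kernel2 Sigmoid parameterisations of the hidden and
#'   output non-linearities.
#' @param W1 Optionally, a pre-drawn hidden matrix (used by the
#'   leave-one-out harness to keep `W1` fixed across folds).
#' @return Object of class `rlsfn` with `W1`, `W2`, kernels, `n_h`,
#'   `seed`.
#' @export
rlsfn_train <- function(X, labels, n_h = 200, seed = 1L,
                        kernel1 = list(slope = 1, offset = 0),
                        kernel2 = list(slope = 1, offset = 0),
                        W1 = NULL) {
  X <- as.matrix(X)
  if (is.null(W1)) W1 <- init_hidden(ncol(X), n_h, seed)
  if (nrow(W1) != ncol(X)) stop_input("W1 does not match feature dimension")
  Y <- hidden_map(X, W1, kernel1)
  W2 <- fit_output(Y, target_coding(labels))
  structure(list(W1 = W1, W2 = W2, kernel1 = kernel1, kernel2 = kernel2,
                 n_h = ncol(W1), seed = as.integer(seed)),
            class = "rlsfn")
}

#' @export
print.rlsfn <- function(x, ...) {
  cat(sprintf("rlsfn: %d features -> %d hidden hyperplanes -> 2 memberships (seed %d)\n",
              nrow(x$W1), x$n_h, x$seed))
  invisible(x)
}

#' Predict class memberships
#'
#' Column 1 is the pathological membership `z_sp`, column 2 the normative
#' membership `z_sn`, both in (0, 1): the linear outputs `Y W2` (fitted by
#' least squares against the one-hot targets) are passed through a sigmoid
#' centred at the origin. The sigmoid is applied at prediction only — the
#' closed-form output fit targets the raw linear outputs.
#'
#' @param object A trained `rlsfn`.
#' @param X Feature matrix to score.
#' @param ... Unused.
#' @return `n_s x 2` membership matrix.
#' @export
predict.rlsfn <- function(object, X, ...) {
  if (is.null(object$W2)) stop_input("model has no trained output layer")
  Y <- hidden_map(as.matrix(X), object$W1, object$kernel1)
  lin <- Y %*% object$W2
  Z <- sigmoid(lin, object$kernel2$slope, object$kernel2$offset)
  colnames(Z) <- c("pathological", "normative")
  Z
}

#' Log-likelihood-ratio scores
#'
#' The unified detection score
#' \eqn{\lambda_s = \log z_{sp} - \log z_{sn}}: positive values call the
#' subject pathological.
#'
#' @param Z Membership matrix from [predict.rlsfn()].
#' @param eps Floor added inside the logs.
#' @return Numeric vector of scores.
#' @export
llr_scores <- function(Z, eps = 1e-12) {
  Z <- as.matrix(Z)
  if (ncol(Z) != 2L) stop_input("membership matrix must have 2 columns")
  log(Z[, 1] + eps) - log(Z[, 2] + eps)
}

#' Serialise / restore an RLSFN model
#'
#' JSON round trip of all weights and kernel settings for exact
#' reproducibility.
#'
#' @param model A trained `rlsfn`.
#' @param path JSON file path.
#' @return `save_rlsfn`: `path` invisibly; `load_rlsfn`: the model.
#' @export
save_rlsfn <- function(model, path) {
  stopifnot(inherits(model, "rlsfn"))
  jsonlite::write_json(
    list(W1 = model$W1, W2 = model$W2, kernel1 = model$kernel1,
         kernel2 = model$kernel2, n_h = model$n_h, seed = model$seed),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_rlsfn
#' @export
load_rlsfn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = obj$W1, W2 = obj$W2,
                 kernel1 = as.list(obj$kernel1),
                 kernel2 = as.list(obj$kernel2),
                 n_h = obj$n_h, seed = as.integer(obj$seed)),
            class = "rlsfn")
}
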