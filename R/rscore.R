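#' @include AllClasses.R AllGenerics.R
NULL

#' Build an r-score evaluation context
#'
#' Precomputes the reference-set quantities of the r-score criterion: the
#' centered Gram matrix Theta = X0' (I - Jbar) X0 and
#' q1 = (n0 - 1) + Tr(Theta). Both depend only on the reference set — the
#' test set X0 for the targeted method, the candidate set Xc for the
#' untargeted method — so repeated training-set evaluations need only
#' training-set-sized algebra.
#'
#' @param reference reference-set PC score matrix (n0 x p, n0 >= 2).
#' @param lambda ridge shrinkage of the criterion; the default 1 is used
#'   throughout the size-determination procedure.
#' @return an [RScoreContext-class].
#' @export
buildRScoreContext <- function(reference, lambda = 1) {
  reference <- as.matrix(reference)
  if (!all(is.finite(reference))) stop("non-finite entries in reference scores")
  n0 <- nrow(reference)
  if (n0 < 2L) stop("reference set needs at least 2 rows (n0 >= 2)")
  centered <- sweep(reference, 2L, colMeans(reference))
  theta <- crossprod(centered)        # X0' (I - Jbar) X0
  q1 <- (n0 - 1) + sum(centered^2)    # (n0 - 1) + Tr(Theta)
  new("RScoreContext", reference = reference, theta = theta, q1 = q1,
      n0 = as.integer(n0), lambda = as.numeric(lambda))
}

#' Evaluate the r-score of a training set
#'
#' Computes the r-score criterion
#' \deqn{r = q_{12} / \sqrt{q_1 q_2}}
#' with A = X_t' (X_t X_t' + lambda I)^{-1},
#' q12 = Tr\[Theta A X_t\], q2 = Tr\[A' Theta A\] + Tr\[X_t' A' Theta A X_t\]
#' and Theta the centered reference Gram matrix held by `ctx`. Internally the
#' traces are reduced to the training-set-sized identities
#' q12 = Tr\[B G^{-1}\] and q2 = q12 + (1 - lambda) Tr\[B G^{-2}\] with
#' B = X_t Theta X_t' and G = X_t X_t' + lambda I; tests verify this against
#' the naive dense formulation.
#'
#' @param ctx an [RScoreContext-class].
#' @param training training-set PC score matrix X_t (n_t x p, same column
#'   space as the reference).
#' @return an [RScoreValue-class].
#' @export
rScore <- function(ctx, training) {
  stopifnot(is(ctx, "RScoreContext"))
  training <- as.matrix(training)
  if (!all(is.finite(training))) stop("non-finite entries in training scores")
  nt <- nrow(training)
  if (nt < 1L) stop("training set must have at least 1 row")
  if (ncol(training) != ncol(ctx@reference))
    stop("training and reference scores must share the PC space")
  lambda <- ctx@lambda
  G <- tcrossprod(training)
  diag(G) <- diag(G) + lambda
  B <- training %*% ctx@theta %*% t(training)
  ch <- tryCatch(chol(G), error = function(e)
    stop("training Gram matrix is not positive definite: ", conditionMessage(e)))
  GinvB <- chol2inv(ch) %*% B
  q12 <- sum(diag(GinvB))
  t2 <- sum(chol2inv(ch) * t(GinvB))   # Tr[G^-2 B]
  q2 <- q12 + (1 - lambda) * t2
  if (!is.finite(q2) || q2 <= 1e-14 * ctx@q1)
    stop("degenerate r-score criterion: q2 is numerically zero ",
         "(training scores carry no reference-set signal)")
  new("RScoreValue", value = q12 / sqrt(ctx@q1 * q2), q12 = q12, q2 = q2,
      q1 = ctx@q1, nTrain = as.integer(nt))
}
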