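#' HKY-style nucleotide substitution model
#'
#' Builds a reversible rate matrix with equilibrium frequencies `pi` and
#' transition/transversion ratio `kappa`, normalised to one expected
#' substitution per unit time at equilibrium. `kappa = 1` with uniform `pi`
#' reduces to the equal-rate (Jukes-Cantor) model, which has closed-form
#' transition probabilities used by the test suite.
#'
#' The reversible Q is diagonalised once through its symmetrised form
#' `diag(sqrt(pi)) Q diag(1/sqrt(pi))`; transition matrices are then exact
#' matrix exponentials `P(t) = U exp(L t) U^-1`.
#'
#' @param pi equilibrium base frequencies (A, C, G, T); positive, summing to 1.
#' @param kappa transition/transversion rate ratio, > 0.
#' @return an object of class `subst_model` with elements `pi`, `kappa`, `Q`,
#'   and the eigendecomposition (`U`, `lambda`, `Uinv`).
#' @export
hky_model <- function(pi = rep(0.25, 4), kappa = 1) {
  stopifnot(length(pi) == 4, all(is.finite(pi)))
  if (any(pi <= 0)) stop("all equilibrium frequencies must be > 0")
  if (abs(sum(pi) - 1) > 1e-8) stop("equilibrium frequencies must sum to 1")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  pi <- pi / sum(pi)
  names(pi) <- DNA_BASES4

  transition <- matrix(FALSE, 4, 4)  # A<->G, C<->T
  transition[1, 3] <- transition[3, 1] <- TRUE
  transition[2, 4] <- transition[4, 2] <- TRUE

  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES4, DNA_BASES4))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- pi[j] * ifelse(transition[i, j], kappa, 1)
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))  # expected substitutions per unit time
  Q <- Q / rate

  # symmetrised eigendecomposition (exact for reversible Q)
  d <- sqrt(pi)
  S <- diag(d) %*% Q %*% diag(1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  U <- diag(1 / d) %*% es$vectors
  Uinv <- t(es$vectors) %*% diag(d)

  structure(
    list(pi = pi, kappa = kappa, Q = Q,
         U = U, lambda = es$values, Uinv = Uinv),
    class = "subst_model"
  )
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [hky_model()].
#' @param t branch length (expected substitutions/site), >= 0.
#' @return 4x4 row-stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be finite and >= 0")
  P <- model$U %*% diag(exp(model$lambda * t)) %*% model$Uinv
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- list(DNA_BASES4, DNA_BASES4)
  P
}
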