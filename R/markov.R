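# Discrete-state Markov machinery used by the synthetic cohort generator.

#' Construct Markov chain parameters
#'
#' @param transition_matrix K x K row-stochastic matrix; the diagonal
#'   carries the self-transition mass that governs dwell times.
#' @param initial_probs length-K simplex of start probabilities; default is
#'   the stationary distribution of `transition_matrix`.
#' @return object of class `markov_params`.
#' @export
markov_params <- function(transition_matrix, initial_probs = NULL) {
  P <- as.matrix(transition_matrix)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(P < 0)) stop("transition probabilities must be non-negative")
  rs <- rowSums(P)
  if (any(rs == 0)) stop("degenerate transition matrix: row of zeros")
  if (any(abs(rs - 1) > 1e-12)) stop("transition matrix rows must sum to 1 (tolerance 1e-12)")
  obj <- structure(list(transition_matrix = P, initial_probs = NULL),
                   class = "markov_params")
  if (is.null(initial_probs)) initial_probs <- stationary_distribution(obj)
  initial_probs <- as.numeric(initial_probs)
  if (length(initial_probs) != nrow(P) || any(initial_probs < 0) ||
      abs(sum(initial_probs) - 1) > 1e-12)
    stop("initial_probs must be a length-K simplex")
  obj$initial_probs <- initial_probs
  obj
}

# Strong connectivity of the directed graph of positive transitions.
.is_irreducible <- function(P) {
  A <- P > 0
  R <- A | diag(TRUE, nrow(A))
  for (i in seq_len(ceiling(log2(nrow(A))) + 1)) R <- (R %*% R) > 0
  all(R)
}

#' Stationary distribution of a Markov chain
#'
#' The left eigenvector of the transition matrix with eigenvalue 1,
#' normalized to a probability vector: the expected long-run fraction of
#' time in each state, used to set planted occupancy targets.
#'
#' @param markov a [markov_params()] object (or a bare row-stochastic matrix).
#' @return length-K numeric simplex.
#' @export
#' @examples
#' stationary_distribution(markov_params(matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)))
stationary_distribution <- function(markov) {
  P <- if (inherits(markov, "markov_params")) markov$transition_matrix else as.matrix(markov)
  if (!.is_irreducible(P))
    stop("chain is reducible: no unique stationary distribution")
  ev <- eigen(t(P))
  mods <- Mod(ev$values)
  i1 <- which.min(abs(ev$values - 1))
  if (sum(mods > 1 - 1e-10) > 1)
    stop("chain is periodic (degenerate): multiple eigenvalues on the unit circle")
  v <- Re(ev$vectors[, i1])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("failed to extract a valid stationary distribution")
  pmax(v, 0) / sum(pmax(v, 0))
}

# Sample one run of a Markov chain; assumes RNG state is already set.
sample_chain <- function(markov, n) {
  P <- markov$transition_matrix
  K <- nrow(P)
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = markov$initial_probs)
  for (t in seq_len(n - 1)) s[t + 1] <- sample.int(K, 1, prob = P[s[t], ])
  s
}

#' Embedded jump chain of a Markov transition matrix
#'
#' Conditioning out self-transitions gives the chain of state *changes*:
#' `Q[i, j] = P[i, j] / (1 - P[i, i])` off the diagonal, 0 on it. This is
#' the analytic prediction for transition probabilities estimated on a
#' duplicate-collapsed state sequence.
#'
#' @param markov a [markov_params()] object or row-stochastic matrix.
#' @return K x K matrix with zero diagonal and stochastic rows.
#' @export
embedded_jump_chain <- function(markov) {
  P <- if (inherits(markov, "markov_params")) markov$transition_matrix else as.matrix(markov)
  stay <- diag(P)
  if (any(stay >= 1)) stop("absorbing state: embedded jump chain undefined")
  Q <- P / (1 - stay)
  diag(Q) <- 0
  Q
}
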