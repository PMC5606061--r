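#' Single-cell genotyping error rates
#'
#' Container for the false-positive rate `alpha` (a non-mutated site reported
#' as mutated) and the false-negative rate `beta` (allelic dropout: a true
#' heterozygous mutation missed or mis-typed). In ternary mode the observation
#' model additionally requires `alpha + alpha * beta / 2 <= 1` so that the
#' observation probabilities for a true genotype 0 form a distribution; this
#' is validated at construction rather than renormalized.
#'
#' @param alpha False-positive probability, in \[0, 1\].
#' @param beta False-negative (allelic dropout) probability, in \[0, 1\].
#' @return An object of class `error_rates`.
#' @export
#' @examples
#' error_rates(0.01, 0.2)
error_rates <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1)
    stop("alpha and beta must lie in [0, 1]")
  if (alpha + alpha * beta / 2 > 1 + 1e-12)
    stop("invalid error rates: alpha + alpha*beta/2 exceeds 1")
  structure(list(alpha = alpha, beta = beta), class = "error_rates")
}

#' Finite-sites evolution-model parameters
#'
#' Rates of deletion (`lambda_d`) and loss of heterozygosity (`lambda_l`)
#' relative to the point-mutation rate, which is fixed at 1. These two
#' parameters fully determine the genotype transition-rate matrix.
#'
#' @param lambda_d Deletion rate relative to point mutation, `>= 0`.
#' @param lambda_l LOH rate relative to point mutation, `>= 0`.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(lambda_d, lambda_l) {
  stopifnot(is.numeric(lambda_d), length(lambda_d) == 1L, is.finite(lambda_d),
            is.numeric(lambda_l), length(lambda_l) == 1L, is.finite(lambda_l))
  if (lambda_d < 0 || lambda_l < 0) stop("lambda_d and lambda_l must be non-negative")
  structure(list(lambda_d = lambda_d, lambda_l = lambda_l),
            class = "evolution_params")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("error rates: alpha (FP) = %g, beta (FN/ADO) = %g\n", x$alpha, x$beta))
  invisible(x)
}

#' @export
print.evolution_params <- function(x, ...) {
  cat(sprintf("evolution model: lambda_d = %g, lambda_l = %g (relative to point-mutation rate 1)\n",
              x$lambda_d, x$lambda_l))
  invisible(x)
}

mode_states <- function(mode) {
  mode <- match.arg(mode, c("binary", "ternary"))
  if (mode == "binary") 0:1 else 0:2
}

#' Observation probability Pr(D = d | G = g)
#'
#' Probability of observing genotype `d` when the true genotype is `g`,
#' under the single-cell error model. Missing observations (`NA`) have
#' probability 1 for every true genotype, which marginalizes missing data
#' out of the likelihood.
#'
#' In binary mode: a true 0 is observed as 1 with probability `alpha`; a
#' true 1 is observed as 0 with probability `beta`. In ternary mode a true
#' heterozygote (1) drops to either homozygote with probability `beta/2`
#' each; a true homozygous reference (0) is mis-called heterozygous with
#' probability `alpha`, or homozygous non-reference with probability
#' `alpha*beta/2`; a true homozygous non-reference (2) is never altered.
#'
#' @param d Observed genotype (or `NA` for missing).
#' @param g True genotype.
#' @param theta An [error_rates()] object.
#' @param mode `"binary"` or `"ternary"`.
#' @return A probability.
#' @export
observation_probability <- function(d, g, theta, mode = c("ternary", "binary")) {
  mode <- match.arg(mode)
  states <- mode_states(mode)
  if (!g %in% states) stop("true genotype ", g, " outside ", mode, " alphabet")
  if (is.na(d)) return(1)
  if (!d %in% states) stop("observed genotype ", d, " outside ", mode, " alphabet")
  k <- length(states)
  cpp_leaf_partial(as.integer(d), theta$alpha, theta$beta, k)[g + 1L]
}

#' Leaf partial-likelihood vector
#'
#' Vector over true genotype states `g` of Pr(D = d | G = g); this is the
#' quantity entering the pruning recursion at a leaf. Missing data yields
#' the all-ones vector.
#'
#' @inheritParams observation_probability
#' @return Numeric vector of length 2 (binary) or 3 (ternary).
#' @export
leaf_partial_vector <- function(d, theta, mode = c("ternary", "binary")) {
  mode <- match.arg(mode)
  k <- length(mode_states(mode))
  if (is.na(d)) return(rep(1, k))
  if (!d %in% mode_states(mode)) stop("observed genotype ", d, " outside ", mode, " alphabet")
  as.numeric(cpp_leaf_partial(as.integer(d), theta$alpha, theta$beta, k))
}

#' Scaled transition-rate matrix Qt
#'
#' The product of the genotype transition-rate matrix and the branch length
#' `t`. Point mutation 0 to 1 has rate 1; LOH and deletion move a
#' heterozygote to either homozygote at combined rate
#' `(lambda_d + lambda_l)/2` each way, and deletion moves a homozygous
#' non-reference genotype back to heterozygous at rate `lambda_d`. Direct
#' 0 to 2 transitions are impossible. Rows sum to zero.
#'
#' @param t Branch length (expected mutations per site), `>= 0`.
#' @param params An [evolution_params()] object.
#' @param mode `"binary"` or `"ternary"`.
#' @return A 2x2 or 3x3 matrix.
#' @export
scaled_rate_matrix <- function(t, params, mode = c("ternary", "binary")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  if (t < 0) stop("branch length t must be non-negative")
  k <- length(mode_states(mode))
  Q <- cpp_rate_matrix(t, params$lambda_d, params$lambda_l, k)
  dimnames(Q) <- list(as.character(seq_len(k) - 1L), as.character(seq_len(k) - 1L))
  Q
}

#' Genotype transition-probability matrix
#'
#' `P_t = exp(Qt)` computed by a dense Pade scaling-and-squaring matrix
#' exponential; entry (i, j) is the probability that a site with genotype
#' i at the top of a branch of length `t` has genotype j at the bottom.
#'
#' @inheritParams scaled_rate_matrix
#' @return A stochastic matrix (rows sum to 1).
#' @export
transition_probabilities <- function(t, params, mode = c("ternary", "binary")) {
  mode <- match.arg(mode)
  Q <- scaled_rate_matrix(t, params, mode)
  P <- cpp_expm(Q)
  dimnames(P) <- dimnames(Q)
  P
}
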