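#' Per-chain confidence of a domain assignment
#'
#' Treats the network's soft adjacency as a multivariate Bernoulli
#' distribution and scores the final assignment's binary co-membership
#' matrix as an observation from it. The score is the likelihood normalized
#' by chain length: exp(log-likelihood / L), the geometric-mean per-residue
#' likelihood. It lies in (0, 1], equals 1 only when a saturated prediction
#' exactly matches the assignment, and decreases as the prediction diverges
#' from the assignment. Pair-normalization (divide by the number of residue
#' pairs instead of L) is available as an option.
#'
#' @inheritParams log_likelihood
#' @param normalization "residue" (default) or "pair".
#' @return Confidence score in (0, 1].
#' @export
confidence_score <- function(assignment, soft, eps = 1e-4,
                             normalization = c("residue", "pair")) {
  normalization <- match.arg(normalization)
  L <- nrow(soft)
  ll <- log_likelihood(assignment, soft, eps = eps)
  n <- if (normalization == "residue") L else max(1, L * (L - 1) / 2)
  exp(ll / n)
}
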