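#' Options for the greedy domain assigner
#'
#' @param k_init initial number of candidate domains (columns of the
#'   assignment matrix). The search appends an overflow column whenever the
#'   last column is used, so this is not a cap on the number of domains.
#' @param n_iter maximum number of full passes over the sequence; each pass
#'   revisits every residue to allow corrections. The search stops early
#'   when a pass changes nothing.
#' @param eps probability clip applied to the soft adjacency before taking
#'   logs; guards against saturated network outputs.
#' @param min_domain_size if positive, domains smaller than this many
#'   residues are demoted to null after the search. Off (0) by default.
#' @return A list of class \code{assigner_config}.
#' @export
assigner_config <- function(k_init = 4, n_iter = 3, eps = 1e-4,
                            min_domain_size = 0) {
  stopifnot(k_init >= 1, n_iter >= 1, eps > 0, eps < 0.5,
            min_domain_size >= 0)
  structure(list(k_init = as.integer(k_init), n_iter = as.integer(n_iter),
                 eps = eps, min_domain_size = as.integer(min_domain_size)),
            class = "assigner_config")
}

#' Log-likelihood of a domain assignment under a soft adjacency
#'
#' Treats the soft adjacency as an independent Bernoulli distribution over
#' residue pairs and scores the binary co-membership matrix induced by the
#' assignment: sum over pairs i < j of
#' a_ij log p_ij + (1 - a_ij) log(1 - p_ij). Diagonal terms are excluded.
#'
#' @param assignment integer vector of per-residue domain labels
#'   (0 = no domain).
#' @param soft symmetric L x L matrix of co-membership probabilities.
#' @param eps probability clip.
#' @return Scalar log-likelihood (non-positive).
#' @export
log_likelihood <- function(assignment, soft, eps = 1e-4) {
  labels <- as.integer(assignment)
  if (length(labels) != nrow(soft)) {
    stop("assignment length does not match soft adjacency size", call. = FALSE)
  }
  p <- clip_prob(soft, eps)
  A <- assignment_to_adjacency(labels)
  ut <- upper.tri(p)
  sum(A[ut] * log(p[ut]) + (1 - A[ut]) * log1p(-p[ut]))
}

#' Incremental score of moving one residue to another domain
#'
#' Computes the change in \code{\link{log_likelihood}} caused by reassigning
#' residue \code{j} to domain \code{k} (or to null, \code{k = 0}), touching
#' only the L - 1 pair terms that involve \code{j}; cost O(L) rather than
#' O(L^2).
#'
#' @inheritParams log_likelihood
#' @param j residue index (1-based).
#' @param k target domain id; 0 for null; may be one larger than the current
#'   number of domains (a new domain).
#' @return Scalar score difference.
#' @export
delta_score <- function(assignment, soft, j, k, eps = 1e-4) {
  labels <- as.integer(assignment)
  L <- length(labels)
  if (length(labels) != nrow(soft)) {
    stop("assignment length does not match soft adjacency size", call. = FALSE)
  }
  if (j < 1 || j > L) stop("residue index out of range", call. = FALSE)
  K <- max(0L, labels)
  if (k < 0 || k > K + 1L) {
    stop("target domain must be in {0, 1, ..., K + 1}", call. = FALSE)
  }
  s <- logit(clip_prob(soft[, j], eps))
  s[j] <- 0
  gain <- function(lab) if (lab == 0L) 0 else sum(s[labels == lab &
                                                      seq_len(L) != j])
  gain(as.integer(k)) - gain(labels[j])
}

#' Greedy maximum-likelihood domain assignment
#'
#' Resolves a soft adjacency matrix into discrete domain assignments by
#' greedy coordinate ascent on the Bernoulli log-likelihood. Residues start
#' unassigned (all-null one-hot matrix with \code{k_init} empty columns) and
#' are swept in sequence order; each residue moves to its best-scoring
#' domain when that is at least as good as the null assignment, with ties
#' broken toward the lowest domain index. Moving on ties is what lets the
#' search leave the all-null start: the first residue of a prospective
#' domain "seeds" an empty column at zero gain, and co-members then join at
#' strictly positive gain. Whenever the last column is used an overflow
#' column is appended, so the number of domains is unbounded. Up to
#' \code{n_iter} passes are made, stopping early once a pass changes
#' nothing. Terminal domains holding a single residue contribute no pair
#' terms, so they are exact likelihood ties with null and are demoted
#' (matching the exhaustive oracle's preference for null on ties); empty
#' domains are dropped and labels canonicalized at the end.
#'
#' For an exact (clipped binary) adjacency the procedure provably recovers
#' the generating assignment.
#'
#' @param soft symmetric L x L matrix of co-membership probabilities.
#' @param config an \code{\link{assigner_config}}.
#' @return Integer vector of per-residue domain labels (0 = no domain), with
#'   attribute \code{"sweeps"} giving the number of passes performed.
#' @export
assign_domains <- function(soft, config = assigner_config()) {
  check_soft_adjacency(soft)
  L <- nrow(soft)
  S <- logit(clip_prob(soft, config$eps))
  diag(S) <- 0
  K <- config$k_init
  labels <- integer(L)
  members <- rep(list(integer(0)), K)
  sweeps <- 0L
  for (it in seq_len(config$n_iter)) {
    changed <- FALSE
    for (j in seq_len(L)) {
      sj <- S[, j]
      gains <- vapply(members, function(ix) sum(sj[ix]), numeric(1))
      # own contribution is sj[j] = 0, so gains are scores relative to null
      k_star <- which.max(gains)
      new_lab <- if (gains[k_star] >= 0) k_star else 0L
      cur <- labels[j]
      if (new_lab != cur) {
        if (cur != 0L) members[[cur]] <- setdiff(members[[cur]], j)
        if (new_lab != 0L) members[[new_lab]] <- c(members[[new_lab]], j)
        labels[j] <- new_lab
        changed <- TRUE
      }
      if (new_lab == K) {  # overflow: keep an empty candidate column
        K <- K + 1L
        members[[K]] <- integer(0)
      }
    }
    sweeps <- it
    if (!changed) break
  }
  # singleton domains are likelihood ties with null: demote them
  min_size <- max(2L, config$min_domain_size)
  sizes <- tabulate(labels, nbins = K)
  labels[labels != 0L & sizes[pmax(labels, 1L)] < min_size] <- 0L
  out <- canonicalize_assignment(labels)
  attr(out, "sweeps") <- sweeps
  out
}

#' Exhaustive maximum-likelihood assignment (validation oracle)
#'
#' Enumerates every canonical labelling of the residues over
#' {null, 1, ..., max_domains} (restricted-growth order, so each labelling
#' is visited once up to domain permutation) and returns the global
#' maximizer of \code{\link{log_likelihood}}. Ties resolve to the
#' lexicographically smallest canonical labelling. Intended as an
#' independent check of the greedy search at small L; refuses L > 10.
#'
#' @inheritParams assign_domains
#' @param max_domains maximum number of domains to enumerate.
#' @param eps probability clip.
#' @return Integer vector of per-residue domain labels (0 = no domain).
#' @export
brute_force_assign <- function(soft, max_domains = 4, eps = 1e-4) {
  check_soft_adjacency(soft)
  L <- nrow(soft)
  if (L > 10) {
    stop("brute_force_assign enumerates all labelings and refuses L > 10",
         call. = FALSE)
  }
  S <- logit(clip_prob(soft, eps))
  diag(S) <- 0
  best_labels <- integer(L)
  best_score <- 0  # score of the all-null labelling (first in lex order)
  labels <- integer(L)
  recurse <- function(pos, max_used, score) {
    if (pos > L) {
      if (score > best_score + 1e-12) {
        best_score <<- score
        best_labels <<- labels[seq_len(L)]
      }
      return(invisible())
    }
    for (k in 0:min(max_used + 1L, max_domains)) {
      inc <- if (k == 0L) 0 else {
        prev <- which(labels[seq_len(pos - 1L)] == k)
        sum(S[prev, pos])
      }
      labels[pos] <<- k
      recurse(pos + 1L, max(max_used, k), score + inc)
    }
    labels[pos] <<- 0L
  }
  recurse(1L, 0L, 0)
  canonicalize_assignment(best_labels)
}
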