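#' Intersection-over-union between two domain assignments
#'
#' Matches predicted to reference domains one-to-one so as to maximize the
#' total number of shared residues (exact bipartite matching via dynamic
#' programming over subsets), then scores each matched pair by
#' |intersection| / |union| of residue sets. Unmatched reference domains
#' score 0. The chain-level score is the mean over reference domains, so it
#' is 1 exactly when the assignments agree up to domain relabelling.
#'
#' @param pred,truth integer vectors of per-residue domain labels
#'   (0 = no domain), same length.
#' @return A list of class \code{iou_result}: \code{iou} (chain score) and
#'   \code{per_domain}, a data frame with one row per reference domain
#'   (matched predicted domain or NA, intersection, union, iou).
#' @export
iou_score <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("assignments must have the same length", call. = FALSE)
  }
  ref_ids <- setdiff(unique(truth), 0L)
  pred_ids <- setdiff(unique(pred), 0L)
  m <- length(ref_ids); n <- length(pred_ids)
  if (m == 0) {
    return(structure(list(
      iou = if (n == 0) 1 else 0,
      per_domain = data.frame(ref = integer(0), pred = integer(0),
                              intersection = integer(0), union = integer(0),
                              iou = numeric(0))), class = "iou_result"))
  }
  inter <- matrix(0L, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      inter[i, j] <- sum(truth == ref_ids[i] & pred == pred_ids[j])
    }
  }
  match_vec <- match_domains(inter)
  ref_size <- vapply(ref_ids, function(d) sum(truth == d), integer(1))
  pred_size <- vapply(pred_ids, function(d) sum(pred == d), integer(1))
  rows <- lapply(seq_len(m), function(i) {
    j <- match_vec[i]
    if (is.na(j) || inter[i, j] == 0) {
      data.frame(ref = ref_ids[i], pred = NA_integer_, intersection = 0L,
                 union = ref_size[i], iou = 0)
    } else {
      u <- ref_size[i] + pred_size[j] - inter[i, j]
      data.frame(ref = ref_ids[i], pred = pred_ids[j],
                 intersection = inter[i, j], union = u,
                 iou = inter[i, j] / u)
    }
  })
  per_domain <- do.call(rbind, rows)
  structure(list(iou = mean(per_domain$iou), per_domain = per_domain),
            class = "iou_result")
}

#' @export
print.iou_result <- function(x, ...) {
  cat(sprintf("<iou_result> chain IoU %.4f over %d reference domain(s)\n",
              x$iou, nrow(x$per_domain)))
  print(x$per_domain)
  invisible(x)
}

# one-to-one matching maximizing total intersection; returns, for each
# reference domain (row), the matched prediction column or NA.
# DP over subsets of predicted domains; sizes here are small (tens at most).
# Beyond 12 predicted domains (degenerate over-split output) fall back to
# greedy matching on decreasing intersection.
match_domains <- function(inter) {
  m <- nrow(inter); n <- ncol(inter)
  if (n == 0) return(rep(NA_integer_, m))
  if (n > 12) {
    out <- rep(NA_integer_, m)
    used <- logical(n)
    ord <- order(-inter)
    for (pos in ord) {
      i <- (pos - 1L) %% m + 1L
      j <- (pos - 1L) %/% m + 1L
      if (is.na(out[i]) && !used[j] && inter[i, j] > 0) {
        out[i] <- j
        used[j] <- TRUE
      }
    }
    return(out)
  }
  n_mask <- bitwShiftL(1L, n)
  dp <- matrix(-Inf, m + 1L, n_mask)
  dp[1L, 1L] <- 0
  choice <- matrix(NA_integer_, m + 1L, n_mask)
  from <- matrix(NA_integer_, m + 1L, n_mask)
  for (i in seq_len(m)) {
    for (mask in 0:(n_mask - 1L)) {
      base <- dp[i, mask + 1L]
      if (!is.finite(base)) next
      # ref i unmatched
      if (base > dp[i + 1L, mask + 1L]) {
        dp[i + 1L, mask + 1L] <- base
        choice[i + 1L, mask + 1L] <- 0L
        from[i + 1L, mask + 1L] <- mask
      }
      for (j in seq_len(n)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        v <- base + inter[i, j]
        if (v > dp[i + 1L, mask + bit + 1L]) {
          dp[i + 1L, mask + bit + 1L] <- v
          choice[i + 1L, mask + bit + 1L] <- j
          from[i + 1L, mask + bit + 1L] <- mask
        }
      }
    }
  }
  best_mask <- which.max(dp[m + 1L, ]) - 1L
  out <- rep(NA_integer_, m)
  mask <- best_mask
  for (i in rev(seq_len(m))) {
    j <- choice[i + 1L, mask + 1L]
    if (!is.na(j) && j > 0L) out[i] <- j
    mask <- from[i + 1L, mask + 1L]
  }
  out
}

#' Fraction of correctly parsed reference domains
#'
#' A reference domain counts as correctly parsed when its matched predicted
#' domain reaches an intersection-over-union of at least \code{threshold}
#' (0.8 by convention). The fraction is computed over all reference domains
#' pooled across chains.
#'
#' @param pairs a list of chains, each a list with elements \code{pred} and
#'   \code{truth} (per-residue label vectors), or a single such pair.
#' @param threshold domain-level IoU cutoff.
#' @return Fraction in \[0, 1\].
#' @export
domain_correct_fraction <- function(pairs, threshold = 0.8) {
  if (!is.null(pairs$pred)) pairs <- list(pairs)
  if (length(pairs) == 0) stop("empty evaluation set", call. = FALSE)
  ious <- unlist(lapply(pairs, function(p) {
    iou_score(p$pred, p$truth)$per_domain$iou
  }))
  if (length(ious) == 0) stop("no reference domains to evaluate",
                              call. = FALSE)
  mean(ious >= threshold)
}

#' Domain boundary distance score
#'
#' Boundaries are the sequence positions where the domain label changes
#' between consecutive residues (including null-to-domain transitions).
#' For each tolerance t = 1..max_tol the score takes the harmonic mean of
#' the fraction of predicted boundaries within t positions of a true
#' boundary and the fraction of true boundaries within t of a predicted
#' one; the final score is the mean over tolerances. Identical boundary
#' sets score 1; if exactly one assignment has no boundaries the score is
#' 0; two boundary-free assignments score 1 by convention. This
#' tolerance-sweep formulation is this package's documented interpretation
#' of the CASP-style boundary score.
#'
#' @inheritParams iou_score
#' @param max_tol largest boundary tolerance, in residues.
#' @return Score in \[0, 1\].
#' @export
boundary_distance_score <- function(pred, truth, max_tol = 8) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("assignments must have the same length", call. = FALSE)
  }
  bp <- domain_boundaries(pred)
  bt <- domain_boundaries(truth)
  if (length(bp) == 0 && length(bt) == 0) return(1)
  if (length(bp) == 0 || length(bt) == 0) return(0)
  scores <- vapply(seq_len(max_tol), function(t) {
    prec <- mean(vapply(bp, function(b) min(abs(bt - b)) <= t, logical(1)))
    rec <- mean(vapply(bt, function(b) min(abs(bp - b)) <= t, logical(1)))
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(scores)
}

# boundary positions: p means a label change between residues p and p + 1
domain_boundaries <- function(labels) {
  which(labels[-length(labels)] != labels[-1])
}

#' Evaluate a predicted assignment against a reference
#'
#' Bundles the chain-level metrics and a coarse fault taxonomy:
#' over/under-splitting (more/fewer predicted than reference domains),
#' missing domains (reference domains with no overlapping prediction),
#' false domains (predicted domains matching no reference domain) and
#' boundary errors (matched domains below the IoU threshold).
#'
#' @inheritParams iou_score
#' @param threshold domain-level IoU cutoff for a correct parse.
#' @param max_tol boundary-score tolerance.
#' @return A list of class \code{eval_result} with elements \code{iou},
#'   \code{per_domain}, \code{domain_correct_fraction},
#'   \code{boundary_score} and logical \code{fault_flags}.
#' @export
evaluate_assignment <- function(pred, truth, threshold = 0.8, max_tol = 8) {
  res <- iou_score(pred, truth)
  n_ref <- nrow(res$per_domain)
  n_pred <- length(setdiff(unique(as.integer(pred)), 0L))
  matched <- res$per_domain$pred[!is.na(res$per_domain$pred)]
  flags <- c(
    over_split = n_pred > n_ref,
    under_split = n_pred < n_ref,
    boundary_error = any(res$per_domain$iou < threshold &
                           res$per_domain$iou > 0),
    missing_domain = any(res$per_domain$iou == 0) && n_ref > 0,
    false_domain = n_pred > length(matched)
  )
  structure(list(
    iou = res$iou,
    per_domain = res$per_domain,
    domain_correct_fraction = if (n_ref > 0) mean(res$per_domain$iou >=
                                                    threshold) else NA_real_,
    boundary_score = boundary_distance_score(pred, truth, max_tol = max_tol),
    fault_flags = flags), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> IoU %.4f | correct domains %.2f | boundary %.4f\n",
    x$iou, x$domain_correct_fraction, x$boundary_score))
  faults <- names(x$fault_flags)[x$fault_flags]
  cat("faults:", if (length(faults)) paste(faults, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
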