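#' Canonicalize a domain assignment
#'
#' Relabels domains so that ids appear in order of first occurrence along the
#' sequence (1, 2, ...). Label 0 (no domain) is preserved. All functions in
#' the package that return assignments return them in this canonical form,
#' which makes assignments comparable independently of arbitrary domain
#' numbering.
#'
#' @param labels integer vector of per-residue domain labels (0 = no domain).
#' @return Canonicalized integer vector.
#' @export
canonicalize_assignment <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  nz <- labels[labels != 0L]
  if (length(nz) == 0) return(labels)
  first <- unique(nz)
  out <- labels
  out[labels != 0L] <- match(nz, first)
  out
}

#' Convert a domain assignment to its binary co-membership matrix
#'
#' Builds the L x L adjacency label A with a_ij = 1 exactly when residues i
#' and j carry the same non-null domain label. Equivalently A = V V' for the
#' one-hot assignment matrix V, so A is block-structured (blocks appear off
#' the diagonal for discontinuous domains). The diagonal is 1 for assigned
#' residues and 0 for null residues, making "assigned to no domain"
#' representable inside A.
#'
#' @param assignment integer vector of per-residue domain labels
#'   (0 = no domain).
#' @return Binary symmetric L x L matrix.
#' @export
assignment_to_adjacency <- function(assignment) {
  labels <- as.integer(assignment)
  A <- outer(labels, labels, "==")
  A[labels == 0L, ] <- FALSE
  A[, labels == 0L] <- FALSE
  storage.mode(A) <- "double"
  A
}

#' Recover a domain assignment from a binary co-membership matrix
#'
#' Interprets the matrix as the adjacency matrix of a graph on residues and
#' returns its connected components as domains. Residues whose diagonal
#' entry is 0 become null. For valid block-structured inputs this is the
#' exact inverse of \code{\link{assignment_to_adjacency}} up to canonical
#' relabelling; inputs violating transitivity are rejected.
#'
#' @param adj binary symmetric L x L matrix.
#' @return Integer vector of per-residue domain labels (0 = no domain).
#' @export
adjacency_to_assignment <- function(adj) {
  if (!is_square_matrix(adj)) stop("adj must be a square matrix", call. = FALSE)
  if (!all(adj %in% c(0, 1))) stop("adj must be binary", call. = FALSE)
  if (any(adj != t(adj))) stop("adj must be symmetric", call. = FALSE)
  L <- nrow(adj)
  labels <- integer(L)
  assigned <- diag(adj) != 0 | rowSums(adj) > 0
  nxt <- 0L
  for (i in seq_len(L)) {
    if (!assigned[i] || labels[i] != 0L) next
    nxt <- nxt + 1L
    # breadth-first search for the connected component of i
    frontier <- i
    labels[i] <- nxt
    while (length(frontier) > 0) {
      nbrs <- which(colSums(adj[frontier, , drop = FALSE] != 0) > 0)
      nbrs <- nbrs[labels[nbrs] == 0L]
      labels[nbrs] <- nxt
      frontier <- nbrs
    }
  }
  # transitivity check: every pair inside a component must be connected
  for (d in seq_len(nxt)) {
    idx <- which(labels == d)
    if (length(idx) < 2) next
    block <- adj[idx, idx, drop = FALSE]
    diag(block) <- 1
    if (any(block == 0)) {
      bad <- which(block == 0, arr.ind = TRUE)[1, ]
      i <- idx[bad[1]]; j <- idx[bad[2]]
      k <- idx[which(adj[idx, i] != 0 & adj[idx, j] != 0)]
      k <- if (length(k)) k[1] else idx[1]
      stop(sprintf(paste0("adjacency violates transitivity: a[%d,%d] = ",
                          "a[%d,%d] = 1 but a[%d,%d] = 0"),
                   i, k, k, j, i, j), call. = FALSE)
    }
  }
  canonicalize_assignment(labels)
}
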