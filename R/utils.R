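#' @useDynLib domseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif plogis cor dist median predict
#' @importFrom utils read.delim write.table
NULL

# clip probabilities away from {0, 1} so logs stay finite
clip_prob <- function(p, eps) {
  pmin(pmax(p, eps), 1 - eps)
}

logit <- function(p) log(p) - log1p(-p)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_square_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && nrow(m) == ncol(m)
}

check_soft_adjacency <- function(soft, tol = 1e-8) {
  if (!is_square_matrix(soft)) {
    stop("soft adjacency must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(soft) || any(soft < 0) || any(soft > 1)) {
    stop("soft adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(soft - t(soft))) > tol) {
    stop("soft adjacency must be symmetric", call. = FALSE)
  }
  invisible(soft)
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# uniform point in a ball of given radius
random_in_ball <- function(radius) {
  random_unit_vector() * radius * runif(1)^(1 / 3)
}
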