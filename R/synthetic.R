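#' Specification for a synthetic multi-domain chain
#'
#' Synthetic chains are point-cloud Calpha traces with known domain labels,
#' built to satisfy the structural premise the segmenter relies on: contact
#' density is higher within domains than between them. Each domain is a
#' bounded random walk (step 3.8 Angstroms, confined to a ball of radius
#' \code{intra_spread}) around its own centroid; centroids are mutually at
#' least \code{centroid_separation} apart, so intra-domain distances are
#' typically much smaller than inter-domain ones. Linkers are extended walks
#' between domains; a discontinuous domain revisits its centroid after an
#' intervening domain. Secondary-structure segments (alternating helix and
#' strand runs inside domains, coil in linkers and tails) are synthesized
#' jointly with the domain labels.
#'
#' @param n_domains number of domains (>= 0; 0 gives an all-null chain of
#'   coil, only useful for edge-case testing).
#' @param domain_sizes explicit residue counts per domain, or NULL to sample
#'   each uniformly from \code{size_range}.
#' @param size_range range domain sizes are sampled from (default 30-120
#'   residues, typical of globular domains).
#' @param linker_range range of linker lengths between consecutive segments.
#' @param discontinuous_prob probability that a domain (other than the last)
#'   is split into two sequence segments with the next domain in between.
#' @param null_tail_prob probability of appending a disordered tail of
#'   unassigned (null) residues.
#' @param tail_range range of tail lengths.
#' @param centroid_separation minimum distance between domain centroids, in
#'   Angstroms; must exceed twice \code{intra_spread}.
#' @param intra_spread radius of the ball confining each domain's walk, in
#'   Angstroms.
#' @param seed optional integer seed carried with the spec.
#' @return A list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_domains = 2, domain_sizes = NULL,
                           size_range = c(30, 120), linker_range = c(3, 8),
                           discontinuous_prob = 0.2, null_tail_prob = 0.1,
                           tail_range = c(5, 15), centroid_separation = 25,
                           intra_spread = 8, seed = NULL) {
  stopifnot(n_domains >= 0, discontinuous_prob >= 0, discontinuous_prob <= 1,
            null_tail_prob >= 0, null_tail_prob <= 1,
            length(size_range) == 2, size_range[1] >= 5,
            length(linker_range) == 2, linker_range[1] >= 1)
  if (!is.null(domain_sizes)) {
    stopifnot(length(domain_sizes) == n_domains, all(domain_sizes >= 5))
  }
  if (centroid_separation <= 2 * intra_spread) {
    stop("centroid_separation must exceed 2 * intra_spread so that ",
         "intra-domain distances stay below inter-domain ones", call. = FALSE)
  }
  structure(list(n_domains = as.integer(n_domains),
                 domain_sizes = domain_sizes, size_range = size_range,
                 linker_range = linker_range,
                 discontinuous_prob = discontinuous_prob,
                 null_tail_prob = null_tail_prob, tail_range = tail_range,
                 centroid_separation = centroid_separation,
                 intra_spread = intra_spread, seed = seed),
            class = "synthetic_spec")
}

#' Generate one synthetic chain with known domain structure
#'
#' Fully deterministic given a seed (argument, or the spec's \code{seed}
#' field). See \code{\link{synthetic_spec}} for the generative model.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param seed integer seed; overrides \code{spec$seed}.
#' @return A list with elements \code{chain} (\code{protein_chain}),
#'   \code{assignment} (integer labels, 0 = null) and \code{ss}
#'   (\code{secondary_structure}).
#' @export
generate_chain <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_domains
  sizes <- spec$domain_sizes %||%
    sample(spec$size_range[1]:spec$size_range[2], n, replace = TRUE)
  sizes <- as.integer(sizes)

  segs <- plan_segments(n, sizes, spec$discontinuous_prob)
  centroids <- place_centroids(n, spec$centroid_separation)

  coords <- matrix(0, 0, 3)
  labels <- integer(0)
  ss <- character(0)
  dom_last <- vector("list", max(n, 1))  # walk state per domain
  prev_pt <- NULL
  for (s in seq_along(segs)) {
    d <- segs[[s]]$dom
    len <- segs[[s]]$len
    if (!is.null(prev_pt)) {
      # linker: extended walk from the previous segment toward the next
      # domain's centroid
      n_link <- sample(spec$linker_range[1]:spec$linker_range[2], 1)
      lk <- linker_walk(prev_pt, centroids[d, ], n_link)
      coords <- rbind(coords, lk)
      labels <- c(labels, rep(0L, n_link))
      ss <- c(ss, rep("C", n_link))
      prev_pt <- lk[nrow(lk), ]
    }
    start <- dom_last[[d]] %||%
      (centroids[d, ] + random_in_ball(spec$intra_spread / 2))
    w <- bounded_walk(len, centroids[d, ], start, spec$intra_spread)
    coords <- rbind(coords, w)
    labels <- c(labels, rep(d, len))
    ss <- c(ss, domain_ss_pattern(len))
    dom_last[[d]] <- w[nrow(w), ]
    prev_pt <- w[nrow(w), ]
  }
  if (n > 0 && runif(1) < spec$null_tail_prob) {
    n_tail <- sample(spec$tail_range[1]:spec$tail_range[2], 1)
    away <- prev_pt - centroids[segs[[length(segs)]]$dom, ]
    tail_target <- prev_pt + 100 * away / max(sqrt(sum(away^2)), 1e-8)
    tl <- linker_walk(prev_pt, tail_target, n_tail)
    coords <- rbind(coords, tl)
    labels <- c(labels, rep(0L, n_tail))
    ss <- c(ss, rep("C", n_tail))
  }
  if (nrow(coords) == 0) stop("spec generated an empty chain", call. = FALSE)
  aa <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               nrow(coords), replace = TRUE)
  list(chain = protein_chain(coords, aa = aa),
       assignment = canonicalize_assignment(labels),
       ss = secondary_structure(ss))
}

# sequence plan: one segment per domain, with marked domains split into two
# segments around the following domain
plan_segments <- function(n, sizes, discontinuous_prob) {
  if (n == 0) return(list(list(dom = 0L, len = 8L)))
  split <- runif(n) < discontinuous_prob
  split[n] <- FALSE
  segs <- list()
  carry <- NULL
  for (d in seq_len(n)) {
    if (split[d]) {
      s1 <- ceiling(sizes[d] / 2)
      segs <- c(segs, list(list(dom = d, len = as.integer(s1))))
      new_carry <- list(dom = d, len = as.integer(sizes[d] - s1))
    } else {
      segs <- c(segs, list(list(dom = d, len = sizes[d])))
      new_carry <- NULL
    }
    if (!is.null(carry)) {
      segs <- c(segs, list(carry))
      carry <- NULL
    }
    carry <- new_carry
  }
  if (!is.null(carry)) segs <- c(segs, list(carry))
  segs
}

place_centroids <- function(n, sep) {
  if (n == 0) return(matrix(0, 1, 3))
  cen <- matrix(0, n, 3)
  for (k in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in 1:500) {
      anchor <- cen[sample.int(k - 1, 1), ]
      cand <- anchor + random_unit_vector() * sep * runif(1, 1.05, 1.6)
      d2 <- rowSums((cen[seq_len(k - 1), , drop = FALSE] -
                       matrix(cand, k - 1, 3, byrow = TRUE))^2)
      if (all(d2 >= sep^2)) {
        cen[k, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place domain centroids at the requested ",
                      "separation", call. = FALSE)
  }
  cen
}

# random walk with fixed step, confined to a ball around the centroid
bounded_walk <- function(n, centroid, start, radius, step = 3.8) {
  pts <- matrix(0, n, 3)
  cur <- start
  if (sqrt(sum((cur - centroid)^2)) > radius) {
    cur <- centroid + random_in_ball(radius / 2)
  }
  pts[1, ] <- cur
  for (i in seq_len(n)[-1]) {
    ok <- FALSE
    for (try in 1:50) {
      cand <- cur + step * random_unit_vector()
      if (sum((cand - centroid)^2) <= radius^2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {  # step back toward the centroid
      to_c <- centroid - cur
      cand <- cur + step * to_c / max(sqrt(sum(to_c^2)), 1e-8)
    }
    pts[i, ] <- cand
    cur <- cand
  }
  pts
}

# extended walk from a point toward a target, with mild jitter
linker_walk <- function(from, target, n, step = 3.8) {
  pts <- matrix(0, n, 3)
  cur <- from
  for (i in seq_len(n)) {
    dir <- target - cur
    dir <- dir / max(sqrt(sum(dir^2)), 1e-8)
    d <- 0.8 * dir + 0.2 * random_unit_vector()
    d <- d / max(sqrt(sum(d^2)), 1e-8)
    cur <- cur + step * d
    pts[i, ] <- cur
  }
  pts
}

# plausible secondary structure inside one domain segment: alternating
# helix/strand runs separated by short coils
domain_ss_pattern <- function(len) {
  out <- character(0)
  next_type <- if (runif(1) < 0.5) "H" else "E"
  while (length(out) < len) {
    run_len <- if (next_type == "H") sample(6:9, 1) else sample(4:6, 1)
    out <- c(out, rep(next_type, run_len), rep("C", sample(2:3, 1)))
    next_type <- if (next_type == "H") "E" else "H"
  }
  out <- out[seq_len(len)]
  # truncation may leave a too-short trailing run
  r <- rle(out)
  k <- length(r$values)
  if ((r$values[k] == "H" && r$lengths[k] < 4) ||
      (r$values[k] == "E" && r$lengths[k] < 3)) {
    r$values[k] <- "C"
  }
  inverse.rle(r)
}

#' Blend an exact adjacency label with uniform noise
#'
#' Produces a stress-test soft adjacency: (1 - noise) * A + noise * U with
#' U i.i.d. uniform(0, 1), symmetrized by averaging with its transpose and
#' clipped to \[eps, 1 - eps\]. Noise 0 reproduces the clipped truth (the
#' perfect-predictor case); noise 1 is independent of the truth.
#'
#' @param truth binary L x L adjacency label.
#' @param noise blend weight in \[0, 1\].
#' @param seed optional integer seed.
#' @param eps probability clip.
#' @return Symmetric L x L soft adjacency matrix.
#' @export
corrupt_adjacency <- function(truth, noise, seed = NULL, eps = 1e-4) {
  stopifnot(noise >= 0, noise <= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(truth)
  U <- matrix(runif(L * L), L, L)
  M <- (1 - noise) * truth + noise * U
  M <- (M + t(M)) / 2
  clip_prob(M, eps)
}

#' Draw a random ground-truth domain assignment
#'
#' Samples an assignment directly (no geometry): K domains with sizes in
#' \code{size_range}, optional discontinuous domains, short null linkers
#' between segments and an optional null tail. Used for assigner validation
#' at scale.
#'
#' @param n_domains number of domains; default samples 1..6.
#' @param size_range domain size range (minimum 5).
#' @param discontinuous_prob probability a domain is split in two segments.
#' @param null_linker_prob probability a junction gets a short null linker.
#' @return Integer label vector (canonical form).
#' @export
random_assignment <- function(n_domains = sample.int(6, 1),
                              size_range = c(5, 35),
                              discontinuous_prob = 0.2,
                              null_linker_prob = 0.3) {
  stopifnot(size_range[1] >= 5)
  n <- n_domains
  sizes <- sample(size_range[1]:size_range[2], n, replace = TRUE)
  segs <- plan_segments(n, sizes, discontinuous_prob)
  labels <- integer(0)
  for (s in seq_along(segs)) {
    if (s > 1 && runif(1) < null_linker_prob) {
      labels <- c(labels, rep(0L, sample.int(4, 1)))
    }
    labels <- c(labels, rep(segs[[s]]$dom, segs[[s]]$len))
  }
  if (runif(1) < 0.15) labels <- c(labels, rep(0L, sample.int(8, 1)))
  canonicalize_assignment(labels)
}

#' Build a featurized synthetic dataset
#'
#' Generates chains, featurizes them and pairs each feature stack with its
#' binary adjacency label and a single/multi-domain class flag, ready for
#' \code{\link{train_segmenter}}. Secondary structure for the feature
#' channels is computed from the generated coordinates with
#' \code{\link{assign_secondary_structure}} — the same operator inference
#' applies to a structure file — so trained models see identically
#' distributed features at train and predict time. Set
#' \code{use_designed_ss = TRUE} to featurize against the generator's
#' designed secondary-structure labels instead.
#'
#' @param n_chains number of chains.
#' @param spec_sampler function returning a \code{\link{synthetic_spec}} for
#'   each chain; the default draws single-domain chains with probability 0.5
#'   and 2-3 domain chains otherwise, with domain sizes 20-40 residues.
#' @param seed integer seed controlling both the sampler and the chains.
#' @param config a \code{\link{feature_config}}.
#' @param use_designed_ss featurize with the generator's designed
#'   secondary-structure labels instead of the geometric assigner.
#' @return A list of items, each with elements \code{features},
#'   \code{label}, \code{flag} ("single" or "multi"), \code{assignment} and
#'   \code{chain}.
#' @export
make_dataset <- function(n_chains, spec_sampler = NULL, seed = NULL,
                         config = feature_config(),
                         use_designed_ss = FALSE) {
  stopifnot(n_chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  spec_sampler <- spec_sampler %||% default_spec_sampler
  lapply(seq_len(n_chains), function(i) {
    spec <- spec_sampler()
    g <- generate_chain(spec)  # no reseeding: draws from the current stream
    ss <- if (use_designed_ss) g$ss else NULL
    list(features = featurize(g$chain, ss, config = config),
         label = assignment_to_adjacency(g$assignment),
         flag = if (length(setdiff(unique(g$assignment), 0L)) <= 1) "single"
                else "multi",
         assignment = g$assignment,
         chain = g$chain)
  })
}

# compact chains: fast to featurize and train on while exercising
# multi-domain, discontinuous and null-tail structure
default_spec_sampler <- function() {
  n <- if (runif(1) < 0.5) 1L else if (runif(1) < 0.8) 2L else 3L
  synthetic_spec(n_domains = n, size_range = c(20, 40))
}
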