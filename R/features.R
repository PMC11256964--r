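#' Feature construction options
#'
#' @param dist_scale divisor applied to the Calpha distance channel, in
#'   Angstroms. The default 10 keeps typical inputs O(1), which stabilizes
#'   training; set to 1 for raw Angstrom values.
#' @return A list of class \code{feature_config}.
#' @export
feature_config <- function(dist_scale = 10) {
  stopifnot(is.numeric(dist_scale), length(dist_scale) == 1, dist_scale > 0)
  structure(list(dist_scale = dist_scale), class = "feature_config")
}

#' Pairwise Calpha distance matrix
#'
#' @param chain a \code{\link{protein_chain}}.
#' @return Symmetric L x L matrix of Euclidean Calpha distances in Angstroms
#'   with a zero diagonal.
#' @export
distance_matrix <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  d <- as.matrix(stats::dist(chain$ca_coords))
  dimnames(d) <- NULL
  d
}

#' Geometric secondary-structure assignment from the Calpha trace
#'
#' A distance-based assigner in the spirit of P-SEA: helices are recognized
#' by i,i+3 and i,i+4 Calpha distances near their canonical alpha-helical
#' values (about 5.1 and 6.2 Angstroms), strands by extended i,i+2 distances
#' (near 6.7-7.6 Angstroms) together with a large i,i+3 distance, which
#' excludes curved turns. Helix segments shorter than 4 residues and strand
#' segments shorter than 3 are suppressed. Chains shorter than 5 residues
#' and degenerate geometry yield an all-coil assignment.
#'
#' An externally computed assignment (e.g. STRIDE or DSSP output read with
#' \code{\link{read_ss_file}}) can be used anywhere a
#' \code{secondary_structure} object is accepted.
#'
#' @param chain a \code{\link{protein_chain}}.
#' @return An object of class \code{secondary_structure} with per-residue
#'   \code{labels} in {H, E, C} and a \code{segments} data frame.
#' @export
assign_secondary_structure <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  L <- length(chain)
  labels <- rep("C", L)
  if (L >= 5) {
    x <- chain$ca_coords
    dk <- function(k) {
      i <- seq_len(L - k)
      sqrt(rowSums((x[i + k, , drop = FALSE] - x[i, , drop = FALSE])^2))
    }
    d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
    i4 <- seq_len(L - 4)  # windows needing both d3[i] and d4[i]
    helix_win <- d3[i4] >= 4.4 & d3[i4] <= 5.8 & d4 >= 5.5 & d4 <= 6.9
    strand_win <- d2[seq_len(L - 3)] >= 5.9 & d2[seq_len(L - 3)] <= 7.8 &
      d3 >= 8.5 & d3 <= 11.8
    is_h <- rep(FALSE, L)
    for (i in which(helix_win)) is_h[i:(i + 4)] <- TRUE
    is_e <- rep(FALSE, L)
    for (i in which(strand_win)) is_e[i:(i + 2)] <- TRUE
    labels[is_e] <- "E"
    labels[is_h] <- "H"  # helix takes precedence
    labels <- enforce_min_runs(labels)
  }
  secondary_structure(labels)
}

# suppress H runs < 4 and E runs < 3
enforce_min_runs <- function(labels) {
  r <- rle(labels)
  drop <- (r$values == "H" & r$lengths < 4) | (r$values == "E" & r$lengths < 3)
  r$values[drop] <- "C"
  inverse.rle(r)
}

#' Construct a secondary-structure object from per-residue labels
#'
#' @param labels character vector of per-residue codes in {H, E, C}.
#' @return An object of class \code{secondary_structure}.
#' @export
secondary_structure <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("H", "E", "C"))) {
    stop("labels must be in {H, E, C}", call. = FALSE)
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "C"
  segments <- data.frame(type = r$values[keep], start = starts[keep],
                         end = ends[keep], stringsAsFactors = FALSE)
  structure(list(labels = labels, segments = segments),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d residues, %d segments (%s)\n",
              length(x$labels), nrow(x$segments),
              paste(table(factor(x$labels, c("H", "E", "C"))),
                    collapse = "/")))
  invisible(x)
}

#' Read a STRIDE or DSSP output file
#'
#' Extracts per-residue secondary-structure codes and maps them onto the
#' three-state alphabet used here: H/G/I become H, E/B (and DSSP's b) become
#' E, everything else C.
#'
#' @param path path to a STRIDE (\code{ASG} records) or classic DSSP output
#'   file.
#' @param format "stride" or "dssp".
#' @return An object of class \code{secondary_structure}.
#' @export
read_ss_file <- function(path, format = c("stride", "dssp")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "stride") {
    asg <- grep("^ASG ", lines, value = TRUE)
    if (length(asg) == 0) stop("no ASG records found in ", path, call. = FALSE)
    code <- toupper(substr(asg, 25, 25))
  } else {
    hdr <- grep("^  #  RESIDUE", lines)
    if (length(hdr) == 0) stop("no DSSP data header in ", path, call. = FALSE)
    body <- lines[(hdr[1] + 1):length(lines)]
    body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
    code <- toupper(substr(body, 17, 17))
  }
  labels <- ifelse(code %in% c("H", "G", "I"), "H",
                   ifelse(code %in% c("E", "B"), "E", "C"))
  secondary_structure(labels)
}

#' Secondary-structure feature channels
#'
#' Expands a secondary-structure assignment into the four 2D channels used
#' as network input: helix and strand segment co-membership matrices
#' (entry (i, j) is 1 when residues i and j lie in the same segment,
#' including i = j), and helix and strand boundary channels. The boundary
#' information is a per-residue vector b with +1 at the first residue of a
#' segment and -1 at the last; it is lifted to 2D by row broadcast
#' (channel\[i, j\] = b\[i\]), so the symmetrized network sees both
#' orientations.
#'
#' @param ss a \code{secondary_structure}.
#' @param L chain length.
#' @return An L x L x 4 array: helix co-membership, strand co-membership,
#'   helix boundary, strand boundary.
#' @export
ss_channels <- function(ss, L) {
  stopifnot(inherits(ss, "secondary_structure"))
  if (length(ss$labels) != L) {
    stop("secondary structure is inconsistent with chain length", call. = FALSE)
  }
  out <- array(0, dim = c(L, L, 4))
  seg <- ss$segments
  for (type in c("H", "E")) {
    co <- matrix(0, L, L)
    b <- numeric(L)
    rows <- seg[seg$type == type, , drop = FALSE]
    for (r in seq_len(nrow(rows))) {
      idx <- rows$start[r]:rows$end[r]
      co[idx, idx] <- 1
      b[rows$start[r]] <- 1
      b[rows$end[r]] <- -1
    }
    ch <- if (type == "H") 1L else 2L
    out[, , ch] <- co
    out[, , ch + 2L] <- matrix(b, L, L)  # row broadcast: value depends on i
  }
  out
}

#' Build the network input feature stack
#'
#' Stacks five L x L channels: the (scaled) Calpha distance matrix and the
#' four secondary-structure channels of \code{\link{ss_channels}}. All
#' channels depend only on pairwise geometry and per-residue secondary
#' structure, never on the coordinate frame, so the stack is exactly
#' invariant under rotations, translations and reflections of the input
#' coordinates.
#'
#' @param chain a \code{\link{protein_chain}}.
#' @param ss optional \code{secondary_structure}; computed with
#'   \code{\link{assign_secondary_structure}} when omitted.
#' @param config a \code{\link{feature_config}}.
#' @return An L x L x 5 array of class \code{feature_stack}.
#' @export
featurize <- function(chain, ss = NULL, config = feature_config()) {
  stopifnot(inherits(chain, "protein_chain"))
  ss <- ss %||% assign_secondary_structure(chain)
  L <- length(chain)
  x <- array(0, dim = c(L, L, 5))
  x[, , 1] <- distance_matrix(chain) / config$dist_scale
  x[, , 2:5] <- ss_channels(ss, L)
  class(x) <- c("feature_stack", class(x))
  x
}
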