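#' Construct a protein chain from Calpha coordinates
#'
#' The internal structural representation used throughout the package: an
#' ordered list of residues, each with an author residue number, a one-letter
#' amino-acid code and one Calpha coordinate. Residue indices used by all
#' matrices are dense positions 1..L in file order; author numbering is kept
#' only for chopping-string input/output.
#'
#' @param ca_coords numeric L x 3 matrix of Calpha coordinates in Angstroms.
#' @param resno integer vector of author residue numbers (default 1..L).
#' @param aa character vector of one-letter amino-acid codes (default "A").
#' @param chain_id single chain identifier (default "A").
#' @param plddt optional per-residue confidence in \[0, 100\].
#' @return An object of class \code{protein_chain}.
#' @export
protein_chain <- function(ca_coords, resno = NULL, aa = NULL,
                          chain_id = "A", plddt = NULL) {
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3) stop("ca_coords must have 3 columns", call. = FALSE)
  L <- nrow(ca_coords)
  if (L < 1) stop("a chain needs at least one residue", call. = FALSE)
  if (!all(is.finite(ca_coords))) {
    stop("all Calpha coordinates must be finite", call. = FALSE)
  }
  resno <- as.integer(resno %||% seq_len(L))
  aa <- as.character(aa %||% rep("A", L))
  if (length(resno) != L || length(aa) != L) {
    stop("resno and aa must have one entry per residue", call. = FALSE)
  }
  if (anyDuplicated(resno)) {
    stop("author residue numbers must be unique within a chain", call. = FALSE)
  }
  if (!is.null(plddt)) {
    plddt <- as.numeric(plddt)
    if (length(plddt) != L || any(plddt < 0 | plddt > 100, na.rm = TRUE)) {
      stop("plddt must be per-residue values in [0, 100]", call. = FALSE)
    }
  }
  dimnames(ca_coords) <- NULL
  structure(
    list(chain_id = as.character(chain_id)[1], resno = resno, aa = aa,
         ca_coords = ca_coords, plddt = plddt),
    class = "protein_chain"
  )
}

#' @export
length.protein_chain <- function(x) nrow(x$ca_coords)

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain> chain %s, %d residues (author %d..%d)\n",
              x$chain_id, length(x), min(x$resno), max(x$resno)))
  invisible(x)
}
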