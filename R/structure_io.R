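#' Read a protein structure into a chain representation
#'
#' Parses a PDB or mmCIF file (dispatching on file extension, with fallback
#' probing) and extracts the Calpha trace of one chain. Only ATOM records are
#' considered; HETATM is ignored. For residues with alternate locations the
#' highest-occupancy Calpha is kept. Multi-model files use the first model.
#' Residues lacking a Calpha atom are dropped with a warning. Irregular or
#' unknown residues are kept and mapped to the one-letter code "X".
#'
#' @param path path to a PDB or mmCIF file.
#' @param chain_id chain to extract; default: the first chain in the file.
#' @param plddt_from_b if TRUE, read the B-factor column as per-residue
#'   pLDDT (the convention of predicted-structure repositories).
#' @return A \code{\link{protein_chain}}.
#' @export
read_structure <- function(path, chain_id = NULL, plddt_from_b = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)
  parsed <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path, verbose = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("could not parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- parsed$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", path, call. = FALSE)
  chains <- unique(atoms$chain)
  if (is.null(chain_id)) {
    chain_id <- chains[1]
  } else if (!chain_id %in% chains) {
    stop("chain '", chain_id, "' not found in ", path,
         " (available: ", paste(chains, collapse = ", "), ")", call. = FALSE)
  }
  atoms <- atoms[atoms$chain == chain_id, , drop = FALSE]
  ins <- atoms$insert
  if (is.null(ins)) ins <- rep("", nrow(atoms))
  ins[is.na(ins)] <- ""
  res_key <- paste(atoms$resno, ins, sep = "|")
  res_order <- unique(res_key)

  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$resno, ifelse(is.na(ca$insert %||% ""), "",
                                   ca$insert %||% ""), sep = "|")
  # alternate locations: keep the highest-occupancy CA per residue
  occ <- ca$o
  if (is.null(occ) || all(is.na(occ))) occ <- rep(1, nrow(ca))
  occ[is.na(occ)] <- 1
  keep <- order(ca_key, -occ)
  ca <- ca[keep, , drop = FALSE]
  ca_key <- ca_key[keep]
  first <- !duplicated(ca_key)
  ca <- ca[first, , drop = FALSE]
  ca_key <- ca_key[first]
  # back to file order of residues
  m <- match(res_order, ca_key)
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    warning(sprintf("chain %s: dropped %d residue(s) without a Calpha atom",
                    chain_id, n_missing), call. = FALSE)
  }
  ca <- ca[m[!is.na(m)], , drop = FALSE]
  if (nrow(ca) == 0) {
    stop("chain ", chain_id, " has no residues with Calpha atoms",
         call. = FALSE)
  }
  aa <- suppressWarnings(bio3d::aa321(ca$resid))
  aa[is.na(aa) | !aa %in% LETTERS] <- "X"
  resno <- ca$resno
  if (anyDuplicated(resno)) {
    warning("duplicate author residue numbers (insertion codes); ",
            "renumbering residues 1..L", call. = FALSE)
    resno <- seq_len(nrow(ca))
  }
  plddt <- NULL
  if (plddt_from_b && !is.null(ca$b) && all(is.finite(ca$b)) &&
      all(ca$b >= 0 & ca$b <= 100)) {
    plddt <- ca$b
  }
  protein_chain(ca_coords = cbind(ca$x, ca$y, ca$z), resno = resno,
                aa = aa, chain_id = chain_id, plddt = plddt)
}

#' Write a Calpha-only structure file
#'
#' Emits a minimal PDB or mmCIF file containing one CA atom per residue.
#' Used to materialize synthetic chains as inputs for the end-to-end
#' pipeline and for fixtures.
#'
#' @param chain a \code{\link{protein_chain}}.
#' @param path output path.
#' @param format "pdb" or "cif".
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(chain, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  stopifnot(inherits(chain, "protein_chain"))
  L <- length(chain)
  res3 <- vapply(chain$aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || nchar(r) != 3) "UNK" else r
  }, character(1))
  b <- chain$plddt %||% rep(0, L)
  xyz <- chain$ca_coords
  if (format == "pdb") {
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(L), res3, substr(chain$chain_id, 1, 1), chain$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, b)
    lines <- c(lines, "END")
  } else {
    header <- c(
      "data_domseg",
      "#",
      "loop_",
      "_atom_site.group_PDB",
      "_atom_site.id",
      "_atom_site.type_symbol",
      "_atom_site.label_atom_id",
      "_atom_site.label_alt_id",
      "_atom_site.label_comp_id",
      "_atom_site.label_asym_id",
      "_atom_site.label_entity_id",
      "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x",
      "_atom_site.Cartn_y",
      "_atom_site.Cartn_z",
      "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv",
      "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id",
      "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id",
      "_atom_site.pdbx_PDB_model_num")
    body <- sprintf(
      "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d %s %s CA 1",
      seq_len(L), res3, chain$chain_id, seq_len(L),
      xyz[, 1], xyz[, 2], xyz[, 3], b, chain$resno, res3, chain$chain_id)
    lines <- c(header, body, "#")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Encode a domain assignment as a CATH-style chopping string
#'
#' Each domain becomes a comma-separated item; a discontinuous domain is one
#' or more author-numbered inclusive ranges joined by "_". Residues assigned
#' to no domain (label 0) are omitted. Domains are ordered by first residue.
#'
#' @param assignment integer vector of per-residue domain labels
#'   (0 = no domain).
#' @param chain the \code{\link{protein_chain}} the labels refer to, or an
#'   integer vector of author residue numbers.
#' @return A chopping string, e.g. \code{"1-100,101-150_201-250"}; \code{""}
#'   for an all-null assignment.
#' @export
format_chopping <- function(assignment, chain) {
  resno <- if (inherits(chain, "protein_chain")) chain$resno else
    as.integer(chain)
  labels <- as.integer(assignment)
  if (length(labels) != length(resno)) {
    stop("assignment length does not match chain length", call. = FALSE)
  }
  labels <- canonicalize_assignment(labels)
  doms <- setdiff(unique(labels), 0L)
  items <- vapply(doms, function(d) {
    idx <- which(labels == d)
    run_start <- idx[c(TRUE, diff(idx) != 1)]
    run_end <- idx[c(diff(idx) != 1, TRUE)]
    paste(sprintf("%d-%d", resno[run_start], resno[run_end]), collapse = "_")
  }, character(1))
  paste(items, collapse = ",")
}

#' Parse a chopping string into a domain assignment
#'
#' Inverse of \code{\link{format_chopping}} up to canonical relabelling of
#' domains (ids in order of first occurrence).
#'
#' @param text chopping string; \code{""} yields the all-null assignment.
#' @inheritParams format_chopping
#' @return Integer vector of per-residue domain labels (0 = no domain).
#' @export
parse_chopping <- function(text, chain) {
  resno <- if (inherits(chain, "protein_chain")) chain$resno else
    as.integer(chain)
  L <- length(resno)
  labels <- integer(L)
  text <- trimws(text %||% "")
  if (is.na(text) || text == "") return(labels)
  doms <- strsplit(text, ",", fixed = TRUE)[[1]]
  for (d in seq_along(doms)) {
    segs <- strsplit(trimws(doms[d]), "_", fixed = TRUE)[[1]]
    for (seg in segs) {
      m <- regmatches(seg, regexec("^(-?[0-9]+)-(-?[0-9]+)$", seg))[[1]]
      if (length(m) == 3) {
        a <- as.integer(m[2]); b <- as.integer(m[3])
      } else if (grepl("^-?[0-9]+$", seg)) {
        a <- b <- as.integer(seg)
      } else {
        stop("malformed chopping segment: '", seg, "'", call. = FALSE)
      }
      if (!a %in% resno || !b %in% resno) {
        stop("chopping segment ", seg, " refers to residue numbers ",
             "absent from the chain", call. = FALSE)
      }
      idx <- which(resno >= a & resno <= b)
      if (length(idx) == 0) {
        stop("chopping segment ", seg, " matches no residues", call. = FALSE)
      }
      if (any(labels[idx] != 0L)) {
        stop("overlapping ranges in chopping string at segment '", seg, "'",
             call. = FALSE)
      }
      labels[idx] <- d
    }
  }
  canonicalize_assignment(labels)
}
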