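# ---------------------------------------------------------------------------
# PDB input / output
#
# Reading goes through bio3d; this module extracts per-residue C-alpha
# coordinates and side-chain centroids (geometric centre of the non-hydrogen
# side-chain atoms), groups residues into contiguous fragments, and writes
# fitted models back out as PDB or XYZ.
# ---------------------------------------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# maximum C-alpha - C-alpha distance still considered bonded; flags chain
# breaks while tolerating CIS-PRO (~2.9 A) and trans (~3.8 A) linkages
CHAIN_BREAK_DIST <- 4.5

pdb_source_to_file <- function(source) {
  if (length(source) > 1L || any(grepl("\n", source))) {
    f <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(source, "\n")), f)
    return(f)
  }
  source <- as.character(source)
  if (file.exists(source)) return(source)
  # a bare 4-character identifier is handed to bio3d, which fetches it;
  # never exercised by tests (no network assumed)
  if (grepl("^[0-9][A-Za-z0-9]{3}$", source)) return(source)
  lf_not_found(sprintf("PDB file '%s' not found", source))
}

#' Extract a fitting target from a PDB file
#'
#' Reads a PDB file (via bio3d), keeps the first MODEL and alternate
#' location ' '/'A', and extracts per residue the C-alpha coordinate and, in
#' side-chain mode, the geometric centre of the non-hydrogen side-chain
#' atoms (backbone atoms N/CA/C/O/OXT excluded). Glycine, having no heavy
#' side-chain atoms, uses its C-alpha coordinate as the side-chain target.
#' Residues are grouped into contiguous fragments; a new fragment starts at
#' a gap in residue numbering or when consecutive C-alpha atoms are more
#' than 4.5 A apart.
#'
#' @param source Path to a PDB file, PDB-format text (with newlines), or a
#'   4-character PDB identifier (fetched by bio3d; requires network).
#' @param chain Chain identifier; default: first chain in the file.
#' @param mode `"backbone"` or `"side_chain"`.
#' @return A `target_structure`. Errors: missing chain (not-found), no
#'   residues with C-alpha (empty-structure), C-alpha-only input in
#'   side-chain mode (unsupported-input).
#' @export
parse_pdb <- function(source, chain = NULL, mode = c("backbone", "side_chain")) {
  mode <- match.arg(mode)
  file <- pdb_source_to_file(source)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)),
    error = function(e) lf_parse_error(paste("cannot parse PDB input:",
                                             conditionMessage(e)))
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  atoms$chain[is.na(atoms$chain)] <- " "
  chains <- unique(atoms$chain)
  if (!length(chains)) lf_abort("no ATOM records in input",
                                "latticefit_empty_structure")
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains)
    lf_not_found(sprintf("chain '%s' not found (available: %s)", chain,
                         paste(chains, collapse = ", ")))
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", " ", "A"), ,
                 drop = FALSE]
  atoms$insert[is.na(atoms$insert)] <- ""

  res_key <- paste(atoms$resno, atoms$insert)
  res_order <- unique(res_key)
  is_h <- if ("elesy" %in% names(atoms)) {
    hy <- atoms$elesy %in% c("H", "D")
    hy[is.na(atoms$elesy) | atoms$elesy == ""] <-
      grepl("^[0-9]*[HD]", atoms$elety[is.na(atoms$elesy) | atoms$elesy == ""])
    hy
  } else grepl("^[0-9]*[HD]", atoms$elety)

  residues <- list()
  for (rk in res_order) {
    rows <- atoms[res_key == rk, , drop = FALSE]
    rh <- is_h[res_key == rk]
    ca <- rows[rows$elety == "CA" & !rh, , drop = FALSE]
    if (nrow(ca) == 0L) next                     # unresolved C-alpha: gap
    ca <- ca[1, ]
    sc <- rows[!(rows$elety %in% BACKBONE_ATOMS) & !rh, , drop = FALSE]
    residues[[length(residues) + 1L]] <- list(
      resno = ca$resno, insert = ca$insert, resname = ca$resid,
      ca = c(ca$x, ca$y, ca$z),
      centroid = if (nrow(sc)) colMeans(cbind(sc$x, sc$y, sc$z))
                 else c(ca$x, ca$y, ca$z),
      has_sc = nrow(sc) > 0L
    )
  }
  if (!length(residues))
    lf_abort(sprintf("chain '%s' contains no residues with C-alpha atoms",
                     chain), "latticefit_empty_structure")

  if (mode == "side_chain") {
    non_gly <- vapply(residues, function(r) r$resname != "GLY", TRUE)
    with_sc <- vapply(residues, function(r) r$has_sc, TRUE)
    if (any(non_gly) && !any(with_sc[non_gly]))
      lf_unsupported_input(
        "input appears to be C-alpha-only: no residue has side-chain atoms")
  }

  # split into contiguous fragments
  frag_idx <- integer(length(residues))
  frag_idx[1] <- 1L
  for (i in seq_along(residues)[-1]) {
    a <- residues[[i - 1]]; b <- residues[[i]]
    consecutive <- (b$resno == a$resno + 1L) ||
      (b$resno == a$resno && b$insert != a$insert)
    close_enough <- sqrt(sum((b$ca - a$ca)^2)) <= CHAIN_BREAK_DIST
    frag_idx[i] <- frag_idx[i - 1] + as.integer(!(consecutive && close_enough))
  }
  fragments <- lapply(split(seq_along(residues), frag_idx), function(ii) {
    rs <- residues[ii]
    target_fragment(
      Pb = do.call(rbind, lapply(rs, `[[`, "ca")),
      Ps = if (mode == "side_chain")
        do.call(rbind, lapply(rs, `[[`, "centroid")),
      resno = vapply(rs, `[[`, 0L, "resno"),
      resname = vapply(rs, `[[`, "", "resname"),
      insert = vapply(rs, `[[`, "", "insert")
    )
  })
  names(fragments) <- NULL
  target_structure(fragments, mode = mode, chain = chain,
                   source = if (is.character(source) && length(source) == 1L &&
                                !grepl("\n", source)) source else "text")
}

collect_fit_results <- function(fit) {
  if (inherits(fit, "fit_result")) return(list(fit))
  if (inherits(fit, "lattice_fit_set")) {
    if (!length(fit$results)) lf_domain_error("fit set contains no results")
    return(unname(fit$results))
  }
  lf_domain_error("expected a fit_result or lattice_fit_set")
}

pdb_atom_line <- function(serial, name, resname, chain, resno, icode, xyz,
                          element) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, " ", resname, chain, resno,
          if (nzchar(icode)) icode else " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Write a fitted model as PDB
#'
#' One ATOM record per backbone monomer (atom name CA) and, for side-chain
#' models, one per side-chain monomer (atom name CB), carrying the original
#' residue names and numbers, with the superposed real-space coordinates in
#' Angstrom. Fragments are separated by TER records.
#'
#' @param fit A `fit_result` or `lattice_fit_set`.
#' @param file Output path; if `NULL`, the PDB text is returned as a
#'   character vector.
#' @param chain Chain identifier to write (default `"A"`).
#' @param conect Also write CONECT records for backbone and side-chain
#'   bonds.
#' @return The PDB lines (invisibly when `file` is given).
#' @export
write_model_pdb <- function(fit, file = NULL, chain = "A", conect = FALSE) {
  results <- collect_fit_results(fit)
  lines <- character()
  conect_lines <- character()
  serial <- 0L
  for (res in results) {
    frag <- res$target
    l <- fragment_length(frag)
    side <- res$mode == "side_chain"
    prev_ca <- NA_integer_
    for (i in seq_len(l)) {
      serial <- serial + 1L
      ca_serial <- serial
      lines <- c(lines, pdb_atom_line(
        serial, " CA ", frag$resname[i], chain, frag$resno[i],
        frag$insert[i], res$coords$backbone[i, ], " C"))
      if (side) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(
          serial, " CB ", frag$resname[i], chain, frag$resno[i],
          frag$insert[i], res$coords$side_chains[i, ], " C"))
        if (conect)
          conect_lines <- c(conect_lines,
                            sprintf("CONECT%5d%5d", ca_serial, serial))
      }
      if (conect && !is.na(prev_ca))
        conect_lines <- c(conect_lines,
                          sprintf("CONECT%5d%5d", prev_ca, ca_serial))
      prev_ca <- ca_serial
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, conect_lines, "END")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Write a fitted model as XYZ
#'
#' Standard XYZ: a count line, a comment line, then one element-labelled
#' coordinate line per monomer (backbone first, then the side-chain monomer
#' of each residue, per residue).
#'
#' @param fit A `fit_result` or `lattice_fit_set`.
#' @param file Output path; if `NULL`, lines are returned.
#' @param comment Comment line content.
#' @return The XYZ lines (invisibly when `file` is given).
#' @export
write_xyz <- function(fit, file = NULL, comment = NULL) {
  results <- collect_fit_results(fit)
  coord_lines <- character()
  n <- 0L
  for (res in results) {
    l <- fragment_length(res$target)
    side <- res$mode == "side_chain"
    for (i in seq_len(l)) {
      coord_lines <- c(coord_lines, sprintf("C %12.6f %12.6f %12.6f",
                                            res$coords$backbone[i, 1],
                                            res$coords$backbone[i, 2],
                                            res$coords$backbone[i, 3]))
      n <- n + 1L
      if (side) {
        coord_lines <- c(coord_lines, sprintf("C %12.6f %12.6f %12.6f",
                                              res$coords$side_chains[i, 1],
                                              res$coords$side_chains[i, 2],
                                              res$coords$side_chains[i, 3]))
        n <- n + 1L
      }
    }
  }
  if (n == 0L) lf_domain_error("cannot write an empty model")
  if (is.null(comment))
    comment <- sprintf("lattice protein model, %d monomers", n)
  lines <- c(as.character(n), comment, coord_lines)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
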