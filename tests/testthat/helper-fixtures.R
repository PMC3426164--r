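# Shared helpers: independent brute-force checkers and tiny fixtures built
# in code. Nothing here calls the code paths it is used to verify.

ALL_LATTICES <- c("sqr", "cub", "fcc", "210")

# independent validity checker: direct pairwise comparison against the
# definition (connectivity via the neighbour list, self-avoidance by
# comparing every node pair)
brute_force_valid <- function(bb, sc, lat) {
  nb <- make_lattice(lat)$neighbors
  in_nb <- function(v) any(apply(nb, 1, function(w) all(w == v)))
  l <- nrow(bb)
  if (l > 1) {
    for (i in seq_len(l - 1)) {
      if (!in_nb(bb[i + 1, ] - bb[i, ])) return(FALSE)
    }
  }
  if (!is.null(sc)) {
    for (i in seq_len(l)) {
      if (!in_nb(bb[i, ] - sc[i, ])) return(FALSE)
    }
  }
  nodes <- rbind(bb, sc)
  for (i in seq_len(nrow(nodes) - 1)) {
    for (j in (i + 1):nrow(nodes)) {
      if (all(nodes[i, ] == nodes[j, ])) return(FALSE)
    }
  }
  TRUE
}

# a square-lattice self-avoiding walk whose end node is enclosed by the
# walk itself; extending it past 8 residues is impossible for a greedy
# (n_keep = 1) dRMSD fit because only the generating path scores zero
trapped_sqr_target <- function(extra = 1) {
  path <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 2, 0),
    c(0, 2, 0), c(-1, 2, 0), c(-1, 1, 0), c(0, 1, 0)
  )
  pts <- path * 3.8
  for (i in seq_len(extra)) {
    pts <- rbind(pts, c(0.5 + 0.1 * i, 0.5, 0) * 3.8)
  }
  target_fragment(pts)
}

random_rigid_motion <- function(X) {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  sweep(X %*% t(Q), 2, runif(3, -15, 15), "+")
}

# minimal but complete PDB text for a peptide: full backbone plus the given
# side-chain atoms per residue
peptide_pdb_lines <- function(resnames, ca, side_atoms = NULL, chain = "A",
                              resno = seq_along(resnames)) {
  fmt <- function(serial, name, elesy, rn, no, xyz) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, rn, chain, no, xyz[1], xyz[2], xyz[3], 1, 0, elesy)
  }
  lines <- character(); serial <- 0
  for (i in seq_along(resnames)) {
    base <- ca[i, ]
    for (at in list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"))) {
      serial <- serial + 1
      off <- switch(at[1], N = c(-1.2, 0.3, 0), CA = c(0, 0, 0),
                    C = c(1.2, 0.4, 0), O = c(1.4, 1.5, 0))
      lines <- c(lines, fmt(serial, at[1], at[2], resnames[i], resno[i],
                            base + off))
    }
    if (!is.null(side_atoms) && !is.null(side_atoms[[i]])) {
      sa <- side_atoms[[i]]
      for (k in seq_len(nrow(sa))) {
        serial <- serial + 1
        lines <- c(lines, fmt(serial, rownames(sa)[k], substr(rownames(sa)[k], 1, 1),
                              resnames[i], resno[i], sa[k, ]))
      }
    }
  }
  c(lines, "TER", "END")
}
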