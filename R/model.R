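# ---------------------------------------------------------------------------
# Lattice protein models
#
# A model of length l is a backbone node sequence and, in side-chain mode,
# one side-chain node per residue (two on-lattice monomers per amino acid).
# Validity means backbone connectivity, side-chain connectivity and
# self-avoidance over all occupied nodes.
# ---------------------------------------------------------------------------

as_node_matrix <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.vector(x) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  x <- as.matrix(x)
  if (ncol(x) != 3L) lf_domain_error(sprintf("%s must be an n x 3 matrix", what))
  if (any(x != round(x))) lf_domain_error(sprintf("%s must be integer lattice nodes", what))
  storage.mode(x) <- "integer"
  dimnames(x) <- NULL
  x
}

#' Construct a lattice protein model
#'
#' @param backbone Integer matrix (l x 3) of backbone lattice nodes.
#' @param side_chains Optional integer matrix (l x 3) of side-chain nodes;
#'   side-chain presence is all-or-none per model.
#' @param lattice Lattice name or `lattice_spec`.
#' @param check If `TRUE` (default), reject invalid structures.
#' @return Object of class `lattice_model`.
#' @export
lattice_model <- function(backbone, side_chains = NULL, lattice, check = TRUE) {
  lat <- make_lattice(lattice)
  bb <- as_node_matrix(backbone, "backbone")
  if (nrow(bb) < 1L) lf_domain_error("model must contain at least one residue")
  sc <- as_node_matrix(side_chains, "side_chains")
  if (!is.null(sc) && nrow(sc) != nrow(bb))
    lf_domain_error("side_chains must have one node per backbone residue")
  m <- structure(list(backbone = bb, side_chains = sc, lattice = lat),
                 class = "lattice_model")
  if (check) {
    rep <- validate_model(m)
    if (!rep$valid) lf_invalid_structure(rep$message)
  }
  m
}

model_length <- function(m) nrow(m$backbone)

has_side_chains <- function(m) !is.null(m$side_chains)

# flattened node matrix: backbone rows then side-chain rows
model_nodes <- function(m) rbind(m$backbone, m$side_chains)

#' Validate a lattice model
#'
#' Checks, in order: backbone connectivity (consecutive nodes differ by a
#' neighbour vector), side-chain connectivity (each side-chain node adjacent
#' to its backbone node), and self-avoidance (all occupied nodes distinct).
#' Reports the first violation rather than raising an error.
#'
#' @param m A `lattice_model`.
#' @return List with `valid` (logical), and when invalid: `type` (one of
#'   `"backbone_break"`, `"side_chain_break"`, `"collision"`), `indices`
#'   (violating positions, in backbone-then-side-chain flattened order for
#'   collisions) and `message`.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "lattice_model"))
  lat <- m$lattice
  nb_key <- paste(lat$neighbors[, 1], lat$neighbors[, 2], lat$neighbors[, 3])
  vkey <- function(v) paste(v[, 1], v[, 2], v[, 3])
  l <- model_length(m)
  if (l > 1L) {
    steps <- diff(m$backbone)
    ok <- vkey(steps) %in% nb_key
    if (!all(ok)) {
      i <- which(!ok)[1]
      return(list(valid = FALSE, type = "backbone_break", indices = i,
                  message = sprintf("backbone break at step %d", i)))
    }
  }
  if (has_side_chains(m)) {
    sc <- m$backbone - m$side_chains
    ok <- vkey(sc) %in% nb_key
    if (!all(ok)) {
      i <- which(!ok)[1]
      return(list(valid = FALSE, type = "side_chain_break", indices = i,
                  message = sprintf("side-chain break at residue %d", i)))
    }
  }
  nodes <- model_nodes(m)
  keys <- vkey(nodes)
  if (anyDuplicated(keys)) {
    j <- which(duplicated(keys))[1]
    i <- which(keys == keys[j])[1]
    return(list(valid = FALSE, type = "collision", indices = c(i, j),
                message = sprintf("node collision at positions (%d,%d)", i, j)))
  }
  list(valid = TRUE, type = NULL, indices = NULL, message = "valid")
}

#' Convert a lattice model to real-space coordinates
#'
#' Nodes are multiplied by `bond_length / |v|` so every covalent bond
#' (backbone step and backbone-side-chain bond) has length `bond_length`.
#'
#' @param m A valid `lattice_model`.
#' @param bond_length Bond length in Angstrom (default: the lattice scale,
#'   3.8 A).
#' @return Object of class `real_model`: `backbone` and `side_chains`
#'   coordinate matrices in Angstrom plus `bond_length`.
#' @export
to_real <- function(m, bond_length = NULL) {
  stopifnot(inherits(m, "lattice_model"))
  rep <- validate_model(m)
  if (!rep$valid) lf_invalid_structure(rep$message)
  if (is.null(bond_length)) bond_length <- m$lattice$scale
  if (bond_length <= 0) lf_domain_error("bond_length must be positive")
  u <- lattice_unit(m$lattice, bond_length)
  structure(list(backbone = m$backbone * u,
                 side_chains = if (has_side_chains(m)) m$side_chains * u,
                 bond_length = bond_length),
            class = "real_model")
}

# real-space points in backbone-then-side-chain order (the order used by
# the metrics module for both targets and models)
real_points <- function(x) {
  if (inherits(x, "real_model")) rbind(x$backbone, x$side_chains)
  else if (is.matrix(x)) x
  else lf_domain_error("expected a real_model or coordinate matrix")
}

#' Canonical form of a lattice model under lattice symmetry
#'
#' Applies every point-group transform, translates the image so its first
#' backbone node is at the origin, flattens the node sequence (backbone then
#' side chains) and returns the lexicographically smallest image. Two models
#' related by lattice symmetry and/or translation share one canonical form;
#' the map is idempotent.
#'
#' @param m A valid `lattice_model`.
#' @param group Optional precomputed `point_group` of the model's lattice.
#' @return A `lattice_model` in canonical form.
#' @export
canonical_form <- function(m, group = NULL) {
  stopifnot(inherits(m, "lattice_model"))
  if (is.null(group)) group <- point_group(m$lattice)
  l <- model_length(m)
  nodes <- model_nodes(m)
  best <- NULL
  best_key <- NULL
  for (g in group) {
    img <- nodes %*% t(g)
    img <- sweep(img, 2, img[1, ])
    key <- as.integer(t(img))
    if (is.null(best_key) || lex_less(key, best_key)) {
      best <- img
      best_key <- key
    }
  }
  storage.mode(best) <- "integer"
  lattice_model(best[seq_len(l), , drop = FALSE],
                if (has_side_chains(m)) best[l + seq_len(l), , drop = FALSE],
                m$lattice, check = FALSE)
}

# lexicographic comparison of equal-length integer vectors
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  length(i) > 0L && d[i[1]] < 0L
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("Lattice model on '%s': %d residues, %s\n", x$lattice$name,
              model_length(x),
              if (has_side_chains(x)) "backbone + side chains" else "backbone only"))
  invisible(x)
}
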