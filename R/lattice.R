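#' @useDynLib latticefit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate dist rnorm runif setNames
#' @importFrom utils head write.csv
NULL

# ---------------------------------------------------------------------------
# Lattice definitions
#
# A lattice is described by its neighbourhood N: an ordered set of integer
# vectors of equal (unscaled) length, closed under negation.  All positions a
# chain may occupy are integer combinations of these vectors.  One neighbour
# vector is assigned a physical length (3.8 Angstrom by default, the mean
# C-alpha - C-alpha distance), so that fitted models report RMSDs in Angstrom.
# ---------------------------------------------------------------------------

# all distinct signed permutations of a base integer 3-vector
signed_permutations <- function(base) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1L, -1L), c(1L, -1L), c(1L, -1L)))
  out <- list()
  for (p in perms) {
    v <- base[p]
    for (s in seq_len(nrow(signs))) {
      out[[length(out) + 1L]] <- as.integer(v * signs[s, ])
    }
  }
  m <- unique(do.call(rbind, out))
  m[rowSums(m != 0L) > 0L, , drop = FALSE]
}

# canonical ordering of neighbour vectors: lexicographic on (x, y, z)
order_neighbors <- function(m) {
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

lattice_registry <- new.env(parent = emptyenv())

#' Register a lattice by its neighbourhood vectors
#'
#' The registry is open: any lattice can be added by supplying its neighbour
#' vectors. Vectors must be nonzero integer 3-vectors of identical Euclidean
#' length, with the set closed under negation.
#'
#' @param name Lattice identifier (stored lower-case).
#' @param neighbors Integer matrix with one neighbour vector per row
#'   (2D lattices use z = 0).
#' @param scale Physical length, in Angstrom, assigned to one neighbour
#'   vector (default 3.8, the mean consecutive C-alpha distance).
#' @return The registered `lattice_spec`, invisibly.
#' @export
register_lattice <- function(name, neighbors, scale = 3.8) {
  neighbors <- as.matrix(neighbors)
  storage.mode(neighbors) <- "integer"
  if (ncol(neighbors) != 3L) lf_domain_error("neighbor vectors must be 3-vectors")
  if (any(rowSums(neighbors != 0L) == 0L)) lf_domain_error("zero neighbor vector")
  if (anyDuplicated(neighbors)) lf_domain_error("duplicate neighbor vectors")
  len2 <- rowSums(neighbors^2)
  if (length(unique(len2)) != 1L)
    lf_domain_error("neighbor vectors must have identical length")
  # closure under negation
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  if (!all(key(-neighbors) %in% key(neighbors)))
    lf_domain_error("neighborhood not closed under negation")
  neighbors <- order_neighbors(neighbors)
  spec <- structure(
    list(name = tolower(name), neighbors = neighbors, scale = scale),
    class = "lattice_spec"
  )
  assign(tolower(name), spec, envir = lattice_registry)
  invisible(spec)
}

register_builtin_lattices <- function() {
  register_lattice("sqr", rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                                c(0L, 1L, 0L), c(0L, -1L, 0L)))
  register_lattice("cub", rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L),
                                c(0L, 1L, 0L), c(0L, -1L, 0L),
                                c(0L, 0L, 1L), c(0L, 0L, -1L)))
  register_lattice("fcc", signed_permutations(c(1L, 1L, 0L)))
  register_lattice("210", signed_permutations(c(2L, 1L, 0L)))
}

#' Names of registered lattices
#' @return Character vector of lattice identifiers.
#' @export
lattice_names <- function() sort(ls(lattice_registry))

#' Retrieve a lattice specification
#'
#' Built-in lattices: `"sqr"` (2D square, 4 neighbours), `"cub"` (3D cubic,
#' 6 neighbours), `"fcc"` (face-centred cubic, 12 neighbours: signed
#' permutations of (1,1,0)) and `"210"` (knight's walk, 24 neighbours: signed
#' permutations of (2,1,0)). Names are case-insensitive.
#'
#' @param name Lattice identifier, or a `lattice_spec` (returned unchanged).
#' @return A `lattice_spec`: list with `name`, integer `neighbors` matrix in
#'   canonical (lexicographic) order, and `scale` in Angstrom.
#' @examples
#' nrow(make_lattice("fcc")$neighbors)  # 12
#' @export
make_lattice <- function(name) {
  if (inherits(name, "lattice_spec")) return(name)
  key <- tolower(as.character(name)[1])
  if (!exists(key, envir = lattice_registry))
    lf_unsupported_lattice(sprintf(
      "unknown lattice '%s' (available: %s)", name,
      paste(lattice_names(), collapse = ", ")))
  get(key, envir = lattice_registry)
}

lattice_is_2d <- function(lat) all(lat$neighbors[, 3] == 0L)

# physical length of one lattice unit when a neighbour vector spans `bond` A
lattice_unit <- function(lat, bond_length = lat$scale) {
  bond_length / sqrt(sum(lat$neighbors[1, ]^2))
}

#' Neighbour vectors scaled to a physical bond length
#'
#' @param lat Lattice name or `lattice_spec`.
#' @param bond_length Target length in Angstrom for every neighbour vector.
#' @return Numeric matrix; every row has Euclidean norm `bond_length`.
#' @export
scaled_neighbors <- function(lat, bond_length = NULL) {
  lat <- make_lattice(lat)
  if (is.null(bond_length)) bond_length <- lat$scale
  if (!is.numeric(bond_length) || length(bond_length) != 1L || bond_length <= 0)
    lf_domain_error("bond_length must be a positive number")
  lat$neighbors * lattice_unit(lat, bond_length)
}

#' Point-group symmetries of a lattice
#'
#' Brute-forces all 48 signed-permutation matrices (the full cubic group) and
#' keeps those mapping the neighbourhood onto itself as a set. For 2D
#' lattices (all z = 0) the group is restricted to matrices fixing the z axis,
#' giving the 8-element dihedral group for the square lattice.
#'
#' @param lat Lattice name or `lattice_spec`.
#' @return Object of class `point_group`: list of integer 3x3 matrices,
#'   containing the identity and closed under composition and inverse.
#' @export
point_group <- function(lat) {
  lat <- make_lattice(lat)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  nb_key <- sort(key(lat$neighbors))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1L, -1L), c(1L, -1L), c(1L, -1L)))
  twod <- lattice_is_2d(lat)
  mats <- list()
  for (p in perms) {
    for (s in seq_len(nrow(signs))) {
      g <- matrix(0L, 3, 3)
      for (i in 1:3) g[i, p[i]] <- signs[s, i]
      if (twod && !(g[3, 3] == 1L && all(g[3, 1:2] == 0L) && all(g[1:2, 3] == 0L)))
        next
      img <- lat$neighbors %*% t(g)
      if (identical(sort(key(img)), nb_key)) mats[[length(mats) + 1L]] <- g
    }
  }
  structure(mats, class = "point_group")
}

# ---------------------------------------------------------------------------
# Absolute move strings
#
# A lattice structure is encoded as one token per backbone step (and, for
# side-chain models, one token per backbone->side-chain bond, reported as a
# separate string).  Tokens are letters A, B, C, ... assigned to the
# neighbour vectors in their canonical lexicographic order.
# ---------------------------------------------------------------------------

#' Move-string alphabet of a lattice
#'
#' @param lat Lattice name or `lattice_spec`.
#' @return Named character vector mapping `"x y z"` neighbour keys to tokens.
#' @export
move_alphabet <- function(lat) {
  lat <- make_lattice(lat)
  n <- nrow(lat$neighbors)
  setNames(LETTERS[seq_len(n)],
           paste(lat$neighbors[, 1], lat$neighbors[, 2], lat$neighbors[, 3]))
}

#' Encode a lattice model as absolute move strings
#'
#' @param model A `lattice_model`.
#' @return List with `backbone` (one token per backbone step; empty string
#'   for a single-residue chain) and `side` (one token per backbone to
#'   side-chain bond, `NULL` for backbone-only models). Decoding the strings
#'   reproduces the model up to translation.
#' @export
encode_move_string <- function(model) {
  stopifnot(inherits(model, "lattice_model"))
  lat <- model$lattice
  alpha <- move_alphabet(lat)
  step_token <- function(v) {
    k <- paste(v[1], v[2], v[3])
    tok <- alpha[k]
    if (is.na(tok))
      lf_invalid_structure(sprintf("step (%s) is not a neighbor vector of lattice '%s'",
                                   paste(v, collapse = ","), lat$name))
    tok
  }
  l <- nrow(model$backbone)
  bb <- if (l < 2L) "" else {
    steps <- diff(model$backbone)
    paste(vapply(seq_len(nrow(steps)), function(i) step_token(steps[i, ]), ""),
          collapse = "")
  }
  side <- NULL
  if (!is.null(model$side_chains)) {
    sc <- model$side_chains - model$backbone
    side <- paste(vapply(seq_len(l), function(i) step_token(sc[i, ]), ""),
                  collapse = "")
  }
  list(backbone = bb, side = side)
}

#' Decode absolute move strings into a lattice model
#'
#' The decoded structure is anchored with its first backbone node at the
#' origin. Self-avoidance and connectivity are verified; a self-colliding
#' path raises an invalid-structure error (distinct from a parse error for
#' unknown tokens).
#'
#' @param backbone Backbone move string (may be `""` for a single node).
#' @param lat Lattice name or `lattice_spec`.
#' @param side Optional side-chain move string, one token per residue.
#' @return A valid `lattice_model`.
#' @export
decode_move_string <- function(backbone, lat, side = NULL) {
  lat <- make_lattice(lat)
  alpha <- move_alphabet(lat)
  tok2vec <- function(s, what) {
    if (nchar(s) == 0L) return(matrix(integer(), 0L, 3L))
    toks <- strsplit(s, "")[[1]]
    bad <- setdiff(toks, alpha)
    if (length(bad))
      lf_parse_error(sprintf("unknown %s move token(s): %s", what,
                             paste(unique(bad), collapse = ", ")))
    idx <- match(toks, alpha)
    lat$neighbors[idx, , drop = FALSE]
  }
  steps <- tok2vec(backbone, "backbone")
  bb <- apply(rbind(c(0L, 0L, 0L), steps), 2, cumsum)
  bb <- matrix(as.integer(bb), ncol = 3L)
  sc <- NULL
  if (!is.null(side)) {
    sv <- tok2vec(side, "side-chain")
    if (nrow(sv) != nrow(bb))
      lf_parse_error("side-chain string length must equal number of residues")
    sc <- bb + sv
  }
  m <- lattice_model(bb, sc, lat, check = FALSE)
  rep <- validate_model(m)
  if (!rep$valid)
    lf_invalid_structure(paste("decoded path is invalid:", rep$message))
  m
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Lattice '%s': %d neighbor vectors, scale %.3f A/bond\n",
              x$name, nrow(x$neighbors), x$scale))
  invisible(x)
}
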