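# ---------------------------------------------------------------------------
# Fitting targets
#
# A target structure is an ordered list of contiguous fragments; each
# fragment carries per-residue C-alpha coordinates (P^b) and, in side-chain
# mode, side-chain centroids (P^s), plus the original residue bookkeeping.
# ---------------------------------------------------------------------------

#' Construct a target fragment
#'
#' @param Pb Numeric matrix (l x 3) of C-alpha coordinates in Angstrom.
#' @param Ps Optional numeric matrix (l x 3) of side-chain centroids.
#' @param resno Integer residue numbers (default 1..l).
#' @param resname Residue names (default "ALA").
#' @param insert Insertion codes (default "").
#' @return Object of class `target_fragment`.
#' @export
target_fragment <- function(Pb, Ps = NULL, resno = NULL, resname = NULL,
                            insert = NULL) {
  Pb <- as.matrix(Pb)
  if (ncol(Pb) != 3L) lf_domain_error("Pb must be an l x 3 matrix")
  l <- nrow(Pb)
  if (l < 1L) lf_domain_error("fragment must contain at least one residue")
  if (!is.null(Ps)) {
    Ps <- as.matrix(Ps)
    if (!all(dim(Ps) == dim(Pb)))
      lf_domain_error("Ps must match Pb in dimensions")
  }
  structure(list(
    Pb = unname(Pb), Ps = if (!is.null(Ps)) unname(Ps),
    resno = if (is.null(resno)) seq_len(l) else as.integer(resno),
    resname = if (is.null(resname)) rep("ALA", l) else as.character(resname),
    insert = if (is.null(insert)) rep("", l) else as.character(insert)
  ), class = "target_fragment")
}

#' Construct a target structure from fragments
#'
#' @param fragments List of `target_fragment`s (or a single fragment).
#' @param mode `"backbone"` or `"side_chain"`.
#' @param chain Chain identifier (bookkeeping only).
#' @param source Description of where the target came from.
#' @return Object of class `target_structure`.
#' @export
target_structure <- function(fragments, mode = c("backbone", "side_chain"),
                             chain = "A", source = "constructed") {
  mode <- match.arg(mode)
  if (inherits(fragments, "target_fragment")) fragments <- list(fragments)
  if (!length(fragments)) lf_domain_error("at least one fragment required")
  for (f in fragments) {
    stopifnot(inherits(f, "target_fragment"))
    if (mode == "side_chain" && is.null(f$Ps))
      lf_domain_error("side_chain mode requires Ps in every fragment")
  }
  structure(list(fragments = fragments, mode = mode, chain = chain,
                 source = source),
            class = "target_structure")
}

fragment_length <- function(frag) nrow(frag$Pb)

# target points in backbone-then-side-chain order (metrics order)
fragment_points <- function(frag, mode) {
  if (mode == "side_chain") rbind(frag$Pb, frag$Ps) else frag$Pb
}

# target points interleaved b1,s1,b2,s2,... (chain-growth order)
fragment_points_interleaved <- function(frag, mode) {
  if (mode != "side_chain") return(frag$Pb)
  l <- fragment_length(frag)
  out <- matrix(0, 2 * l, 3)
  out[seq(1, 2 * l, by = 2), ] <- frag$Pb
  out[seq(2, 2 * l, by = 2), ] <- frag$Ps
  out
}

# coerce the various accepted inputs to a single fragment + mode
as_target_fragment <- function(target, mode = NULL) {
  if (inherits(target, "target_structure")) {
    if (length(target$fragments) != 1L)
      lf_domain_error("target has multiple fragments; use fit() instead")
    frag <- target$fragments[[1]]
    if (is.null(mode)) mode <- target$mode
  } else if (inherits(target, "target_fragment")) {
    frag <- target
  } else if (inherits(target, "real_model")) {
    frag <- target_fragment(target$backbone, target$side_chains)
  } else if (is.matrix(target)) {
    frag <- target_fragment(target)
  } else {
    lf_domain_error("unsupported target type")
  }
  if (is.null(mode)) mode <- if (is.null(frag$Ps)) "backbone" else "side_chain"
  if (mode == "side_chain" && is.null(frag$Ps))
    lf_domain_error("side_chain mode requires side-chain centroids")
  if (mode == "backbone") frag$Ps <- NULL
  list(fragment = frag, mode = mode)
}

#' @export
print.target_structure <- function(x, ...) {
  lens <- vapply(x$fragments, fragment_length, 0L)
  cat(sprintf("Target structure (%s mode): %d fragment(s), %d residues [%s]\n",
              x$mode, length(x$fragments), sum(lens), x$source))
  invisible(x)
}
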