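# ---------------------------------------------------------------------------
# Fitting strategies
#
# fit_drmsd: chain-growth beam search minimising distance RMSD (rotation and
#   reflection independent), with per-iteration point-group symmetry
#   filtering, finalised by Kabsch superposition of the model and its mirror
#   image.
# fit_crmsd: rotation-grid scan; for each orientation of the target a
#   chain growth minimises coordinate RMSD with an additive score update;
#   a refinement pass scans sub-interval rotations around the coarse best.
# fit: applies a strategy independently to every fragment of a target.
# ---------------------------------------------------------------------------

finalize_fit <- function(nodes, frag, mode, lat, bond_length, params,
                         raw_score) {
  l <- fragment_length(frag)
  side <- mode == "side_chain"
  if (side) {
    bb <- nodes[seq(1, 2 * l, by = 2), , drop = FALSE]
    sc <- nodes[seq(2, 2 * l, by = 2), , drop = FALSE]
  } else {
    bb <- nodes
    sc <- NULL
  }
  model <- lattice_model(bb, sc, lat)
  rm <- to_real(model, bond_length)
  Pbs <- fragment_points(frag, mode)
  Mbs <- real_points(rm)
  d <- if (nrow(Pbs) >= 2L) drmsd(Pbs, Mbs) else NA_real_
  bs <- best_superposition(Pbs, Mbs)
  coords <- list(
    backbone = bs$coords[seq_len(l), , drop = FALSE],
    side_chains = if (side) bs$coords[l + seq_len(l), , drop = FALSE]
  )
  structure(list(
    model = model, coords = coords, target = frag, mode = mode,
    drmsd = d, crmsd = bs$crmsd, superposition = bs$superposition,
    moves = encode_move_string(model), params = params,
    raw_score = raw_score
  ), class = "fit_result")
}

#' Fit a target fragment by dRMSD-optimising chain growth
#'
#' Grows lattice models one residue at a time from the amino terminus. At
#' each iteration every beam entry is extended by all valid placements of
#' the next backbone node (and, in side-chain mode, every valid adjacent
#' side-chain node); extensions are scored by the partial sum of squared
#' pairwise-distance deviations, symmetry-equivalent partial models are
#' collapsed via their canonical form, and the best `n_keep` are retained.
#' The finished model and its mirror image are superposed onto the target
#' with the Kabsch algorithm and the lower-cRMSD branch is returned.
#'
#' @param target A `target_fragment`, single-fragment `target_structure`,
#'   coordinate matrix (backbone mode) or `real_model`.
#' @param lattice Lattice name or `lattice_spec`.
#' @param n_keep Beam width (default 1000).
#' @param mode `"backbone"` or `"side_chain"`; default inferred from the
#'   target.
#' @param bond_length Physical bond length in Angstrom (default 3.8).
#' @return A `fit_result`: the `lattice_model`, superposed real-space
#'   `coords`, final `drmsd`/`crmsd` in Angstrom, move strings and the
#'   parameters used.
#' @export
fit_drmsd <- function(target, lattice, n_keep = 1000, mode = NULL,
                      bond_length = 3.8) {
  if (!is.numeric(n_keep) || length(n_keep) != 1L || n_keep < 1)
    lf_domain_error("n_keep must be a positive integer")
  lat <- make_lattice(lattice)
  tf <- as_target_fragment(target, mode)
  frag <- tf$fragment; mode <- tf$mode
  l <- fragment_length(frag)
  side <- mode == "side_chain"
  Pint <- fragment_points_interleaved(frag, mode)
  targetD <- as.matrix(dist(Pint))
  unit <- lattice_unit(lat, bond_length)
  res <- .cg_fit_drmsd(targetD, l, side, lat$neighbors, unit,
                       unclass(point_group(lat)), as.integer(n_keep))
  if (!res$ok)
    lf_fit_failure(sprintf("no valid extension at residue %d", res$failed_at),
                   residue = res$failed_at)
  params <- list(strategy = "drmsd", lattice = lat$name, mode = mode,
                 n_keep = as.integer(n_keep), bond_length = bond_length)
  finalize_fit(res$nodes, frag, mode, lat, bond_length, params, res$score)
}

rotation_matrix <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Fit a target fragment by rotation-scanning cRMSD optimisation
#'
#' For each grid rotation of the target (`r` uniform steps per XYZ axis;
#' the default range `[0, pi/2)` per axis exploits cubic point-group
#' redundancy), the rotated target is anchored with its first C-alpha on a
#' lattice node and a chain growth keeps the `n_keep` best partial models by
#' the additive sum of squared coordinate deviations (the first side-chain
#' monomer goes to the adjacent node closest to its centroid). A refinement
#' pass then scans `r_ref` sub-interval rotations per axis within half a
#' coarse step of the best coarse rotation; `r_ref = 0` disables refinement.
#' The overall best model is finalised exactly as in [fit_drmsd()].
#'
#' @inheritParams fit_drmsd
#' @param r Rotation steps per axis for the coarse screen (default 10).
#' @param r_ref Refinement steps per axis around the best coarse rotation
#'   (default 5).
#' @param full_sphere Scan `[0, 2*pi)` per axis instead of `[0, pi/2)`; only
#'   useful for lattices without full cubic symmetry.
#' @return A `fit_result`; `params$grid_crmsd` holds the cRMSD achieved in
#'   the anchored grid frame and `params$rotation` the winning angles.
#' @export
fit_crmsd <- function(target, lattice, n_keep = 1000, r = 10, r_ref = 5,
                      mode = NULL, bond_length = 3.8, full_sphere = FALSE) {
  if (!is.numeric(n_keep) || length(n_keep) != 1L || n_keep < 1)
    lf_domain_error("n_keep must be a positive integer")
  if (!is.numeric(r) || length(r) != 1L || r < 1)
    lf_domain_error("r must be a positive integer")
  if (!is.numeric(r_ref) || length(r_ref) != 1L || r_ref < 0)
    lf_domain_error("r_ref must be a non-negative integer")
  lat <- make_lattice(lattice)
  tf <- as_target_fragment(target, mode)
  frag <- tf$fragment; mode <- tf$mode
  l <- fragment_length(frag)
  side <- mode == "side_chain"
  Pint <- fragment_points_interleaved(frag, mode)
  unit <- lattice_unit(lat, bond_length)

  eval_rotation <- function(ang) {
    Rm <- rotation_matrix(ang[1], ang[2], ang[3])
    Prot <- Pint %*% t(Rm)
    Prot <- sweep(Prot, 2, Prot[1, ])          # anchor P_1^b at the origin
    .cg_fit_crmsd(Prot, l, side, lat$neighbors, unit, as.integer(n_keep))
  }

  range <- if (full_sphere) 2 * pi else pi / 2
  step <- range / r
  axis_angles <- step * (seq_len(r) - 1L)
  grid <- as.matrix(expand.grid(ax = axis_angles, ay = axis_angles,
                                az = axis_angles))
  best <- NULL; best_ang <- NULL; failed_at <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    res <- eval_rotation(grid[i, ])
    if (!res$ok) { failed_at <- res$failed_at; next }
    if (is.null(best) || res$score < best$score) {
      best <- res; best_ang <- grid[i, ]
    }
  }
  if (is.null(best))
    lf_fit_failure(sprintf("no valid extension at residue %d", failed_at),
                   residue = failed_at)
  if (r_ref >= 1) {
    offsets <- if (r_ref == 1) 0 else seq(-step / 2, step / 2,
                                          length.out = r_ref)
    ref_grid <- as.matrix(expand.grid(ax = offsets, ay = offsets,
                                      az = offsets))
    for (i in seq_len(nrow(ref_grid))) {
      ang <- best_ang + ref_grid[i, ]
      res <- eval_rotation(ang)
      if (res$ok && res$score < best$score) {
        best <- res; best_ang <- ang
      }
    }
  }
  npts <- if (side) 2 * l else l
  params <- list(strategy = "crmsd", lattice = lat$name, mode = mode,
                 n_keep = as.integer(n_keep), r = as.integer(r),
                 r_ref = as.integer(r_ref), bond_length = bond_length,
                 full_sphere = full_sphere,
                 rotation = as.numeric(best_ang),
                 grid_crmsd = sqrt(best$score / npts))
  finalize_fit(best$nodes, frag, mode, lat, bond_length, params, best$score)
}

#' Fit every fragment of a target structure
#'
#' Applies the chosen strategy independently to each fragment; per-fragment
#' failures are recorded without aborting the remaining fragments. Overall
#' metrics combine fragments as length-weighted root mean squares (weighted
#' by point count for cRMSD and by pair count for dRMSD).
#'
#' @param target A `target_structure`.
#' @param lattice Lattice name or `lattice_spec`.
#' @param strategy `"drmsd"` (default) or `"crmsd"`.
#' @param ... Passed to [fit_drmsd()] or [fit_crmsd()].
#' @return Object of class `lattice_fit_set`: `results` (one `fit_result`
#'   per fitted fragment), `failures` (named list of conditions), and
#'   `overall` (length-weighted dRMSD/cRMSD and total length).
#' @export
fit <- function(target, lattice, strategy = c("drmsd", "crmsd"), ...) {
  stopifnot(inherits(target, "target_structure"))
  strategy <- match.arg(strategy)
  fitter <- if (strategy == "drmsd") fit_drmsd else fit_crmsd
  results <- list(); failures <- list()
  for (i in seq_along(target$fragments)) {
    frag <- target$fragments[[i]]
    out <- tryCatch(
      fitter(frag, lattice, mode = target$mode, ...),
      latticefit_error = function(e) e
    )
    key <- sprintf("fragment_%d", i)
    if (inherits(out, "fit_result")) results[[key]] <- out
    else failures[[key]] <- out
  }
  overall <- NULL
  if (length(results)) {
    side <- target$mode == "side_chain"
    lens <- vapply(results, function(f) fragment_length(f$target), 0L)
    npts <- if (side) 2L * lens else lens
    pairs <- npts * (npts - 1L) / 2L
    cs <- vapply(results, function(f) f$crmsd, 0)
    ds <- vapply(results, function(f) f$drmsd, 0)
    keep <- pairs > 0L & !is.na(ds)
    overall <- list(
      n_residues = sum(lens),
      n_fragments = length(results),
      crmsd = sqrt(sum(npts * cs^2) / sum(npts)),
      drmsd = if (any(keep))
        sqrt(sum(pairs[keep] * ds[keep]^2) / sum(pairs[keep]))
      else NA_real_
    )
  }
  structure(list(results = results, failures = failures, overall = overall,
                 strategy = strategy, mode = target$mode),
            class = "lattice_fit_set")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Lattice fit (%s, %s, %s): %d residues, dRMSD %s A, cRMSD %.4f A\n",
    x$params$strategy, x$params$lattice, x$mode,
    fragment_length(x$target),
    if (is.na(x$drmsd)) "NA" else sprintf("%.4f", x$drmsd), x$crmsd))
  invisible(x)
}

#' @export
print.lattice_fit_set <- function(x, ...) {
  cat(sprintf("Lattice fit set (%s): %d fragment(s) fitted, %d failed\n",
              x$strategy, length(x$results), length(x$failures)))
  if (!is.null(x$overall))
    cat(sprintf("  overall: %d residues, dRMSD %s A, cRMSD %.4f A\n",
                x$overall$n_residues,
                if (is.na(x$overall$drmsd)) "NA"
                else sprintf("%.4f", x$overall$drmsd),
                x$overall$crmsd))
  invisible(x)
}
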