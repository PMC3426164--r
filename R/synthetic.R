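# ---------------------------------------------------------------------------
# Synthetic fixtures and brute-force oracles
#
# Everything needed to exercise the fitting machinery without external
# data: seeded self-avoiding walk generation, coordinate perturbation into
# off-lattice targets, exhaustive enumeration oracles for tiny instances,
# and synthetic PDB fixtures for the end-to-end path.
# ---------------------------------------------------------------------------

MAX_RANDOM_LENGTH <- 500L

node_key <- function(v) paste(v[1], v[2], v[3])

#' Generate a random self-avoiding lattice structure
#'
#' Uniform-restart self-avoiding growth: at each step one of the valid
#' backbone extensions is picked uniformly (then, in side-chain mode, one of
#' the free adjacent side-chain nodes); the walk restarts on dead ends. No
#' claim of uniformity across walks is made.
#'
#' @param lattice Lattice name or `lattice_spec`.
#' @param l Number of residues (1 to 500).
#' @param mode `"backbone"` or `"side_chain"`.
#' @param seed Optional integer seed; the global RNG state is restored.
#' @param max_restarts Restart budget before giving up.
#' @return A valid `lattice_model`.
#' @export
random_structure <- function(lattice, l, mode = c("backbone", "side_chain"),
                             seed = NULL, max_restarts = 10000L) {
  mode <- match.arg(mode)
  lat <- make_lattice(lattice)
  if (l < 1L) lf_domain_error("l must be >= 1")
  if (l > MAX_RANDOM_LENGTH)
    lf_domain_error(sprintf("l exceeds the configured bound of %d",
                            MAX_RANDOM_LENGTH))
  side <- mode == "side_chain"
  nb <- lat$neighbors
  k <- nrow(nb)
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      occ <- new.env(parent = emptyenv(), size = 4L * l)
      bb <- matrix(0L, l, 3L)
      sc <- if (side) matrix(0L, l, 3L)
      assign(node_key(bb[1, ]), TRUE, envir = occ)
      ok <- TRUE
      if (side) {
        s1 <- bb[1, ] + nb[sample.int(k, 1L), ]
        sc[1, ] <- s1
        assign(node_key(s1), TRUE, envir = occ)
      }
      if (l > 1L) {
        for (i in 2:l) {
          cand <- sweep(nb, 2, bb[i - 1, ], "+")
          free <- !vapply(seq_len(k), function(j)
            exists(node_key(cand[j, ]), envir = occ), TRUE)
          if (!any(free)) { ok <- FALSE; break }
          pick <- which(free)[sample.int(sum(free), 1L)]
          bb[i, ] <- cand[pick, ]
          assign(node_key(bb[i, ]), TRUE, envir = occ)
          if (side) {
            scand <- sweep(nb, 2, bb[i, ], "+")
            sfree <- !vapply(seq_len(k), function(j)
              exists(node_key(scand[j, ]), envir = occ), TRUE)
            if (!any(sfree)) { ok <- FALSE; break }
            spick <- which(sfree)[sample.int(sum(sfree), 1L)]
            sc[i, ] <- scand[spick, ]
            assign(node_key(sc[i, ]), TRUE, envir = occ)
          }
        }
      }
      if (ok) return(lattice_model(bb, sc, lat))
    }
    lf_fit_failure(sprintf("self-avoiding growth failed after %d restarts",
                           max_restarts))
  })
}

random_rotation <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Perturb a lattice model into an off-lattice fitting target
#'
#' Converts the model to real coordinates (3.8 A bonds by default), applies
#' a seeded random rigid motion plus isotropic Gaussian displacement of
#' standard deviation `sigma` per monomer, and packages the result as a
#' `target_structure` (optionally split into fragments).
#'
#' @param m A valid `lattice_model`.
#' @param sigma Noise standard deviation per coordinate, in Angstrom.
#' @param seed Optional integer seed.
#' @param rigid Apply a random rigid motion (default `TRUE`); with `FALSE`
#'   the target stays in the model's own frame (identity orientation).
#' @param fragments Optional integer vector of fragment lengths summing to
#'   the model length; residue numbering jumps by 2 across fragment breaks.
#' @param bond_length Bond length in Angstrom.
#' @return A `target_structure`.
#' @export
perturb <- function(m, sigma = 0, seed = NULL, rigid = TRUE,
                    fragments = NULL, bond_length = 3.8) {
  stopifnot(inherits(m, "lattice_model"))
  if (sigma < 0) lf_domain_error("sigma must be >= 0")
  rm <- to_real(m, bond_length)
  l <- model_length(m)
  side <- has_side_chains(m)
  with_seed(seed, {
    R <- if (rigid) random_rotation() else diag(3)
    tr <- if (rigid) runif(3, -20, 20) else c(0, 0, 0)
    jitter <- function(x) x + matrix(rnorm(length(x), sd = sigma), nrow(x), 3)
    Pb <- sweep(jitter(rm$backbone) %*% t(R), 2, tr, "+")
    Ps <- if (side) sweep(jitter(rm$side_chains) %*% t(R), 2, tr, "+")
    if (is.null(fragments)) fragments <- l
    if (sum(fragments) != l || any(fragments < 1))
      lf_domain_error("fragment lengths must be positive and sum to l")
    ends <- cumsum(fragments)
    starts <- c(1L, head(ends, -1L) + 1L)
    frs <- lapply(seq_along(fragments), function(f) {
      ii <- starts[f]:ends[f]
      target_fragment(Pb[ii, , drop = FALSE],
                      if (side) Ps[ii, , drop = FALSE],
                      resno = ii + (f - 1L))   # +1 gap per break
    })
    target_structure(frs, mode = if (side) "side_chain" else "backbone",
                     source = "synthetic")
  })
}

#' Enumerate self-avoiding lattice structures
#'
#' Depth-first enumeration of all valid structures of `l` residues anchored
#' with the first backbone node at the origin. With `dedup = TRUE` one
#' canonical representative per point-group/translation orbit is returned.
#'
#' @param lattice Lattice name or `lattice_spec`.
#' @param l Number of residues.
#' @param mode `"backbone"` or `"side_chain"`.
#' @param dedup Collapse symmetry-equivalent structures (default `TRUE`).
#' @param max_states Refusal bound on the enumeration size.
#' @return List of `lattice_model`s.
#' @export
walk_cache <- new.env(parent = emptyenv())

enumerate_walks <- function(lattice, l, mode = c("backbone", "side_chain"),
                            dedup = TRUE, max_states = 2e6) {
  mode <- match.arg(mode)
  lat <- make_lattice(lattice)
  cache_key <- paste(lat$name, l, mode, dedup, sep = "|")
  if (exists(cache_key, envir = walk_cache))
    return(get(cache_key, envir = walk_cache))
  side <- mode == "side_chain"
  k <- nrow(lat$neighbors)
  est <- if (side) as.numeric(k)^(2 * l - 1) else as.numeric(k)^(l - 1)
  if (est > max_states)
    lf_domain_error(sprintf(
      "enumeration size ~%g exceeds the bound of %g (backbone l <= 6 on SQR/CUB, side-chain l <= 3)",
      est, max_states))
  nb <- lat$neighbors
  group <- point_group(lat)
  out <- list()
  seen <- new.env(parent = emptyenv())

  emit <- function(bb, sc) {
    m <- lattice_model(bb, sc, lat, check = FALSE)
    if (dedup) {
      cf <- canonical_form(m, group)
      key <- paste(as.integer(t(model_nodes(cf))), collapse = ",")
      if (exists(key, envir = seen)) return()
      assign(key, TRUE, envir = seen)
      out[[length(out) + 1L]] <<- cf
    } else {
      out[[length(out) + 1L]] <<- m
    }
  }

  occ_has <- function(occ, v) exists(node_key(v), envir = occ)

  grow <- function(bb, sc, occ, i) {
    if (i > l) { emit(bb, sc); return(invisible()) }
    if (i == 1L) {
      bb1 <- matrix(0L, 1L, 3L)
      if (!side) {
        occ2 <- new.env(parent = emptyenv())
        assign(node_key(c(0L, 0L, 0L)), TRUE, envir = occ2)
        grow(bb1, NULL, occ2, 2L)
      } else {
        for (j in seq_len(k)) {
          occ2 <- new.env(parent = emptyenv())
          assign(node_key(c(0L, 0L, 0L)), TRUE, envir = occ2)
          s <- nb[j, , drop = FALSE]
          assign(node_key(s[1, ]), TRUE, envir = occ2)
          grow(bb1, s, occ2, 2L)
        }
      }
      return(invisible())
    }
    cand <- sweep(nb, 2, bb[i - 1, ], "+")
    for (j in seq_len(k)) {
      v <- cand[j, ]
      if (occ_has(occ, v)) next
      assign(node_key(v), TRUE, envir = occ)
      bb2 <- rbind(bb, v)
      if (!side) {
        grow(bb2, NULL, occ, i + 1L)
      } else {
        scand <- sweep(nb, 2, v, "+")
        for (jj in seq_len(k)) {
          s <- scand[jj, ]
          if (occ_has(occ, s)) next
          assign(node_key(s), TRUE, envir = occ)
          grow(bb2, rbind(sc, s), occ, i + 1L)
          rm(list = node_key(s), envir = occ)
        }
      }
      rm(list = node_key(v), envir = occ)
    }
    invisible()
  }
  grow(NULL, NULL, NULL, 1L)
  assign(cache_key, out, envir = walk_cache)
  out
}

#' Exhaustive brute-force fitting oracle
#'
#' Enumerates every valid structure of the target's length (one canonical
#' representative per symmetry orbit for the rotation-invariant dRMSD
#' objective; all orientations for the cRMSD objective), scores each with
#' the metrics module, and returns the global optimum. Only feasible for
#' tiny instances; larger ones are refused with the size bound.
#'
#' @param target A `target_fragment`, single-fragment `target_structure`,
#'   coordinate matrix or `real_model`.
#' @param lattice Lattice name or `lattice_spec`.
#' @param mode `"backbone"` or `"side_chain"` (default inferred).
#' @param objective `"drmsd"`, or `"crmsd"` (over a supplied rotation list).
#' @param rotations For the cRMSD objective: matrix of rotation angles, one
#'   row of (ax, ay, az) per rotation, matching the grid convention of
#'   [fit_crmsd()].
#' @param bond_length Bond length in Angstrom.
#' @return List with `model` (optimal `lattice_model`), `score` (optimal
#'   dRMSD or cRMSD in Angstrom), and `n_enumerated`.
#' @export
exhaustive_oracle <- function(target, lattice, mode = NULL,
                              objective = c("drmsd", "crmsd"),
                              rotations = NULL, bond_length = 3.8) {
  objective <- match.arg(objective)
  lat <- make_lattice(lattice)
  tf <- as_target_fragment(target, mode)
  frag <- tf$fragment; mode <- tf$mode
  l <- fragment_length(frag)
  Pbs <- fragment_points(frag, mode)
  models <- enumerate_walks(lat, l, mode, dedup = objective == "drmsd")
  best <- NULL; best_score <- Inf
  if (objective == "drmsd") {
    if (nrow(Pbs) < 2L)
      return(list(model = models[[1]], score = 0, n_enumerated = length(models)))
    for (m in models) {
      s <- drmsd(Pbs, real_points(to_real(m, bond_length)))
      if (s < best_score) { best_score <- s; best <- m }
    }
  } else {
    if (is.null(rotations))
      lf_domain_error("the crmsd objective requires a rotation list")
    rotations <- as.matrix(rotations)
    for (m in models) {
      Mbs <- real_points(to_real(m, bond_length))
      for (ri in seq_len(nrow(rotations))) {
        Rm <- rotation_matrix(rotations[ri, 1], rotations[ri, 2],
                              rotations[ri, 3])
        Prot <- Pbs %*% t(Rm)
        Prot <- sweep(Prot, 2, Prot[1, ])      # anchor P_1^b at the origin
        s <- crmsd(Prot, Mbs)
        if (s < best_score) { best_score <- s; best <- m }
      }
    }
  }
  list(model = best, score = best_score, n_enumerated = length(models))
}

#' Write a synthetic PDB fixture
#'
#' Generates a random on-lattice structure, perturbs it into a target, and
#' emits a synthetic PDB file with CA records (and one pseudo side-chain CB
#' atom per residue in side-chain mode) so the full parse/fit/write path
#' runs without downloads. Identical arguments produce byte-identical
#' output.
#'
#' @param lattice Lattice name or `lattice_spec`.
#' @param l Number of residues.
#' @param mode `"backbone"` or `"side_chain"`.
#' @param sigma Perturbation noise in Angstrom.
#' @param seed Integer seed (drives both the walk and the perturbation).
#' @param fragments Optional fragment-length pattern (see [perturb()]).
#' @param rigid Apply a random rigid motion in [perturb()].
#' @param file Output path; if `NULL` the PDB text is only returned.
#' @return Invisibly, a list with `model` (the generating `lattice_model`),
#'   `target` (the perturbed `target_structure`), `lines` and `file`.
#' @export
write_fixture_pdb <- function(lattice, l, mode = c("backbone", "side_chain"),
                              sigma = 0, seed = 1, fragments = NULL,
                              rigid = TRUE, file = NULL) {
  mode <- match.arg(mode)
  out <- with_seed(seed, {
    m <- random_structure(lattice, l, mode)
    tgt <- perturb(m, sigma = sigma, rigid = rigid, fragments = fragments)
    list(model = m, target = tgt)
  })
  lines <- character(); serial <- 0L
  for (frag in out$target$fragments) {
    for (i in seq_len(fragment_length(frag))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, " CA ", frag$resname[i], "A",
                                      frag$resno[i], "", frag$Pb[i, ], " C"))
      if (mode == "side_chain") {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, " CB ", frag$resname[i], "A",
                                        frag$resno[i], "", frag$Ps[i, ], " C"))
      }
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(c(out, list(lines = lines, file = file)))
}
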