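test_that("validation reports the first violated constraint", {
  # collision between positions 1 and 3
  m <- lattice_model(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)),
                     lattice = "cub", check = FALSE)
  rep <- validate_model(m)
  expect_false(rep$valid)
  expect_identical(rep$type, "collision")
  expect_identical(rep$indices, c(1L, 3L))

  # backbone break at step 1
  m <- lattice_model(rbind(c(0, 0, 0), c(2, 0, 0)), lattice = "cub",
                     check = FALSE)
  rep <- validate_model(m)
  expect_identical(rep$type, "backbone_break")
  expect_identical(rep$indices, 1L)

  # single residue with adjacent side chain is valid
  m <- lattice_model(c(0, 0, 0), c(1, 0, 0), "cub")
  expect_true(validate_model(m)$valid)

  # side-chain break
  m <- lattice_model(c(0, 0, 0), c(2, 0, 0), "cub", check = FALSE)
  expect_identical(validate_model(m)$type, "side_chain_break")
})

test_that("validation agrees with a brute-force pairwise checker", {
  set.seed(31)
  for (i in 1:40) {
    name <- sample(ALL_LATTICES, 1)
    mode <- sample(c("backbone", "side_chain"), 1)
    m <- random_structure(name, sample(3:10, 1), mode)
    # valid as constructed
    expect_true(validate_model(m)$valid)
    expect_true(brute_force_valid(m$backbone, m$side_chains, name))
    # corrupt one node and compare verdicts
    bb <- m$backbone
    bb[sample(nrow(bb), 1), ] <- bb[sample(nrow(bb), 1), ] +
      sample(c(-1L, 0L, 1L), 3, replace = TRUE)
    mc <- lattice_model(bb, m$side_chains, name, check = FALSE)
    expect_identical(validate_model(mc)$valid,
                     brute_force_valid(bb, m$side_chains, name))
  }
})

test_that("real-space conversion scales every bond to the bond length", {
  m <- lattice_model(rbind(c(0, 0, 0), c(1, 0, 0)), lattice = "cub")
  rm <- to_real(m, 3.8)
  expect_equal(sqrt(sum((rm$backbone[2, ] - rm$backbone[1, ])^2)), 3.8)

  m <- lattice_model(rbind(c(0, 0, 0), c(1, 1, 0)), lattice = "fcc")
  rm <- to_real(m, 3.8)
  expect_equal(sqrt(sum((rm$backbone[2, ] - rm$backbone[1, ])^2)), 3.8)

  # unit scaling on an already-unit lattice leaves coordinates unchanged
  m <- lattice_model(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)), lattice = "cub")
  rm <- to_real(m, 1)
  expect_equal(rm$backbone, m$backbone + 0)

  # all bonds (backbone and side-chain) have the bond length
  m <- random_structure("210", 8, "side_chain", seed = 3)
  rm <- to_real(m, 3.8)
  bl <- sqrt(rowSums((rm$backbone - rm$side_chains)^2))
  expect_equal(bl, rep(3.8, 8), tolerance = 1e-9)
  expect_error(to_real(lattice_model(rbind(c(0, 0, 0), c(3, 0, 0)),
                                     lattice = "cub", check = FALSE)),
               class = "latticefit_invalid_structure")
})

test_that("canonical form is constant on symmetry orbits and idempotent", {
  group <- point_group("fcc")
  set.seed(17)
  for (i in 1:15) {
    m <- random_structure("fcc", 8, sample(c("backbone", "side_chain"), 1))
    cf <- canonical_form(m, group)
    # idempotent
    expect_identical(latticefit:::model_nodes(canonical_form(cf, group)),
                     latticefit:::model_nodes(cf))
    # same canonical form after random symmetry transform + translation
    g <- group[[sample(length(group), 1)]]
    shift <- sample(-5:5, 3, replace = TRUE)
    mg <- lattice_model(sweep(m$backbone %*% t(g), 2, shift, "+"),
                        if (!is.null(m$side_chains))
                          sweep(m$side_chains %*% t(g), 2, shift, "+"),
                        "fcc")
    expect_identical(latticefit:::model_nodes(canonical_form(mg, group)),
                     latticefit:::model_nodes(cf))
  }
})

test_that("mirror images and translates share a canonical form; distinct folds do not", {
  m <- lattice_model(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
                     lattice = "cub")
  mirror <- lattice_model(m$backbone %*% diag(c(1L, 1L, -1L)), lattice = "cub")
  translated <- lattice_model(sweep(m$backbone, 2, c(5L, 5L, 5L), "+"),
                              lattice = "cub")
  cf <- canonical_form(m)
  expect_identical(latticefit:::model_nodes(canonical_form(mirror)),
                   latticefit:::model_nodes(cf))
  expect_identical(latticefit:::model_nodes(canonical_form(translated)),
                   latticefit:::model_nodes(cf))

  # all symmetry-distinct 4-residue folds on SQR have distinct canonical forms
  folds <- enumerate_walks("sqr", 4)
  keys <- vapply(folds, function(f)
    paste(latticefit:::model_nodes(f), collapse = ","), "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_true(length(folds) >= 2)
})
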