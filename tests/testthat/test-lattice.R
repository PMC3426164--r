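test_that("registered lattices have the expected neighbourhoods", {
  expected_coord <- c(sqr = 4L, cub = 6L, fcc = 12L, `210` = 24L)
  for (name in names(expected_coord)) {
    lat <- make_lattice(name)
    nb <- lat$neighbors
    expect_identical(nrow(nb), expected_coord[[name]])
    # equal unscaled lengths
    expect_length(unique(rowSums(nb^2)), 1L)
    # closure under negation, no zero vector, no duplicates
    key <- paste(nb[, 1], nb[, 2], nb[, 3])
    expect_setequal(paste(-nb[, 1], -nb[, 2], -nb[, 3]), key)
    expect_false(any(rowSums(nb != 0) == 0))
    expect_identical(anyDuplicated(nb), 0L)
  }
  expect_identical(make_lattice("FCC")$name, "fcc")  # case-insensitive
  expect_error(make_lattice("hexagonal"), class = "latticefit_unsupported_lattice")
})

test_that("scaled neighbours have the requested bond length", {
  cub <- scaled_neighbors("cub", 3.8)
  expect_equal(sort(abs(cub[cub != 0])), rep(3.8, 6))
  for (name in ALL_LATTICES) {
    for (b in c(1.0, 3.8)) {
      sc <- scaled_neighbors(name, b)
      expect_equal(sqrt(rowSums(sc^2)), rep(b, nrow(sc)), tolerance = 1e-12)
    }
  }
  expect_error(scaled_neighbors("cub", 0), class = "latticefit_domain_error")
  expect_error(scaled_neighbors("cub", -1), class = "latticefit_domain_error")
})

test_that("point groups have the brute-force sizes and group structure", {
  expect_length(point_group("cub"), 48L)
  expect_length(point_group("fcc"), 48L)
  expect_length(point_group("210"), 48L)
  expect_length(point_group("sqr"), 8L)

  g <- point_group("fcc")
  keys <- vapply(g, function(m) paste(m, collapse = ","), "")
  expect_true(paste(diag(3), collapse = ",") %in% keys)        # identity
  nb <- make_lattice("fcc")$neighbors
  nbk <- sort(paste(nb[, 1], nb[, 2], nb[, 3]))
  for (m in g) {
    img <- nb %*% t(m)
    expect_identical(sort(paste(img[, 1], img[, 2], img[, 3])), nbk)
    expect_true(paste(m %*% t(m), collapse = ",") == paste(diag(3), collapse = ","))
  }
  # closure under composition (spot check on a subsample)
  for (i in c(1, 5, 17)) {
    for (j in c(2, 30, 48)) {
      expect_true(paste(g[[i]] %*% g[[j]], collapse = ",") %in% keys)
    }
  }
})

test_that("point-group transforms preserve validity and dRMSD", {
  set.seed(11)
  target <- matrix(rnorm(30, sd = 4), 10, 3)
  m <- random_structure("fcc", 10, seed = 42)
  d0 <- drmsd(target, latticefit:::real_points(to_real(m)))
  for (g in point_group("fcc")[c(1, 7, 20, 48)]) {
    mg <- lattice_model(m$backbone %*% t(g), lattice = "fcc")
    expect_true(validate_model(mg)$valid)
    expect_equal(drmsd(target, latticefit:::real_points(to_real(mg))), d0,
                 tolerance = 1e-12)
  }
})

test_that("move strings encode one token per step and round-trip", {
  m <- lattice_model(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), lattice = "cub")
  ms <- encode_move_string(m)
  expect_identical(nchar(ms$backbone), 2L)
  expect_null(ms$side)

  # singleton chain: empty move string
  m1 <- lattice_model(c(0, 0, 0), lattice = "cub")
  expect_identical(encode_move_string(m1)$backbone, "")
  d1 <- decode_move_string("", "cub")
  expect_identical(d1$backbone, matrix(0L, 1, 3))

  # round trip (up to translation) across lattices and modes
  for (name in ALL_LATTICES) {
    for (mode in c("backbone", "side_chain")) {
      for (seed in 1:5) {
        m <- random_structure(name, 9, mode, seed = seed)
        shifted <- lattice_model(sweep(m$backbone, 2, c(5L, -3L, 2L), "+"),
                                 if (!is.null(m$side_chains))
                                   sweep(m$side_chains, 2, c(5L, -3L, 2L), "+"),
                                 name)
        ms <- encode_move_string(shifted)
        m2 <- decode_move_string(ms$backbone, name, ms$side)
        anchored <- sweep(latticefit:::model_nodes(shifted), 2,
                          shifted$backbone[1, ])
        expect_identical(latticefit:::model_nodes(m2), anchored)
      }
    }
  }
})

test_that("decoding rejects bad tokens and self-colliding paths", {
  expect_error(decode_move_string("AZ!", "sqr"), class = "latticefit_parse_error")
  # A = (-1,0,0) and D = (1,0,0) on SQR: out and straight back revisits origin
  alpha <- move_alphabet("sqr")
  fwd <- alpha[["1 0 0"]]; back <- alpha[["-1 0 0"]]
  expect_error(decode_move_string(paste0(fwd, back), "sqr"),
               class = "latticefit_invalid_structure")
  expect_error(decode_move_string("A", "sqr", side = "AAA"),
               class = "latticefit_parse_error")
})

test_that("the lattice registry is open to user-defined neighbourhoods", {
  spec <- register_lattice("bcc_test", latticefit:::signed_permutations(c(1L, 1L, 1L)))
  expect_identical(nrow(make_lattice("bcc_test")$neighbors), 8L)
  m <- random_structure("bcc_test", 8, seed = 1)
  expect_true(validate_model(m)$valid)
  expect_error(register_lattice("bad", rbind(c(1L, 0L, 0L))),
               class = "latticefit_domain_error")  # not closed under negation
})
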