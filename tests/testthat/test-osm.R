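test_that("edge lifts are Kronecker products over descendant taxa", {
  tr <- fig1_tree()
  s1 <- group_element(k3st, "s1")

  m12 <- as.matrix(lift_to_edge(tr, k3st, "e_12", "s1"))
  expect_identical(dim(m12), c(16L, 16L))
  expect_true(isSymmetric(m12))
  expect_equal(unname(m12),
               kronecker(as.matrix(s1), as.matrix(s1)), ignore_attr = TRUE)

  m1 <- as.matrix(lift_to_edge(tr, k3st, "e_1", "s1"))
  expect_equal(unname(m1),
               kronecker(as.matrix(s1), diag(4L)), ignore_attr = TRUE)

  # K3ST elements are involutions: pendant lift applied twice is identity
  op <- lift_to_edge(tr, k3st, "e_2", "s3")
  f <- c(`1` = "A", `2` = "C")
  expect_identical(op_apply(op, op_apply(op, f)), f)

  expect_error(lift_to_edge(tr, k3st, "e_1", "s0"), "identity")
})

test_that("internal-edge lifts equal the product of pendant lifts", {
  set.seed(31)
  for (k in 1:50) {
    tr <- random_tree(sample(3:6, 1L))
    g <- if (k %% 2L) k3st else z4
    elem <- sample(2:4, 1L)
    for (e in tr$edges$name) {
      d <- descendants(tr, e)
      if (length(d) < 2L) next
      lifted <- op_index_map(lift_to_edge(tr, g, e, elem))
      pend <- seq_len(length(lifted))
      for (taxon in d) {
        pmap <- op_index_map(lift_to_edge(tr, g, paste0("e_", taxon), elem))
        pend <- pmap[pend]
      }
      expect_identical(lifted, pend)
    }
  }
})

test_that("Sigma_T enumerates (edge, non-identity type) operators", {
  expect_length(build_sigma_T(fig1_tree(), k3st), 9L)
  expect_length(build_sigma_T(read_osm_tree("(1);"), k3st), 3L)
  expect_length(build_sigma_T(fig2_tree(), k3st), 27L)
})

test_that("the OSM matrix is doubly stochastic with the expected support", {
  tr <- fig1_tree()
  w <- normalize_weights(tr, uniform = TRUE)
  m <- build_osm(tr, k3st, w)
  expect_equal(max(abs(Matrix::rowSums(m$matrix) - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(Matrix::colSums(m$matrix) - 1)), 0, tolerance = 1e-12)

  # only s^{e12,1} maps AA to GG; weight p_e12 * alpha = (1/3)(1/3)
  dm <- as.matrix(m)
  expect_equal(dm["AA", "GG"], 1 / 9)
  expect_equal(dm["AA", "GA"], 1 / 9)  # s1 on e_1 only
  expect_equal(dm["AA", "GC"], 0)      # needs two substitutions

  # symmetric for the involution group (even with skewed type weights,
  # every lifted operator is its own transpose); the cyclic group loses
  # symmetry as soon as a 4-cycle outweighs its inverse
  skew <- matrix(rep(c(0.5, 0.3, 0.2), each = 3), 3, 3)
  mk <- build_osm(tr, k3st, normalize_weights(tr, uniform = TRUE,
                                              alpha = skew))
  expect_equal(max(abs(mk$matrix - Matrix::t(mk$matrix))), 0)
  mzu <- build_osm(tr, z4, normalize_weights(tr, uniform = TRUE))
  expect_equal(max(abs(mzu$matrix - Matrix::t(mzu$matrix))), 0,
               tolerance = 1e-15)  # uniform weights pair s'1 with s'3
  mz <- build_osm(tr, z4, normalize_weights(tr, uniform = TRUE,
                                            alpha = skew))
  expect_gt(max(abs(mz$matrix - Matrix::t(mz$matrix))), 0.01)

  expect_error(build_osm(tr, k3st,
                         structure(list(p = c(e_12 = 1, e_1 = 1, e_2 = 1),
                                        alpha = w$alpha),
                                   class = "osm_weights")),
               "sum to 1")
})

test_that("minimal positive power matches the substitution distance", {
  tr <- fig1_tree()
  m <- build_osm(tr, k3st, normalize_weights(tr, uniform = TRUE))
  expect_identical(min_power_positive(m, "AA", "AA"), 0L)
  expect_identical(min_power_positive(m, "AA", "GG"), 1L)

  five <- fig2_tree()
  w5 <- normalize_weights(five, uniform = TRUE)
  m5 <- build_osm(five, k3st, w5)
  expect_identical(min_power_positive(m5, "GTAGA", "ACCTC"),
                   min_substitutions(five, k3st, "GTAGA", "ACCTC"))

  # zero weights are refused
  a <- w5$alpha; p <- w5$p
  p["e_1"] <- 0; p <- p / sum(p)
  mz <- build_osm(five, k3st,
                  structure(list(p = p, alpha = a), class = "osm_weights"))
  expect_error(min_power_positive(mz, "GTAGA", "ACCTC"), "positive")
})

test_that("Cayley BFS returns distances and witness generator paths", {
  tr <- fig1_tree()
  expect_identical(cayley_shortest_path(tr, k3st, "AA", "AA")$length, 0L)

  sp <- cayley_shortest_path(tr, k3st, "AA", "GC")
  expect_identical(sp$length, 2L)
  expect_length(sp$path, 2L)
  # replay the witness path
  ops <- build_sigma_T(tr, k3st)
  f <- c(`1` = "A", `2` = "A")
  for (lab in sp$path) f <- op_apply(ops[[lab]], f)
  expect_identical(unname(f), c("G", "C"))

  five <- fig2_tree()
  expect_identical(cayley_shortest_path(five, k3st, "GTAGA", "ACCTC")$length,
                   2L)
})

test_that("Sigma_T generates the whole character-space group", {
  for (g in list(k3st, z4, build_cyclic(3))) {
    for (nwk in c("((1,2));", "((1,2),3);")) {
      tr <- read_osm_tree(nwk)
      D <- igraph::distances(osmkit:::cayley_igraph(tr, g), mode = "out")
      expect_true(all(is.finite(D)))
    }
  }
})

test_that("the uniform distribution is stationary and attracting", {
  tr <- fig1_tree()
  m <- build_osm(tr, k3st, normalize_weights(tr, uniform = TRUE))
  st <- stationary_check(m, steps = 200, tol = 1e-6)
  expect_true(st$uniform_fixed)
  expect_lt(st$max_dev_power, 1e-6)
  expect_true(st$converged)

  # products of doubly stochastic matrices stay doubly stochastic
  m2 <- m$matrix %*% m$matrix
  expect_equal(max(abs(Matrix::rowSums(m2) - 1)), 0, tolerance = 1e-12)
})

test_that("OSM and Cayley exports round-trip", {
  tr <- fig1_tree()
  m <- build_osm(tr, k3st, normalize_weights(tr, uniform = TRUE))
  mtx <- tempfile(fileext = ".mtx"); dec <- tempfile(fileext = ".tsv")
  export_osm(m, mtx, dec)
  back <- Matrix::readMM(mtx)
  expect_equal(max(abs(back - m$matrix)), 0, tolerance = 1e-12)
  dtab <- read.table(dec, header = TRUE, sep = "\t")
  expect_identical(nrow(dtab), 9L)
  expect_equal(sum(dtab$weight), 1)

  edges <- export_cayley_edges(tr, k3st)
  expect_identical(nrow(edges), 16L * 9L)
  expect_true(all(c("from", "to", "edge", "type") %in% names(edges)))

  guard_err <- tryCatch(build_osm(fig2_tree(), k3st,
                                  normalize_weights(fig2_tree(),
                                                    uniform = TRUE),
                                  guard = 100),
                        error = function(e) conditionMessage(e))
  expect_match(guard_err, "guard")
})
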