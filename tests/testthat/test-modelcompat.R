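test_that("the sGTR permutation set matches the printed transpositions", {
  ps <- sgtr_permutation_set()
  expect_equal(unname(as.matrix(ps$sa)),
               matrix(c(0, 1, 0, 0,
                        1, 0, 0, 0,
                        0, 0, 1, 0,
                        0, 0, 0, 1), 4, 4, byrow = TRUE),
               ignore_attr = TRUE)
  expect_identical(perm_apply(ps$sb, c("A", "G")), c("G", "A"))
  expect_identical(perm_apply(ps$sf, c("G", "T")), c("T", "G"))

  # non-commuting witness and closure violation, as in the model audit
  ac <- compose(ps$sa, ps$sc)
  ca <- compose(ps$sc, ps$sa)
  expect_false(identical(ac$map, ca$map))
  keys <- vapply(ps, function(p) paste(p$map, collapse = ","), "")
  af <- compose(ps$sa, ps$sf)
  expect_false(paste(af$map, collapse = ",") %in% keys)
})

test_that("the sGTR matrix is the convex sum of its permutation set", {
  params <- c(a = 0.10, b = 0.15, c = 0.22, d = 0.18, e = 0.05, f = 0.30)
  ps <- sgtr_permutation_set()
  s <- Reduce(`+`, Map(function(w, p) w * as.matrix(p), params,
                       ps[c("sa", "sb", "sc", "sd", "se", "sf")]))
  expect_equal(max(abs(s - do.call(p_sgtr, as.list(params)))), 0,
               tolerance = 1e-12)
})

test_that("Birkhoff decomposition reconstructs doubly stochastic matrices", {
  d <- birkhoff_decompose(diag(4))
  expect_length(d$weights, 1L)
  expect_equal(d$weights, 1)
  expect_identical(d$permutations[[1]]$map, 1:4)

  dg <- birkhoff_decompose(p_sgtr(1 / 6, 1 / 6, 1 / 6, 1 / 6, 1 / 6, 1 / 6))
  expect_lt(max(abs(birkhoff_reconstruct(dg) -
                      p_sgtr(1 / 6, 1 / 6, 1 / 6, 1 / 6, 1 / 6, 1 / 6))),
            1e-12)
  expect_equal(sum(dg$weights), 1, tolerance = 1e-12)

  # seeded convex combination of 3 known permutations: only the sum is
  # contractual, not the term list
  set.seed(41)
  w <- rexp(3); w <- w / sum(w)
  M <- Reduce(`+`, lapply(1:3, function(i) w[i] * as.matrix(random_perm(5))))
  dd <- birkhoff_decompose(M)
  expect_lt(max(abs(birkhoff_reconstruct(dd) - M)), 1e-10)

  expect_error(birkhoff_decompose(matrix(c(0.5, 0.4, 0.5, 0.6), 2, 2)),
               "not doubly stochastic")
})

test_that("Birkhoff reconstruction holds across sizes and seeds", {
  set.seed(47)
  for (k in 1:100) {
    r <- sample(2:8, 1L)
    M <- random_doubly_stochastic(r)
    d <- birkhoff_decompose(M)
    expect_lt(max(abs(birkhoff_reconstruct(d) - M)), 1e-10)
    expect_equal(sum(d$weights), 1, tolerance = 1e-10)
    expect_true(all(d$weights > 0))
  }
})

test_that("decomposing a regular group's convex sum recovers its elements", {
  set.seed(53)
  for (g in list(k3st, z4, build_cyclic(5))) {
    r <- length(g$letters)
    w <- sort(rexp(r), decreasing = TRUE); w <- w / sum(w)  # distinct
    M <- Reduce(`+`, Map(function(wi, p) wi * as.matrix(p), w, g$elements))
    d <- birkhoff_decompose(M)
    gkeys <- vapply(g$elements, function(p) paste(p$map, collapse = ","), "")
    dkeys <- vapply(d$permutations, function(p) paste(p$map, collapse = ","),
                    "")
    expect_true(all(dkeys %in% gkeys))
  }
})

test_that("model audits classify K3ST, sGTR and unequal-frequency models", {
  set.seed(59)
  w <- rexp(4); w <- w / sum(w)
  M <- Reduce(`+`, Map(function(wi, p) wi * as.matrix(p), w, k3st$elements))
  a1 <- audit_model(M)
  expect_true(a1$decomposable)
  expect_true(conditions_pass(a1$report))
  expect_true(a1$report$C7$pass)

  a2 <- audit_model(p_sgtr(0.10, 0.15, 0.22, 0.18, 0.05, 0.30))
  expect_true(a2$decomposable)
  expect_false(a2$report$C3$pass)
  expect_false(a2$report$C4$pass)
  expect_false(a2$report$C5$pass)

  # row-stochastic but not column-stochastic (unequal stationary
  # distribution, synthetic Tamura-Nei-style matrix): no decomposition
  tn <- matrix(c(0.70, 0.10, 0.10, 0.10,
                 0.05, 0.80, 0.05, 0.10,
                 0.10, 0.05, 0.80, 0.05,
                 0.10, 0.10, 0.10, 0.70), 4, 4, byrow = TRUE)
  a3 <- audit_model(tn)
  expect_false(a3$decomposable)
  expect_match(a3$reason, "column")

  js <- audit_to_json(a2)
  parsed <- jsonlite::fromJSON(js)
  expect_false(parsed$conditions$C4$pass)
})

test_that("audits pass for every product construction up to 20 states", {
  set.seed(61)
  for (r in c(4L, 6L, 20L)) {
    for (fs in enumerate_constructions(r)) {
      g <- if (length(fs) == 1L) build_cyclic(fs) else
        build_product(lapply(fs, build_cyclic))
      w <- sort(rexp(r), decreasing = TRUE); w <- w / sum(w)
      M <- Reduce(`+`, Map(function(wi, p) wi * as.matrix(p), w,
                           g$elements))
      a <- audit_model(M, letters = g$letters)
      expect_true(a$decomposable)
      expect_true(conditions_pass(a$report))
    }
  }
})

test_that("model matrices round-trip through TSV", {
  m <- p_sgtr(0.1, 0.1, 0.1, 0.2, 0.2, 0.2)
  f <- tempfile(fileext = ".tsv")
  write.table(m, f, sep = "\t", quote = FALSE, col.names = NA)
  back <- read_model_matrix(f)
  expect_equal(back, m)
})
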