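test_that("composition follows apply-right-first and the matrix product", {
  s1 <- group_element(k3st, "s1")
  expect_same_perm(compose(s1, s1), group_element(k3st, "s0"))

  sp1 <- group_element(z4, "s'1")
  expect_same_perm(compose(sp1, sp1), group_element(z4, "s'2"))

  set.seed(11)
  for (k in 1:50) {
    r <- sample(2:20, 1L)
    p <- random_perm(r)
    id <- perm_identity(p$letters)
    expect_same_perm(compose(p, id), p)
    expect_same_perm(compose(id, p), p)
  }

  # matrix form of a.b equals M_b %*% M_a (row convention, b applied first)
  for (k in 1:100) {
    r <- sample(2:20, 1L)
    a <- random_perm(r); b <- random_perm(r)
    expect_equal(as.matrix(compose(a, b)),
                 as.matrix(b) %*% as.matrix(a), ignore_attr = TRUE)
  }

  expect_error(compose(random_perm(3), random_perm(4)), "alphabet")
})

test_that("kronecker products match the printed K3ST matrices", {
  tau0 <- perm_identity(c("0", "1"), "tau0")
  tau1 <- perm(c(2, 1), c("0", "1"), "tau1")
  s1 <- perm_kronecker(tau1, tau0, letters = DNA)
  expect_equal(unname(as.matrix(s1)),
               matrix(c(0, 0, 1, 0,
                        0, 0, 0, 1,
                        1, 0, 0, 0,
                        0, 1, 0, 0), 4, 4, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(as.matrix(perm_kronecker(tau0, tau0, letters = DNA)),
               as.matrix(perm_identity(DNA)))

  # three binary flips, applied twice, are the identity on 8 states
  f3 <- perm_kronecker(tau1, perm_kronecker(tau1, tau1))
  expect_identical(compose(f3, f3)$map, 1:8)

  # associativity on flat indices
  set.seed(7)
  a <- random_perm(2); b <- random_perm(3); c <- random_perm(4)
  expect_identical(perm_kronecker(a, perm_kronecker(b, c))$map,
                   perm_kronecker(perm_kronecker(a, b), c)$map)

  # matrix form is the matrix Kronecker product
  expect_equal(unname(as.matrix(perm_kronecker(b, c))),
               kronecker(as.matrix(b), as.matrix(c)), ignore_attr = TRUE)
})

test_that("cyclic groups are built from a full cycle", {
  g <- build_cyclic(4, cycle = c("A", "G", "T", "C"))
  expect_equal(unname(as.matrix(g$elements[[2]])),
               matrix(c(0, 0, 1, 0,
                        1, 0, 0, 0,
                        0, 0, 0, 1,
                        0, 1, 0, 0), 4, 4, byrow = TRUE),
               ignore_attr = TRUE)

  z2 <- build_cyclic(2)
  expect_length(z2$elements, 2L)
  expect_identical(z2$elements[[2]]$map, c(2L, 1L))

  z5 <- build_cyclic(5)
  expect_length(z5$elements, 5L)
  for (p in z5$elements[-1]) expect_false(any(p$map == 1:5))

  # a double transposition is not a 4-cycle: rejected as generator
  expect_error(
    build_cyclic(4, cycle = perm(c(2L, 1L, 4L, 3L), DNA)),
    "full 4-cycle")
})

test_that("direct products act on the product alphabet", {
  z2 <- osm_group_preset("Z2")
  prod22 <- build_product(list(z2, z2), letters = DNA)
  expect_length(prod22$elements, 4L)
  expect_setequal(vapply(prod22$elements, function(p) paste(p$map, collapse = ","), ""),
                  vapply(k3st$elements, function(p) paste(p$map, collapse = ","), ""))

  z4c <- build_cyclic(4); z5c <- build_cyclic(5)
  p20 <- build_product(list(z4c, z5c))
  expect_length(p20$elements, 20L)
  expect_true(conditions_pass(check_conditions(p20)))

  single <- build_product(list(z2))
  expect_length(single$elements, 2L)

  expect_error(build_product(list()), "empty")
})

test_that("condition checks accept regular Abelian groups and flag sGTR", {
  expect_true(conditions_pass(check_conditions(k3st)))
  expect_true(conditions_pass(check_conditions(z4)))

  rep <- check_conditions(sgtr_permutation_set())
  expect_false(rep$C3$pass)
  expect_true(any(rep$C3$witnesses$a == "sa" & rep$C3$witnesses$b == "sf"))
  expect_false(rep$C4$pass)
  expect_true(any(rep$C4$witnesses$a == "sa" & rep$C4$witnesses$b == "sc"))
  expect_false(rep$C5$pass)
  expect_setequal(rep$C5$witnesses$element,
                  c("sa", "sb", "sc", "sd", "se", "sf"))
  expect_true(rep$C1$pass)
  expect_true(rep$C6$pass)
  expect_true(rep$C7$pass)

  triv <- check_conditions(list(perm_identity("A")))
  expect_true(conditions_pass(triv))
})

test_that("transformer returns the unique regular-action element", {
  expect_identical(transformer(k3st, "G", "A")$label, "s1")
  expect_identical(transformer(z4, "G", "A")$label, "s'3")

  set.seed(3)
  for (g in list(k3st, z4, build_cyclic(5))) {
    for (x in g$letters) {
      expect_identical(transformer(g, x, x)$map, seq_along(g$letters))
      for (y in g$letters) {
        tf <- transformer(g, x, y)
        expect_identical(perm_apply(tf, x), y)
        expect_identical(perm_apply(perm_inverse(tf), y), x)
      }
    }
  }

  sgtr <- osm_group(sgtr_permutation_set(), DNA, validate = FALSE)
  expect_error(transformer(sgtr, "A", "A"), "regular")
})

test_that("four-cycle enumeration collapses six cycles into three groups", {
  e <- enumerate_four_cycle_groups()
  expect_identical(e$count_cycles, 6L)
  expect_identical(e$distinct_groups, 3L)
  expect_identical(as.integer(table(e$class_of)), rep(2L, 3L))
  expect_error(enumerate_four_cycle_groups(c("0", "1")), "4 states")
})

test_that("construction enumeration lists unordered factorizations", {
  f20 <- enumerate_constructions(20)
  expect_length(f20, 4L)
  expect_setequal(vapply(f20, function(x) paste(sort(x), collapse = "x"), ""),
                  c("20", "2x10", "4x5", "2x2x5"))

  f4 <- enumerate_constructions(4)
  expect_length(f4, 2L)

  expect_length(enumerate_constructions(2), 1L)
  expect_error(enumerate_constructions(1), "at least 2")

  # Z20 and Z4xZ5 are abstractly isomorphic; Z2xZ10 and Z2x2x5 likewise
  cls <- reduce_isomorphism_classes(f20)
  expect_length(cls, 2L)
})

test_that("coset partitions are orbit blocks of subgroup size", {
  g20 <- parse_group_spec("Z2xZ2xZ5")
  z5 <- subgroup_generated(g20, "g1")
  expect_length(z5$elements, 5L)
  cp <- coset_partition(g20, z5)
  expect_length(cp, 4L)
  expect_true(all(lengths(cp) == 5L))
  expect_setequal(unlist(cp), g20$letters)

  triv <- subgroup_generated(k3st, "s0")
  expect_identical(lengths(coset_partition(k3st, triv)), rep(1L, 4L))

  first_factor <- subgroup_generated(k3st, "s1")
  blocks <- coset_partition(k3st, first_factor)
  expect_length(blocks, 2L)
  expect_true(all(lengths(blocks) == 2L))
  expect_true(any(vapply(blocks, function(b) setequal(b, c("A", "G")), TRUE)))

  expect_error(
    coset_partition(k3st, subgroup_generated(z4, "s'1")),
    "not contained")
})

test_that("group spec mini-language parses presets, cycles and products", {
  expect_identical(parse_group_spec("K3ST")$name, "K3ST")
  expect_identical(parse_group_spec("Z4")$elements[[2]]$label, "s'1")
  expect_identical(perm_apply(parse_group_spec("Z4:A>C>G>T>A")$elements[[2]],
                              "A"), "C")
  expect_length(parse_group_spec("Z4xZ5")$elements, 20L)
  expect_identical(parse_group_spec("Z20")$name, "Z20")
  expect_length(parse_group_spec("Z2xZ2xZ5")$elements, 20L)

  cyc <- parse_group_spec("cycles:(A G)(C T);(A C)(G T);(A T)(C G)",
                          letters = DNA)
  expect_true(conditions_pass(check_conditions(cyc)))

  expect_error(parse_group_spec("Q8"), "parse")
})

test_that("every cyclic and product construction up to 20 is a regular Abelian group", {
  for (r in 2:20) {
    for (fs in enumerate_constructions(r)) {
      g <- if (length(fs) == 1L) build_cyclic(fs) else
        build_product(lapply(fs, build_cyclic))
      expect_length(g$elements, r)
      expect_true(conditions_pass(check_conditions(g)))
    }
  }
})
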