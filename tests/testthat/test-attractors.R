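test_that("attractor search from a start state finds cycle and transient", {
  swap <- boolean_network(c(A = "B", B = "A"))
  res <- find_attractor_from(swap, c(0, 1))
  expect_equal(res$attractor$length, 2L)
  expect_equal(res$transient, 0L)
  expect_setequal(res$attractor$codes, c(1, 2))

  const <- boolean_network(c(A = "1", B = "0"))
  res2 <- find_attractor_from(const, c(0, 1))
  expect_equal(res2$attractor$length, 1L)
  expect_lte(res2$transient, 1L)

  # start on a fixed point: zero transient
  ident <- boolean_network(c(A = "A", B = "B"))
  res3 <- find_attractor_from(ident, c(1, 1))
  expect_equal(res3$transient, 0L)
  expect_equal(res3$attractor$codes, 3)
})

test_that("exhaustive enumeration partitions the full state space", {
  swap <- boolean_network(c(A = "B", B = "A"))
  ls <- exhaustive_attractors(swap)
  expect_true(ls$exact)
  expect_equal(sum(ls$basin_counts), 4)
  expect_setequal(ls$basin_counts, c(1, 1, 2))
  expect_same_landscape(ls, oracle_exhaustive(swap))

  ident <- boolean_network(c(A = "A", B = "B", C = "C"))
  li <- exhaustive_attractors(ident)
  expect_equal(length(li$attractors), 8L)
  expect_true(all(li$basin_counts == 1))

  # partition property on random networks, against the brute-force oracle
  set.seed(31)
  for (rep in 1:8) {
    net <- random_nk_network(7, sample(1:3, 7, TRUE))
    ls <- exhaustive_attractors(net)
    expect_equal(sum(ls$basin_counts), 2^7)
    expect_same_landscape(ls, oracle_exhaustive(net))
  }

  big <- random_nk_network(25, 2, seed = 1)
  expect_error(exhaustive_attractors(big), "sampled_attractors")
})

test_that("sampling recovers the exhaustive landscape on small networks", {
  swap <- boolean_network(c(A = "B", B = "A"))
  ls <- sampled_attractors(swap, 1e5, seed = 42)
  expect_false(ls$exact)
  o <- order(landscape_keys(ls))
  expect_equal(sum(ls$basin_ratios), 1)
  ratios <- ls$basin_ratios[match(c("0", "3", "1,2"), landscape_keys(ls))]
  expect_equal(ratios, c(0.25, 0.25, 0.5), tolerance = 0.05)

  single <- sampled_attractors(swap, 1, seed = 3)
  expect_equal(length(single$attractors), 1L)
  expect_equal(single$basin_ratios, 1)

  # determinism under an identical seed
  a <- sampled_attractors(swap, 1000, seed = 9)
  b <- sampled_attractors(swap, 1000, seed = 9)
  expect_identical(landscape_keys(a), landscape_keys(b))
  expect_identical(a$basin_counts, b$basin_counts)
})

test_that("a cycle entered at different states canonicalizes identically", {
  ring <- boolean_network(c(A = "C", B = "A", C = "B"))
  keys <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(s)
    find_attractor_from(ring, s)$attractor$canonical_key, "")
  expect_length(unique(keys), 1L)
})

test_that("landscape fusion averages activity weighted by basin ratio", {
  # single fixed point: activities equal its bits
  const <- boolean_network(c(A = "1", B = "0"))
  expect_equal(fuse_landscape(exhaustive_attractors(const)),
               c(A = 1, B = 0))
  # two equal fixed points, node ON in exactly one -> 0.5
  ident <- boolean_network(c(A = "A"))
  expect_equal(fuse_landscape(exhaustive_attractors(ident)), c(A = 0.5))
  # 2-cycle with node ON in one of two states -> 0.5
  swap2 <- boolean_network(c(A = "!A"))
  expect_equal(fuse_landscape(exhaustive_attractors(swap2)), c(A = 0.5))
  # invariance to attractor ordering
  set.seed(5)
  net <- random_nk_network(6, 2)
  ls <- exhaustive_attractors(net)
  perm <- sample(seq_along(ls$attractors))
  ls2 <- ls
  ls2$attractors <- ls$attractors[perm]
  ls2$basin_ratios <- ls$basin_ratios[perm]
  ls2$basin_counts <- ls$basin_counts[perm]
  expect_equal(fuse_landscape(ls2), fuse_landscape(ls))
})

test_that("phenotype classification follows the indicator definitions", {
  ind <- cll_indicators()
  nodes <- c("Anergy", "SPhase", "Apoptosis", "CCND1", "CCNE1")
  mk <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    colnames(m) <- nodes
    structure(list(codes = apply(m, 1, state_to_index), states = m,
                   length = nrow(m),
                   canonical_key = "x"), class = "attractor")
  }
  expect_equal(classify_phenotype(mk(c(1, 0, 0, 0, 0)), ind)$label, "anergy")
  expect_equal(classify_phenotype(mk(c(0, 1, 0, 1, 1)), ind)$label,
               "proliferation")
  expect_equal(classify_phenotype(mk(c(0, 0, 1, 0, 0)), ind)$label, "apoptosis")
  expect_equal(classify_phenotype(mk(c(0, 0, 0, 1, 1)), ind)$label,
               "cell_cycle_alert")
  expect_equal(classify_phenotype(mk(c(0, 0, 0, 0, 0)), ind)$label,
               "quiescent_G0")
  # precedence: apoptosis beats proliferation within one state
  expect_equal(classify_phenotype(mk(c(0, 1, 1, 1, 1)), ind)$label, "apoptosis")
  # heterogeneous cycles are mixed, with a precedence-dominant label
  call <- classify_phenotype(mk(c(1, 0, 0, 0, 0), c(0, 1, 0, 1, 1)), ind)
  expect_equal(call$label, "mixed")
  expect_equal(call$dominant, "proliferation")
  expect_equal(call$indicator_fractions[["s_phase"]], 0.5)
  expect_error(classify_phenotype(mk(c(1, 0, 0, 0, 0)),
                                  c(ind[-1], anergy = "NOPE")), "NOPE")
})

test_that("phenotype fractions are basin-weighted and sum to one", {
  rules <- c(NFAT = "NFAT", NFKB = "0", AKT = "0",
             CCND1 = "0", CCNE1 = "0", E2F = "0",
             SPhase = "0", Apoptosis = "0",
             Anergy = "NFAT & !NFKB & !AKT & !SPhase")
  net <- boolean_network(rules)
  ls <- exhaustive_attractors(net)
  fr <- phenotype_fractions(ls)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["anergy"]), 0.5)
  expect_equal(unname(fr["quiescent_G0"]), 0.5)
})
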