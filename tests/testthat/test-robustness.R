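test_that("normalized Hamming distance behaves like a scaled metric", {
  x <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  expect_equal(normalized_hamming(x, x), 0)
  expect_equal(normalized_hamming(x, 1 - x), 1)
  y <- x; y[3] <- 1 - y[3]
  expect_equal(normalized_hamming(x, y), 0.1)
  expect_error(normalized_hamming(x, x[-1]), "lengths differ")
  # triangle inequality on random triples
  set.seed(8)
  for (i in 1:20) {
    a <- random_state(12); b <- random_state(12); c <- random_state(12)
    expect_lte(normalized_hamming(a, c),
               normalized_hamming(a, b) + normalized_hamming(b, c) + 1e-12)
  }
})

test_that("bit-flip response matches hand-derivable networks", {
  const <- boolean_network(c(A = "1", B = "0", C = "1"))
  expect_true(all(bitflip_response(const, 200, seed = 1) == 0))
  ident <- boolean_network(c(A = "A", B = "B", C = "C", D = "D"))
  expect_true(all(bitflip_response(ident, 200, seed = 2) == 0.25))
  swap <- boolean_network(c(A = "B", B = "A"))
  expect_true(all(bitflip_response(swap, 200, seed = 3) == 0.5))
})

test_that("random N-K networks have the requested structure", {
  net <- random_nk_network(5, 2, seed = 10)
  expect_true(all(vapply(net$regulators, length, integer(1)) == 2L))
  # drawn in-degrees survive even when a truth table is constant
  net_k <- random_nk_network(12, c(0, 1, 2, 3, rep(2, 8)), seed = 11)
  deg <- degree_distribution(net_k)
  expect_equal(deg$in_degree, c(0L, 1L, 2L, 3L, rep(2L, 8)))
  expect_true(networks_equal(random_nk_network(6, 2, seed = 12),
                             random_nk_network(6, 2, seed = 12)))
  expect_error(random_nk_network(4, 5), "exceed")
  # truth tables are fair coin flips
  set.seed(13)
  bits <- unlist(lapply(1:300, function(i)
    random_nk_network(4, 2)$truth))
  frac <- mean(unlist(bits))
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("degree bookkeeping matches hand counts and the handshake identity", {
  swap <- boolean_network(c(A = "B", B = "A"))
  d <- degree_distribution(swap)
  expect_equal(d$in_degree, c(1, 1))
  expect_equal(d$out_degree, c(1, 1))
  expect_equal(d$total_degree, c(2, 2))
  net <- boolean_network(c(A = "1", B = "A & C", C = "A | !C"))
  d2 <- degree_distribution(net)
  expect_equal(d2$in_degree[d2$node == "A"], 0L)
  expect_equal(sum(d2$in_degree), sum(d2$out_degree))
})

test_that("robustness test ranks a maximally stable network as significant", {
  const <- boolean_network(setNames(rep("1", 8), paste0("N", 1:8)))
  # compare against nulls with nontrivial in-degrees
  res <- robustness_test(const, n_networks = 60, n_states = 100,
                         seed = 14, k = 2)
  expect_equal(res$observed, 0)
  expect_lte(res$p_value, 0.05)
  expect_true(res$q05 >= 0)
})

test_that("robustness p-value is invariant to node relabeling", {
  net <- random_nk_network(8, 2, seed = 20)
  relab <- net
  perm <- c(3, 1, 2, 5, 4, 7, 8, 6)
  relab$nodes <- net$nodes[perm]
  names(relab$functions) <- relab$nodes
  r1 <- robustness_test(net, n_networks = 40, n_states = 100, seed = 5)
  r2 <- robustness_test(relab, n_networks = 40, n_states = 100, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  # single null network: uncorrected p is 0 or 1
  r3 <- robustness_test(net, n_networks = 1, n_states = 50, seed = 6)
  expect_true(r3$p_uncorrected %in% c(0, 1))
})
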