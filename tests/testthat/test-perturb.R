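test_that("interventions clamp nodes without touching the original network", {
  net <- boolean_network(c(A = "A", B = "A"))
  ko <- apply_interventions(net, intervention(A = 0))
  for (code in 0:3)
    expect_identical(unname(synchronous_step(ko, index_to_state(code, 2))["A"]),
                     0L)
  expect_true(all(is.na(net$fixed)))
  expect_error(intervention(values = c(A = 1, A = 0)), "conflicting")
  expect_error(apply_interventions(net, intervention(Z = 1)), "Z")
  # releasing nothing: empty interventions are rejected as meaningless
  expect_error(intervention(), "at least one")
})

test_that("intervention enumeration matches the closed form", {
  expect_equal(n_interventions(49, 2), 4802)
  expect_lte(n_interventions(49, 2), 5000)
  expect_equal(length(enumerate_interventions(1, 1)), 2L)
  expect_equal(length(enumerate_interventions(5, 2)), 50L)
  # brute-force cross-check of the count law and uniqueness
  for (c_ in c(3, 5, 7)) {
    for (m in 1:min(c_, 3)) {
      ivs <- enumerate_interventions(c_, m)
      expect_equal(length(ivs), n_interventions(c_, m))
      sig <- vapply(ivs, function(iv)
        paste(sort(paste(names(iv), iv, sep = "=")), collapse = ";"), "")
      expect_equal(anyDuplicated(sig), 0L)
    }
  }
  # deterministic order
  expect_identical(
    vapply(enumerate_interventions(c("X", "Y"), 2), function(iv)
      paste(names(iv), iv, sep = "=", collapse = ","), ""),
    c("X=0", "X=1", "Y=0", "Y=1",
      "X=0,Y=0", "X=1,Y=0", "X=0,Y=1", "X=1,Y=1"))
  expect_error(enumerate_interventions(3, 4), "m must")
})

test_that("screening returns exactly the interventions meeting the criteria", {
  net <- boolean_network(c(R = "R", T = "!R"))
  res <- screen_interventions(net, screen_criteria(node_constraints = c(T = 1)),
                              m = 1, basin_method = "exhaustive")
  expect_setequal(res$intervention, c("R:KO", "T:KI"))
  # unconstrained criteria accept every candidate
  res_all <- screen_interventions(net, screen_criteria(), m = 2,
                                  basin_method = "exhaustive")
  expect_equal(nrow(res_all), n_interventions(2, 2))
  # single-hit results are a subset of the two-hit candidate set
  sigs2 <- vapply(enumerate_interventions(c("R", "T"), 2), function(iv)
    paste(names(iv), iv, sep = "=", collapse = ","), "")
  sigs1 <- vapply(enumerate_interventions(c("R", "T"), 1), function(iv)
    paste(names(iv), iv, sep = "=", collapse = ","), "")
  expect_true(all(sigs1 %in% sigs2))
})

test_that("inconsistent criteria are rejected", {
  expect_error(screen_criteria(forbidden_phenotypes = "anergy",
                               required_phenotype = list(label = "anergy",
                                                         min_fraction = 0.5)),
               "both required and forbidden")
  expect_error(screen_criteria(forbidden_phenotypes = "nonsense"), "unknown")
})

test_that("exhaustive and sampled screening agree on small networks", {
  rules <- c(NFAT = "NFAT", NFKB = "0", AKT = "AKT",
             CCND1 = "AKT", CCNE1 = "AKT", E2F = "CCND1",
             SPhase = "E2F & CCNE1", Apoptosis = "0",
             Anergy = "NFAT & !NFKB & !AKT & !SPhase")
  net <- boolean_network(rules)
  crit <- screen_criteria(forbidden_phenotypes = "anergy",
                          node_constraints = c(SPhase = 1))
  cand <- c("NFAT", "AKT", "NFKB")
  ex <- screen_interventions(net, crit, m = 2, candidates = cand,
                             basin_method = "exhaustive")
  sm <- screen_interventions(net, crit, m = 2, candidates = cand,
                             basin_method = "sampled", n_samples = 1e4,
                             seed = 77)
  expect_setequal(ex$intervention, sm$intervention)
  expect_true(all(grepl("AKT:KI", ex$intervention)))
})
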