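test_that("toy fixtures ship their own exhaustive ground truth", {
  toys <- toy_networks()
  swap_ls <- toys$swap$landscape
  expect_setequal(swap_ls$basin_counts, c(1, 1, 2))
  expect_equal(sum(toys$constant$landscape$basin_counts), 2^3)
  expect_equal(length(toys$constant$landscape$attractors), 1L)
  for (nm in names(toys)) {
    fresh <- exhaustive_attractors(toys[[nm]]$network)
    expect_identical(landscape_keys(fresh),
                     landscape_keys(toys[[nm]]$landscape))
    expect_identical(fresh$basin_counts, toys[[nm]]$landscape$basin_counts)
  }
})

test_that("random states are uniform and reproducible", {
  expect_identical(random_state(20, seed = 1), random_state(20, seed = 1))
  expect_length(random_state(7), 7L)
  set.seed(2)
  frac <- mean(replicate(2000, random_state(1)))
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("the reconstruction declares its nodes, rules and provenance", {
  card <- reconstructed_cll_network()
  net <- card$network
  expect_equal(length(net$nodes), 39L)
  expect_true(all(c("BCR", "TME", "NFAT", "AKT", "TP53", "MYC", "BMI1",
                    "SPhase", "Apoptosis", "Anergy") %in% net$nodes))
  expect_setequal(names(card$provenance), net$nodes)
  # the rule file round-trips
  expect_true(networks_equal(net, parse_network(serialize_network(net))))
  # indicator logic: S phase requires E2F and CCNE1 jointly
  expect_identical(sort(net$nodes[net$regulators[[match("SPhase", net$nodes)]]]),
                   c("CCNE1", "E2F"))
})

test_that("unperturbed CLL is anergic with the described marker profile", {
  card <- reconstructed_cll_network()
  net <- apply_interventions(card$network, cll_scenarios()$cll)
  tr <- trajectory(net, bcr_start_state(net))
  expect_equal(tr$phenotype$label, "anergy")
  fp <- tr$attractor$states[1, ]
  expect_equal(unname(fp[c("NFAT", "CD5", "SHP1", "ERK", "PTEN",
                           "CDKN1A", "CDKN2B")]),
               rep(1L, 7))
  expect_equal(unname(fp[c("AKT", "NFKB", "SYK", "MYC", "SPhase",
                           "Apoptosis")]),
               rep(0L, 6))
})

test_that("IgM withdrawal turns the landscape apoptotic, rescued by BCL2", {
  card <- reconstructed_cll_network()
  ls <- simulate_cll_scenario("igm_ko", n_samples = 5000, seed = 71,
                              card = card)
  fr <- phenotype_fractions(ls, use_dominant = TRUE)
  expect_equal(unname(fr["apoptosis"]), 1)
  ls2 <- simulate_cll_scenario("igm_ko_bcl2_ki", n_samples = 5000, seed = 72,
                               card = card)
  f2 <- fuse_landscape(ls2)
  expect_equal(unname(f2["Apoptosis"]), 0)
  expect_equal(unname(f2["SPhase"]), 0)
})

test_that("synthetic expression matrices honor their specification", {
  sx <- synth_expression(n_genes = 50, n_cells = 200, dropout = 0.25,
                         n_flat = 5, seed = 73)
  expect_equal(dim(sx$matrix), c(50L, 200L))
  expect_true(all(sx$matrix >= 0))
  expect_length(sx$flat_genes, 5L)
  expect_true(all(sx$matrix[sx$flat_genes, ] == 0))
  # observed zero fraction among live genes matches the dropout rate
  live <- setdiff(rownames(sx$matrix), sx$flat_genes)
  zfrac <- mean(sx$matrix[live, ] == 0)
  expect_lt(abs(zfrac - 0.25), 0.02)
  # dropout cells retain their mode label in the truth matrix
  expect_true(any(sx$truth[sx$dropped] == 1))
  # reproducibility
  sx2 <- synth_expression(n_genes = 50, n_cells = 200, dropout = 0.25,
                          n_flat = 5, seed = 73)
  expect_identical(sx$matrix, sx2$matrix)
  # planted named genes with their own mixing fractions
  sp <- synth_expression(n_genes = 40, n_cells = 300, seed = 74,
                         planted = c(TP53 = 0.9, MYC = 0.05))
  expect_true(all(c("TP53", "MYC") %in% rownames(sp$matrix)))
  expect_gt(mean(sp$truth["TP53", ]), 0.8)
  expect_lt(mean(sp$truth["MYC", ]), 0.15)
})

test_that("fixture export writes a re-loadable bundle", {
  dir <- tempfile("fixtures")
  export_fixtures(dir, seed = 75)
  expect_true(file.exists(file.path(dir, "cll_rs_model.bn")))
  net <- read_network(file.path(dir, "cll_rs_model.bn"))
  expect_true(networks_equal(net, reconstructed_cll_network()$network))
  m <- read_expression_tsv(file.path(dir, "synthetic_expression.tsv"))
  mm <- read_expression_mtx(file.path(dir, "synthetic_expression.mtx"),
                            file.path(dir, "genes.tsv"),
                            file.path(dir, "barcodes.tsv"))
  expect_equal(dim(m), dim(mm))
  expect_equal(unname(as.matrix(mm)), unname(m), tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
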