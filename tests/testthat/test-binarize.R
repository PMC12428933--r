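test_that("a clean two-level vector binarizes at the separating gap", {
  bb <- basca_binarize(c(1, 1, 1, 10, 10, 10), seed = 1)
  expect_gt(bb$threshold, 1)
  expect_lt(bb$threshold, 10)
  expect_identical(bb$binary, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_true(bb$significant)
  # order of the input does not matter for the calls
  v <- c(10, 1, 10, 1, 1, 10)
  expect_identical(basca_binarize(v, seed = 1)$binary, c(1L, 0L, 1L, 0L, 0L, 1L))
})

test_that("a featureless ramp is not called significant", {
  set.seed(2)
  pvals <- vapply(1:10, function(i) basca_binarize(1:20)$p_value, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("degenerate inputs are rejected", {
  expect_error(basca_binarize(c(2, 2, 2, 2)), "degenerate")
  expect_error(basca_binarize(c(1, 2)), "at least 3")
  expect_error(basca_binarize(c(1, NA, 3)), "finite")
})

test_that("binarization is monotone and duplication-invariant", {
  base <- c(1, 1.2, 0.9, 8, 9, 8.5, 1.1, 9.5)
  bb <- basca_binarize(base, seed = 3)
  # raising one value never flips another sample's call
  raised <- base; raised[1] <- 1.6
  bb2 <- basca_binarize(raised, seed = 3)
  expect_identical(bb$binary[-1], bb2$binary[-1])
  # duplicating every value leaves the separating interval unchanged
  bb3 <- basca_binarize(rep(base, each = 2), seed = 3)
  expect_gt(bb3$threshold, max(base[base < 5]))
  expect_lt(bb3$threshold, min(base[base > 5]))
})

test_that("matrix binarization excludes flat genes and matches row-wise calls", {
  m <- rbind(Gz = rep(0, 30),
             Gc = rep(2, 30),
             Gb = c(rep(1, 15), rep(20, 15)))
  colnames(m) <- paste0("C", 1:30)
  br <- binarize_matrix(m, seed = 4)
  expect_identical(br$reason[["Gz"]], "all_zero")
  expect_identical(br$reason[["Gc"]], "not_significant")
  expect_false(br$excluded[["Gb"]])
  single <- basca_binarize(log1p(m["Gb", ]), seed = (4 + 3 * 7919) %% 2147483647,
                           d_max = 30)
  expect_identical(unname(br$binary["Gb", ]), single$binary)
})

test_that("planted bimodal structure is recovered from sparse synthetic data", {
  sx <- synth_expression(n_genes = 60, n_cells = 250, seed = 5)
  br <- binarize_matrix(sx$matrix, seed = 6)
  expect_setequal(names(which(br$reason == "all_zero")), sx$flat_genes)
  g <- rownames(br$binary)
  observed <- !sx$dropped[g, , drop = FALSE]
  acc <- mean((br$binary == sx$truth[g, , drop = FALSE])[observed])
  expect_gte(acc, 0.95)
})

test_that("proliferative cells are selected by the cyclin OR-signature", {
  bin <- matrix(0L, 6, 4,
                dimnames = list(c("CCNE1", "CCNE2", "CCND1", "CCND2", "CCND3",
                                  "OTHER"),
                                paste0("C", 1:4)))
  bin["CCND2", 2] <- 1L
  bin[c("CCNE1", "CCND1"), 3] <- 1L
  bin["OTHER", 4] <- 1L
  br <- structure(list(binary = bin, cells = colnames(bin),
                       excluded = setNames(rep(FALSE, 6), rownames(bin))),
                  class = "binarization_result")
  expect_identical(select_proliferative_cells(br), c("C2", "C3"))
  br_no <- br
  rownames(br_no$binary) <- paste0("X", 1:6)
  expect_error(select_proliferative_cells(br_no), "no cyclin")
})

test_that("concordance calls match iff both sides cross the 30% threshold", {
  bin <- rbind(NOTCH1 = c(1L, 1L, 0L, 0L), NOTCH2 = c(0L, 1L, 0L, 0L),
               TP53 = c(0L, 0L, 0L, 1L), MYC = c(0L, 0L, 0L, 0L))
  colnames(bin) <- paste0("C", 1:4)
  br <- structure(list(binary = bin, cells = colnames(bin)),
                  class = "binarization_result")
  map <- list(NOTCH1 = c("NOTCH1", "NOTCH2"), TP53 = "TP53", MYC = "MYC")
  act <- c(NOTCH1 = 1.0, TP53 = 0.0, MYC = 0.6)
  cc <- concordance(act, br, map)
  # NOTCH group: OR -> 50% data vs 100% model: both active -> match
  expect_true(cc$match[cc$node == "NOTCH1"])
  # TP53: 25% vs 0%: both inactive -> match
  expect_true(cc$match[cc$node == "TP53"])
  # MYC: 0% data vs 60% model -> mismatch
  expect_false(cc$match[cc$node == "MYC"])
  # threshold-crossing symmetry: the match decision only depends on which
  # side of the threshold each fraction falls
  expect_equal(cc$match,
               (cc$data_fraction >= 0.3) == (cc$model_fraction >= 0.3))
  expect_error(concordance(act[-3], br, map), "MYC")
})

test_that("ROC binarization maximizes Youden's J with deterministic ties", {
  r <- roc_binarize(c(1, 2, 3, 8, 9), c("A", "A", "A", "B", "B"))
  expect_equal(r$threshold, 5.5)
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # identical distributions: J = 0, smallest candidate returned
  r0 <- roc_binarize(c(1, 2, 1, 2), c("A", "A", "B", "B"))
  expect_equal(r0$youden, 0)
  expect_equal(r0$threshold, 1.5)
  expect_error(roc_binarize(1:4, rep("A", 4)), "two classes")
})

test_that("ROC sweep agrees with the pROC reference on interleaved scores", {
  set.seed(7)
  scores <- c(rnorm(40, 1), rnorm(40, 2.2))
  labels <- rep(c("ctl", "case"), each = 40)
  mine <- roc_binarize(scores, labels, positive = "case")
  ref <- pROC::roc(labels, scores, levels = c("ctl", "case"),
                   direction = "<", quiet = TRUE)
  best <- pROC::coords(ref, "best", best.method = "youden", transpose = FALSE)
  expect_equal(mine$sensitivity + mine$specificity,
               best$sensitivity[1] + best$specificity[1], tolerance = 1e-9)
})
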