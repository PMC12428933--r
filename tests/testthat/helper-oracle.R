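# Independent reference implementations used as oracles.  These evaluate
# the rule text directly with R's own parser/evaluator and enumerate state
# spaces by brute force, sharing no code path with the package's compiled
# truth-table dynamics.

oracle_step <- function(net, state) {
  env <- as.list(setNames(as.logical(state), net$nodes))
  out <- vapply(seq_along(net$nodes), function(i) {
    if (!is.na(net$fixed[i])) return(as.integer(net$fixed[i]))
    txt <- gsub("\\bAND\\b", "&", net$functions[i], ignore.case = TRUE)
    txt <- gsub("\\bOR\\b", "|", txt, ignore.case = TRUE)
    txt <- gsub("\\bNOT\\b", "!", txt, ignore.case = TRUE)
    val <- eval(parse(text = txt), envir = env)
    as.integer(as.logical(val))
  }, integer(1))
  setNames(out, net$nodes)
}

oracle_code <- function(bits) sum(as.numeric(bits) * 2^(seq_along(bits) - 1))

oracle_bits <- function(code, n) as.integer(floor(code / 2^(0:(n - 1))) %% 2)

# full brute-force landscape: every state walked to its cycle
oracle_exhaustive <- function(net) {
  n <- length(net$nodes)
  stopifnot(n <= 12)
  succ <- vapply(0:(2^n - 1), function(code) {
    oracle_code(oracle_step(net, oracle_bits(code, n)))
  }, numeric(1))
  label <- rep(NA_integer_, 2^n)
  cycles <- list()
  for (s0 in 0:(2^n - 1)) {
    if (!is.na(label[s0 + 1])) next
    path <- integer(0)
    cur <- s0
    while (is.na(label[cur + 1]) && !(cur %in% path)) {
      path <- c(path, cur)
      cur <- succ[cur + 1]
    }
    if (cur %in% path) {
      cyc <- path[seq(match(cur, path), length(path))]
      rot <- which.min(cyc)
      cyc <- cyc[c(seq(rot, length(cyc)), seq_len(rot - 1))]
      cycles[[length(cycles) + 1]] <- cyc
      attr_id <- length(cycles)
    } else {
      attr_id <- label[cur + 1]
    }
    label[path + 1] <- attr_id
  }
  basin <- tabulate(label, nbins = length(cycles))
  keys <- vapply(cycles, function(cc) paste(cc, collapse = ","), "")
  list(cycles = cycles, basin = basin, keys = keys)
}

landscape_keys <- function(landscape)
  vapply(landscape$attractors, `[[`, "", "canonical_key")

expect_same_landscape <- function(landscape, oracle, tol = 0) {
  keys <- landscape_keys(landscape)
  expect_setequal(keys, oracle$keys)
  o <- match(keys, oracle$keys)
  if (landscape$exact) {
    expect_equal(landscape$basin_counts, oracle$basin[o])
  } else {
    expect_true(all(abs(landscape$basin_ratios -
                          oracle$basin[o] / sum(oracle$basin)) <= tol))
  }
}
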