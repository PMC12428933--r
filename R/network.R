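# Boolean network representation -------------------------------------------
#
# A `boolean_network` is a list with:
#   nodes      character vector of unique node names (declaration order;
#              node 1 is the least-significant bit of integer state codes)
#   functions  named character vector of Boolean expressions over node names
#              using & | ! ( ) and the constants 0/1
#   exprs      parsed expression trees (internal)
#   regulators list of integer vectors: distinct nodes referenced by each
#              function, in order of first appearance
#   truth      list of integer truth tables (length 2^k; regulator j is
#              bit j-1 of the table index)
#   fixed      integer vector, NA = free, 0/1 = clamped (KO/KI)

# --- expression trees ------------------------------------------------------

.tokenize_expr <- function(text) {
  pat <- "\\s*([A-Za-z_.][A-Za-z0-9_.-]*|[01]|&{1,2}|\\|{1,2}|!|\\(|\\))\\s*"
  out <- character(0)
  rest <- text
  while (nzchar(trimws(rest))) {
    m <- regexpr(pat, rest)
    if (m != 1L)
      stop("cannot tokenize expression near: ", sQuote(trimws(rest)), call. = FALSE)
    tok <- trimws(regmatches(rest, m))
    rest <- substring(rest, attr(m, "match.length") + 1L)
    up <- toupper(tok)
    if (up == "AND" || tok == "&&") tok <- "&"
    else if (up == "OR" || tok == "||") tok <- "|"
    else if (up == "NOT") tok <- "!"
    out <- c(out, tok)
  }
  out
}

# recursive-descent parser: expr := term ('|' term)*
#                           term := factor ('&' factor)*
#                           factor := '!' factor | '(' expr ')' | name | 0 | 1
.parse_tokens <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  parse_expr <- function() {
    args <- list(parse_term())
    while (identical(peek(), "|")) { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "&")) { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- take()
    if (is.na(tok)) stop("unexpected end of expression", call. = FALSE)
    if (tok == "!") return(list(op = "not", args = list(parse_factor())))
    if (tok == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("missing closing parenthesis", call. = FALSE)
      return(e)
    }
    if (tok %in% c("0", "1")) return(list(op = "const", value = as.integer(tok)))
    if (tok %in% c(")", "&", "|"))
      stop("unexpected token ", sQuote(tok), " in expression", call. = FALSE)
    list(op = "var", name = tok)
  }
  out <- parse_expr()
  if (pos <= length(tokens))
    stop("trailing tokens in expression: ", paste(tokens[pos:length(tokens)], collapse = " "),
         call. = FALSE)
  out
}

.parse_expr_text <- function(text) {
  if (!nzchar(trimws(text))) stop("empty expression", call. = FALSE)
  .parse_tokens(.tokenize_expr(text))
}

.expr_vars <- function(tree) {
  if (tree$op == "var") return(tree$name)
  if (tree$op == "const") return(character(0))
  unique(unlist(lapply(tree$args, .expr_vars), use.names = FALSE))
}

# evaluate a tree under a named logical/integer assignment (vectorized)
.eval_expr <- function(tree, assign) {
  switch(tree$op,
    var = as.logical(assign[[tree$name]]),
    const = rep(as.logical(tree$value),
                if (length(assign)) length(assign[[1L]]) else 1L),
    not = !.eval_expr(tree$args[[1L]], assign),
    and = Reduce(`&`, lapply(tree$args, .eval_expr, assign = assign)),
    or = Reduce(`|`, lapply(tree$args, .eval_expr, assign = assign)),
    stop("unknown expression node")
  )
}

.deparse_expr <- function(tree, parent = "or") {
  out <- switch(tree$op,
    var = tree$name,
    const = as.character(tree$value),
    not = {
      a <- tree$args[[1L]]
      body <- .deparse_expr(a, parent = "not")
      if (a$op %in% c("and", "or")) paste0("!(", body, ")") else paste0("!", body)
    },
    and = paste(vapply(tree$args, .deparse_expr, "", parent = "and"), collapse = " & "),
    or = paste(vapply(tree$args, .deparse_expr, "", parent = "or"), collapse = " | ")
  )
  if (tree$op == "or" && parent == "and") out <- paste0("(", out, ")")
  out
}

# build the truth table for one parsed function
.truth_table <- function(tree, regulators, nodes) {
  k <- length(regulators)
  if (k == 0L) {
    val <- .eval_expr(tree, list())
    return(as.integer(val[1L]))
  }
  if (k > 20L)
    stop("function with more than 20 distinct regulators is not supported")
  combos <- 0:(2L^k - 1L)
  assign <- list()
  for (j in seq_len(k))
    assign[[nodes[regulators[j]]]] <- bitwAnd(bitwShiftR(combos, j - 1L), 1L)
  as.integer(.eval_expr(tree, assign))
}

.compile_network <- function(net) {
  nodes <- net$nodes
  net$regulators <- lapply(net$exprs, function(tr) {
    vars <- .expr_vars(tr)
    idx <- match(vars, nodes)
    if (anyNA(idx))
      stop("undeclared node(s) referenced: ",
           paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  })
  net$truth <- mapply(function(tr, reg) .truth_table(tr, reg, nodes),
                      net$exprs, net$regulators, SIMPLIFY = FALSE)
  net
}

#' Construct a Boolean network from named rule expressions
#'
#' @param rules named character vector; names are node names, values are
#'   Boolean expressions over node names using `&`, `|`, `!`, parentheses and
#'   the constants `0`/`1` (the synonyms `AND`/`OR`/`NOT` are accepted).
#' @param fixed optional named vector of clamped values in `{0,1}`
#'   (knockout/knockin); clamped nodes ignore their function.
#' @return an object of class `boolean_network`.
#' @examples
#' net <- boolean_network(c(A = "B", B = "A"))
#' synchronous_step(net, c(1, 0))
#' @export
boolean_network <- function(rules, fixed = NULL) {
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes)))
    stop("rules must be a fully named character vector")
  if (anyDuplicated(nodes))
    stop("duplicate node name(s): ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  net <- list(nodes = nodes,
              functions = setNames(as.character(rules), nodes),
              exprs = lapply(as.character(rules), .parse_expr_text),
              fixed = setNames(rep(NA_integer_, length(nodes)), nodes))
  net <- .compile_network(net)
  class(net) <- "boolean_network"
  if (!is.null(fixed)) net <- fix_nodes(net, fixed)
  net
}

#' Clamp nodes to fixed values (knockout / knockin)
#'
#' @param net a `boolean_network`.
#' @param values named vector of 0/1 values, or `NULL` entries to release.
#' @return the modified network (the input is untouched).
#' @export
fix_nodes <- function(net, values) {
  stopifnot(inherits(net, "boolean_network"))
  idx <- match(names(values), net$nodes)
  if (anyNA(idx))
    stop("unknown node(s): ", paste(names(values)[is.na(idx)], collapse = ", "))
  v <- suppressWarnings(as.integer(values))
  if (any(!is.na(v) & !(v %in% c(0L, 1L))))
    stop("fixed values must be 0, 1, or NA")
  net$fixed[idx] <- v
  net
}

#' Number of nodes of a network
#' @param net a `boolean_network`.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Size of the synchronous state space
#'
#' A network over `n` binary nodes has `2^n` states.
#'
#' @param net a `boolean_network` or a node count.
#' @return the number of states as a double (exact for `n <= 53`).
#' @export
state_space_size <- function(net) {
  n <- if (inherits(net, "boolean_network")) n_nodes(net) else as.integer(net)
  2^n
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", length(x$nodes), "nodes\n")
  fixed <- which(!is.na(x$fixed))
  for (i in seq_along(x$nodes)) {
    cat("  ", x$nodes[i], " <- ", x$functions[i], sep = "")
    if (i %in% fixed) cat("   [fixed: ", x$fixed[i], "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

# internal: representation handed to the C++ core
.cpp_net <- function(net) {
  list(reg = net$regulators,
       tt = lapply(net$truth, as.integer),
       fixed = ifelse(is.na(net$fixed), -1L, net$fixed))
}

# --- rule-file parsing / serialization -------------------------------------

#' Parse a Boolean rule file in the "targets, factors" dialect
#'
#' The expected format is a header line (`targets, factors`) followed by one
#' `name, expression` line per node.  Lines starting with `#` are skipped.
#'
#' @param text character scalar (file content) or vector of lines.
#' @return a `boolean_network`.
#' @examples
#' parse_network("targets, factors\nA, B\nB, A")
#' @export
parse_network <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("rule file needs a header and at least one rule line")
  header <- tolower(gsub("\\s", "", lines[1L]))
  if (!grepl("^targets[,;]factors$", header))
    stop("missing 'targets, factors' header line")
  body <- lines[-1L]
  comma <- regexpr(",", body, fixed = TRUE)
  if (any(comma < 0L))
    stop("rule line without comma separator: ", sQuote(body[which(comma < 0L)[1L]]))
  targets <- trimws(substring(body, 1L, comma - 1L))
  exprs <- trimws(substring(body, comma + 1L))
  if (any(!nzchar(exprs)))
    stop("empty expression for node(s): ",
         paste(targets[!nzchar(exprs)], collapse = ", "))
  boolean_network(setNames(exprs, targets))
}

#' Read a Boolean rule file from disk
#' @param path file path (UTF-8 text).
#' @return a `boolean_network`.
#' @export
read_network <- function(path) {
  parse_network(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Serialize a network to "targets, factors" text
#' @param net a `boolean_network`.
#' @return a character scalar that [parse_network()] accepts.
#' @export
serialize_network <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  paste(c("targets, factors",
          paste0(net$nodes, ", ", vapply(net$exprs, .deparse_expr, ""))),
        collapse = "\n")
}

#' Write a network rule file
#' @param net a `boolean_network`.
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  writeLines(serialize_network(net), path, useBytes = TRUE)
  invisible(path)
}

#' Semantic network equality
#'
#' Two networks are considered equal when they declare the same nodes in the
#' same order with the same fixed values and logically equivalent functions
#' (identical regulator sets and truth tables).
#'
#' @param a,b `boolean_network` objects.
#' @export
networks_equal <- function(a, b) {
  identical(a$nodes, b$nodes) &&
    identical(unname(ifelse(is.na(a$fixed), -1L, a$fixed)),
              unname(ifelse(is.na(b$fixed), -1L, b$fixed))) &&
    all(mapply(function(ra, rb, ta, tb) {
      o <- match(rb, ra)
      if (anyNA(o) || length(ra) != length(rb)) return(FALSE)
      # reorder b's truth table into a's regulator order
      if (length(ra) == 0L) return(identical(as.integer(ta), as.integer(tb)))
      k <- length(ra)
      idx <- 0:(2L^k - 1L)
      bits <- vapply(seq_len(k), function(j) bitwAnd(bitwShiftR(idx, j - 1L), 1L),
                     integer(2L^k))
      # index into b's table given a-ordered bits
      bidx <- integer(2L^k)
      for (j in seq_len(k)) bidx <- bidx + bits[, o[j]] * 2L^(j - 1L)
      identical(as.integer(ta), as.integer(tb)[bidx + 1L])
    }, a$regulators, b$regulators, a$truth, b$truth))
}

# --- states ----------------------------------------------------------------

.check_state <- function(net, state) {
  state <- as.integer(state)
  if (length(state) != length(net$nodes))
    stop("state length ", length(state), " does not match network size ",
         length(net$nodes))
  if (any(!(state %in% c(0L, 1L)))) stop("state entries must be 0 or 1")
  state
}

#' Encode a 0/1 state vector as an integer code
#'
#' Node 1 (declaration order) is the least-significant bit.  Codes are exact
#' doubles for up to 53 nodes.
#'
#' @param bits 0/1 vector.
#' @export
state_to_index <- function(bits) {
  sum(as.numeric(bits) * 2^(seq_along(bits) - 1L))
}

#' Decode an integer state code into a 0/1 vector
#' @param index nonnegative state code.
#' @param n number of nodes.
#' @export
index_to_state <- function(index, n) {
  as.integer(floor(index / 2^(0:(n - 1L))) %% 2)
}

#' Evaluate one node's Boolean function in a state
#'
#' Returns the node's fixed value when it is clamped, regardless of its
#' expression.
#'
#' @param net a `boolean_network`.
#' @param node node name.
#' @param state 0/1 vector in node order.
#' @export
evaluate_node <- function(net, node, state) {
  state <- .check_state(net, state)
  i <- match(node, net$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  if (!is.na(net$fixed[i])) return(unname(net$fixed[i]))
  reg <- net$regulators[[i]]
  idx <- if (length(reg)) sum(state[reg] * 2L^(seq_along(reg) - 1L)) else 0L
  net$truth[[i]][idx + 1L]
}

#' One synchronous update of all nodes
#'
#' All functions are evaluated on the current state simultaneously; clamped
#' nodes take their fixed value.
#'
#' @param net a `boolean_network`.
#' @param state 0/1 vector in node order.
#' @return the successor state (named 0/1 integer vector).
#' @export
synchronous_step <- function(net, state) {
  state <- .check_state(net, state)
  out <- cpp_step_matrix(.cpp_net(net), matrix(state, nrow = 1L))
  setNames(as.integer(out[1L, ]), net$nodes)
}
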