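# Synchronous Boolean networks: construction, truth tables, states.

#' Construct a synchronous Boolean network
#'
#' A Boolean network is a set of named binary nodes, each updated
#' synchronously by a Boolean function of its regulators. Rules are given as
#' expression strings in the \code{.bnet} dialect (operators \code{!},
#' \code{&}, \code{|}, parentheses, and the constants \code{0}/\code{1};
#' the word forms \code{NOT}/\code{AND}/\code{OR} are also accepted).
#'
#' Each rule is compiled at construction time to a truth table over its
#' regulators (listed in order of first appearance in the expression). The
#' truth-table row order reads the regulator tuple as a binary number with
#' the first-listed regulator as the most significant bit.
#'
#' @param rules named character vector: \code{rules[[node]]} is the update
#'   expression for \code{node}. Every node referenced must itself have a
#'   rule.
#' @param name a label for the network.
#' @param nodes optional character vector fixing the canonical node order;
#'   defaults to \code{names(rules)} as given.
#' @param provenance optional character vector of free-text notes recorded
#'   with the model.
#' @return an object of class \code{boolean_network}, a list with elements
#'   \code{name}, \code{nodes}, \code{rules} (one compiled rule per node:
#'   \code{target}, \code{regulators}, \code{table}, \code{expression}) and
#'   \code{provenance}.
#' @examples
#' toy <- boolean_network(c(A = "A", B = "A & !C", C = "B"), name = "toy")
#' source_nodes(toy)
#' @export
boolean_network <- function(rules, name = "network", nodes = names(rules),
                            provenance = character(0)) {
  if (is.null(names(rules)) || anyNA(names(rules)) || any(names(rules) == ""))
    stop("'rules' must be a fully named character vector", call. = FALSE)
  if (anyDuplicated(names(rules)))
    stop("duplicate rule targets: ",
         paste(unique(names(rules)[duplicated(names(rules))]), collapse = ", "),
         call. = FALSE)
  if (!setequal(nodes, names(rules)) || length(nodes) != length(rules))
    stop("'nodes' must be a permutation of names(rules)", call. = FALSE)
  if (length(nodes) > 29L)
    stop("networks with more than 29 nodes are not supported", call. = FALSE)
  compiled <- lapply(nodes, function(tgt) {
    ast <- parse_bool_expr(rules[[tgt]])
    regs <- ast_vars(ast)
    missing <- setdiff(regs, nodes)
    if (length(missing) > 0L)
      stop(sprintf("rule for %s references undeclared factor(s): %s",
                   tgt, paste(missing, collapse = ", ")), call. = FALSE)
    k <- length(regs)
    reg_values <- truth_table_inputs(k, regs)
    prog_local <- ast_to_postfix(ast, regs)
    tab <- as.integer(eval_postfix(prog_local, regs, reg_values))
    list(target = tgt,
         regulators = regs,
         table = tab,
         expression = ast_to_bnet(ast))
  })
  names(compiled) <- nodes
  structure(list(name = name, nodes = nodes, rules = compiled,
                 provenance = provenance),
            class = "boolean_network")
}

# Regulator value columns for all 2^k truth-table rows, first regulator most
# significant.
#' @keywords internal
truth_table_inputs <- function(k, regs) {
  rows <- seq_len(2^k) - 1L
  vals <- lapply(seq_len(k), function(r) {
    bitwAnd(bitwShiftR(rows, k - r), 1L) == 1L
  })
  names(vals) <- regs
  vals
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Synchronous Boolean network '%s': %d nodes (%d source%s)\n",
              x$name, length(x$nodes), sum(source_nodes(x)),
              if (sum(source_nodes(x)) == 1L) "" else "s"))
  for (nd in x$nodes)
    cat(sprintf("  %s <- %s\n", nd, x$rules[[nd]]$expression))
  invisible(x)
}

#' Identify source (input) nodes
#'
#' A source node holds an identity rule on itself, so its value is a
#' constant of the dynamics; the joint assignment of all source nodes
#' defines the (micro)environment.
#'
#' @param network a \code{boolean_network}.
#' @return named logical vector over the nodes, \code{TRUE} for sources.
#' @export
source_nodes <- function(network) {
  out <- vapply(network$nodes, function(nd) {
    r <- network$rules[[nd]]
    identical(r$regulators, nd) && identical(r$table, c(0L, 1L))
  }, logical(1))
  names(out) <- network$nodes
  out
}

#' Evaluate a single update rule on a state
#'
#' @param network a \code{boolean_network}.
#' @param node node name.
#' @param state a network state: an integer encoding, a 0/1 vector in
#'   canonical node order, or a named 0/1 vector.
#' @return the updated bit (0 or 1) for \code{node}.
#' @examples
#' net <- boolean_network(c(A = "A", B = "A & !C", C = "B"))
#' evaluate_rule(net, "B", c(A = 1, B = 0, C = 0))
#' @export
evaluate_rule <- function(network, node, state) {
  if (!node %in% network$nodes)
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  bits <- as_state_bits(network, state)
  rule <- network$rules[[node]]
  rule$table[rule_row_index(rule, bits[match(rule$regulators, network$nodes)])]
}

# 1-based truth-table row for a vector of regulator bits.
#' @keywords internal
rule_row_index <- function(rule, reg_bits) {
  k <- length(rule$regulators)
  if (k == 0L) return(1L)
  sum(as.integer(reg_bits) * bitwShiftL(1L, (k - 1L):0L)) + 1L
}

# ---- state representations ------------------------------------------------
# A state is canonically a 0/1 integer vector in node order; it can also be
# carried as a single integer with node 1 as the least significant bit, or as
# a named 0/1 vector.

#' Convert between state representations
#'
#' Network states can be held as a 0/1 vector in canonical node order, as a
#' non-negative integer with the first node as the least significant bit, or
#' as a named 0/1 vector. These helpers convert losslessly between the three.
#'
#' @param network a \code{boolean_network}.
#' @param state a state in any of the three representations.
#' @return \code{as_state_bits}: an unnamed integer 0/1 vector in node
#'   order; \code{state_to_int}: the integer encoding; \code{state_to_named}:
#'   a named 0/1 vector.
#' @examples
#' net <- boolean_network(c(A = "A", B = "A & !C", C = "B"))
#' state_to_int(net, c(1, 1, 0))
#' as_state_bits(net, 3)
#' @export
as_state_bits <- function(network, state) {
  n <- length(network$nodes)
  if (length(state) == 1L && is.null(names(state))) {
    x <- as.numeric(state)
    if (is.na(x) || x < 0 || x >= 2^n || x != floor(x))
      stop(sprintf("integer state must be in [0, 2^%d)", n), call. = FALSE)
    return(int_to_bits(x, n))
  }
  if (!is.null(names(state))) {
    if (!setequal(names(state), network$nodes))
      stop("named state must cover exactly the network nodes", call. = FALSE)
    state <- state[network$nodes]
  }
  if (length(state) != n)
    stop(sprintf("state length %d does not match %d nodes",
                 length(state), n), call. = FALSE)
  bits <- as.integer(state)
  if (any(is.na(bits)) || any(bits < 0L | bits > 1L))
    stop("state entries must be 0 or 1", call. = FALSE)
  unname(bits)
}

#' @rdname as_state_bits
#' @export
state_to_int <- function(network, state) {
  bits <- as_state_bits(network, state)
  bits_to_int(bits)
}

#' @rdname as_state_bits
#' @export
state_to_named <- function(network, state) {
  bits <- as_state_bits(network, state)
  names(bits) <- network$nodes
  bits
}

# Integer encodings use doubles internally so that up to 29 bits round-trip
# exactly without integer-overflow concerns.
#' @keywords internal
int_to_bits <- function(x, n) {
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- as.integer(x %% 2)
    x <- x %/% 2
  }
  out
}

#' @keywords internal
bits_to_int <- function(bits) {
  sum(as.numeric(bits) * 2^(seq_along(bits) - 1))
}

# ---- validation -----------------------------------------------------------

#' Structural validation of a Boolean network
#'
#' Checks each rule for non-functional (vacuous) regulators and truth
#' tables of the wrong length. Findings are returned as a character vector
#' rather than raised, so that a network can be inspected without failing.
#' Sink nodes (targets that regulate nothing, typical for marker outputs)
#' are reported only when \code{report_sinks} is set.
#'
#' @param network a \code{boolean_network}.
#' @param report_sinks also report nodes that are not a regulator of any
#'   rule (default FALSE).
#' @return character vector of findings; empty if none.
#' @examples
#' net <- boolean_network(c(A = "A", B = "A | !A"))
#' validate_network(net)  # flags A as non-functional for B
#' @export
validate_network <- function(network, report_sinks = FALSE) {
  findings <- character(0)
  referenced <- character(0)
  for (nd in network$nodes) {
    rule <- network$rules[[nd]]
    k <- length(rule$regulators)
    if (length(rule$table) != 2^k)
      findings <- c(findings,
                    sprintf("rule for %s: truth table length %d, expected %d",
                            nd, length(rule$table), 2^k))
    referenced <- union(referenced, rule$regulators)
    for (r in seq_len(k)) {
      w <- regulator_witnesses(rule$table, k, r)
      if (!w$activating && !w$inhibiting)
        findings <- c(findings,
                      sprintf("regulator %s non-functional for %s",
                              rule$regulators[r], nd))
    }
  }
  if (report_sinks) {
    # a source node references itself, so genuine sinks are the only hits
    unref <- setdiff(network$nodes, referenced)
    if (length(unref) > 0L)
      findings <- c(findings,
                    sprintf("node %s is not a regulator of any rule", unref))
  }
  findings
}

# Activation/inhibition witnesses for regulator position r (1-based) in a
# truth table of k regulators: compare paired rows differing only in bit r.
#' @keywords internal
regulator_witnesses <- function(table, k, r) {
  rows <- seq_len(2^k) - 1L
  bit <- bitwShiftL(1L, k - r)
  low <- rows[bitwAnd(rows, bit) == 0L]
  f0 <- table[low + 1L]
  f1 <- table[low + bit + 1L]
  act <- which(f1 > f0)
  inh <- which(f1 < f0)
  list(activating = length(act) > 0L,
       inhibiting = length(inh) > 0L,
       # witness pair of (low-row, high-row) 0-based row indices, if any
       activating_witness = if (length(act)) c(low[act[1]], low[act[1]] + bit),
       inhibiting_witness = if (length(inh)) c(low[inh[1]], low[inh[1]] + bit))
}

# ---- JSON dump ------------------------------------------------------------

#' Serialize a network to JSON
#'
#' Writes \code{{name, nodes, rules: [{target, regulators, expression}]}}.
#'
#' @param network a \code{boolean_network}.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
network_to_json <- function(network, path = NULL) {
  obj <- list(
    name = network$name,
    nodes = network$nodes,
    rules = lapply(unname(network$rules), function(r)
      list(target = r$target, regulators = r$regulators,
           expression = r$expression)),
    provenance = network$provenance
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
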