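# The signed functional-interaction graph derived from the update rules,
# elementary feedback circuits, and circuit functionality.

#' Extract the signed functional-interaction graph
#'
#' A regulator j of node i is a functional activator (inhibitor) when some
#' pair of regulator configurations differing only in j raises (lowers)
#' f_i; both witnesses make the edge dual. Because f_i depends only on its
#' own regulators, scanning the 2^k truth-table rows of each rule is
#' equivalent to scanning all 2^n network states.
#'
#' Identity self-loops of source nodes are modeling artifacts that hold the
#' microenvironmental inputs constant rather than regulations, and are
#' excluded from the graph by default; set
#' \code{include_source_autoregulation = TRUE} to keep them (they are
#' positive self-loops).
#'
#' @param network a \code{boolean_network}.
#' @param include_source_autoregulation keep the identity self-loops of
#'   source nodes (default FALSE).
#' @return a list of class \code{bn_interaction_graph}: \code{edges}
#'   (data.frame source, target, sign with sign in
#'   \code{c("activating","inhibiting","dual")}), \code{nodes}, and
#'   \code{witnesses} (per edge, a re-checkable witness: regulator row pair
#'   as 0-based truth-table row indices).
#' @examples
#' g <- extract_interactions(build_endmt_network())
#' nrow(g$edges)  # 77
#' @export
extract_interactions <- function(network, include_source_autoregulation = FALSE) {
  is_src <- source_nodes(network)
  src_names <- names(which(is_src))
  source <- target <- sign <- character(0)
  witnesses <- list()
  for (nd in network$nodes) {
    rule <- network$rules[[nd]]
    k <- length(rule$regulators)
    for (r in seq_len(k)) {
      reg <- rule$regulators[r]
      if (!include_source_autoregulation && reg == nd && nd %in% src_names)
        next
      w <- regulator_witnesses(rule$table, k, r)
      if (!w$activating && !w$inhibiting) next
      sg <- if (w$activating && w$inhibiting) "dual"
            else if (w$activating) "activating" else "inhibiting"
      source <- c(source, reg)
      target <- c(target, nd)
      sign <- c(sign, sg)
      witnesses[[length(witnesses) + 1L]] <-
        list(activating = w$activating_witness,
             inhibiting = w$inhibiting_witness)
    }
  }
  structure(list(nodes = network$nodes,
                 edges = data.frame(source = source, target = target,
                                    sign = sign),
                 witnesses = witnesses),
            class = "bn_interaction_graph")
}

#' @export
print.bn_interaction_graph <- function(x, ...) {
  cat(sprintf("Signed interaction graph: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s %d", names(table(x$edges$sign)),
                            table(x$edges$sign)), collapse = ", ")))
  invisible(x)
}

# Johnson's algorithm for all elementary directed cycles; self-loops are
# enumerated separately. Vertices are 1-based indices into `nodes`.
#' @keywords internal
johnson_cycles <- function(nodes, from, to, max_circuits = 1e6) {
  n <- length(nodes)
  cycles <- list()
  selfloop <- from == to
  for (v in sort(unique(from[selfloop])))
    cycles[[length(cycles) + 1L]] <- v
  adj_all <- lapply(seq_len(n), function(v) sort(unique(to[!selfloop & from == v])))
  for (s in seq_len(n)) {
    # subgraph induced by vertices >= s
    adj <- lapply(adj_all, function(nb) nb[nb >= s])
    blocked <- rep(FALSE, n)
    blist <- vector("list", n)
    stack <- integer(0)
    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w == s) {
          cycles[[length(cycles) + 1L]] <<- stack
          if (length(cycles) > max_circuits)
            stop(sprintf("circuit count exceeds the cap of %g; raise max_circuits",
                         max_circuits), call. = FALSE)
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) {
        unblock <- function(u) {
          blocked[u] <<- FALSE
          for (w in blist[[u]]) if (blocked[w]) unblock(w)
          blist[[u]] <<- integer(0)
        }
        unblock(v)
      } else {
        for (w in adj[[v]])
          if (!v %in% blist[[w]]) blist[[w]] <<- c(blist[[w]], v)
      }
      stack <<- stack[-length(stack)]
      found
    }
    if (length(adj[[s]]) > 0L) circuit(s)
  }
  cycles
}

#' Enumerate elementary feedback circuits
#'
#' All elementary directed cycles of the interaction graph, including
#' length-1 self-loops. Each circuit's sign is the parity of its inhibiting
#' edges (negative iff odd); a circuit traversing a dual edge is reported
#' once per sign assignment of that edge.
#'
#' @param graph a \code{bn_interaction_graph}.
#' @param max_circuits guard against combinatorial explosion (default 1e6).
#' @return a list of class \code{bn_circuits} with \code{circuits}: a list
#'   of entries \code{nodes} (cycle order, starting at the lexicographically
#'   smallest name), \code{length}, \code{n_inhibiting}, \code{sign}
#'   (\code{"positive"}/\code{"negative"}), and a summary data.frame
#'   \code{table}.
#' @examples
#' g <- extract_interactions(build_endmt_network())
#' circ <- enumerate_circuits(g)
#' nrow(circ$table)  # 74
#' @export
enumerate_circuits <- function(graph, max_circuits = 1e6) {
  from <- match(graph$edges$source, graph$nodes)
  to <- match(graph$edges$target, graph$nodes)
  raw <- johnson_cycles(graph$nodes, from, to, max_circuits)
  edge_sign <- function(s, t) {
    hit <- graph$edges$source == s & graph$edges$target == t
    graph$edges$sign[hit][1]
  }
  circuits <- list()
  for (vs in raw) {
    nm <- graph$nodes[vs]
    # rotate to start at the smallest node name (rotation-invariant identity)
    k <- which.min(match(nm, sort(nm)))
    nm <- if (k == 1L) nm else nm[c(k:length(nm), seq_len(k - 1L))]
    signs <- vapply(seq_along(nm), function(i)
      edge_sign(nm[i], nm[if (i == length(nm)) 1L else i + 1L]), character(1))
    n_dual <- sum(signs == "dual")
    base_inh <- sum(signs == "inhibiting")
    # a dual edge contributes one circuit per sign assignment
    for (d in 0:n_dual) {
      reps <- choose(n_dual, d)
      for (i in seq_len(reps)) {
        n_inh <- base_inh + d
        circuits[[length(circuits) + 1L]] <- list(
          nodes = nm, length = length(nm), n_inhibiting = n_inh,
          sign = if (n_inh %% 2 == 1) "negative" else "positive",
          has_dual = n_dual > 0)
      }
    }
  }
  tab <- data.frame(
    circuit = vapply(circuits, function(cc) paste(cc$nodes, collapse = ">"),
                     character(1)),
    length = vapply(circuits, `[[`, numeric(1), "length"),
    sign = vapply(circuits, `[[`, character(1), "sign"))
  structure(list(circuits = circuits, table = tab,
                 n_node_cycles = length(raw)),
            class = "bn_circuits")
}

#' @export
print.bn_circuits <- function(x, ...) {
  cat(sprintf("%d elementary feedback circuits (%d positive, %d negative)\n",
              length(x$circuits), sum(x$table$sign == "positive"),
              sum(x$table$sign == "negative")))
  invisible(x)
}

#' Assess circuit functionality
#'
#' A circuit is flagged functional when a single context (one joint
#' assignment to all non-circuit regulators of the circuit's targets)
#' exists under which every circuit edge simultaneously has a definite
#' (non-dual) sign witness, and the edge signs multiply to the circuit's
#' sign. Regulators belonging to the circuit other than the edge's own
#' source are left free within each context.
#'
#' @param network a \code{boolean_network}.
#' @param circuits a \code{bn_circuits} from the same network's interaction
#'   graph.
#' @param max_context_nodes guard: skip (flag NA) circuits whose joint
#'   context exceeds this many nodes (default 20).
#' @return \code{circuits} with a logical \code{functional} flag added per
#'   circuit and to the summary table.
#' @examples
#' net <- build_endmt_network()
#' fc <- functional_circuits(net, enumerate_circuits(extract_interactions(net)))
#' sum(fc$table$functional)
#' @export
functional_circuits <- function(network, circuits, max_context_nodes = 20L) {
  flags <- vapply(circuits$circuits, function(cc)
    circuit_is_functional(network, cc$nodes, max_context_nodes), logical(1))
  circuits$circuits <- Map(function(cc, fl) {
    cc$functional <- fl
    cc
  }, circuits$circuits, flags)
  circuits$table$functional <- flags
  circuits
}

# Single-context functionality test for one elementary node cycle.
#' @keywords internal
circuit_is_functional <- function(network, cycle_nodes, max_context_nodes) {
  L <- length(cycle_nodes)
  edges <- lapply(seq_len(L), function(i)
    c(cycle_nodes[i], cycle_nodes[if (i == L) 1L else i + 1L]))
  # context = all regulators of the circuit's targets outside the circuit
  ctx_nodes <- character(0)
  for (e in edges) {
    regs <- network$rules[[e[2]]]$regulators
    ctx_nodes <- union(ctx_nodes, setdiff(regs, cycle_nodes))
  }
  if (length(ctx_nodes) > max_context_nodes)
    return(NA)
  n_ctx <- length(ctx_nodes)
  for (ctx in seq_len(2^n_ctx) - 1L) {
    ctx_vals <- bitwAnd(bitwShiftR(ctx, seq_len(n_ctx) - 1L), 1L)
    names(ctx_vals) <- ctx_nodes
    ok <- TRUE
    for (e in edges) {
      sg <- edge_sign_in_context(network, e[1], e[2], ctx_vals, cycle_nodes)
      if (sg == "none" || sg == "dual") {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Sign of edge src -> tgt with non-circuit regulators pinned by the context;
# circuit regulators other than src range free. "none" when no witness,
# "dual" when both.
#' @keywords internal
edge_sign_in_context <- function(network, src, tgt, ctx_vals, cycle_nodes) {
  rule <- network$rules[[tgt]]
  regs <- rule$regulators
  k <- length(regs)
  rows <- seq_len(2^k) - 1L
  keep <- rep(TRUE, length(rows))
  for (r in seq_len(k)) {
    reg <- regs[r]
    if (reg %in% names(ctx_vals)) {
      bit <- bitwAnd(bitwShiftR(rows, k - r), 1L)
      keep <- keep & (bit == ctx_vals[[reg]])
    }
  }
  r_src <- match(src, regs)
  bit_src <- bitwShiftL(1L, k - r_src)
  low <- rows[keep & bitwAnd(rows, bit_src) == 0L]
  f0 <- rule$table[low + 1L]
  f1 <- rule$table[low + bit_src + 1L]
  act <- any(f1 > f0)
  inh <- any(f1 < f0)
  if (act && inh) "dual" else if (act) "activating"
  else if (inh) "inhibiting" else "none"
}

#' Export the interaction graph
#'
#' @param graph a \code{bn_interaction_graph}.
#' @param path optional file path for the DOT output.
#' @return \code{interactions_to_dot}: DOT lines (invisibly when written).
#' @export
interactions_to_dot <- function(graph, path = NULL) {
  style <- c(activating = "[color=black]",
             inhibiting = "[color=red, arrowhead=tee]",
             dual = "[color=blue, arrowhead=diamond]")
  lines <- c("digraph interactions {",
             sprintf("  \"%s\";", graph$nodes),
             sprintf("  \"%s\" -> \"%s\" %s;", graph$edges$source,
                     graph$edges$target, style[graph$edges$sign]),
             "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
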