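# Synchronous update engine: single-state stepping, trajectory convergence,
# and per-environment successor maps.

# Compile a network once into the flat structures the C++ engine consumes.
# Cached on the network object's environment-free list via attribute.
#' @keywords internal
engine_compile <- function(network) {
  cached <- attr(network, "engine", exact = TRUE)
  if (!is.null(cached)) return(cached)
  nodes <- network$nodes
  regs <- lapply(nodes, function(nd)
    match(network$rules[[nd]]$regulators, nodes) - 1L)
  tabs <- lapply(nodes, function(nd) network$rules[[nd]]$table)
  progs <- lapply(nodes, function(nd) {
    ast <- parse_bool_expr(network$rules[[nd]]$expression)
    ast_to_postfix(ast, nodes)
  })
  list(regs = regs, tables = tabs, programs = progs, n = length(nodes))
}

# Attach the compiled engine so repeated analyses avoid recompilation.
#' @keywords internal
with_engine <- function(network) {
  if (is.null(attr(network, "engine", exact = TRUE)))
    attr(network, "engine") <- engine_compile(network)
  network
}

#' Synchronous update step
#'
#' Applies every node's update rule simultaneously to the same input state.
#'
#' @param network a \code{boolean_network}.
#' @param state a state (integer encoding, 0/1 vector, or named 0/1 vector).
#' @return the successor state, in the same representation class as the
#'   input (integer in, integer out; vector in, vector out).
#' @examples
#' net <- boolean_network(c(A = "A", B = "A & !C", C = "B"))
#' step_state(net, c(1, 0, 0))  # -> 1 1 0
#' @export
step_state <- function(network, state) {
  eng <- engine_compile(network)
  as_int <- length(state) == 1L && is.null(names(state))
  x <- state_to_int(network, state)
  nxt <- cpp_step_batch(eng$regs, eng$tables, eng$n, as.integer(x))
  if (as_int) return(as.numeric(nxt))
  out <- int_to_bits(nxt, eng$n)
  if (!is.null(names(state))) names(out) <- network$nodes
  out
}

#' Iterate a state to its attractor
#'
#' Runs the synchronous dynamics from \code{state} until a state repeats,
#' using Brent's cycle-detection algorithm (constant memory), then returns
#' the transient length and the attractor in canonical form.
#'
#' @param network a \code{boolean_network}.
#' @param state initial state.
#' @param max_steps hard bound on the number of update steps (default
#'   10000; transients of biological Boolean networks are far shorter).
#' @return a list of class \code{bn_trajectory} with elements
#'   \code{transient_length} and \code{attractor} (see
#'   \code{\link{canonicalize_attractor}}); \code{states} holds the visited
#'   prefix of the trajectory (transient plus one full cycle) as integer
#'   encodings.
#' @export
simulate_to_attractor <- function(network, state, max_steps = 10000L) {
  stopifnot(max_steps >= 1L)
  eng <- engine_compile(network)
  step1 <- function(x) cpp_step_batch(eng$regs, eng$tables, eng$n,
                                      as.integer(x))
  x0 <- state_to_int(network, state)
  # Brent: find cycle length lam and start mu
  power <- 1L; lam <- 1L
  tortoise <- x0
  hare <- step1(x0)
  steps <- 1L
  while (tortoise != hare) {
    if (power == lam) {
      tortoise <- hare
      power <- power * 2L
      lam <- 0L
    }
    hare <- step1(hare)
    lam <- lam + 1L
    steps <- steps + 1L
    if (steps > max_steps)
      stop(sprintf("no cycle detected within %d steps", max_steps),
           call. = FALSE)
  }
  # find position mu of the first cycle state
  tortoise <- x0
  hare <- x0
  for (i in seq_len(lam)) hare <- step1(hare)
  mu <- 0L
  while (tortoise != hare) {
    tortoise <- step1(tortoise)
    hare <- step1(hare)
    mu <- mu + 1L
  }
  cyc <- numeric(lam)
  x <- tortoise
  for (i in seq_len(lam)) {
    cyc[i] <- x
    x <- step1(x)
  }
  prefix <- numeric(mu + lam)
  x <- x0
  for (i in seq_len(mu + lam)) {
    prefix[i] <- x
    x <- step1(x)
  }
  structure(list(states = prefix,
                 transient_length = mu,
                 attractor = canonicalize_attractor(network, cyc)),
            class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: transient %d step%s to a period-%d attractor\n",
              x$transient_length, if (x$transient_length == 1L) "" else "s",
              x$attractor$period))
  invisible(x)
}

#' Trajectory export
#'
#' One row per step, one 0/1 column per node, plus a \code{step} counter.
#'
#' @param network the network the trajectory belongs to.
#' @param trajectory a \code{bn_trajectory}.
#' @return a data.frame.
#' @export
trajectory_to_df <- function(network, trajectory) {
  bits <- t(vapply(trajectory$states, function(s) int_to_bits(s, length(network$nodes)),
                   integer(length(network$nodes))))
  colnames(bits) <- network$nodes
  cbind(data.frame(step = seq_len(nrow(bits)) - 1L), as.data.frame(bits))
}

# ---- environments ---------------------------------------------------------

#' Enumerate microenvironments
#'
#' An environment is a joint 0/1 assignment to all source nodes; its id
#' packs the assignment with the first source node (in canonical node
#' order) as the least significant bit.
#'
#' @param network a \code{boolean_network}.
#' @return data.frame with one row per environment: \code{env_id} and one
#'   column per source node.
#' @export
environments <- function(network) {
  src <- names(which(source_nodes(network)))
  s <- length(src)
  ids <- seq_len(2^s) - 1L
  df <- data.frame(env_id = ids)
  for (k in seq_along(src))
    df[[src[k]]] <- bitwAnd(bitwShiftR(ids, k - 1L), 1L)
  df
}

#' @keywords internal
environment_assignment <- function(network, env) {
  src <- names(which(source_nodes(network)))
  if (length(env) == 1L && is.null(names(env))) {
    id <- as.integer(env)
    if (is.na(id) || id < 0L || id >= 2^length(src))
      stop(sprintf("unknown environment id %s", format(env)), call. = FALSE)
    vals <- bitwAnd(bitwShiftR(id, seq_along(src) - 1L), 1L)
    names(vals) <- src
    return(vals)
  }
  if (!setequal(names(env), src))
    stop("environment must assign exactly the source nodes: ",
         paste(src, collapse = ", "), call. = FALSE)
  vals <- as.integer(env[src])
  if (any(is.na(vals)) || any(vals < 0L | vals > 1L))
    stop("environment values must be 0 or 1", call. = FALSE)
  names(vals) <- src
  vals
}

#' @keywords internal
environment_id <- function(network, env) {
  vals <- environment_assignment(network, env)
  sum(vals * 2^(seq_along(vals) - 1L))
}

#' Per-environment successor map
#'
#' Pins the source nodes to an environment (and constant-rule nodes to
#' their constants) and tabulates the successor of every configuration of
#' the remaining free nodes, bit-parallel over 64 states per word.
#'
#' @param network a \code{boolean_network}.
#' @param env an environment id or named 0/1 vector over the source nodes.
#' @return a list of class \code{bn_successor_map}: \code{free_nodes},
#'   \code{fixed} (named 0/1 vector), \code{successors} (integer vector of
#'   length \code{2^length(free_nodes)}, 0-based configuration indices;
#'   node \code{free_nodes[j]} is bit \code{j-1}), and \code{env_id}.
#' @export
build_successor_map <- function(network, env) {
  eng <- engine_compile(network)
  part <- free_fixed_partition(network, env)
  succ <- cpp_build_succ(eng$programs, eng$n,
                         part$free_idx0, part$fixed_idx0, part$fixed_val)
  structure(list(free_nodes = network$nodes[part$free_idx0 + 1L],
                 fixed = part$fixed_named,
                 successors = succ,
                 env_id = part$env_id),
            class = "bn_successor_map")
}

# Partition nodes into free vs fixed (sources pinned by env + constant
# rules), 0-based for the engine.
#' @keywords internal
free_fixed_partition <- function(network, env) {
  n <- length(network$nodes)
  is_src <- source_nodes(network)
  is_const <- vapply(network$nodes, function(nd)
    length(network$rules[[nd]]$regulators) == 0L, logical(1))
  vals <- environment_assignment(network, env)
  fixed_idx <- which(is_src | is_const)
  fixed_val <- integer(length(fixed_idx))
  for (i in seq_along(fixed_idx)) {
    nd <- network$nodes[fixed_idx[i]]
    fixed_val[i] <- if (is_src[nd]) vals[[nd]] else network$rules[[nd]]$table[1L]
  }
  free_idx <- setdiff(seq_len(n), fixed_idx)
  fixed_named <- fixed_val
  names(fixed_named) <- network$nodes[fixed_idx]
  list(free_idx0 = as.integer(free_idx - 1L),
       fixed_idx0 = as.integer(fixed_idx - 1L),
       fixed_val = as.integer(fixed_val),
       fixed_named = fixed_named,
       env_id = environment_id(network, env))
}

# Assemble full integer states from free-configuration indices (vectorized).
#' @keywords internal
free_config_to_int <- function(free_idx0, fixed_idx0, fixed_val, configs) {
  base <- sum(as.numeric(fixed_val) * 2^fixed_idx0)
  if (length(free_idx0) == 0L) return(rep(base, length(configs)))
  out <- rep(base, length(configs))
  for (j in seq_along(free_idx0)) {
    bit <- bitwAnd(bitwShiftR(as.integer(configs), j - 1L), 1L)
    out <- out + as.numeric(bit) * 2^free_idx0[j]
  }
  out
}
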