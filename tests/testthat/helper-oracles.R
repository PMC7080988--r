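# Shared fixtures and independent reference implementations used as
# oracles. The reference dynamics below go through evaluate_rule()'s plain
# R truth-table lookup only, independently of the bit-parallel C++ engine.

toy_net <- function() {
  boolean_network(c(A = "A", B = "A & !C", C = "B"), name = "toy")
}

# One synchronous step computed node-by-node in R.
r_step <- function(net, bits) {
  vapply(net$nodes, function(nd) evaluate_rule(net, nd, bits), integer(1))
}

# Brute-force attractor enumeration: step every state of the full space
# until it revisits, collect the distinct cycles (as sorted key strings).
brute_attractor_keys <- function(net) {
  n <- length(net$nodes)
  succ <- vapply(0:(2^n - 1), function(s)
    bits_to_int_ref(r_step(net, int_to_bits_ref(s, n))), numeric(1))
  color <- integer(2^n)  # 0 new, 1 in progress, 2 done
  keys <- character(0)
  for (s0 in 0:(2^n - 1)) {
    if (color[s0 + 1] != 0) next
    path <- integer(0)
    x <- s0
    while (color[x + 1] == 0) {
      color[x + 1] <- 1L
      path <- c(path, x)
      x <- succ[x + 1]
    }
    if (color[x + 1] == 1L) {
      cyc <- path[seq(match(x, path), length(path))]
      keys <- c(keys, paste(sort(cyc), collapse = ","))
    }
    color[path + 1] <- 2L
  }
  sort(keys)
}

int_to_bits_ref <- function(x, n) {
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- x %% 2
    x <- x %/% 2
  }
  out
}

bits_to_int_ref <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

# Atlas attractors as the same sorted key strings for comparison.
atlas_attractor_keys <- function(atlas) {
  sort(vapply(atlas$attractors, function(a)
    paste(sort(a$states), collapse = ","), character(1)))
}

# Random Boolean network with n nodes: each non-source node gets a random
# expression over <= max_k regulators (as a random truth table rendered to
# an expression); the first n_src nodes are sources.
random_network <- function(n, n_src = 1L, max_k = 3L) {
  nodes <- paste0("N", seq_len(n))
  exprs <- character(n)
  names(exprs) <- nodes
  for (i in seq_len(n)) {
    if (i <= n_src) {
      exprs[i] <- nodes[i]
      next
    }
    k <- sample.int(max_k, 1L)
    regs <- sample(nodes, k)
    tab <- sample(0:1, 2^k, replace = TRUE)
    exprs[i] <- endmtbn:::table_to_expression(regs, tab)
  }
  boolean_network(exprs, name = "random")
}

# Lazily computed, session-cached wild-type EndMT results shared across
# test files (the enumeration is exact, so caching cannot mask failures).
.wt_cache <- new.env(parent = emptyenv())

wt_network <- function() {
  if (is.null(.wt_cache$net)) .wt_cache$net <- build_endmt_network()
  .wt_cache$net
}

wt_atlas <- function() {
  if (is.null(.wt_cache$atlas))
    .wt_cache$atlas <- enumerate_attractors(wt_network())
  .wt_cache$atlas
}

wt_classification <- function() {
  if (is.null(.wt_cache$cls))
    .wt_cache$cls <- classify_atlas(wt_network(), wt_atlas())
  .wt_cache$cls
}

# The published 12-column attractor table for the EndMT-inducing
# microenvironment (DLL4, TGFB, WNT5b, WNT7a, PDGF_AB present; HIF1a, FGF2
# absent): three period-4 attractors, columns in step order.
printed_attractor_table <- function() {
  m <- rbind(
    AP1     = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    CTNNB   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    DLL4    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    ETS1    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    FGF2    = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    FLI1    = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0),
    GATA2   = c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0),
    HIF1a   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    LEF1    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    NFkB    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    NOTCH   = c(0, 1, 1, 0, 0, 0, 1, 1, 0, 1, 1, 0),
    NRARP   = c(0, 0, 1, 1, 1, 0, 0, 1, 0, 0, 1, 1),
    NRP1    = c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0),
    PDGF_AB = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    SMAD1   = c(0, 1, 1, 0, 0, 0, 1, 1, 1, 1, 1, 1),
    SMAD2   = c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0),
    SMAD6   = c(0, 0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0),
    SNAI1   = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    SNAI2   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    STAT3   = c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0),
    TGFB    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    TGFBR   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    TWIST1  = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    VEGFA   = c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0),
    VEGFR2  = c(0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0),
    WNT5b   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    WNT7a   = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    ZEB1    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    ZEB2    = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  stopifnot(nrow(m) == 29, ncol(m) == 12)
  m
}

# Environment of the printed table.
printed_table_env <- function() {
  c(DLL4 = 1L, FGF2 = 0L, HIF1a = 0L, PDGF_AB = 1L, TGFB = 1L,
    WNT5b = 1L, WNT7a = 1L)
}
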