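# Signed interaction graph, feedback circuits, circuit functionality.

test_that("interaction extraction finds exactly the functional regulators", {
  # B' = A OR NOT A is vacuous in A; C sees a definite sign from each input
  net <- boolean_network(c(A = "A", B = "A | !A", C = "A & !B"))
  g <- extract_interactions(net, include_source_autoregulation = TRUE)
  expect_true(any(g$edges$source == "A" & g$edges$target == "A" &
                    g$edges$sign == "activating"))
  expect_false(any(g$edges$target == "B"))
  expect_setequal(g$edges$sign[g$edges$target == "C"],
                  c("activating", "inhibiting"))
  # a XOR-like rule yields a dual edge
  net2 <- boolean_network(c(A = "A", B = "B",
                            C = "(A & !B) | (!A & B)"))
  g2 <- extract_interactions(net2)
  expect_true(all(g2$edges$sign[g2$edges$target == "C"] == "dual"))
})

test_that("stored witnesses re-check against the truth tables", {
  net <- wt_network()
  g <- extract_interactions(net)
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    rule <- net$rules[[e$target]]
    k <- length(rule$regulators)
    w <- g$witnesses[[i]]
    if (!is.null(w$activating)) {
      expect_equal(rule$table[w$activating[1] + 1L], 0L)
      expect_equal(rule$table[w$activating[2] + 1L], 1L)
    }
    if (!is.null(w$inhibiting)) {
      expect_equal(rule$table[w$inhibiting[1] + 1L], 1L)
      expect_equal(rule$table[w$inhibiting[2] + 1L], 0L)
    }
  }
})

test_that("the EndMT interaction graph has 77 signed edges", {
  g <- extract_interactions(wt_network())
  expect_equal(nrow(g$edges), 77L)
  # SNAI1 inhibits itself
  expect_true(any(g$edges$source == "SNAI1" & g$edges$target == "SNAI1" &
                    g$edges$sign == "inhibiting"))
  # source identity self-loops are input artifacts, excluded by default
  expect_false(any(g$edges$source == "DLL4" & g$edges$target == "DLL4"))
  g2 <- extract_interactions(wt_network(),
                             include_source_autoregulation = TRUE)
  expect_equal(nrow(g2$edges), 84L)
  expect_true(any(g2$edges$source == "DLL4" & g2$edges$target == "DLL4" &
                    g2$edges$sign == "activating"))
})

test_that("circuit enumeration equals exhaustive search on toy graphs", {
  toy <- toy_net()  # cycles: A self-loop (+) and B -> C -| B (-)
  g <- extract_interactions(toy, include_source_autoregulation = TRUE)
  circ <- enumerate_circuits(g)
  expect_setequal(circ$table$circuit, c("A", "B>C"))
  expect_equal(circ$table$sign[circ$table$circuit == "A"], "positive")
  expect_equal(circ$table$sign[circ$table$circuit == "B>C"], "negative")
  net <- boolean_network(c(A = "B", B = "A", C = "A & !C"))
  gc <- enumerate_circuits(extract_interactions(net))
  expect_setequal(gc$table$circuit, c("A>B", "C"))
  expect_equal(gc$table$sign[gc$table$circuit == "C"], "negative")
  expect_equal(gc$table$sign[gc$table$circuit == "A>B"], "positive")
})

test_that("the EndMT graph contains 74 elementary feedback circuits", {
  circ <- enumerate_circuits(extract_interactions(wt_network()))
  expect_equal(nrow(circ$table), 74L)
  expect_true("NOTCH>NRARP" %in% circ$table$circuit)
  expect_equal(circ$table$sign[circ$table$circuit == "NOTCH>NRARP"],
               "negative")
})

test_that("the three published negative circuits are functional", {
  net <- wt_network()
  circ <- enumerate_circuits(extract_interactions(net))
  named <- c("SNAI1", "NOTCH>NRARP", "SMAD1>SMAD6")
  rows <- match(named, circ$table$circuit)
  expect_false(anyNA(rows))
  expect_true(all(circ$table$sign[rows] == "negative"))
  for (r in rows) {
    nodes <- circ$circuits[[r]]$nodes
    expect_true(endmtbn:::circuit_is_functional(net, nodes, 20L))
  }
  # a source self-loop is functional in every context
  g2 <- extract_interactions(net, include_source_autoregulation = TRUE)
  expect_true(endmtbn:::circuit_is_functional(net, "DLL4", 20L))
})

test_that("functionality flags work end to end on a small graph", {
  net <- boolean_network(c(A = "B", B = "A", C = "A & !C"))
  fc <- functional_circuits(net, enumerate_circuits(extract_interactions(net)))
  expect_true(all(fc$table$functional))
})

test_that("DOT export lists every edge", {
  g <- extract_interactions(wt_network())
  dot <- interactions_to_dot(g)
  expect_length(grep("->", dot), 77L)
})
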