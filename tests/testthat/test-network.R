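# Network construction, rule evaluation, state representations.

test_that("expression parsing, truth tables and bnet rendering agree", {
  net <- boolean_network(c(A = "A", B = "A & !C | B", C = "!(A & B)"))
  expect_equal(net$rules$B$regulators, c("A", "C", "B"))
  # table row order: first regulator is the most significant bit
  # B' = (A & !C) | B over (A, C, B) rows 000..111
  expect_equal(net$rules$B$table, c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L))
  # word operators and parentheses parse to the same table
  net2 <- boolean_network(c(A = "A", B = "(A AND NOT C) OR B", C = "NOT (A AND B)"))
  expect_equal(net2$rules$B$table, net$rules$B$table)
  expect_equal(net2$rules$C$table, net$rules$C$table)
  # rendering keeps semantics
  rt <- read_bnet(write_bnet(net))
  for (nd in net$nodes) expect_equal(rt$rules[[nd]]$table, net$rules[[nd]]$table)
})

test_that("construction rejects malformed input", {
  expect_error(boolean_network(c(A = "B")), "undeclared")
  expect_error(boolean_network(c(A = "A &")), "unexpected end")
  expect_error(boolean_network(c(A = "A @ B")), "unexpected token")
  expect_error(boolean_network(c("A", "B")), "named")
})

test_that("state conversions compose to identity", {
  net <- random_network(7, n_src = 2L)
  for (s in c(0, 1, 37, 2^7 - 1, sample.int(2^7, 10) - 1)) {
    bits <- as_state_bits(net, s)
    expect_equal(bits_to_int_ref(bits), s)
    named <- state_to_named(net, bits)
    expect_equal(state_to_int(net, named), s)
    expect_equal(as_state_bits(net, named), bits)
  }
  expect_error(as_state_bits(net, 2^7), "in \\[0")
  expect_error(as_state_bits(net, c(A = 1)), "exactly")
})

test_that("the bundled EndMT model has the documented shape", {
  net <- wt_network()
  expect_length(net$nodes, 29L)
  src <- source_nodes(net)
  expect_equal(names(which(src)), endmt_source_names())
  expect_equal(sum(src), 7L)
  # every listed regulator is functional: no findings
  expect_length(validate_network(net), 0L)
  # NOTCH rule: DLL4 AND NOT NRARP
  r <- net$rules$NOTCH
  expect_setequal(r$regulators, c("DLL4", "NRARP"))
  expect_equal(r$table[endmtbn:::rule_row_index(r, c(DLL4 = 1, NRARP = 0)[r$regulators])], 1L)
  expect_equal(r$table[endmtbn:::rule_row_index(r, c(DLL4 = 1, NRARP = 1)[r$regulators])], 0L)
})

test_that("evaluate_rule matches the printed attractor states", {
  net <- wt_network()
  col1 <- printed_attractor_table()[, 1]
  expect_equal(evaluate_rule(net, "NOTCH", col1), 1L)
  expect_equal(evaluate_rule(net, "SNAI1", col1), 0L)
  # identity rule on a source node returns the state bit
  s <- state_to_named(net, col1)
  expect_equal(evaluate_rule(net, "DLL4", s), unname(s["DLL4"]))
  expect_error(evaluate_rule(net, "XYZ", col1), "XYZ")
})

test_that("validate_network flags vacuous regulators and sinks on request", {
  net <- boolean_network(c(A = "A", B = "A | !A"))
  expect_match(validate_network(net), "regulator A non-functional for B")
  toy <- toy_net()
  expect_length(validate_network(toy), 0L)
  net2 <- boolean_network(c(A = "A", B = "A"))
  expect_length(validate_network(net2), 0L)
  expect_match(validate_network(net2, report_sinks = TRUE), "node B")
})

test_that("aliases normalize to canonical node names", {
  expect_equal(normalize_endmt_names(c("VEGF2", "NPR1", "TGFbeta", "AP1")),
               c("VEGFR2", "NRP1", "TGFB", "AP1"))
})

test_that("JSON dump carries rules and provenance", {
  js <- jsonlite::fromJSON(network_to_json(wt_network()), simplifyVector = FALSE)
  expect_equal(js$name, "EndMT")
  expect_length(js$rules, 29L)
  expect_true(any(grepl("VEGFR2", unlist(js$provenance))))
})
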