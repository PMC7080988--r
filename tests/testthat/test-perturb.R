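# Mutants, rule-flip robustness, sensitivity, transition mapping.

test_that("clamps produce constant rules and are sound in every attractor", {
  net <- wt_network()
  mut <- apply_mutations(net, c(DLL4 = 0L, SNAI1 = 1L))
  expect_equal(mut$rules$DLL4$table, 0L)
  expect_equal(mut$rules$SNAI1$table, 1L)
  expect_length(mut$rules$DLL4$regulators, 0L)
  # clamping DLL4 removes it from the sources: environment space halves
  expect_equal(nrow(environments(mut)), 64L)
  # every attractor of the mutant holds the clamped values
  atlas <- enumerate_attractors(mut, envs = c(0L, 21L, 63L))
  pos <- match(c("DLL4", "SNAI1"), net$nodes)
  for (a in atlas$attractors)
    for (s in a$states) {
      bits <- as_state_bits(mut, s)
      expect_equal(bits[pos], c(0L, 1L))
    }
  # rebuilding the original network restores the rules
  expect_equal(build_endmt_network()$rules$DLL4$table, c(0L, 1L))
  expect_error(apply_mutations(net, c(DLL4 = 0L, DLL4 = 1L)), "uniquely")
  expect_error(apply_mutations(net, c(NOPE = 0L)), "NOPE")
})

test_that("rule-flip robustness matches exhaustive brute force on a toy", {
  net <- toy_net()
  cfg <- endmt_classifier()
  # exhaustive: flip each of the 2+4+2 truth-table bits once and count
  # attractors; the Monte Carlo sampler must land in the same support
  totals <- c()
  for (nd in net$nodes)
    for (row in seq_along(net$rules[[nd]]$table)) {
      pert <- endmtbn:::flip_rule_bit(net, nd, row)
      totals <- c(totals, length(enumerate_attractors(pert)$attractors))
    }
  set.seed(5)
  # the sampler draws (node, row) pairs from that same flip set
  for (i in 1:5) {
    nd <- sample(net$nodes, 1)
    row <- sample.int(length(net$rules[[nd]]$table), 1)
    pert <- endmtbn:::flip_rule_bit(net, nd, row)
    expect_true(length(enumerate_attractors(pert)$attractors) %in% totals)
  }
})

test_that("rule-flip robustness is reproducible under a fixed seed", {
  net <- wt_network()
  r1 <- rule_flip_robustness(net, n_instances = 2L, seed = 99L)
  r2 <- rule_flip_robustness(net, n_instances = 2L, seed = 99L)
  expect_equal(r1$counts, r2$counts)
  expect_equal(r1$flips, r2$flips)
  expect_equal(nrow(r1$per_class), 9L)
})

test_that("sensitivity of identity and constant rules is analytic", {
  net <- wt_network()
  sens <- rule_sensitivity(net, n_samples_1bit = 60000L,
                           n_samples_kbit = 20000L, k_range = c(1L, 15L),
                           seed = 3L)
  n <- 29
  for (src in c("DLL4", "WNT7a")) {
    se1 <- sqrt((1 / n) * (1 - 1 / n) / 60000)
    expect_lt(abs(sens$sensitivity[src, "k1"] - 1 / n), 3 * se1)
    se15 <- sqrt((15 / n) * (1 - 15 / n) / 20000)
    expect_lt(abs(sens$sensitivity[src, "k15"] - 15 / n), 3 * se15)
  }
  # a clamped node's component never changes
  mut <- apply_mutations(net, c(STAT3 = 1L))
  sens_mut <- rule_sensitivity(mut, n_samples_1bit = 5000L,
                               n_samples_kbit = 5000L, k_range = c(1L, 8L),
                               seed = 3L)
  expect_equal(unname(sens_mut$sensitivity["STAT3", ]), c(0, 0))
})

test_that("no-op perturbation patterns return the source attractor", {
  net <- wt_network()
  atlas <- enumerate_attractors(net, envs = 121L)
  eng <- endmtbn:::engine_compile(net)
  nodes10 <- c("DLL4", "FGF2", "FLI1", "GATA2", "HIF1a", "PDGF_AB", "TGFB",
               "VEGFA", "WNT5b", "WNT7a")
  pos <- match(nodes10, net$nodes)
  states <- unlist(lapply(atlas$attractors, `[[`, "states"))
  owner <- rep(seq_along(atlas$attractors),
               vapply(atlas$attractors, `[[`, numeric(1), "period"))
  ord <- order(states)
  for (i in seq_along(atlas$attractors))
    for (s in atlas$attractors[[i]]$states) {
      # overwriting with the state's own bits must stay in the attractor
      res <- endmtbn:::cpp_walk_to_known(eng$regs, eng$tables, eng$n,
                                         as.integer(s),
                                         as.integer(states[ord]),
                                         as.integer(owner[ord]), 100L)
      expect_equal(res$attractor, i)
      expect_equal(res$transient, 0L)
    }
})

test_that("transition mapping rejects unknown perturbation nodes", {
  net <- wt_network()
  atlas <- enumerate_attractors(net, envs = 0L)
  expect_error(perturbation_transitions(net, atlas,
                                        perturb_nodes = c("DLL4", "XX")),
               "XX")
})

test_that("double mutant machinery reports profiles against wild type", {
  # small-scale check on a clamp that kills a source: qualitative profile
  # and counts are internally consistent
  net <- wt_network()
  rep1 <- mutant_report(net, c(HIF1a = 0L))
  expect_equal(sum(rep1$nine_counts), rep1$n_attractors)
  expect_error(double_mutant_analysis(net, c(A = 0L)), "two distinct")
})
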