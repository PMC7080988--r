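# Synchronous stepping, trajectory convergence, successor maps.

test_that("step matches hand evaluation on the toy network", {
  toy <- toy_net()
  expect_equal(step_state(toy, c(1, 0, 0)), c(1, 1, 0))
  # integer in, integer out
  expect_equal(step_state(toy, 1), bits_to_int_ref(c(1, 1, 0)))
})

test_that("step is deterministic and never alters source bits", {
  net <- wt_network()
  set.seed(21)
  src <- which(source_nodes(net))
  for (s in sample.int(2^29, 25) - 1) {
    a <- step_state(net, s)
    expect_identical(step_state(net, s), a)
    expect_equal(as_state_bits(net, a)[src], as_state_bits(net, s)[src])
  }
})

test_that("trajectories converge with correct transients and attractors", {
  toy <- toy_net()
  tr <- simulate_to_attractor(toy, c(0, 1, 1))
  expect_equal(tr$attractor$period, 1L)
  expect_equal(tr$attractor$states, 0)
  expect_lte(tr$transient_length, 3L)
  # a fixed point has transient 0
  tr0 <- simulate_to_attractor(toy, c(0, 0, 0))
  expect_equal(tr0$transient_length, 0L)
  expect_equal(tr0$attractor$states, 0)
  # trajectory states chain under the step map
  df <- trajectory_to_df(toy, tr)
  expect_equal(nrow(df), length(tr$states))
  for (i in seq_len(length(tr$states) - 1))
    expect_equal(step_state(toy, tr$states[i]), tr$states[i + 1])
})

test_that("a printed cyclic attractor state converges with transient 0", {
  net <- wt_network()
  tab <- printed_attractor_table()
  tr <- simulate_to_attractor(net, tab[, 5])
  expect_equal(tr$transient_length, 0L)
  expect_equal(tr$attractor$period, 4L)
  expect_setequal(tr$attractor$states,
                  vapply(5:8, function(cc) state_to_int(net, tab[, cc]),
                         numeric(1)))
})

test_that("successor maps equal reference stepping on small networks", {
  set.seed(31)
  for (rep in 1:6) {
    net <- random_network(sample(4:9, 1), n_src = sample(0:2, 1))
    n <- length(net$nodes)
    envs <- environments(net)
    for (e in envs$env_id) {
      sm <- build_successor_map(net, e)
      part <- endmtbn:::free_fixed_partition(net, e)
      for (cfg in seq_len(min(2^length(sm$free_nodes), 64)) - 1L) {
        full <- endmtbn:::free_config_to_int(part$free_idx0, part$fixed_idx0,
                                             part$fixed_val, cfg)
        nxt_ref <- r_step(net, as_state_bits(net, full))
        # project the reference successor onto the free nodes
        free_bits <- nxt_ref[part$free_idx0 + 1L]
        expect_equal(sm$successors[cfg + 1L],
                     as.integer(bits_to_int_ref(free_bits)))
      }
    }
  }
})

test_that("successor maps pin source bits to the environment", {
  net <- wt_network()
  sm <- build_successor_map(net, printed_table_env())
  expect_equal(length(sm$successors), 2^22)
  expect_equal(sort(names(sm$fixed)), sort(endmt_source_names()))
  expect_equal(sm$fixed[endmt_source_names()], printed_table_env())
})

test_that("environment bookkeeping covers all source assignments", {
  net <- wt_network()
  envs <- environments(net)
  expect_equal(nrow(envs), 128L)
  expect_equal(endmtbn:::environment_id(net, printed_table_env()),
               sum(c(1, 0, 0, 1, 1, 1, 1) * 2^(0:6)))
  expect_error(endmtbn:::environment_assignment(net, 128L), "unknown")
  expect_error(endmtbn:::environment_assignment(net, c(DLL4 = 1)), "source")
})
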