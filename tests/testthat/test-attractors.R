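# Exhaustive attractor enumeration and canonical representation.

test_that("toy network has the expected two attractors", {
  atlas <- enumerate_attractors(toy_net())
  expect_length(atlas$attractors, 2L)
  periods <- sort(vapply(atlas$attractors, `[[`, numeric(1), "period"))
  expect_equal(periods, c(1, 4))
  # the fixed point is the all-zero state; the cycle has A = 1 throughout
  fp <- atlas$attractors[[which(periods == 1)]]
  expect_equal(fp$states, 0)
  cyc <- atlas$attractors[[which.max(periods)]]
  expect_true(all(bitwAnd(as.integer(cyc$states), 1L) == 1L))
  # restricting to the A = 1 environment returns only the cycle
  expect_length(attractors_in_environment(atlas, 1L), 1L)
  expect_error(attractors_in_environment(atlas, 5L), "not covered")
})

test_that("enumeration equals brute-force simulation on random networks", {
  set.seed(41)
  for (rep in 1:8) {
    net <- random_network(sample(4:10, 1), n_src = sample(0:3, 1))
    atlas <- enumerate_attractors(net)
    expect_equal(atlas_attractor_keys(atlas), brute_attractor_keys(net))
  }
})

test_that("every state drains into an enumerated attractor", {
  set.seed(43)
  net <- random_network(8, n_src = 2L)
  atlas <- enumerate_attractors(net)
  keys <- unlist(lapply(atlas$attractors, `[[`, "states"))
  for (s in 0:(2^8 - 1)) {
    tr <- simulate_to_attractor(net, s)
    expect_true(all(tr$attractor$states %in% keys))
  }
})

test_that("canonicalization is rotation invariant and validates cycles", {
  net <- wt_network()
  tab <- printed_attractor_table()
  cyc <- vapply(1:4, function(cc) state_to_int(net, tab[, cc]), numeric(1))
  a1 <- canonicalize_attractor(net, cyc)
  for (k in 2:4) {
    rot <- cyc[c(k:4, seq_len(k - 1))]
    expect_equal(canonicalize_attractor(net, rot)$canonical_key,
                 a1$canonical_key)
    expect_equal(canonicalize_attractor(net, rot)$states, a1$states)
  }
  expect_equal(a1$period, 4L)
  # a fixed point canonicalizes to itself
  fp <- canonicalize_attractor(toy_net(), 0)
  expect_equal(fp$period, 1L)
  expect_equal(fp$canonical_key, 0)
  # a non-cycle is rejected
  expect_error(canonicalize_attractor(net, cyc[c(1, 3)]), "cycle")
  expect_error(canonicalize_attractor(net, c(cyc, cyc[1])), "distinct")
})

test_that("the printed-environment enumeration matches the published table", {
  net <- wt_network()
  atlas <- enumerate_attractors(net, envs = endmtbn:::environment_id(
    net, printed_table_env()))
  expect_length(atlas$attractors, 3L)
  expect_true(all(vapply(atlas$attractors, `[[`, numeric(1), "period") == 4))
  tab <- printed_attractor_table()
  printed <- lapply(c(1, 5, 9), function(c0)
    sort(vapply(c0:(c0 + 3), function(cc) state_to_int(net, tab[, cc]),
                numeric(1))))
  enumerated <- lapply(atlas$attractors, function(a) sort(a$states))
  expect_setequal(printed, enumerated)
})

test_that("atlas export has one row per attractor phase", {
  net <- toy_net()
  atlas <- enumerate_attractors(net)
  df <- atlas_to_df(net, atlas)
  expect_equal(nrow(df), sum(vapply(atlas$attractors, `[[`, numeric(1),
                                    "period")))
  expect_true(all(c("attractor", "period", "phase", "env_id", net$nodes)
                  %in% names(df)))
  cens <- attractor_census(atlas)
  expect_equal(unname(cens["total"]), 2L)
})
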