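# Generic resistive-network machinery: resistance/source formulas, nodal
# solver, least-squares oracle, and the conservation/branch-law contract.

test_that("Poiseuille resistance follows 128*mu*l/(pi*d^4)", {
  # 40 mm x 1.2 mm outlet tube in water, evaluated by hand
  R <- poiseuille_resistance(water, tube_spec(0.040, 0.0012))
  expect_equal(R, 128 * 0.001 * 0.040 / (pi * 0.0012^4))
  expect_equal(R, 7.8595e8, tolerance = 1e-4)

  # zero-length tube has no resistance
  expect_identical(poiseuille_resistance(water, tube_spec(0, 0.001)), 0)

  # d^4 scaling: doubling the diameter divides R by 16
  R1 <- poiseuille_resistance(water, tube_spec(0.1, 0.001))
  R2 <- poiseuille_resistance(water, tube_spec(0.1, 0.002))
  expect_equal(R1 / R2, 16)

  expect_error(tube_spec(0.1, 0), "diameter")
  expect_error(tube_spec(0.1, -0.001), "diameter")
  expect_error(tube_spec(-0.1, 0.001), "length")
})

test_that("hydrostatic source pressure is rho*g*z", {
  expect_equal(source_pressure(water, 0.110), 1078)   # upper reservoir head
  expect_equal(source_pressure(water, 0.200), 1960)   # pump head
  expect_identical(source_pressure(water, 0), 0)
  expect_equal(source_pressure(water, -0.05), -490)   # negative gauge allowed
  expect_equal(source_pressure(blood_mimic_fluid(), 0.1), 1050 * 9.8 * 0.1)
})

test_that("fluid and network constructors validate their invariants", {
  expect_error(fluid_properties(density = -1), "density")
  expect_error(fluid_properties(viscosity = 0), "viscosity")
  nodes <- data.frame(id = c("a", "b"), kind = "boundary", pressure = c(1, 0))
  expect_error(flow_network(nodes,
                            data.frame(id = "t", from = "a", to = "zz", R = 1)),
               "endpoints")
  expect_error(flow_network(nodes,
                            data.frame(id = "t", from = "a", to = "b", R = -1)),
               "resistances")
  expect_error(flow_network(data.frame(id = c("a", "b"), kind = "interior",
                                       pressure = c(1, NA)),
                            data.frame(id = "t", from = "a", to = "b", R = 1)),
               "interior")
})

test_that("nodal assembly has one equation per interior node, sorted", {
  # two boundary ends: nothing to solve
  sys0 <- assemble_nodal_system(make_single_tube())
  expect_identical(dim(sys0$matrix), c(0L, 0L))
  expect_length(sys0$unknowns, 0)

  # Y-network: one interior junction
  sys1 <- assemble_nodal_system(make_y_network())
  expect_identical(dim(sys1$matrix), c(1L, 1L))
  expect_identical(sys1$unknowns, "j")

  # full IVM: one unknown per interior node, deterministically ordered
  net <- default_ivm()
  sys <- assemble_nodal_system(net)
  interior <- sort(net$nodes$id[net$nodes$kind == "interior"])
  expect_identical(sys$unknowns, interior)
  expect_identical(nrow(sys$matrix), length(interior))
})

test_that("solve_flow matches hand-computed closed forms", {
  # single tube: q = dp / R
  net <- make_single_tube(1960, 1078, 7.8595e8)
  sol <- solve_flow(net)
  expect_equal(unname(sol$branch_flows["t"]), (1960 - 1078) / 7.8595e8)
  expect_equal(unname(sol$branch_flows["t"]), 1.1222e-6, tolerance = 1e-4)
  expect_equal(flow_to_ml_min(unname(sol$branch_flows["t"])), 67.33,
               tolerance = 1e-3)
  expect_valid_solution(net, sol)

  # equal end pressures: no flow anywhere
  sol0 <- solve_flow(make_single_tube(1000, 1000))
  expect_equal(unname(sol0$branch_flows["t"]), 0)

  # Y-network reduced by hand: series 1e8 with parallel(2e8, 2e8) = 2e8,
  # so q_total = 1960/2e8 = 9.8e-6, split equally
  ynet <- make_y_network()
  ysol <- solve_flow(ynet)
  expect_equal(unname(ysol$branch_flows["in"]), 9.8e-6)
  expect_equal(unname(ysol$branch_flows["l1"]), 4.9e-6)
  expect_equal(unname(ysol$branch_flows["l2"]), 4.9e-6)
  expect_equal(unname(ysol$node_pressures["j"]), 980)
  expect_valid_solution(ynet, ysol)
})

test_that("unsolvable components are reported, not silently NaN", {
  # interior node cut off from every boundary by a blocked bridge
  nodes <- data.frame(id = c("src", "mid", "tip"),
                      kind = c("boundary", "interior", "interior"),
                      pressure = c(1000, NA, NA))
  br <- data.frame(id = c("b1", "b2"), from = c("src", "mid"),
                   to = c("mid", "tip"), R = c(1e8, 1e8),
                   blocked = c(TRUE, FALSE))
  net <- flow_network(nodes, br)
  expect_error(solve_flow(net), "singular")
  expect_error(solve_flow(net), "mid")
  # oracle shares the same error path
  expect_error(oracle_solve(net), "singular")
})

test_that("blocked branches carry exactly zero flow and leave the rest intact", {
  ynet <- make_y_network()
  ynet$branches$blocked[ynet$branches$id == "l2"] <- TRUE
  sol <- solve_flow(ynet)
  expect_identical(unname(sol$branch_flows["l2"]), 0)
  # remaining series circuit: 1960 / 3e8
  expect_equal(unname(sol$branch_flows["in"]), 1960 / 3e8)
  expect_valid_solution(ynet, sol)
})

test_that("verify_solution flags violated branches and nodes", {
  net <- make_y_network()
  sol <- solve_flow(net)
  expect_true(verify_solution(net, sol)$pass)

  bad <- sol
  bad$branch_flows["l1"] <- bad$branch_flows["l1"] * 1.1
  chk <- verify_solution(net, bad)
  expect_false(chk$pass)
  expect_identical(chk$worst_branch, "l1")

  # all-zero flows on unequal boundary pressures violate the branch law
  zero <- sol
  zero$branch_flows[] <- 0
  expect_false(verify_solution(net, zero)$pass)

  sol$node_pressures <- sol$node_pressures[-1]
  expect_error(verify_solution(net, sol), "incomplete")
})

test_that("oracle and nodal solver agree on hand examples and seeded networks", {
  for (net in list(make_single_tube(), make_single_tube(1000, 1000),
                   make_y_network())) {
    s1 <- solve_flow(net)
    s2 <- oracle_solve(net)
    expect_lt(max_rel_diff(s1$branch_flows, s2$branch_flows), 1e-8)
  }
  for (seed in 1:25) {
    net <- random_network_fixture(seed, n_nodes = 5 + seed %% 16,
                                  n_boundary = 1 + seed %% 4)
    s1 <- solve_flow(net)
    s2 <- oracle_solve(net)
    expect_lt(max_rel_diff(s1$branch_flows, s2$branch_flows), 1e-8)
    expect_lt(max_rel_diff(s1$node_pressures, s2$node_pressures), 1e-8)
    expect_valid_solution(net, s1)
  }
})

test_that("solutions are linear in the boundary pressures (superposition)", {
  for (seed in c(3, 11, 42)) {
    net <- random_network_fixture(seed, 12, 3)
    s1 <- solve_flow(net)
    k <- 2.5
    net2 <- net
    bnd <- net2$nodes$kind == "boundary"
    net2$nodes$pressure[bnd] <- k * net2$nodes$pressure[bnd]
    s2 <- solve_flow(net2)
    expect_equal(s2$branch_flows, k * s1$branch_flows, tolerance = 1e-10)
  }
})

test_that("raising one branch resistance never raises its own flow magnitude", {
  for (seed in 1:10) {
    net <- random_network_fixture(seed, 10, 3)
    sol <- solve_flow(net)
    k <- 1 + (seed %% nrow(net$branches))
    net2 <- net
    net2$branches$R[k] <- net2$branches$R[k] * 4
    sol2 <- solve_flow(net2)
    id <- net$branches$id[k]
    expect_lte(abs(sol2$branch_flows[[id]]),
               abs(sol$branch_flows[[id]]) * (1 + 1e-12) + 1e-30)
  }
})

test_that("Reynolds diagnostic uses 4*rho*q/(pi*mu*d)", {
  net <- default_ivm()
  sol <- solve_flow(net)
  re <- branch_reynolds(net, sol, water)
  q7 <- abs(sol$branch_flows[["t_S7"]])
  expect_equal(re[["t_S7"]], 4 * 1000 * q7 / (pi * 0.001 * 0.0012))
  # bench circuit stays laminar
  expect_true(all(re < 2300, na.rm = TRUE))
})
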