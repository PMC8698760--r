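# shared fixtures: tiny hand-reducible networks and default IVM pieces

water <- fluid_properties()

# one tube between two fixed-pressure ends (pump head vs upper reservoir)
make_single_tube <- function(p_from = 1960, p_to = 1078, R = 7.8595e8) {
  flow_network(
    nodes = data.frame(id = c("a", "b"), kind = "boundary",
                       pressure = c(p_from, p_to)),
    branches = data.frame(id = "t", from = "a", to = "b", R = R)
  )
}

# source -> junction -> two identical legs to ground
make_y_network <- function(p_src = 1960, R_in = 1e8, R_leg = 2e8) {
  flow_network(
    nodes = data.frame(id = c("src", "j", "g1", "g2"),
                       kind = c("boundary", "interior", "boundary", "boundary"),
                       pressure = c(p_src, NA, 0, 0)),
    branches = data.frame(id = c("in", "l1", "l2"),
                          from = c("src", "j", "j"),
                          to = c("j", "g1", "g2"),
                          R = c(R_in, R_leg, R_leg))
  )
}

default_ivm <- function(scenario = cancer_scenario("S7")) {
  build_ivm_network(ivm_config(), scenario)
}

expect_valid_solution <- function(network, solution, tol = 1e-9) {
  chk <- verify_solution(network, solution, tol = tol)
  expect_true(chk$pass,
              info = sprintf("residuals: branch %.3e (%s), node %.3e (%s)",
                             chk$max_branch_residual, chk$worst_branch,
                             chk$max_node_residual, chk$worst_node))
  invisible(chk)
}

max_rel_diff <- function(a, b, floor = 1e-12) {
  stopifnot(length(a) == length(b))
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}
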