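# BOASP, PGE detection (dual criterion), injectate tracing, outcome
# classification and occlusion-site sweeps.

case1 <- cancer_scenario("S7")
case2 <- cancer_scenario(c("S5", "S7"))
REF <- ivm_reference_pressures(ivm_config())

test_that("BOASP is the stump pressure distal to the balloon", {
  net <- default_ivm(case1)
  base <- solve_flow(net)

  occ_c <- apply_occlusion(net, "c")
  sol_c <- solve_flow(occ_c)
  bo_c <- compute_boasp(base, sol_c, occ_c)
  expect_equal(bo_c$pressure_before, base$node_pressures[["n_RHA"]])
  expect_equal(bo_c$boasp, sol_c$node_pressures[["n_RHA"]])
  expect_lt(bo_c$boasp, REF[["URP"]])        # distal to the CA: PGE regime
  expect_lt(bo_c$boasp, bo_c$pressure_before)

  occ_b <- apply_occlusion(net, "b")
  bo_b <- compute_boasp(base, solve_flow(occ_b), occ_b)
  expect_gt(bo_b$boasp, REF[["URP"]])        # between the CA pathways

  # occluding a branch that carried no baseline flow changes nothing:
  # the left-lateral sibling collateral is flowless under Case 1 symmetry
  expect_lt(abs(base$branch_flows[["c_S2_S3_1"]]), 1e-15)
  occ_z <- apply_occlusion(net, "c_S2_S3_1")
  bo_z <- compute_boasp(base, solve_flow(occ_z), occ_z)
  expect_equal(bo_z$boasp, bo_z$pressure_before, tolerance = 1e-12)

  expect_error(compute_boasp(base, base, net), "no occlusion")
})

test_that("PGE window is strict and agrees with the flow-reversal criterion", {
  # boundary equality maps to FALSE
  expect_false(detect_pge(REF[["URP"]], REF[["URP"]], REF[["LRP"]]))
  expect_false(detect_pge(REF[["LRP"]], REF[["URP"]], REF[["LRP"]]))
  expect_true(detect_pge(mean(REF[c("URP", "LRP")]), REF[["URP"]], REF[["LRP"]]))
  expect_error(detect_pge(900, 1000, 1000), "URP must exceed LRP")

  # Experiment 1 (site 'c', Case 1): PGE with reversal at S5, S6, S8
  a1 <- assess_occlusion(ivm_config(), case1, "c")
  expect_true(a1$pge)
  q <- outlet_flows(a1$occluded)
  expect_true(all(q[c("S5", "S6", "S8")] < 0))
  expect_gt(q[["S7"]], 0)

  # site 'h': effective without PGE
  ah <- assess_occlusion(ivm_config(), case1, "h")
  expect_false(ah$pge)

  # dual criterion agrees on every site and both cases
  for (sc in list(case1, case2))
    for (s in letters[1:9])
      expect_s3_class(assess_occlusion(ivm_config(), sc, s),
                      "occlusion_assessment")
})

test_that("injectate tracing follows the occluded flow field", {
  net <- default_ivm(case1)

  # Experiment 1: site 'c' delivers to the tumor-bearing segment only
  a1 <- assess_occlusion(ivm_config(), case1, "c")
  expect_identical(a1$reached, "S7")
  expect_identical(a1$outcome, "successful")

  # Experiment 2: site 'b' floods the whole right lobe via the CA
  a2 <- assess_occlusion(ivm_config(), case1, "b")
  expect_setequal(a2$reached, c("S5", "S6", "S7", "S8"))
  expect_identical(a2$outcome, "unsuccessful")

  # no occlusion, injection at the inlet: all eight outlets
  base <- solve_flow(net)
  all8 <- trace_injectate(net, base)
  expect_setequal(as.character(all8), names(outlet_flows(base)))

  # Experiments 3-4 (Case 2 analogues)
  a3 <- assess_occlusion(ivm_config(), case2, "c")
  expect_setequal(a3$reached, c("S5", "S7"))
  expect_identical(a3$outcome, "successful")
  a4 <- assess_occlusion(ivm_config(), case2, "b")
  expect_setequal(a4$reached, c("S5", "S6", "S7", "S8"))
  expect_identical(a4$outcome, "unsuccessful")
})

test_that("outcome classification requires non-empty tumor-only delivery", {
  expect_identical(classify_outcome("S7", case1), "successful")
  expect_identical(classify_outcome(c("S5", "S6", "S7", "S8"), case1),
                   "unsuccessful")
  expect_identical(classify_outcome(character(0), case1), "unsuccessful")
  expect_identical(classify_outcome(c("S5", "S7"), case2), "successful")
})

test_that("the occlusion-site sweep reproduces the bench classification", {
  sw <- occlusion_sweep(ivm_config(), case1, sites = c("b", "c", "e", "f", "h"))
  expect_identical(sw$site[sw$pge], c("c", "f"))
  expect_identical(sw$site[sw$outcome == "successful"], c("c", "f", "h"))
  h <- sw[sw$site == "h", ]
  expect_false(h$pge)
  expect_identical(h$reached, "S7")
  expect_true(all(sw$physically_tested))
  expect_error(occlusion_sweep(ivm_config(), case1, sites = "q"), "unknown site")
})

test_that("stump pressures fall proximal to distal and stay in [LRP, IP]", {
  sw <- occlusion_sweep(ivm_config(), case1)   # all nine sites
  expect_true(all(diff(sw$p_before_pa) < 0))
  expect_true(all(sw$boasp_pa >= attr(sw, "LRP") - 1e-9))
  expect_true(all(sw$boasp_pa <= attr(sw, "IP") + 1e-9))
  expect_true(all(sw$boasp_pa <= sw$p_before_pa))
})

test_that("occluding between the CA pathways throttles but feeds the right lobe", {
  net <- default_ivm(case1)
  base <- solve_flow(net)
  occ <- apply_occlusion(net, "b")
  sol <- solve_flow(occ)
  right <- c("S5", "S6", "S7", "S8")
  q_base <- outlet_flows(base)[right]
  q_occ <- outlet_flows(sol)[right]
  expect_true(all(q_occ > 0))
  expect_lt(sum(q_occ), sum(q_base))
})

test_that("removing a blocked branch equals the resistance-limit solution", {
  net <- default_ivm(case1)
  occ <- apply_occlusion(net, "c")
  sol_removed <- solve_flow(occ)

  limit <- net
  k <- limit$branches$id == "b_RHA_3"
  limit$branches$R[k] <- limit$branches$R[k] * 1e12
  sol_limit <- solve_flow(limit)

  expect_lt(max_rel_diff(sol_removed$node_pressures, sol_limit$node_pressures,
                         floor = 1), 1e-6)
  keep <- names(sol_removed$branch_flows) != "b_RHA_3"
  expect_lt(max_rel_diff(sol_removed$branch_flows[keep],
                         sol_limit$branch_flows[keep], floor = 1e-10), 1e-6)
})

test_that("reflecting Case 1 to the left lobe mirrors the assessment exactly", {
  cfg <- ivm_config()
  scR <- case1                      # tumor S7, occlusions on the right path
  scL <- cancer_scenario("S2")      # mirrored tumor

  for (site_branch in c("b_RHA_3", "b_RHA_2", "b_RHA_post_3", "b_S7_2")) {
    netR <- apply_occlusion(build_ivm_network(cfg, scR), site_branch)
    netL <- apply_occlusion(build_ivm_network(cfg, scL), mirror_id(site_branch))
    solR <- solve_flow(netR)
    solL <- solve_flow(netL)
    pR <- solR$node_pressures
    expect_lt(max(abs(solL$node_pressures[mirror_id(names(pR))] - pR) /
                    pmax(abs(pR), 1)), 1e-10)
    qR <- outlet_flows(solR)
    qL <- outlet_flows(solL)
    expect_equal(unname(qL[mirror_id(names(qR))]), unname(qR),
                 tolerance = 1e-10)
    expect_setequal(mirror_id(trace_injectate(netR, solR)),
                    as.character(trace_injectate(netL, solL)))
  }
})
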