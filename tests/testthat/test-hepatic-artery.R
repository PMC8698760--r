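# Hepatic artery phantom: binary tree construction, collateral attachment,
# balloon-site map and the left-right mirror.

test_that("the main tree is a full binary tree with 8 labeled outlets", {
  tree <- build_hepatic_tree()
  meta <- attr(tree, "artery")
  expect_length(meta$outlets, 8)
  expect_setequal(names(meta$outlets),
                  c("S2", "S3", "S4a", "S4b", "S5", "S6", "S7", "S8"))
  expect_identical(nrow(tree$branches), 15L)    # 1 + 2 + 4 + 8
  expect_true(all(tree$nodes$kind == "interior"))
  # one inlet, and each outlet is a leaf of the branch graph
  deg <- table(c(tree$branches$from, tree$branches$to))
  expect_identical(unname(deg[["n_inlet"]]), 1L)
  for (o in meta$outlets) expect_identical(unname(deg[[o]]), 1L)
})

test_that("tree construction is deterministic and validates its spec", {
  t1 <- build_hepatic_tree()
  t2 <- build_hepatic_tree()
  expect_identical(t1$nodes, t2$nodes)
  expect_identical(t1$branches, t2$branches)
  # diameters must taper with generation
  expect_error(hepatic_tree_spec(segmental = tube_spec(0.02, 0.005)),
               "non-increasing")
})

test_that("collaterals connect the RHA and LHA sides and keep symmetry", {
  tree <- build_hepatic_tree()
  net <- attach_collaterals(tree)
  # two communicating-arcade pathways exist
  expect_true(all(c("c_RHA_LHA_1", "c_RHA_LHA_2") %in% net$branches$id))
  # removing the PHA still leaves right- and left-side outlets connected
  cut <- net
  cut$branches <- cut$branches[cut$branches$id != "b_PHA", ]
  g <- igraph::graph_from_data_frame(cut$branches[, c("from", "to")],
                                     directed = FALSE)
  expect_true(igraph::distances(g, "o_S7", "o_S2") < Inf)

  # empty collateral spec returns the fragment untouched
  same <- attach_collaterals(tree, collateral_spec(levels = character(0)))
  expect_identical(same$branches, tree$branches)

  # collateral resistance exceeds the same-generation main branch resistance
  R <- setNames(net$branches$R, net$branches$id)
  expect_gt(R[["c_RHA_LHA_1"]], 3 * R[["b_RHA_1"]])

  # left and right subtrees are structurally mirror images: node ids and
  # main-branch ids are closed under the mirror; collateral edges mirror to
  # edges with the same (unordered) endpoints
  expect_setequal(mirror_id(net$nodes$id), net$nodes$id)
  main_ids <- net$branches$id[!startsWith(net$branches$id, "c_")]
  expect_setequal(mirror_id(main_ids), main_ids)
  ep <- function(from, to) paste(pmin(from, to), pmax(from, to))
  coll <- net$branches[startsWith(net$branches$id, "c_"), ]
  expect_setequal(ep(mirror_id(coll$from), mirror_id(coll$to)),
                  ep(coll$from, coll$to))
})

test_that("the balloon-site map orders a..i proximal to distal on the S7 path", {
  net <- attach_collaterals(build_hepatic_tree())
  map <- map_balloon_sites(net)
  expect_identical(map$site, letters[1:9])
  expect_identical(map$level, rep(c("lobar", "sectional", "segmental"), each = 3))

  # 'b' lies between the CA pathways, 'c' distal to both
  expect_identical(map$branch[map$site == "b"], "b_RHA_2")
  expect_identical(map$branch[map$site == "c"], "b_RHA_3")
  expect_identical(balloon_location(1), "c")
  expect_identical(balloon_location(2), "b")
  expect_error(balloon_location(3), "unknown")

  # every site branch lies on the unique inlet -> o_S7 main-tree path
  main <- net$branches[!startsWith(net$branches$id, "c_"), ]
  g <- igraph::graph_from_data_frame(main[, c("from", "to")], directed = TRUE)
  path <- names(igraph::shortest_paths(g, "n_inlet", "o_S7")$vpath[[1]])
  on_path <- main$id[main$from %in% path & main$to %in% path]
  expect_true(all(map$branch %in% on_path))
  # distal nodes appear in strictly increasing path order
  pos <- match(map$distal_node, path)
  expect_false(any(is.na(pos)))
  expect_true(all(diff(pos) > 0))

  expect_setequal(map$site[map$physically_testable], c("b", "c", "e", "f", "h"))
})

test_that("site mapping demands an explicit list on non-default topology", {
  bare <- build_hepatic_tree()   # no collaterals -> no attachment nodes
  expect_error(map_balloon_sites(bare), "explicit site list")
})

test_that("mirror_id is an involution mapping right to left", {
  ids <- c("S7", "S5", "o_S6", "b_RHA_post_2", "n_RHA_att1", "t_S8", "b_PHA")
  expect_identical(mirror_id(ids),
                   c("S2", "S4b", "o_S3", "b_LHA_lat_2", "n_LHA_att1",
                     "t_S4a", "b_PHA"))
  expect_identical(mirror_id(mirror_id(ids)), ids)
})
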