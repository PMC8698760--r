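# Symmetric bifurcating hepatic artery phantom: PHA -> {LHA, RHA} -> four
# sectional -> eight segmental arteries (Couinaud S2..S8), plus collateral
# pathways (communicating arcade between RHA and LHA, and same-generation
# sibling connections), and the proximal-to-distal balloon site map a..i.

SEGMENT_LABELS <- c("S2", "S3", "S4a", "S4b", "S5", "S6", "S7", "S8")

# main-tree topology: full binary tree, deterministic ids.
# level: pha (1 branch), lobar (2), sectional (4), segmental (8)
.tree_topology <- function() {
  data.frame(
    id    = c("b_PHA",
              "b_LHA", "b_RHA",
              "b_LHA_lat", "b_LHA_med", "b_RHA_ant", "b_RHA_post",
              "b_S2", "b_S3", "b_S4a", "b_S4b", "b_S5", "b_S8", "b_S6", "b_S7"),
    from  = c("n_inlet",
              "n_PHA", "n_PHA",
              "n_LHA", "n_LHA", "n_RHA", "n_RHA",
              "n_LHA_lat", "n_LHA_lat", "n_LHA_med", "n_LHA_med",
              "n_RHA_ant", "n_RHA_ant", "n_RHA_post", "n_RHA_post"),
    to    = c("n_PHA",
              "n_LHA", "n_RHA",
              "n_LHA_lat", "n_LHA_med", "n_RHA_ant", "n_RHA_post",
              "o_S2", "o_S3", "o_S4a", "o_S4b", "o_S5", "o_S8", "o_S6", "o_S7"),
    level = c("pha",
              "lobar", "lobar",
              rep("sectional", 4),
              rep("segmental", 8)),
    stringsAsFactors = FALSE
  )
}

# sibling pairs joined by same-generation collaterals; the lobar pair is the
# communicating arcade (CA) between the RHA and the LHA
.collateral_pairs <- function() {
  data.frame(
    level = c("lobar", "sectional", "sectional",
              "segmental", "segmental", "segmental", "segmental"),
    x = c("b_RHA", "b_RHA_ant", "b_LHA_lat", "b_S5", "b_S6", "b_S2", "b_S4a"),
    y = c("b_LHA", "b_RHA_post", "b_LHA_med", "b_S8", "b_S7", "b_S3", "b_S4b"),
    stringsAsFactors = FALSE
  )
}

#' Hepatic artery tree geometry
#'
#' Per-generation tube dimensions of the symmetric bifurcating hepatic
#' artery phantom.  The defaults are calibration values for a real-scale
#' phantom: diameters taper from 4 mm at the proper hepatic artery (PHA) to
#' 2 mm at the segmental arteries, with lengths of a few centimetres per
#' generation.  Their only contract is reproducing the qualitative bench
#' behaviour (flow toward all segments at baseline, tumor preference, and
#' the occlusion-site-dependent pressure-gradient effect); every value can
#' be overridden.
#'
#' @param pha,lobar,sectional,segmental [tube_spec()] objects for the PHA,
#'   the left/right hepatic arteries, the four sectional arteries and the
#'   eight segmental arteries respectively.
#'
#' @return An object of class `hepatic_tree_spec`.
#' @export
hepatic_tree_spec <- function(pha = tube_spec(0.030, 0.0040),
                              lobar = tube_spec(0.030, 0.0030),
                              sectional = tube_spec(0.025, 0.0025),
                              segmental = tube_spec(0.020, 0.0020)) {
  spec <- list(pha = pha, lobar = lobar, sectional = sectional,
               segmental = segmental)
  ok <- vapply(spec, inherits, logical(1), what = "tube_spec")
  if (!all(ok)) stop("all generation specs must be tube_spec objects", call. = FALSE)
  d <- vapply(spec, `[[`, numeric(1), "diameter")
  if (is.unsorted(rev(d)))
    stop("diameters must be non-increasing with generation", call. = FALSE)
  structure(spec, class = "hepatic_tree_spec")
}

#' Collateral pathway specification
#'
#' Collaterals join each pair of sibling branches at two attachment points
#' (at one third and two thirds of the branch length).  The lobar-level pair
#' models the communicating arcade (CA) between the right and left hepatic
#' arteries; sectional- and segmental-level pairs model intersegmental
#' connections (hilar plexus).  Default collateral tubes are thinner than
#' same-generation main branches, hence of higher hydraulic resistance.
#'
#' @param ca [tube_spec()] for the two CA pathways (lobar level).
#' @param same_level [tube_spec()] for sectional/segmental sibling
#'   connections.
#' @param levels Character subset of `c("lobar", "sectional", "segmental")`
#'   selecting which collateral levels to build; `character(0)` disables
#'   collaterals entirely.
#'
#' @return An object of class `collateral_spec`.
#' @export
collateral_spec <- function(ca = tube_spec(0.015, 0.0012),
                            same_level = tube_spec(0.015, 0.0012),
                            levels = c("lobar", "sectional", "segmental")) {
  if (!inherits(ca, "tube_spec") || !inherits(same_level, "tube_spec"))
    stop("'ca' and 'same_level' must be tube_spec objects", call. = FALSE)
  if (!all(levels %in% c("lobar", "sectional", "segmental")))
    stop("unknown collateral level", call. = FALSE)
  structure(list(ca = ca, same_level = same_level, levels = levels),
            class = "collateral_spec")
}

#' Build the main hepatic artery tree
#'
#' Constructs the 15-branch full binary tree (PHA, two lobar, four
#' sectional, eight segmental arteries) as a flow-network fragment with
#' Poiseuille resistances.  All nodes are interior; the single inlet node is
#' `n_inlet` and the eight segmental outlet nodes are `o_S2` .. `o_S8`.
#' Node and branch ids are deterministic.
#'
#' @param spec A [hepatic_tree_spec()].
#' @param fluid A [fluid_properties()] object.
#'
#' @return A [flow_network()] fragment with attribute `artery` (a list with
#'   `inlet`, `outlets`, `segments`, `spec`).
#' @export
build_hepatic_tree <- function(spec = hepatic_tree_spec(),
                               fluid = fluid_properties()) {
  if (!inherits(spec, "hepatic_tree_spec"))
    stop("'spec' must be a hepatic_tree_spec", call. = FALSE)
  topo <- .tree_topology()
  tubes <- lapply(topo$level, function(lv) spec[[lv]])
  nodes <- data.frame(id = unique(c(topo$from, topo$to)),
                      kind = "interior", pressure = NA_real_,
                      elevation = NA_real_, stringsAsFactors = FALSE)
  branches <- data.frame(
    id = topo$id, from = topo$from, to = topo$to,
    R = vapply(tubes, function(t) poiseuille_resistance(fluid, t), numeric(1)),
    blocked = FALSE,
    length = vapply(tubes, `[[`, numeric(1), "length"),
    diameter = vapply(tubes, `[[`, numeric(1), "diameter"),
    level = topo$level,
    stringsAsFactors = FALSE
  )
  net <- flow_network(nodes, branches)
  outlets <- setNames(paste0("o_", SEGMENT_LABELS), SEGMENT_LABELS)
  if (!all(outlets %in% net$nodes$id) || length(outlets) != 8L)
    stop("invalid tree spec: expected exactly 8 labeled segmental outlets",
         call. = FALSE)
  attr(net, "artery") <- list(inlet = "n_inlet", outlets = outlets,
                              segments = SEGMENT_LABELS, spec = spec,
                              collaterals = NULL)
  net
}

# split branch `bid` into three equal-length sub-branches `bid_1..3`,
# inserting attachment nodes <stem>_att1, <stem>_att2 (stem = bid minus the
# "b_" prefix, prefixed "n_")
.split_branch <- function(net, bid) {
  br <- net$branches
  k <- match(bid, br$id)
  if (is.na(k)) stop("cannot split: no branch '", bid, "'", call. = FALSE)
  stem <- sub("^b_", "", bid)
  att <- paste0("n_", stem, "_att", 1:2)
  row <- br[k, ]
  sub <- row[rep(1, 3), ]
  sub$id <- paste0(bid, "_", 1:3)
  sub$from <- c(row$from, att[1], att[2])
  sub$to <- c(att[1], att[2], row$to)
  sub$R <- row$R / 3
  sub$length <- row$length / 3
  net$branches <- rbind(br[-k, ], sub)
  net$nodes <- rbind(net$nodes,
                     data.frame(id = att, kind = "interior",
                                pressure = NA_real_, elevation = NA_real_,
                                stringsAsFactors = FALSE))
  rownames(net$branches) <- rownames(net$nodes) <- NULL
  net
}

#' Attach collateral pathways to the hepatic artery tree
#'
#' For every sibling pair at the selected levels, the two main branches are
#' subdivided into three equal sub-branches (creating attachment nodes at
#' one and two thirds of their length) and joined by two collateral tubes,
#' one per attachment level.  The lobar pair forms the two pathways of the
#' communicating arcade connecting the RHA and LHA sides.  Left--right
#' structural symmetry of the tree is preserved.
#'
#' @param tree Output of [build_hepatic_tree()].
#' @param collaterals A [collateral_spec()]; `levels = character(0)` returns
#'   the tree unchanged.
#' @param fluid A [fluid_properties()] object.
#'
#' @return The augmented [flow_network()] fragment.
#' @export
attach_collaterals <- function(tree, collaterals = collateral_spec(),
                               fluid = fluid_properties()) {
  if (!inherits(collaterals, "collateral_spec"))
    stop("'collaterals' must be a collateral_spec", call. = FALSE)
  meta <- attr(tree, "artery")
  if (is.null(meta)) stop("'tree' must come from build_hepatic_tree", call. = FALSE)
  pairs <- .collateral_pairs()
  pairs <- pairs[pairs$level %in% collaterals$levels, , drop = FALSE]
  if (!nrow(pairs)) return(tree)

  net <- tree
  to_split <- unique(c(pairs$x, pairs$y))
  missing <- setdiff(to_split, net$branches$id)
  if (length(missing))
    stop("dangling collateral attachment: no branch ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (bid in to_split) net <- .split_branch(net, bid)

  coll <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    tube <- if (pairs$level[i] == "lobar") collaterals$ca else collaterals$same_level
    xs <- sub("^b_", "", pairs$x[i]); ys <- sub("^b_", "", pairs$y[i])
    data.frame(
      id = paste0("c_", xs, "_", ys, "_", 1:2),
      from = paste0("n_", xs, "_att", 1:2),
      to = paste0("n_", ys, "_att", 1:2),
      R = poiseuille_resistance(fluid, tube),
      blocked = FALSE,
      length = tube$length, diameter = tube$diameter,
      level = paste0("collateral_", pairs$level[i]),
      stringsAsFactors = FALSE
    )
  }))
  net$branches <- rbind(net$branches, coll)
  rownames(net$branches) <- NULL
  meta$collaterals <- collaterals
  attr(net, "artery") <- meta
  net
}

#' Balloon occlusion site map
#'
#' The nine candidate microballoon sites `a` .. `i` lie on the unique main
#' path PHA -> RHA -> right posterior sectional -> S7 segmental artery.  At
#' each of the three path levels the collaterals attach at two points,
#' giving three occludable sub-branches per level: proximal to both
#' attachments, between them, and distal to both.  Clinically reported
#' "location 1" (RHA distal to the communicating-arcade pathways) is site
#' `c`; "location 2" (RHA between the pathways) is site `b`.
#'
#' @param tree A tree with default collaterals attached
#'   ([attach_collaterals()]).
#'
#' @return A data frame (class `balloon_site_map`) with columns `site`,
#'   `branch`, `distal_node`, `level`, `position`, and
#'   `physically_testable` (the bench subset `b, c, e, f, h`; the balloon
#'   length prevents placement at `a`, `d`, `g`, and `i` is beyond the
#'   segmental artery).
#' @export
map_balloon_sites <- function(tree) {
  map <- data.frame(
    site = letters[1:9],
    branch = c("b_RHA_1", "b_RHA_2", "b_RHA_3",
               "b_RHA_post_1", "b_RHA_post_2", "b_RHA_post_3",
               "b_S7_1", "b_S7_2", "b_S7_3"),
    distal_node = c("n_RHA_att1", "n_RHA_att2", "n_RHA",
                    "n_RHA_post_att1", "n_RHA_post_att2", "n_RHA_post",
                    "n_S7_att1", "n_S7_att2", "o_S7"),
    level = rep(c("lobar", "sectional", "segmental"), each = 3),
    position = rep(c("proximal", "between", "distal"), 3),
    stringsAsFactors = FALSE
  )
  map$physically_testable <- map$site %in% c("b", "c", "e", "f", "h")
  missing <- setdiff(map$branch, tree$branches$id)
  if (length(missing))
    stop("non-default artery topology: sites ",
         paste(map$site[map$branch %in% missing], collapse = ", "),
         " cannot be placed; provide an explicit site list in the config",
         call. = FALSE)
  class(map) <- c("balloon_site_map", "data.frame")
  map
}

#' Resolve a clinically reported microballoon location to a site label
#'
#' @param location 1 (RHA distal to the communicating-arcade pathways) or
#'   2 (RHA between the pathways).
#' @return A site label, `"c"` or `"b"`.
#' @export
balloon_location <- function(location) {
  if (identical(as.numeric(location), 1)) return("c")
  if (identical(as.numeric(location), 2)) return("b")
  stop("unknown microballoon location: ", location, call. = FALSE)
}

#' Mirror an id across the left--right symmetry of the default tree
#'
#' The default geometry is mirror symmetric: the right lobe maps onto the
#' left lobe with RHA <-> LHA, anterior <-> medial, posterior <-> lateral
#' sectional arteries and segment pairs S5<->S4b, S8<->S4a, S6<->S3,
#' S7<->S2.  Applies to node, branch, and segment labels alike.
#'
#' @param ids Character vector of ids or segment labels.
#' @return The mirrored ids.
#' @export
#' @examples
#' mirror_id(c("S7", "b_RHA_post_2", "o_S5"))
mirror_id <- function(ids) {
  pairs <- list(c("RHA_ant", "LHA_med"), c("RHA_post", "LHA_lat"),
                c("RHA", "LHA"), c("S4a", "S8"), c("S4b", "S5"),
                c("S2", "S7"), c("S3", "S6"))
  out <- ids
  for (k in seq_along(pairs)) {
    out <- gsub(pairs[[k]][1], sprintf("@%dA@", k), out, fixed = TRUE)
    out <- gsub(pairs[[k]][2], sprintf("@%dB@", k), out, fixed = TRUE)
  }
  for (k in seq_along(pairs)) {
    out <- gsub(sprintf("@%dA@", k), pairs[[k]][2], out, fixed = TRUE)
    out <- gsub(sprintf("@%dB@", k), pairs[[k]][1], out, fixed = TRUE)
  }
  out
}

#' Print the artery tree as an indented outline
#'
#' @param tree A tree fragment (with or without collaterals).
#' @param ... Unused.
#' @return `tree`, invisibly.
#' @export
describe_tree <- function(tree, ...) {
  br <- tree$branches
  main <- br[!startsWith(br$id, "c_"), , drop = FALSE]
  recurse <- function(node, depth) {
    kids <- main[main$from == node, , drop = FALSE]
    for (i in seq_len(nrow(kids))) {
      cat(strrep("  ", depth), kids$id[i],
          sprintf(" (l=%.1f mm, d=%.2f mm, R=%.3g)", 1000 * kids$length[i],
                  1000 * kids$diameter[i], kids$R[i]),
          " -> ", kids$to[i], "\n", sep = "")
      recurse(kids$to[i], depth + 1)
    }
  }
  cat("n_inlet\n")
  recurse("n_inlet", 1)
  coll <- br[startsWith(br$id, "c_"), , drop = FALSE]
  if (nrow(coll)) {
    cat("collaterals:\n")
    for (i in seq_len(nrow(coll)))
      cat("  ", coll$id[i], ": ", coll$from[i], " <-> ", coll$to[i], "\n", sep = "")
  }
  invisible(tree)
}
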