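# Full in vitro model (IVM) circuit: constant-head pump, inflow tube,
# collateralized hepatic artery phantom, and per-outlet tubes routed by
# three-way stopcocks to the upper (normal tissue) or lower (tumor tissue)
# reservoir.  Reservoir free-surface levels are constant, so reservoirs and
# pump are ideal constant-pressure sources.

#' IVM circuit configuration
#'
#' All geometric parameters of the bench circuit.  The seven sizing
#' parameters default to the values found adequate for demonstrating the
#' pressure-gradient effect: outlet tubes 40 mm x 1.2 mm to both
#' reservoirs, lower-reservoir free surface at 80 mm, upper at 110 mm, and
#' a 200 mm pump head (heights measured from the pump datum; the artery
#' itself is horizontal, so gravity enters only through these heads).
#'
#' @param fluid A [fluid_properties()] object.
#' @param tree A [hepatic_tree_spec()].
#' @param collaterals A [collateral_spec()].
#' @param outlet_tube_lr,outlet_tube_ur [tube_spec()] for the tubes
#'   connecting artery outlets to the lower / upper reservoir.
#' @param z_lr,z_ur Free-surface heights of the lower and upper reservoirs
#'   (m).  The upper reservoir must sit above the lower one
#'   (`z_ur > z_lr`), which is what drives the gravity flow of the
#'   pressure-gradient effect.
#' @param h_pump Pump head (m); must exceed `z_ur` so that the pump can
#'   feed both reservoirs at baseline.
#' @param inflow_tube [tube_spec()] for the tube feeding the artery inlet
#'   (celiac / common hepatic artery surrogate).
#' @param strict If `TRUE` (default) violations of the height ordering
#'   raise an error; the sizing search sets `FALSE` to evaluate infeasible
#'   candidates as failures rather than exceptions.
#'
#' @return An object of class `ivm_config`.
#' @export
ivm_config <- function(fluid = fluid_properties(),
                       tree = hepatic_tree_spec(),
                       collaterals = collateral_spec(),
                       outlet_tube_lr = tube_spec(0.040, 0.0012),
                       outlet_tube_ur = tube_spec(0.040, 0.0012),
                       z_lr = 0.080,
                       z_ur = 0.110,
                       h_pump = 0.200,
                       inflow_tube = tube_spec(0.300, 0.0040),
                       strict = TRUE) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(tree, "hepatic_tree_spec"),
            inherits(collaterals, "collateral_spec"),
            inherits(outlet_tube_lr, "tube_spec"),
            inherits(outlet_tube_ur, "tube_spec"),
            inherits(inflow_tube, "tube_spec"))
  for (v in c("z_lr", "z_ur", "h_pump")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("'", v, "' must be a single strictly positive height (m)", call. = FALSE)
  }
  if (strict) {
    if (z_ur <= z_lr)
      stop("upper reservoir must sit above the lower one (z_ur > z_lr)", call. = FALSE)
    if (h_pump <= z_ur)
      stop("pump head must exceed the upper reservoir height (h_pump > z_ur)",
           call. = FALSE)
  }
  structure(list(fluid = fluid, tree = tree, collaterals = collaterals,
                 outlet_tube_lr = outlet_tube_lr,
                 outlet_tube_ur = outlet_tube_ur,
                 z_lr = z_lr, z_ur = z_ur, h_pump = h_pump,
                 inflow_tube = inflow_tube),
            class = "ivm_config")
}

#' Cancer scenario: which Couinaud segments bear tumors
#'
#' Each tumor-bearing segment is routed by its stopcock to the lower
#' reservoir (tumor-tissue pressure); normal segments route to the upper
#' reservoir.  The two bench scenarios are Case 1 (`"S7"`) and Case 2
#' (`c("S5", "S7")`).
#'
#' @param tumors Character vector of tumor-bearing segment labels, a subset
#'   of `S2, S3, S4a, S4b, S5, S6, S7, S8`.
#'
#' @return An object of class `cancer_scenario`.
#' @export
cancer_scenario <- function(tumors = "S7") {
  tumors <- unique(as.character(tumors))
  bad <- setdiff(tumors, SEGMENT_LABELS)
  if (length(bad))
    stop("unknown segment label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(tumors = tumors), class = "cancer_scenario")
}

#' Reference pressures of the IVM
#'
#' @param config An [ivm_config()].
#' @return Named vector with `pump` (pump source), `URP` and `LRP`
#'   (upper/lower reservoir pressures), in Pa.
#' @export
ivm_reference_pressures <- function(config) {
  c(pump = source_pressure(config$fluid, config$h_pump),
    URP = source_pressure(config$fluid, config$z_ur),
    LRP = source_pressure(config$fluid, config$z_lr))
}

#' Assemble the full IVM flow network
#'
#' Builds the collateralized artery tree, connects its inlet to the pump
#' (a boundary node at `rho*g*h_pump` through the inflow tube), and each
#' segmental outlet through its outlet tube to a boundary node at the upper
#' (`rho*g*z_ur`, normal segment) or lower (`rho*g*z_lr`, tumor segment)
#' reservoir pressure.  All artery nodes are interior.
#'
#' @param config An [ivm_config()].
#' @param scenario A [cancer_scenario()].
#'
#' @return A [flow_network()] with attribute `ivm` recording the config,
#'   scenario, balloon-site map, reference pressures and (if any) the
#'   applied occlusion.  Boundary node ids: `n_pump`, `r_S2` .. `r_S8`;
#'   outlet tube ids `t_S2` .. `t_S8`; inflow branch `b_inflow`.
#' @export
build_ivm_network <- function(config = ivm_config(),
                              scenario = cancer_scenario()) {
  stopifnot(inherits(config, "ivm_config"))
  if (!inherits(scenario, "cancer_scenario"))
    stop("'scenario' must be a cancer_scenario", call. = FALSE)
  fluid <- config$fluid
  tree <- attach_collaterals(build_hepatic_tree(config$tree, fluid),
                             config$collaterals, fluid)
  meta <- attr(tree, "artery")
  ref <- ivm_reference_pressures(config)

  is_tumor <- SEGMENT_LABELS %in% scenario$tumors
  res_nodes <- data.frame(
    id = paste0("r_", SEGMENT_LABELS),
    kind = "boundary",
    pressure = ifelse(is_tumor, ref[["LRP"]], ref[["URP"]]),
    elevation = ifelse(is_tumor, config$z_lr, config$z_ur),
    stringsAsFactors = FALSE
  )
  pump_node <- data.frame(id = "n_pump", kind = "boundary",
                          pressure = ref[["pump"]], elevation = 0,
                          stringsAsFactors = FALSE)
  outlet_R <- ifelse(is_tumor,
                     poiseuille_resistance(fluid, config$outlet_tube_lr),
                     poiseuille_resistance(fluid, config$outlet_tube_ur))
  outlet_tube <- ifelse(is_tumor, list(config$outlet_tube_lr),
                        list(config$outlet_tube_ur))
  out_branches <- data.frame(
    id = paste0("t_", SEGMENT_LABELS),
    from = paste0("o_", SEGMENT_LABELS),
    to = paste0("r_", SEGMENT_LABELS),
    R = outlet_R,
    blocked = FALSE,
    length = vapply(outlet_tube, `[[`, numeric(1), "length"),
    diameter = vapply(outlet_tube, `[[`, numeric(1), "diameter"),
    level = "outlet_tube",
    stringsAsFactors = FALSE
  )
  inflow <- data.frame(
    id = "b_inflow", from = "n_pump", to = meta$inlet,
    R = poiseuille_resistance(fluid, config$inflow_tube),
    blocked = FALSE,
    length = config$inflow_tube$length, diameter = config$inflow_tube$diameter,
    level = "inflow", stringsAsFactors = FALSE
  )

  net <- flow_network(rbind(tree$nodes, pump_node, res_nodes),
                      rbind(tree$branches, inflow, out_branches))
  sites <- if (length(config$collaterals$levels) == 3L &&
               all(c("lobar", "sectional", "segmental") %in%
                   config$collaterals$levels))
    map_balloon_sites(tree) else NULL
  attr(net, "ivm") <- list(config = config, scenario = scenario,
                           artery = meta, sites = sites, ref = ref,
                           occlusion = NULL)
  class(net) <- c("ivm_network", class(net))
  net
}

#' Re-route the three-way stopcocks to a new cancer scenario
#'
#' Updates, in place, each outlet's boundary pressure and outlet-tube
#' resistance to match `scenario`.  Idempotent: applying the current
#' scenario leaves the network unchanged.
#'
#' @param network An IVM network from [build_ivm_network()].
#' @param scenario A [cancer_scenario()].
#'
#' @return The re-routed network.
#' @export
set_stopcocks <- function(network, scenario) {
  meta <- attr(network, "ivm")
  if (is.null(meta)) stop("'network' must come from build_ivm_network", call. = FALSE)
  if (!inherits(scenario, "cancer_scenario"))
    stop("'scenario' must be a cancer_scenario", call. = FALSE)
  cfg <- meta$config
  is_tumor <- SEGMENT_LABELS %in% scenario$tumors
  i_res <- match(paste0("r_", SEGMENT_LABELS), network$nodes$id)
  network$nodes$pressure[i_res] <- ifelse(is_tumor, meta$ref[["LRP"]],
                                          meta$ref[["URP"]])
  network$nodes$elevation[i_res] <- ifelse(is_tumor, cfg$z_lr, cfg$z_ur)
  i_t <- match(paste0("t_", SEGMENT_LABELS), network$branches$id)
  tube <- ifelse(is_tumor, list(cfg$outlet_tube_lr), list(cfg$outlet_tube_ur))
  network$branches$R[i_t] <- ifelse(
    is_tumor, poiseuille_resistance(cfg$fluid, cfg$outlet_tube_lr),
    poiseuille_resistance(cfg$fluid, cfg$outlet_tube_ur))
  network$branches$length[i_t] <- vapply(tube, `[[`, numeric(1), "length")
  network$branches$diameter[i_t] <- vapply(tube, `[[`, numeric(1), "diameter")
  meta$scenario <- scenario
  attr(network, "ivm") <- meta
  network
}

#' Apply (or clear) a balloon occlusion
#'
#' Marks the branch at the given site as blocked and records the node
#' immediately distal to the balloon, which is both the stump-pressure
#' (BOASP) measurement point and the injection point.
#'
#' @param network An IVM network from [build_ivm_network()].
#' @param site A balloon site label (`"a"` .. `"i"`), a raw branch id
#'   (e.g. `"b_LHA_3"` for mirrored experiments), or `"none"` / `NULL` to
#'   clear any occlusion.
#'
#' @return The network with the occlusion applied and recorded in its
#'   `ivm` attribute (`occlusion = list(site, branch, injection_node)`).
#' @export
apply_occlusion <- function(network, site) {
  meta <- attr(network, "ivm")
  if (is.null(meta)) stop("'network' must come from build_ivm_network", call. = FALSE)
  network$branches$blocked <- FALSE
  if (is.null(site) || identical(site, "none")) {
    meta$occlusion <- NULL
    attr(network, "ivm") <- meta
    return(network)
  }
  if (!is.character(site) || length(site) != 1L)
    stop("'site' must be a single site label or branch id", call. = FALSE)
  if (site %in% letters[1:9]) {
    if (is.null(meta$sites))
      stop("no balloon-site map for this topology; occlude by branch id",
           call. = FALSE)
    row <- meta$sites[meta$sites$site == site, ]
    branch <- row$branch
    distal <- row$distal_node
  } else if (site %in% network$branches$id) {
    branch <- site
    distal <- network$branches$to[network$branches$id == site]
  } else {
    stop("unknown occlusion site: '", site, "'", call. = FALSE)
  }
  network$branches$blocked[network$branches$id == branch] <- TRUE
  meta$occlusion <- list(site = site, branch = branch, injection_node = distal)
  attr(network, "ivm") <- meta
  network
}

#' Outlet tube flows by segment
#'
#' Convenience accessor: the signed flowrate through each outlet tube
#' (positive = artery to reservoir), named by segment.
#'
#' @param solution A `flow_solution` of an IVM network.
#' @return Named numeric vector (m^3/s) over `S2` .. `S8`.
#' @export
outlet_flows <- function(solution) {
  setNames(solution$branch_flows[paste0("t_", SEGMENT_LABELS)], SEGMENT_LABELS)
}
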