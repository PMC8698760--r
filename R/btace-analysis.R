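# B-TACE post-processing: balloon-occluded arterial stump pressure (BOASP),
# pressure-gradient-effect (PGE) detection, passive injectate tracing,
# treatment-outcome classification, and proximal-to-distal occlusion-site
# sweeps.

#' Stump pressure before and after balloon occlusion
#'
#' The BOASP is the pressure at the node immediately distal to the inflated
#' balloon.  Its value is set by the collateral network connecting the
#' upstream and downstream compartments; it does not drop to zero.
#'
#' @param baseline `flow_solution` of the un-occluded network.
#' @param occluded `flow_solution` of the occluded network.
#' @param network The occluded IVM network (carries the occlusion record).
#'
#' @return A list with `pressure_before` (Pa, baseline pressure at the
#'   stump node) and `boasp` (Pa, same node after occlusion).
#' @export
compute_boasp <- function(baseline, occluded, network) {
  occ <- attr(network, "ivm")$occlusion
  if (is.null(occ))
    stop("network carries no occlusion; BOASP is undefined", call. = FALSE)
  node <- occ$injection_node
  list(pressure_before = unname(baseline$node_pressures[node]),
       boasp = unname(occluded$node_pressures[node]))
}

#' Detect the pressure-gradient effect
#'
#' PGE holds when the BOASP falls strictly between the lower- and
#' upper-reservoir pressures: the pump-generated flow to the occluded
#' territory has stopped, and the upper reservoir (normal tissue) feeds the
#' artery so that gravity drives flow toward the lower reservoir (tumor).
#' Equality with either reservoir pressure (within `tol`) counts as no PGE.
#'
#' When an occluded solution and its network are supplied, the pressure
#' window is cross-checked against the equivalent flow criterion -- at
#' least one normal-segment outlet tube carrying reversed (reservoir to
#' artery) flow -- and a disagreement raises an error, since it signals an
#' inconsistent geometry or configuration.
#'
#' @param boasp Stump pressure after occlusion (Pa).
#' @param urp,lrp Upper/lower reservoir pressures (Pa).
#' @param occluded Optional `flow_solution` of the occluded network.
#' @param network Optional occluded IVM network (required with `occluded`).
#' @param tol Absolute pressure tolerance for the strict comparisons (Pa).
#' @param flow_floor Flows with magnitude below this (m^3/s) count as zero.
#'
#' @return Logical flag.
#' @export
detect_pge <- function(boasp, urp, lrp, occluded = NULL, network = NULL,
                       tol = 1e-6, flow_floor = 1e-12) {
  if (urp <= lrp)
    stop("URP must exceed LRP for the PGE window to exist", call. = FALSE)
  pge <- (boasp > lrp + tol) && (boasp < urp - tol)
  if (!is.null(occluded)) {
    if (is.null(network))
      stop("'network' is required for the flow cross-check", call. = FALSE)
    meta <- attr(network, "ivm")
    normal <- setdiff(SEGMENT_LABELS, meta$scenario$tumors)
    rev_flow <- if (length(normal)) {
      q <- occluded$branch_flows[paste0("t_", normal)]
      any(q < -flow_floor)
    } else FALSE
    if (xor(pge, rev_flow))
      stop("PGE criteria disagree (pressure window: ", pge,
           ", reversed normal-outlet flow: ", rev_flow,
           "); the geometry/configuration is internally inconsistent",
           call. = FALSE)
  }
  pge
}

#' Trace the injectate from the catheter tip to the segmental outlets
#'
#' The injectate is modeled as a passive tracer infused at an
#' infinitesimal rate at the node distal to the balloon, so it does not
#' perturb the solved flow field.  It is carried along branches in the
#' direction of positive flow.  On branches whose occluded flow is exactly
#' zero (stagnant stumps, symmetric collaterals), the direction is taken
#' from the infinitesimal-injection limit: the network is re-solved with
#' homogeneous boundary pressures and a unit flow source at the injection
#' node, and the sign of that perturbation field breaks the tie.  This is
#' the zero-injection-rate limit of a finite infusion.
#'
#' @param network The occluded IVM network.
#' @param occluded Its `flow_solution`.
#' @param injection_node Node id of the catheter tip; defaults to the node
#'   distal to the recorded occlusion (the artery inlet when un-occluded).
#' @param flow_floor Flows with magnitude below this (m^3/s) are treated as
#'   zero and resolved by the injection perturbation.
#'
#' @return Character vector of reached segment labels (those whose outlet
#'   tube carries tracer into its reservoir), with attribute `stagnant`
#'   (TRUE when every flow incident to the injection node is zero in the
#'   unperturbed field).
#' @export
trace_injectate <- function(network, occluded, injection_node = NULL,
                            flow_floor = 1e-12) {
  meta <- attr(network, "ivm")
  if (is.null(injection_node)) {
    injection_node <- if (!is.null(meta$occlusion)) meta$occlusion$injection_node
                      else meta$artery$inlet
  }
  if (!injection_node %in% network$nodes$id)
    stop("unknown injection node: ", injection_node, call. = FALSE)
  ab <- active_branches(network)
  q <- occluded$branch_flows[ab$id]

  # infinitesimal-injection limit resolves stagnant regions
  zero_net <- network
  bnd <- zero_net$nodes$kind == "boundary"
  zero_net$nodes$pressure[bnd] <- 0
  dq <- solve_flow(zero_net, sources = setNames(1, injection_node))$branch_flows[ab$id]
  dq_rel <- dq / max(abs(dq), .Machine$double.xmin)

  dir <- ifelse(abs(q) > flow_floor, sign(q),
                ifelse(abs(dq_rel) > 1e-9, sign(dq_rel), 0))
  stagnant <- {
    inc <- ab$from == injection_node | ab$to == injection_node
    all(abs(q[inc]) <= flow_floor)
  }

  keep <- dir != 0
  edges <- data.frame(
    from = ifelse(dir[keep] > 0, ab$from[keep], ab$to[keep]),
    to = ifelse(dir[keep] > 0, ab$to[keep], ab$from[keep]),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = network$nodes$id, stringsAsFactors = FALSE))
  reach <- names(igraph::subcomponent(g, injection_node, mode = "out"))
  reached <- SEGMENT_LABELS[paste0("r_", SEGMENT_LABELS) %in% reach]
  structure(reached, stagnant = stagnant)
}

#' Classify the treatment outcome
#'
#' Successful if and only if the injectate reaches at least one outlet and
#' every reached outlet is tumor-bearing (tumor-only delivery).
#'
#' @param reached Character vector of reached segment labels.
#' @param scenario A [cancer_scenario()].
#'
#' @return `"successful"` or `"unsuccessful"`.
#' @export
classify_outcome <- function(reached, scenario) {
  stopifnot(inherits(scenario, "cancer_scenario"))
  ok <- length(reached) > 0 && all(reached %in% scenario$tumors)
  if (ok) "successful" else "unsuccessful"
}

#' Assess one balloon occlusion end to end
#'
#' Solves the baseline and occluded networks, then computes the stump
#' pressures, the PGE flag (with the dual pressure/flow criterion), the
#' injectate trace and the outcome classification.
#'
#' @param config An [ivm_config()].
#' @param scenario A [cancer_scenario()].
#' @param site Balloon site label (or branch id; see [apply_occlusion()]).
#' @param baseline Optional precomputed baseline `flow_solution` (reused by
#'   sweeps).
#'
#' @return An object of class `occlusion_assessment`: a list with `site`,
#'   `pressure_before`, `boasp`, `pge`, `reached`, `outcome`, `stagnant`,
#'   and the `occluded` solution.
#' @export
assess_occlusion <- function(config, scenario, site, baseline = NULL) {
  net <- build_ivm_network(config, scenario)
  if (is.null(baseline)) baseline <- solve_flow(net)
  occ_net <- apply_occlusion(net, site)
  occluded <- solve_flow(occ_net)
  bo <- compute_boasp(baseline, occluded, occ_net)
  ref <- attr(net, "ivm")$ref
  pge <- detect_pge(bo$boasp, ref[["URP"]], ref[["LRP"]],
                    occluded = occluded, network = occ_net)
  reached <- trace_injectate(occ_net, occluded)
  structure(list(site = site,
                 pressure_before = bo$pressure_before,
                 boasp = bo$boasp,
                 pge = pge,
                 reached = as.character(reached),
                 outcome = classify_outcome(reached, scenario),
                 stagnant = isTRUE(attr(reached, "stagnant")),
                 occluded = occluded),
            class = "occlusion_assessment")
}

#' @export
print.occlusion_assessment <- function(x, ...) {
  cat(sprintf("<occlusion_assessment> site '%s'\n", x$site))
  cat(sprintf("  stump pressure: %.1f Pa (%.2f mmHg) before, BOASP %.1f Pa (%.2f mmHg)\n",
              x$pressure_before, pa_to_mmhg(x$pressure_before),
              x$boasp, pa_to_mmhg(x$boasp)))
  cat(sprintf("  PGE: %s; reached: {%s}; outcome: %s\n",
              x$pge, paste(x$reached, collapse = ", "), x$outcome))
  invisible(x)
}

#' Sweep the balloon over proximal-to-distal occlusion sites
#'
#' Reproduces the numerical occlusion-site experiment: one baseline solve,
#' then one occluded solve and assessment per site, summarised as a tidy
#' table together with the inlet pressure (IP) and the reservoir reference
#' pressures (URP, LRP).
#'
#' @param config An [ivm_config()].
#' @param scenario A [cancer_scenario()].
#' @param sites Ordered character vector of site labels (default all nine,
#'   `a` .. `i`).
#'
#' @return A data frame (class `btace_sweep`) with one row per site:
#'   `site`, `p_before_pa`, `boasp_pa`, their mmHg twins, `pge`,
#'   `reached`, `outcome`, `physically_tested`; attributes `IP`, `URP`,
#'   `LRP` (Pa), `scenario` and `assessments` (the full list).
#' @export
occlusion_sweep <- function(config = ivm_config(),
                            scenario = cancer_scenario(),
                            sites = letters[1:9]) {
  net <- build_ivm_network(config, scenario)
  meta <- attr(net, "ivm")
  if (is.null(meta$sites))
    stop("no balloon-site map for this topology", call. = FALSE)
  bad <- setdiff(sites, meta$sites$site)
  if (length(bad))
    stop("unknown site(s): ", paste(bad, collapse = ", "), call. = FALSE)
  baseline <- solve_flow(net)
  ip <- unname(baseline$node_pressures[meta$artery$inlet])

  assessments <- lapply(sites, function(s)
    tryCatch(assess_occlusion(config, scenario, s, baseline = baseline),
             error = function(e) stop("site '", s, "': ", conditionMessage(e),
                                      call. = FALSE)))
  tab <- data.frame(
    site = sites,
    p_before_pa = vapply(assessments, `[[`, numeric(1), "pressure_before"),
    boasp_pa = vapply(assessments, `[[`, numeric(1), "boasp"),
    pge = vapply(assessments, `[[`, logical(1), "pge"),
    reached = vapply(assessments, function(a) paste(a$reached, collapse = "+"),
                     character(1)),
    outcome = vapply(assessments, `[[`, character(1), "outcome"),
    physically_tested = sites %in% meta$sites$site[meta$sites$physically_testable],
    stringsAsFactors = FALSE
  )
  tab$p_before_mmhg <- pa_to_mmhg(tab$p_before_pa)
  tab$boasp_mmhg <- pa_to_mmhg(tab$boasp_pa)
  structure(tab,
            IP = ip, URP = meta$ref[["URP"]], LRP = meta$ref[["LRP"]],
            scenario = scenario, assessments = assessments,
            class = c("btace_sweep", "data.frame"))
}

#' @export
print.btace_sweep <- function(x, ...) {
  cat(sprintf("B-TACE occlusion-site sweep (tumors: %s)\n",
              paste(attr(x, "scenario")$tumors, collapse = ", ")))
  cat(sprintf("  IP = %.1f Pa, URP = %.1f Pa, LRP = %.1f Pa\n",
              attr(x, "IP"), attr(x, "URP"), attr(x, "LRP")))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

#' Plot a pressure--occlusion-site curve
#'
#' Stump pressure before occlusion and BOASP against the proximal-to-distal
#' site ordering, with the inlet and reservoir reference pressures as
#' horizontal lines; BOASP points inside the (LRP, URP) window are the
#' PGE-generating occlusions.
#'
#' @param x A `btace_sweep`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.btace_sweep <- function(x, ...) {
  i <- seq_len(nrow(x))
  ylim <- range(x$p_before_pa, x$boasp_pa,
                attr(x, "IP"), attr(x, "URP"), attr(x, "LRP"))
  graphics::plot(i, x$p_before_pa, type = "b", pch = 16, xaxt = "n",
                 xlab = "Occlusion site (proximal to distal)",
                 ylab = "Pressure (Pa)", ylim = ylim, ...)
  graphics::axis(1, at = i, labels = x$site)
  graphics::lines(i, x$boasp_pa, type = "b", pch = 17, lty = 2)
  graphics::abline(h = attr(x, "IP"), lty = 3)
  graphics::abline(h = attr(x, "URP"), lty = 4)
  graphics::abline(h = attr(x, "LRP"), lty = 4)
  graphics::legend("bottomleft",
                   legend = c("before occlusion", "BOASP", "IP", "URP / LRP"),
                   pch = c(16, 17, NA, NA), lty = c(1, 2, 3, 4), bty = "n")
  invisible(x)
}
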