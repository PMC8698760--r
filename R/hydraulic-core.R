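# Steady-state resistive flow networks: Poiseuille resistances, gravity-head
# pressure sources, Kirchhoff nodal analysis, and an independent least-squares
# solver used for verification.

#' Fluid properties
#'
#' Bundle of the physical constants entering the hydraulic model: density
#' (drives the gravity heads rho*g*z), dynamic viscosity (drives Poiseuille
#' resistances) and gravitational acceleration.
#'
#' @param density Fluid density (kg/m^3). Default 1000 (water).
#' @param viscosity Dynamic viscosity (Pa*s). Default 0.001 (water, ~20 C).
#' @param gravity Gravitational acceleration (m/s^2). Default 9.8.
#'
#' @return An object of class `fluid_properties`.
#' @seealso [blood_mimic_fluid()] for a water--glycol blood surrogate.
#' @export
#' @examples
#' fluid_properties()                  # water
#' fluid_properties(1050, 0.0035)      # blood-mimicking mixture
fluid_properties <- function(density = 1000, viscosity = 0.001, gravity = 9.8) {
  for (v in c("density", "viscosity", "gravity")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("'", v, "' must be a single strictly positive number", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity, gravity = gravity),
            class = "fluid_properties")
}

#' Blood-mimicking fluid preset
#'
#' Water--glycol mixture with density 1050 kg/m^3 and viscosity 0.0035 Pa*s,
#' the standard bench surrogate for blood in steady-state flow phantoms.
#'
#' @return A `fluid_properties` object.
#' @export
blood_mimic_fluid <- function() fluid_properties(density = 1050, viscosity = 0.0035)

#' Tube geometry
#'
#' @param length Tube length (m), `>= 0`.
#' @param diameter Inner diameter (m), `> 0`.
#'
#' @return An object of class `tube_spec`.
#' @export
#' @examples
#' tube_spec(0.040, 0.0012)  # a 40 mm x 1.2 mm reservoir outlet tube
tube_spec <- function(length, diameter) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) || length < 0)
    stop("tube 'length' must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) || diameter <= 0)
    stop("tube 'diameter' must be a single strictly positive number", call. = FALSE)
  structure(list(length = length, diameter = diameter), class = "tube_spec")
}

#' Poiseuille hydraulic resistance of a straight circular tube
#'
#' For laminar, steady flow of a Newtonian fluid the pressure drop across a
#' tube is `dp = R * q` with `R = 128 * mu * l / (pi * d^4)`.
#'
#' @param fluid A [fluid_properties()] object.
#' @param tube A [tube_spec()] object.
#'
#' @return Hydraulic resistance (Pa*s/m^3).
#' @export
#' @examples
#' # a 40 mm long, 1.2 mm diameter outlet tube in water: ~7.86e8 Pa*s/m^3
#' poiseuille_resistance(fluid_properties(), tube_spec(0.040, 0.0012))
poiseuille_resistance <- function(fluid, tube) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!inherits(tube, "tube_spec")) stop("'tube' must be a tube_spec", call. = FALSE)
  128 * fluid$viscosity * tube$length / (pi * tube$diameter^4)
}

#' Hydrostatic source pressure of a fluid column
#'
#' Gauge pressure `rho * g * z` of a free surface (or pump head) at height
#' `z` above the datum.  Used for the reservoir heads and the pump source.
#'
#' @param fluid A [fluid_properties()] object.
#' @param height Height above the pressure datum (m); may be negative.
#'
#' @return Gauge pressure (Pa).
#' @export
#' @examples
#' source_pressure(fluid_properties(), 0.110)  # 110 mm upper reservoir: 1078 Pa
#' source_pressure(fluid_properties(), 0.200)  # 200 mm pump head: 1960 Pa
source_pressure <- function(fluid, height) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(height) || !all(is.finite(height)))
    stop("'height' must be finite numeric", call. = FALSE)
  fluid$density * fluid$gravity * height
}

#' Construct a resistive flow network
#'
#' A flow network is a directed graph of nodes and resistive branches.
#' Interior nodes have unknown pressure; boundary nodes carry a fixed gauge
#' pressure (constant-pressure sources in the fluid--electric analogy:
#' reservoirs and the pump).  Branch orientation only fixes the sign
#' convention of its flowrate.
#'
#' @param nodes A data frame with columns `id` (character, unique), `kind`
#'   (`"interior"` or `"boundary"`), `pressure` (Pa; `NA` for interior
#'   nodes, finite for boundary nodes) and optionally `elevation` (m,
#'   informational).
#' @param branches A data frame with columns `id` (character, unique),
#'   `from`, `to` (node ids), `R` (hydraulic resistance, Pa*s/m^3, `> 0`),
#'   and optionally `blocked` (logical, default `FALSE`), `length`,
#'   `diameter` (m, `NA` when the branch was given an explicit resistance).
#'
#' @return An object of class `flow_network`.
#' @export
flow_network <- function(nodes, branches) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  branches <- as.data.frame(branches, stringsAsFactors = FALSE)
  need_n <- c("id", "kind", "pressure")
  if (!all(need_n %in% names(nodes)))
    stop("nodes must have columns: ", paste(need_n, collapse = ", "), call. = FALSE)
  if (is.null(nodes$elevation)) nodes$elevation <- NA_real_
  need_b <- c("id", "from", "to", "R")
  if (!all(need_b %in% names(branches)))
    stop("branches must have columns: ", paste(need_b, collapse = ", "), call. = FALSE)
  if (is.null(branches$blocked)) branches$blocked <- FALSE
  if (is.null(branches$length)) branches$length <- NA_real_
  if (is.null(branches$diameter)) branches$diameter <- NA_real_

  nodes$id <- as.character(nodes$id)
  branches$id <- as.character(branches$id)
  branches$from <- as.character(branches$from)
  branches$to <- as.character(branches$to)

  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(branches$id)) stop("duplicate branch ids", call. = FALSE)
  if (!all(nodes$kind %in% c("interior", "boundary")))
    stop("node kind must be 'interior' or 'boundary'", call. = FALSE)
  bad <- setdiff(c(branches$from, branches$to), nodes$id)
  if (length(bad))
    stop("branch endpoints not in node set: ", paste(bad, collapse = ", "), call. = FALSE)
  is_b <- nodes$kind == "boundary"
  if (any(!is.finite(nodes$pressure[is_b])))
    stop("boundary nodes must carry a finite pressure", call. = FALSE)
  if (any(!is.na(nodes$pressure[!is_b])))
    stop("interior nodes must not carry a fixed pressure", call. = FALSE)
  if (any(!is.finite(branches$R) | branches$R <= 0))
    stop("branch resistances must be finite and > 0", call. = FALSE)

  rownames(nodes) <- NULL
  rownames(branches) <- NULL
  structure(list(nodes = nodes, branches = branches), class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  nb <- sum(x$nodes$kind == "boundary")
  cat(sprintf("<flow_network> %d nodes (%d boundary), %d branches (%d blocked)\n",
              nrow(x$nodes), nb, nrow(x$branches), sum(x$branches$blocked)))
  invisible(x)
}

# branches participating in the current solve (blocked ones carry q = 0 and
# are removed from the system rather than sent to R -> Inf)
active_branches <- function(network) network$branches[!network$branches$blocked, , drop = FALSE]

# igraph over active branches; isolated nodes kept as vertices
network_graph <- function(network, directed = FALSE) {
  ab <- active_branches(network)
  igraph::graph_from_data_frame(
    d = data.frame(from = ab$from, to = ab$to, stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = network$nodes$id, stringsAsFactors = FALSE)
  )
}

# Every connected component (after blocked-branch removal) that contains an
# interior node must contain at least one boundary node, otherwise the
# pressures in it are undetermined.
check_solvable <- function(network) {
  g <- network_graph(network)
  comp <- igraph::components(g)$membership
  kind <- setNames(network$nodes$kind, network$nodes$id)
  for (k in unique(comp)) {
    ids <- names(comp)[comp == k]
    if (any(kind[ids] == "interior") && !any(kind[ids] == "boundary"))
      stop("singular system: component {", paste(sort(ids), collapse = ", "),
           "} contains no boundary (fixed-pressure) node", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the Kirchhoff nodal system of a flow network
#'
#' One mass-conservation equation per interior node, written in the unknown
#' interior pressures; boundary pressures are folded into the right-hand
#' side.  Blocked branches are excluded.  The unknown ordering is the sorted
#' interior node ids, so the assembly is deterministic.
#'
#' @param network A [flow_network()].
#' @param sources Optional named numeric vector of externally injected
#'   flowrates (m^3/s) at interior nodes (positive into the node); used for
#'   injectate tracing.
#'
#' @return A list with `matrix` (conductance matrix), `rhs`, and `unknowns`
#'   (the interior node ids, in order).
#' @export
assemble_nodal_system <- function(network, sources = NULL) {
  check_solvable(network)
  unknowns <- sort(network$nodes$id[network$nodes$kind == "interior"])
  n <- length(unknowns)
  idx <- setNames(seq_len(n), unknowns)
  p_fix <- setNames(network$nodes$pressure, network$nodes$id)
  is_int <- setNames(network$nodes$kind == "interior", network$nodes$id)

  G <- matrix(0, n, n, dimnames = list(unknowns, unknowns))
  rhs <- setNames(numeric(n), unknowns)
  ab <- active_branches(network)
  for (k in seq_len(nrow(ab))) {
    a <- ab$from[k]; b <- ab$to[k]; g <- 1 / ab$R[k]
    if (is_int[[a]] && is_int[[b]]) {
      i <- idx[[a]]; j <- idx[[b]]
      G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
      G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
    } else if (is_int[[a]]) {
      i <- idx[[a]]
      G[i, i] <- G[i, i] + g
      rhs[i] <- rhs[i] + g * p_fix[[b]]
    } else if (is_int[[b]]) {
      j <- idx[[b]]
      G[j, j] <- G[j, j] + g
      rhs[j] <- rhs[j] + g * p_fix[[a]]
    }
    # boundary-boundary branches do not enter the system
  }
  if (!is.null(sources) && length(sources)) {
    if (is.null(names(sources)) || !all(names(sources) %in% unknowns))
      stop("flow sources must be named after interior nodes", call. = FALSE)
    rhs[names(sources)] <- rhs[names(sources)] + sources
  }
  list(matrix = G, rhs = rhs, unknowns = unknowns)
}

#' Solve a flow network by nodal analysis
#'
#' Computes the steady-state pressure at every node and the flowrate through
#' every branch from Kirchhoff's laws: mass conservation at each interior
#' node and the linear pressure-drop law `dp = R * q` on each branch.
#' Blocked branches are removed from the system and reported with a flowrate
#' of exactly zero.
#'
#' @inheritParams assemble_nodal_system
#'
#' @return An object of class `flow_solution`: a list with `node_pressures`
#'   (named, Pa) and `branch_flows` (named, m^3/s, signed from -> to).
#' @export
#' @examples
#' nodes <- data.frame(id = c("a", "b"), kind = "boundary",
#'                     pressure = c(1960, 1078))
#' br <- data.frame(id = "t", from = "a", to = "b", R = 7.8595e8)
#' solve_flow(flow_network(nodes, br))$branch_flows  # ~1.12e-6 m^3/s
solve_flow <- function(network, sources = NULL) {
  sys <- assemble_nodal_system(network, sources = sources)
  p <- setNames(network$nodes$pressure, network$nodes$id)
  ab <- active_branches(network)
  if (length(sys$unknowns)) {
    G <- sys$matrix
    sol <- tryCatch(solve(G, sys$rhs),
                    error = function(e) stop("singular nodal system: ",
                                             conditionMessage(e), call. = FALSE))
    if (any(!is.finite(sol))) stop("singular nodal system: non-finite solution",
                                   call. = FALSE)
    # iterative refinement against the per-branch conservation defect (the
    # same arithmetic the solution is judged by): resistances spanning
    # several decades make the conductance matrix ill-scaled, and plain
    # matrix-product refinement stagnates
    src <- setNames(numeric(length(sys$unknowns)), sys$unknowns)
    if (!is.null(sources) && length(sources))
      src[names(sources)] <- src[names(sources)] + sources
    for (it in 1:3) {
      p[sys$unknowns] <- sol
      qa <- (p[ab$from] - p[ab$to]) / ab$R
      defect <- src
      for (k in seq_len(nrow(ab))) {
        fr <- ab$from[k]; to <- ab$to[k]
        if (fr %in% sys$unknowns) defect[[fr]] <- defect[[fr]] - qa[[k]]
        if (to %in% sys$unknowns) defect[[to]] <- defect[[to]] + qa[[k]]
      }
      if (max(abs(defect)) == 0) break
      sol <- sol + solve(G, defect)
    }
    p[sys$unknowns] <- sol
  }
  br <- network$branches
  q <- ifelse(br$blocked, 0, (p[br$from] - p[br$to]) / br$R)
  structure(list(node_pressures = p,
                 branch_flows = setNames(as.numeric(q), br$id)),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d node pressures, %d branch flows\n",
              length(x$node_pressures), length(x$branch_flows)))
  cat(sprintf("  pressure range: %.4g .. %.4g Pa\n",
              min(x$node_pressures), max(x$node_pressures)))
  cat(sprintf("  |flow| range:   %.4g .. %.4g m^3/s\n",
              min(abs(x$branch_flows)), max(abs(x$branch_flows))))
  invisible(x)
}

#' Independent least-squares network solver (verification oracle)
#'
#' Solves the full redundant constraint set -- one pressure-drop relation per
#' unblocked branch plus one conservation relation per interior node -- by
#' linear least squares over all interior pressures and branch flowrates,
#' without nodal elimination.  Intended for small networks and used to
#' cross-check [solve_flow()]; the two solvers share no linear algebra
#' beyond the generic least-squares routine.
#'
#' @param network A [flow_network()].
#'
#' @return A `flow_solution`, as for [solve_flow()].
#' @export
oracle_solve <- function(network) {
  check_solvable(network)
  interior <- sort(network$nodes$id[network$nodes$kind == "interior"])
  ab <- active_branches(network)
  nb <- nrow(ab)
  np <- length(interior)
  p_fix <- setNames(network$nodes$pressure, network$nodes$id)
  is_int <- setNames(network$nodes$kind == "interior", network$nodes$id)

  # unknown vector: [interior pressures (Pa), scaled flows x = q * s]
  # scaling by a representative resistance keeps the matrix well conditioned
  s <- stats::median(ab$R)
  if (!is.finite(s) || s <= 0) s <- 1
  A <- matrix(0, nb + np, np + nb)
  b <- numeric(nb + np)
  pidx <- setNames(seq_len(np), interior)

  for (k in seq_len(nb)) {
    # p_from - p_to - (R/s) * x = 0, constants moved to rhs
    fr <- ab$from[k]; to <- ab$to[k]
    if (is_int[[fr]]) A[k, pidx[[fr]]] <- 1 else b[k] <- b[k] - p_fix[[fr]]
    if (is_int[[to]]) A[k, pidx[[to]]] <- -1 else b[k] <- b[k] + p_fix[[to]]
    A[k, np + k] <- -ab$R[k] / s
  }
  for (j in seq_len(np)) {
    node <- interior[j]
    row <- nb + j
    out <- which(ab$from == node)
    inn <- which(ab$to == node)
    if (length(out)) A[row, np + out] <- A[row, np + out] - 1
    if (length(inn)) A[row, np + inn] <- A[row, np + inn] + 1
  }

  fit <- stats::lsfit(A, -b, intercept = FALSE)
  z <- fit$coefficients
  if (any(!is.finite(z))) stop("singular system in oracle_solve", call. = FALSE)
  # one step of least-squares iterative refinement (the system is consistent,
  # so the true residual is zero and refinement converges fast)
  r <- -b - drop(A %*% z)
  z <- z + stats::lsfit(A, r, intercept = FALSE)$coefficients
  p <- p_fix
  if (np) p[interior] <- -z[seq_len(np)]
  qa <- if (nb) -z[np + seq_len(nb)] / s else numeric(0)

  q <- setNames(numeric(nrow(network$branches)), network$branches$id)
  q[ab$id] <- qa
  structure(list(node_pressures = p, branch_flows = q), class = "flow_solution")
}

#' Verify a flow solution against Kirchhoff's laws
#'
#' Recomputes the branch-law residual `dp - R*q` on every unblocked branch
#' and the signed-flow sum at every interior node, relative to the local
#' scale, and flags pass/fail at the given tolerance.
#'
#' @param network A [flow_network()].
#' @param solution A `flow_solution` covering all nodes and branches of
#'   `network`.
#' @param tol Relative tolerance (default `1e-9`).
#'
#' @return An object of class `flow_verification`: a list with
#'   `max_branch_residual`, `max_node_residual` (both relative), `pass`,
#'   and the offending `worst_branch` / `worst_node` ids.
#' @export
verify_solution <- function(network, solution, tol = 1e-9) {
  if (!inherits(solution, "flow_solution"))
    stop("'solution' must be a flow_solution", call. = FALSE)
  if (!all(network$nodes$id %in% names(solution$node_pressures)))
    stop("incomplete solution: missing node pressures", call. = FALSE)
  if (!all(network$branches$id %in% names(solution$branch_flows)))
    stop("incomplete solution: missing branch flows", call. = FALSE)
  eps <- 1e-12
  p <- solution$node_pressures
  q <- solution$branch_flows

  ab <- active_branches(network)
  if (nrow(ab)) {
    dp <- p[ab$from] - p[ab$to]
    qq <- q[ab$id]
    res_b <- abs(dp - ab$R * qq) / pmax(abs(dp), ab$R * abs(qq), eps)
    max_branch <- max(res_b)
    worst_branch <- ab$id[which.max(res_b)]
  } else {
    max_branch <- 0; worst_branch <- NA_character_
  }

  interior <- network$nodes$id[network$nodes$kind == "interior"]
  if (length(interior)) {
    res_n <- vapply(interior, function(node) {
      sgn <- c(rep(-1, sum(ab$from == node)), rep(1, sum(ab$to == node)))
      qs <- c(q[ab$id[ab$from == node]], q[ab$id[ab$to == node]])
      abs(sum(sgn * qs)) / (sum(abs(qs)) + eps)
    }, numeric(1))
    max_node <- max(res_n)
    worst_node <- interior[which.max(res_n)]
  } else {
    max_node <- 0; worst_node <- NA_character_
  }

  structure(list(max_branch_residual = max_branch,
                 max_node_residual = max_node,
                 worst_branch = worst_branch,
                 worst_node = worst_node,
                 tol = tol,
                 pass = max_branch <= tol && max_node <= tol),
            class = "flow_verification")
}

#' @export
print.flow_verification <- function(x, ...) {
  cat(sprintf("<flow_verification> %s (tol %.1e)\n",
              if (x$pass) "PASS" else "FAIL", x$tol))
  cat(sprintf("  max branch-law residual:   %.3e (%s)\n",
              x$max_branch_residual, x$worst_branch))
  cat(sprintf("  max conservation residual: %.3e (%s)\n",
              x$max_node_residual, x$worst_node))
  invisible(x)
}

#' Per-branch Reynolds numbers
#'
#' Diagnostic for the laminar-flow assumption behind the Poiseuille
#' resistance: `Re = 4 * rho * |q| / (pi * mu * d)`.  Branches without a
#' recorded diameter (explicit-resistance branches) return `NA`.
#'
#' @param network A [flow_network()].
#' @param solution The corresponding `flow_solution`.
#' @param fluid A [fluid_properties()] object.
#'
#' @return Named numeric vector of Reynolds numbers, one per branch.
#' @export
branch_reynolds <- function(network, solution, fluid) {
  br <- network$branches
  q <- solution$branch_flows[br$id]
  re <- 4 * fluid$density * abs(q) / (pi * fluid$viscosity * br$diameter)
  setNames(as.numeric(re), br$id)
}

#' Unit conversions for reporting
#'
#' Internally everything is SI (Pa, m^3/s); the clinical and bench
#' literature reports mmHg and mL/min.
#'
#' @param pa Pressure in Pa.
#' @param q Flowrate in m^3/s.
#' @return Converted numeric vector.
#' @export
pa_to_mmhg <- function(pa) pa / 133.322

#' @rdname pa_to_mmhg
#' @export
flow_to_ml_min <- function(q) q * 6e7
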