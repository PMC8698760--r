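# Configuration loading (JSON, mm units as printed on the bench drawings),
# result serialization (CSV + JSON run manifest), and the seeded
# random-network fixture generator used by the verification tests.

.config_schema <- list(
  fluid = c("density", "viscosity", "gravity"),
  tree = c("pha", "lobar", "sectional", "segmental"),
  collaterals = c("ca", "same_level", "levels"),
  ivm = c("l_lr_mm", "d_lr_mm", "l_ur_mm", "d_ur_mm",
          "z_lr_mm", "z_ur_mm", "h_pump_mm",
          "inflow_l_mm", "inflow_d_mm"),
  scenario = c("tumors"),
  occlusion = c("site")
)

.tube_from_mm <- function(x, where) {
  if (!is.list(x) || !all(c("l_mm", "d_mm") %in% names(x)))
    stop("config key '", where, "' must be an object with l_mm and d_mm ",
         "(millimetres)", call. = FALSE)
  extra <- setdiff(names(x), c("l_mm", "d_mm"))
  if (length(extra))
    stop("unknown key(s) under '", where, "': ", paste(extra, collapse = ", "),
         call. = FALSE)
  tube_spec(x$l_mm / 1000, x$d_mm / 1000)
}

#' Load an IVM configuration file
#'
#' Reads a JSON configuration describing the fluid, artery geometry,
#' circuit sizing, cancer scenario and occlusion site, fills defaults for
#' anything omitted, and normalizes units to SI (lengths in the file are
#' millimetres, matching the bench drawings; fluid properties are SI).
#' Unknown keys are rejected with a message naming the key.
#'
#' @param path Path to a JSON file.  Top-level keys (all optional):
#'   `fluid` (`density`, `viscosity`, `gravity`), `tree` /`collaterals`
#'   (tube objects `{l_mm, d_mm}`; `collaterals` also takes `levels`),
#'   `ivm` (`l_lr_mm`, `d_lr_mm`, `l_ur_mm`, `d_ur_mm`, `z_lr_mm`,
#'   `z_ur_mm`, `h_pump_mm`, `inflow_l_mm`, `inflow_d_mm`), `scenario`
#'   (`tumors`), `occlusion` (`site`).
#'
#' @return A list with `config` ([ivm_config()]), `scenario`
#'   ([cancer_scenario()]) and `site` (occlusion site label or `"none"`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), names(.config_schema))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; expected a subset of {", paste(names(.config_schema), collapse = ", "),
         "}", call. = FALSE)
  for (sec in names(.config_schema)) {
    extra <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(extra))
      stop("unknown key(s) under '", sec, "': ", paste(extra, collapse = ", "),
           call. = FALSE)
  }

  fl <- raw$fluid
  fluid <- fluid_properties(
    density = fl$density %||% 1000,
    viscosity = fl$viscosity %||% 0.001,
    gravity = fl$gravity %||% 9.8)

  tr <- raw$tree
  tree_def <- hepatic_tree_spec()
  tree <- hepatic_tree_spec(
    pha = if (!is.null(tr$pha)) .tube_from_mm(tr$pha, "tree.pha") else tree_def$pha,
    lobar = if (!is.null(tr$lobar)) .tube_from_mm(tr$lobar, "tree.lobar") else tree_def$lobar,
    sectional = if (!is.null(tr$sectional)) .tube_from_mm(tr$sectional, "tree.sectional") else tree_def$sectional,
    segmental = if (!is.null(tr$segmental)) .tube_from_mm(tr$segmental, "tree.segmental") else tree_def$segmental)

  cl <- raw$collaterals
  coll_def <- collateral_spec()
  collaterals <- collateral_spec(
    ca = if (!is.null(cl$ca)) .tube_from_mm(cl$ca, "collaterals.ca") else coll_def$ca,
    same_level = if (!is.null(cl$same_level)) .tube_from_mm(cl$same_level, "collaterals.same_level") else coll_def$same_level,
    levels = if (!is.null(cl$levels)) as.character(cl$levels) else coll_def$levels)

  iv <- raw$ivm
  mm <- function(key, default_m) {
    v <- iv[[key]]
    if (is.null(v)) return(default_m)
    if (!is.numeric(v) || length(v) != 1L)
      stop("config key 'ivm.", key, "' must be a single number (millimetres)",
           call. = FALSE)
    v / 1000
  }
  config <- ivm_config(
    fluid = fluid, tree = tree, collaterals = collaterals,
    outlet_tube_lr = tube_spec(mm("l_lr_mm", 0.040), mm("d_lr_mm", 0.0012)),
    outlet_tube_ur = tube_spec(mm("l_ur_mm", 0.040), mm("d_ur_mm", 0.0012)),
    z_lr = mm("z_lr_mm", 0.080), z_ur = mm("z_ur_mm", 0.110),
    h_pump = mm("h_pump_mm", 0.200),
    inflow_tube = tube_spec(mm("inflow_l_mm", 0.300), mm("inflow_d_mm", 0.0040)))

  scenario <- cancer_scenario(raw$scenario$tumors %||% "S7")
  site <- raw$occlusion$site %||% "none"
  if (!identical(site, "none") && !site %in% letters[1:9])
    stop("config key 'occlusion.site' must be one of a..i or 'none'",
         call. = FALSE)
  list(config = config, scenario = scenario, site = site)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a resolved configuration back to the file representation
#'
#' Inverse of [load_config()]: produces the fully resolved list (mm units)
#' that, written as JSON and re-loaded, yields an identical configuration.
#'
#' @param config An [ivm_config()].
#' @param scenario A [cancer_scenario()].
#' @param site Occlusion site label or `"none"`.
#'
#' @return A plain list mirroring the config file schema.
#' @export
dump_config <- function(config, scenario = cancer_scenario(), site = "none") {
  tube_mm <- function(t) list(l_mm = 1000 * t$length, d_mm = 1000 * t$diameter)
  list(
    fluid = list(density = config$fluid$density,
                 viscosity = config$fluid$viscosity,
                 gravity = config$fluid$gravity),
    tree = lapply(unclass(config$tree), tube_mm),
    collaterals = list(ca = tube_mm(config$collaterals$ca),
                       same_level = tube_mm(config$collaterals$same_level),
                       levels = config$collaterals$levels),
    ivm = list(l_lr_mm = 1000 * config$outlet_tube_lr$length,
               d_lr_mm = 1000 * config$outlet_tube_lr$diameter,
               l_ur_mm = 1000 * config$outlet_tube_ur$length,
               d_ur_mm = 1000 * config$outlet_tube_ur$diameter,
               z_lr_mm = 1000 * config$z_lr,
               z_ur_mm = 1000 * config$z_ur,
               h_pump_mm = 1000 * config$h_pump,
               inflow_l_mm = 1000 * config$inflow_tube$length,
               inflow_d_mm = 1000 * config$inflow_tube$diameter),
    scenario = list(tumors = scenario$tumors),
    occlusion = list(site = site)
  )
}

#' Write solver results to disk
#'
#' Writes `node_pressures.csv` (Pa and mmHg), `branch_flows.csv` (m^3/s
#' and mL/min), optionally `sweep.csv`, plus a JSON run manifest.  The CSV
#' tables are byte-identical across repeated runs on identical inputs.
#'
#' @param x A `flow_solution` or a `btace_sweep`.
#' @param out_dir Output directory (created if missing).
#' @param manifest Named list of extra manifest entries (e.g. config path,
#'   seed).
#'
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, out_dir, manifest = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir, call. = FALSE)
  paths <- character(0)
  if (inherits(x, "flow_solution")) {
    np <- data.frame(node = names(x$node_pressures),
                     pressure_pa = unname(x$node_pressures),
                     pressure_mmhg = pa_to_mmhg(unname(x$node_pressures)),
                     stringsAsFactors = FALSE)
    bf <- data.frame(branch = names(x$branch_flows),
                     flow_m3_s = unname(x$branch_flows),
                     flow_ml_min = flow_to_ml_min(unname(x$branch_flows)),
                     stringsAsFactors = FALSE)
    p1 <- file.path(out_dir, "node_pressures.csv")
    p2 <- file.path(out_dir, "branch_flows.csv")
    utils::write.csv(np, p1, row.names = FALSE)
    utils::write.csv(bf, p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  } else if (inherits(x, "btace_sweep")) {
    p3 <- file.path(out_dir, "sweep.csv")
    tab <- as.data.frame(x)
    tab$IP_pa <- attr(x, "IP"); tab$URP_pa <- attr(x, "URP")
    tab$LRP_pa <- attr(x, "LRP")
    utils::write.csv(tab, p3, row.names = FALSE)
    paths <- c(paths, p3)
  } else stop("don't know how to write objects of class ",
              paste(class(x), collapse = "/"), call. = FALSE)
  man <- c(list(package = "btaceflow",
                version = as.character(utils::packageVersion("btaceflow")),
                written = format(Sys.time(), tz = "UTC"),
                files = basename(paths)),
           manifest)
  pman <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, pman, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pman))
}

#' Seeded random solvable flow network
#'
#' Generates a reproducible random network for solver verification: a
#' random spanning tree (guaranteeing connectivity) plus extra random
#' edges, resistances log-uniform in [1e7, 1e10] Pa*s/m^3 and boundary
#' pressures uniform in [0, 2000] Pa.  Always satisfies the solvability
#' invariant.
#'
#' @param seed Integer RNG seed.
#' @param n_nodes Total number of nodes (>= 2).
#' @param n_boundary Number of boundary nodes (>= 1, at most `n_nodes`).
#' @param n_extra Number of extra (non-tree) edges; default
#'   `n_nodes %/% 2`.
#'
#' @return A [flow_network()].
#' @export
random_network_fixture <- function(seed, n_nodes = 10, n_boundary = 3,
                                   n_extra = NULL) {
  if (n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  if (n_boundary < 1 || n_boundary > n_nodes)
    stop("need 1 <= n_boundary <= n_nodes", call. = FALSE)
  if (is.null(n_extra)) n_extra <- n_nodes %/% 2
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n_nodes))
  from <- to <- character(0)
  for (i in 2:n_nodes) {                       # random spanning tree
    j <- if (i == 2) 1L else sample.int(i - 1L, 1L)
    from <- c(from, ids[j]); to <- c(to, ids[i])
  }
  for (k in seq_len(n_extra)) {
    pick <- sample.int(n_nodes, 2L)
    from <- c(from, ids[pick[1]]); to <- c(to, ids[pick[2]])
  }
  nb <- length(from)
  bnd <- sort(sample.int(n_nodes, n_boundary))
  nodes <- data.frame(
    id = ids,
    kind = ifelse(seq_len(n_nodes) %in% bnd, "boundary", "interior"),
    pressure = NA_real_, stringsAsFactors = FALSE)
  nodes$pressure[bnd] <- stats::runif(n_boundary, 0, 2000)
  branches <- data.frame(
    id = sprintf("e%02d", seq_len(nb)), from = from, to = to,
    R = 10^stats::runif(nb, 7, 10), stringsAsFactors = FALSE)
  flow_network(nodes, branches)
}
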