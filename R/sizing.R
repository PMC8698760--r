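# Automated sizing of the seven IVM design parameters (outlet tube lengths
# and diameters to each reservoir, the two reservoir heights, and the pump
# head) against the conceptual-design criteria, evaluated over both cancer
# scenarios and three catheter states (no occlusion, location 1 = site 'c',
# location 2 = site 'b').

#' The seven IVM sizing parameters
#'
#' Defaults are the adequate values found for demonstrating the
#' pressure-gradient effect: 40 mm x 1.2 mm outlet tubes to both
#' reservoirs, reservoir heights 80 mm (lower) and 110 mm (upper), and a
#' 200 mm pump head.
#'
#' @param l_lr,d_lr Length/diameter of the tubes to the lower reservoir (m).
#' @param l_ur,d_ur Length/diameter of the tubes to the upper reservoir (m).
#' @param z_lr,z_ur Free-surface heights of the lower/upper reservoir (m).
#' @param h_pump Pump head (m).
#'
#' @return An object of class `sizing_params`.
#' @export
sizing_params <- function(l_lr = 0.040, d_lr = 0.0012,
                          l_ur = 0.040, d_ur = 0.0012,
                          z_lr = 0.080, z_ur = 0.110,
                          h_pump = 0.200) {
  p <- list(l_lr = l_lr, d_lr = d_lr, l_ur = l_ur, d_ur = d_ur,
            z_lr = z_lr, z_ur = z_ur, h_pump = h_pump)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("all sizing parameters must be single finite numbers", call. = FALSE)
  structure(p, class = "sizing_params")
}

#' Sizing acceptance criteria
#'
#' @param require_baseline_all_fed Require every outlet to carry positive
#'   outflow with no occlusion.
#' @param require_tumor_preference Require every tumor-bearing outlet to
#'   out-flow every normal outlet at baseline.
#' @param require_pge_at Site that must develop PGE (default `"c"`,
#'   microballoon location 1).
#' @param require_no_pge_at Site that must not develop PGE (default `"b"`,
#'   location 2, where flow re-routes through the communicating arcade).
#' @param flow_min,flow_max Optional bounds on baseline outlet flows
#'   (mL/min); `flow_max = 500` matches the pump's delivery envelope.
#'
#' @return An object of class `sizing_criteria`.
#' @export
sizing_criteria <- function(require_baseline_all_fed = TRUE,
                            require_tumor_preference = TRUE,
                            require_pge_at = "c",
                            require_no_pge_at = "b",
                            flow_min = NULL, flow_max = NULL) {
  for (s in c(require_pge_at, require_no_pge_at))
    if (!s %in% letters[1:9]) stop("unknown site: ", s, call. = FALSE)
  structure(list(require_baseline_all_fed = require_baseline_all_fed,
                 require_tumor_preference = require_tumor_preference,
                 require_pge_at = require_pge_at,
                 require_no_pge_at = require_no_pge_at,
                 flow_min = flow_min, flow_max = flow_max),
            class = "sizing_criteria")
}

.sizing_config <- function(params, base_config) {
  ivm_config(fluid = base_config$fluid, tree = base_config$tree,
             collaterals = base_config$collaterals,
             outlet_tube_lr = tube_spec(params$l_lr, params$d_lr),
             outlet_tube_ur = tube_spec(params$l_ur, params$d_ur),
             z_lr = params$z_lr, z_ur = params$z_ur, h_pump = params$h_pump,
             inflow_tube = base_config$inflow_tube, strict = FALSE)
}

# evaluate one scenario under one parameter set; returns rows of
# (case, check, pass, detail)
.check_one_case <- function(config, scenario, criteria, case_label) {
  flow_floor <- 1e-12
  rows <- list()
  add <- function(check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      case = case_label, check = check, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  baseline <- tryCatch({
    net <- build_ivm_network(config, scenario)
    solve_flow(net)
  }, error = function(e) e)
  if (inherits(baseline, "error")) {
    add("baseline_solvable", FALSE, conditionMessage(baseline))
    return(do.call(rbind, rows))
  }
  qo <- outlet_flows(baseline)
  qml <- flow_to_ml_min(qo)
  if (criteria$require_baseline_all_fed)
    add("baseline_all_fed", all(qo > flow_floor),
        sprintf("min outlet flow %.3g mL/min", min(qml)))
  if (criteria$require_tumor_preference) {
    tum <- qo[scenario$tumors]
    nor <- qo[setdiff(SEGMENT_LABELS, scenario$tumors)]
    add("tumor_preference",
        length(nor) == 0L || min(tum) > max(nor),
        sprintf("min tumor %.3g vs max normal %.3g mL/min",
                flow_to_ml_min(min(tum)),
                if (length(nor)) flow_to_ml_min(max(nor)) else NA))
  }
  if (!is.null(criteria$flow_min))
    add("flow_min", all(qml >= criteria$flow_min),
        sprintf("min %.3g mL/min", min(qml)))
  if (!is.null(criteria$flow_max))
    add("flow_max", sum(qml) <= criteria$flow_max,
        sprintf("total %.3g mL/min", sum(qml)))

  for (spec in list(c(criteria$require_pge_at, "TRUE"),
                    c(criteria$require_no_pge_at, "FALSE"))) {
    site <- spec[1]; want <- as.logical(spec[2])
    res <- tryCatch(assess_occlusion(config, scenario, site, baseline = baseline),
                    error = function(e) e)
    if (inherits(res, "error")) {
      add(paste0("pge_", site), FALSE, conditionMessage(res))
    } else {
      add(paste0(if (want) "pge_at_" else "no_pge_at_", site),
          identical(res$pge, want),
          sprintf("BOASP %.1f Pa", res$boasp))
    }
  }
  do.call(rbind, rows)
}

#' Check a sizing candidate against the design criteria
#'
#' Runs the six scenario-by-catheter-state combinations (Case 1 = tumors in
#' S7, Case 2 = tumors in S5 and S7; no occlusion, site `c`, site `b`)
#' through the circuit model and evaluates each criterion.  Infeasible or
#' unsolvable candidates fail with a diagnostic instead of raising.
#'
#' @param params A [sizing_params()] object (or plain named list with the
#'   seven entries).
#' @param criteria A [sizing_criteria()].
#' @param base_config [ivm_config()] supplying everything the seven sizing
#'   parameters do not (fluid, artery geometry, inflow tube).
#'
#' @return An object of class `sizing_result`: list with `params`,
#'   `checks` (data frame case/check/pass/detail), `pass` (overall), and
#'   `margin` (URP minus BOASP at the PGE site for Case 1, Pa; `NA` when
#'   unsolvable).  Deterministic.
#' @export
check_design_criteria <- function(params = sizing_params(),
                                  criteria = sizing_criteria(),
                                  base_config = ivm_config()) {
  if (!inherits(params, "sizing_params")) params <- do.call(sizing_params, params)
  stopifnot(inherits(criteria, "sizing_criteria"))
  config <- tryCatch(.sizing_config(params, base_config),
                     error = function(e) e)
  if (inherits(config, "error")) {
    checks <- data.frame(case = "all", check = "valid_geometry", pass = FALSE,
                         detail = conditionMessage(config),
                         stringsAsFactors = FALSE)
    return(structure(list(params = params, checks = checks, pass = FALSE,
                          margin = NA_real_), class = "sizing_result"))
  }
  cases <- list(case1 = cancer_scenario("S7"),
                case2 = cancer_scenario(c("S5", "S7")))
  checks <- do.call(rbind, lapply(names(cases), function(nm)
    .check_one_case(config, cases[[nm]], criteria, nm)))
  margin <- tryCatch({
    a <- assess_occlusion(config, cases$case1, criteria$require_pge_at)
    source_pressure(config$fluid, config$z_ur) - a$boasp
  }, error = function(e) NA_real_)
  structure(list(params = params, checks = checks,
                 pass = all(checks$pass), margin = margin),
            class = "sizing_result")
}

#' @export
print.sizing_result <- function(x, ...) {
  p <- unlist(x$params)
  cat("<sizing_result> ", if (x$pass) "PASS" else "FAIL",
      sprintf(" (PGE margin %.1f Pa)\n", x$margin), sep = "")
  cat("  ", paste(sprintf("%s=%g mm", names(p), 1000 * p), collapse = ", "),
      "\n", sep = "")
  bad <- x$checks[!x$checks$pass, , drop = FALSE]
  if (nrow(bad)) {
    cat("  failed checks:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("    [%s] %s: %s\n", bad$case[i], bad$check[i], bad$detail[i]))
  }
  invisible(x)
}

#' Grid search over sizing parameters
#'
#' Exhaustive, deterministic evaluation of a finite grid of candidate
#' parameter vectors.  Candidates violating physical validity are evaluated
#' as failures, not errors.  Passing candidates are ranked by the PGE
#' margin (URP minus the BOASP at the PGE site, Case 1): a larger margin
#' means the stump pressure sits more safely below the threshold pressure.
#'
#' @param grid Named list of numeric vectors, one per sizing parameter
#'   (`l_lr`, `d_lr`, `l_ur`, `d_ur`, `z_lr`, `z_ur`, `h_pump`); missing
#'   parameters take their default.  The grid is the Cartesian product.
#' @param criteria A [sizing_criteria()].
#' @param base_config See [check_design_criteria()].
#'
#' @return A list with `passing` (list of `sizing_result`, sorted by
#'   decreasing margin), `table` (data frame of all candidates with
#'   pass/margin), and `n_evaluated`.
#' @export
search_sizing <- function(grid, criteria = sizing_criteria(),
                          base_config = ivm_config()) {
  if (!is.list(grid) || length(grid) == 0L)
    stop("'grid' must be a non-empty named list of parameter ranges", call. = FALSE)
  defaults <- unclass(sizing_params())
  bad <- setdiff(names(grid), names(defaults))
  if (length(bad))
    stop("unknown sizing parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  full <- utils::modifyList(defaults, grid)
  cand <- do.call(expand.grid, c(full, KEEP.OUT.ATTRS = FALSE))
  if (!nrow(cand)) stop("empty sizing grid", call. = FALSE)

  results <- lapply(seq_len(nrow(cand)), function(i) {
    check_design_criteria(as.list(cand[i, , drop = FALSE]), criteria,
                          base_config)
  })
  tab <- cbind(cand,
               pass = vapply(results, `[[`, logical(1), "pass"),
               margin = vapply(results, `[[`, numeric(1), "margin"))
  passing <- results[tab$pass]
  ord <- order(vapply(passing, `[[`, numeric(1), "margin"), decreasing = TRUE)
  list(passing = passing[ord], table = tab, n_evaluated = nrow(cand))
}
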