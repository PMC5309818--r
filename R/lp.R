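# Linear-programming core.
#
# All flux LPs in the package have the form
#     optimize  c'v   subject to  S v = 0,  lb <= v <= ub.
# They are solved by the bounded-variable two-phase simplex in
# simplex.R. Infinite bounds are capped at LP_BIG; an optimum riding an
# artificial cap is reported as "unbounded".

LP_BIG <- 1e6
LP_TOL <- 1e-6

#' Solve a bounded steady-state flux LP
#'
#' @param S stoichiometric matrix (rows metabolites, columns variables);
#'   dense or sparse.
#' @param lb,ub per-variable bounds (infinities allowed; capped internally).
#' @param obj objective coefficient vector.
#' @param maximize logical.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxiter"`), `objective` (value in the original variables; `NA` unless
#'   optimal), and `flux` (one optimal vertex; advisory under degeneracy).
#' @export
solve_lp <- function(S, lb, ub, obj, maximize = TRUE) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(obj) == n)
  if (any(lb > ub)) return(list(status = "infeasible", objective = NA_real_,
                                flux = NULL))
  capped_lo <- is.infinite(lb); capped_hi <- is.infinite(ub)
  lb <- pmax(lb, -LP_BIG); ub <- pmin(ub, LP_BIG)

  res <- simplex_bounded(S, rep(0, nrow(S)),
                         if (maximize) -obj else obj, lb, ub)
  if (res$status != "optimal") {
    status <- if (res$status %in% c("infeasible", "unbounded")) res$status
    else "maxiter"
    return(list(status = status, objective = NA_real_, flux = NULL))
  }
  v <- res$x
  names(v) <- colnames(S)
  objective <- sum(obj * v)
  # an optimum riding an artificial cap means the true problem is unbounded
  at_cap <- (capped_hi & v > LP_BIG * 0.999) | (capped_lo & v < -LP_BIG * 0.999)
  if (any(at_cap & obj != 0) || abs(objective) >= LP_BIG * 0.5) {
    return(list(status = "unbounded", objective = NA_real_, flux = NULL))
  }
  list(status = "optimal", objective = objective, flux = v)
}

#' Media (exchange-bound) constraint sets
#'
#' A media object is a table of exchange-reaction bound overrides plus a
#' label. When applied, listed exchanges replace the model defaults;
#' unlisted exchanges keep their model bounds.
#'
#' @param bounds data.frame with columns `reaction`, `lb`, `ub`.
#' @param label one of `"strict_physiological"`, `"relaxed_physiological"`,
#'   `"open_exchange"`, `"custom"`.
#' @return object of class `"media_constraints"`.
#' @export
media_constraints <- function(bounds, label = "custom") {
  stopifnot(is.data.frame(bounds),
            all(c("reaction", "lb", "ub") %in% names(bounds)))
  label <- match.arg(label, c("strict_physiological", "relaxed_physiological",
                              "open_exchange", "custom"))
  if (any(bounds$lb > bounds$ub)) stop("media with lb > ub")
  structure(list(bounds = bounds[c("reaction", "lb", "ub")], label = label),
            class = "media_constraints")
}

#' @rdname media_constraints
#' @param path tab-delimited file with header `reaction`, `lb`, `ub`.
#' @export
read_media <- function(path, label = "custom") {
  media_constraints(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE), label)
}

#' Apply media constraints to a network
#'
#' @param network `"metabolic_network"`.
#' @param media `"media_constraints"` or `NULL` (no change).
#' @return the network with overridden exchange bounds.
#' @export
apply_media <- function(network, media) {
  if (is.null(media)) return(network)
  stopifnot(inherits(network, "metabolic_network"),
            inherits(media, "media_constraints"))
  j <- match(media$bounds$reaction, network$rxns$id)
  if (anyNA(j)) stop("media references unknown reaction(s): ",
                     paste(media$bounds$reaction[is.na(j)], collapse = ", "))
  if (!all(network$rxns$kind[j] == "exchange")) {
    stop("media constraints must target exchange reactions: ",
         paste(media$bounds$reaction[network$rxns$kind[j] != "exchange"],
               collapse = ", "))
  }
  set_bounds(network, media$bounds$reaction, media$bounds$lb, media$bounds$ub)
}

#' Flux balance analysis
#'
#' Maximizes the flux through an objective reaction subject to steady-state
#' mass balance (`S v = 0`) and flux bounds, optionally under media
#' constraints.
#'
#' @param network `"metabolic_network"`.
#' @param objective reaction id; defaults to the network objective.
#' @param media optional `"media_constraints"`.
#' @return list of class `"fba_result"` with `status`, `objective_value`,
#'   `fluxes` (named vector; one optimal vertex), `objective` (reaction id).
#' @export
fba <- function(network, objective = NULL, media = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  if (is.null(objective)) objective <- network$objective
  if (is.na(objective) || !objective %in% network$rxns$id) {
    stop("objective reaction not found: ", objective)
  }
  net <- apply_media(network, media)
  obj <- as.numeric(net$rxns$id == objective)
  sol <- solve_lp(net$S, net$rxns$lb, net$rxns$ub, obj, maximize = TRUE)
  structure(list(status = sol$status, objective_value = sol$objective,
                 fluxes = sol$flux, objective = objective),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("FBA [", x$objective, "]: status ", x$status, sep = "")
  if (x$status == "optimal") cat(", objective ", format(x$objective_value), sep = "")
  cat("\n")
  invisible(x)
}

#' Doubling time from an exponential growth rate
#'
#' @param growth_rate specific growth rate in 1/h (must be positive).
#' @return doubling time in hours, `log(2) / growth_rate`.
#' @examples
#' doubling_time(0.048)  # 14.44 h
#' @export
doubling_time <- function(growth_rate) {
  if (any(!is.finite(growth_rate)) || any(growth_rate <= 0)) {
    stop("growth rate must be positive and finite")
  }
  log(2) / growth_rate
}

#' Flux variability analysis
#'
#' Computes per-reaction minimum and maximum feasible flux subject to mass
#' balance, bounds and (optionally) an objective floor at a fraction of the
#' FBA optimum. Blocked reactions return `(0, 0)`.
#'
#' @param network `"metabolic_network"`.
#' @param reactions reaction ids (default: all).
#' @param media optional `"media_constraints"`.
#' @param objective_fraction in `[0, 1]`; if `> 0` the network objective is
#'   optimized first and constrained to at least this fraction of its
#'   optimum during the per-reaction solves.
#' @return data.frame with `reaction`, `min_flux`, `max_flux`.
#' @export
fva <- function(network, reactions = NULL, media = NULL, objective_fraction = 0) {
  stopifnot(inherits(network, "metabolic_network"),
            objective_fraction >= 0, objective_fraction <= 1)
  net <- apply_media(network, media)
  if (is.null(reactions)) reactions <- net$rxns$id
  j <- match(reactions, net$rxns$id)
  if (anyNA(j)) stop("unknown reaction(s): ",
                     paste(reactions[is.na(j)], collapse = ", "))
  if (objective_fraction > 0) {
    base <- fba(net)
    if (base$status != "optimal") {
      stop("base FBA not optimal (status ", base$status,
           "); cannot apply objective floor")
    }
    net <- set_bounds(net, net$objective,
                      lb = objective_fraction * base$objective_value)
  } else {
    # fail fast on an infeasible base model
    feas <- solve_lp(net$S, net$rxns$lb, net$rxns$ub,
                     rep(0, ncol(net$S)), maximize = TRUE)
    if (feas$status == "infeasible") stop("model infeasible under given constraints")
  }
  res <- t(vapply(j, function(jj) {
    obj <- numeric(ncol(net$S)); obj[jj] <- 1
    lo <- solve_lp(net$S, net$rxns$lb, net$rxns$ub, obj, maximize = FALSE)
    hi <- solve_lp(net$S, net$rxns$lb, net$rxns$ub, obj, maximize = TRUE)
    c(if (lo$status == "optimal") lo$objective else if (lo$status == "unbounded") -Inf else NA_real_,
      if (hi$status == "optimal") hi$objective else if (hi$status == "unbounded") Inf else NA_real_)
  }, numeric(2)))
  out <- data.frame(reaction = reactions, min_flux = res[, 1], max_flux = res[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  # clean tiny numerical negatives on blocked reactions
  z <- !is.na(out$min_flux) & !is.na(out$max_flux) &
    abs(out$min_flux) < LP_TOL & abs(out$max_flux) < LP_TOL
  out$min_flux[z] <- 0; out$max_flux[z] <- 0
  out
}

#' Weighted parsimonious flux minimization (global network demand)
#'
#' Minimizes the weighted sum of fluxes `sum(w_i v_i)` over an irreversible
#' network subject to `S v = 0` and bounds, with a forced minimum flux
#' through one reaction column (typically the secretion direction of a
#' metabolite's exchange reaction). The optimal value is the global network
#' demand for producing that metabolite; it is unique to solver tolerance
#' even when the flux vector is degenerate.
#'
#' @param irrev `"irreversible_network"`.
#' @param weights strictly positive vector, one per irreversible column
#'   (named or in column order).
#' @param forced_reaction column name of the forced (secretion) direction.
#' @param min_rate forced lower bound on that column.
#' @return list with `demand`, `flux` (advisory), `status`.
#' @export
min_weighted_flux <- function(irrev, weights, forced_reaction, min_rate) {
  stopifnot(inherits(irrev, "irreversible_network"))
  n <- ncol(irrev$S)
  if (!is.null(names(weights))) weights <- weights[colnames(irrev$S)]
  stopifnot(length(weights) == n)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be strictly positive")
  }
  k <- match(forced_reaction, colnames(irrev$S))
  if (is.na(k)) stop("unknown irreversible column: ", forced_reaction)
  lb <- irrev$lb; ub <- irrev$ub
  lb[k] <- max(lb[k], min_rate)
  if (lb[k] > ub[k]) {
    return(list(demand = NA_real_, flux = NULL, status = "infeasible"))
  }
  sol <- solve_lp(irrev$S, lb, ub, weights, maximize = FALSE)
  list(demand = sol$objective, flux = sol$flux, status = sol$status)
}

#' Metabolic task definitions and feasibility checks
#'
#' A task opens only its stated input and output exchanges on an otherwise
#' closed network and asks whether a steady-state flux exists. Inputs are
#' uptake allowances (positive numbers = allowed consumption); outputs are
#' secretion requirements/allowances. A task with `should_fail = TRUE`
#' passes when it is infeasible (species-specific incapability checks).
#'
#' @param id,description task identity.
#' @param inputs,outputs data.frames with columns `mid` (metabolite key,
#'   `id[compartment]`), `lb`, `ub` in uptake/secretion units.
#' @param should_fail logical.
#' @return object of class `"task_definition"`.
#' @export
task_definition <- function(id, description = "", inputs = NULL, outputs = NULL,
                            should_fail = FALSE) {
  empty <- data.frame(mid = character(0), lb = numeric(0), ub = numeric(0))
  chk <- function(x) {
    if (is.null(x)) return(empty)
    stopifnot(all(c("mid", "lb", "ub") %in% names(x)))
    x[c("mid", "lb", "ub")]
  }
  structure(list(id = id, description = description, inputs = chk(inputs),
                 outputs = chk(outputs), should_fail = isTRUE(should_fail)),
            class = "task_definition")
}

#' Check one metabolic task
#'
#' @param network `"metabolic_network"`.
#' @param task `"task_definition"`.
#' @return list of class `"task_result"` with `id`, `feasible`, `passed`
#'   (`feasible` when `should_fail` is `FALSE`, `!feasible` when `TRUE`),
#'   and `error` (message, or `NA`).
#' @export
check_task <- function(network, task) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(task, "task_definition"))
  out <- function(feasible, error = NA_character_) {
    passed <- if (!is.na(error)) FALSE else xor(feasible, task$should_fail)
    structure(list(id = task$id, feasible = feasible, passed = passed,
                   error = error), class = "task_result")
  }
  ex <- exchange_reactions(network)
  # close every exchange, then open only the task's inputs/outputs
  net <- set_bounds(network, ex$rxn, lb = 0, ub = 0)
  lbs <- stats::setNames(rep(0, nrow(ex)), ex$rxn)
  ubs <- lbs
  lookup <- function(mid) ex$rxn[match(mid, ex$mid)]
  for (i in seq_len(nrow(task$inputs))) {
    r <- lookup(task$inputs$mid[i])
    if (is.na(r)) return(out(NA, paste0("no exchange reaction for input ",
                                        task$inputs$mid[i])))
    # uptake: positive allowance maps to negative exchange flux
    lbs[r] <- lbs[r] - task$inputs$ub[i]
    ubs[r] <- ubs[r] - task$inputs$lb[i]
  }
  for (i in seq_len(nrow(task$outputs))) {
    r <- lookup(task$outputs$mid[i])
    if (is.na(r)) return(out(NA, paste0("no exchange reaction for output ",
                                        task$outputs$mid[i])))
    lbs[r] <- lbs[r] + task$outputs$lb[i]
    ubs[r] <- ubs[r] + task$outputs$ub[i]
  }
  net <- set_bounds(net, ex$rxn, lb = pmin(lbs, ubs), ub = pmax(lbs, ubs))
  sol <- solve_lp(net$S, net$rxns$lb, net$rxns$ub, rep(0, ncol(net$S)))
  out(sol$status == "optimal")
}

#' Run a list of tasks and summarize
#'
#' @param network `"metabolic_network"`.
#' @param tasks list of `"task_definition"`.
#' @return list of class `"task_summary"`: `results` data.frame (`id`,
#'   `feasible`, `passed`, `error`), `n_passed`, `n_failed`, `failures`.
#' @export
run_tasks <- function(network, tasks) {
  res <- lapply(tasks, function(t) check_task(network, t))
  df <- data.frame(
    id = vapply(res, `[[`, "", "id"),
    feasible = vapply(res, `[[`, NA, "feasible"),
    passed = vapply(res, `[[`, NA, "passed"),
    error = vapply(res, `[[`, NA_character_, "error"),
    stringsAsFactors = FALSE)
  structure(list(results = df, n_passed = sum(df$passed),
                 n_failed = sum(!df$passed),
                 failures = df$id[!df$passed]), class = "task_summary")
}

#' @export
print.task_summary <- function(x, ...) {
  cat("Metabolic tasks: ", x$n_passed, " passed, ", x$n_failed, " failed\n",
      sep = "")
  if (length(x$failures)) cat("  failed:", paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}

#' Read task definitions from a tab-delimited block file
#'
#' Format: blocks separated by blank lines. Each block:
#' ```
#' TASK <id> <description...>
#' IN  <mid> <lb> <ub>
#' OUT <mid> <lb> <ub>
#' SHOULD_FAIL            # optional
#' ```
#'
#' @param path file path.
#' @return list of `"task_definition"`.
#' @export
read_tasks <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split(lines, cumsum(lines == ""))
  out <- list()
  for (b in blocks) {
    b <- b[nzchar(b)]
    if (!length(b)) next
    toks <- strsplit(b, "[[:space:]]+")
    hd <- toks[[1]]
    if (toupper(hd[1]) != "TASK") stop("task block must start with TASK: ", b[1])
    id <- hd[2]
    descr <- paste(hd[-(1:2)], collapse = " ")
    ins <- list(); outs <- list(); sf <- FALSE
    for (t in toks[-1]) {
      key <- toupper(t[1])
      if (key == "SHOULD_FAIL") { sf <- TRUE; next }
      if (!key %in% c("IN", "OUT")) stop("unknown task row: ", paste(t, collapse = " "))
      row <- data.frame(mid = t[2], lb = as.numeric(t[3]), ub = as.numeric(t[4]))
      if (key == "IN") ins[[length(ins) + 1L]] <- row else outs[[length(outs) + 1L]] <- row
    }
    out[[length(out) + 1L]] <- task_definition(
      id, descr,
      inputs = if (length(ins)) do.call(rbind, ins) else NULL,
      outputs = if (length(outs)) do.call(rbind, outs) else NULL,
      should_fail = sf)
  }
  out
}
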