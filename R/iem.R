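#' Open-exchange media for inborn-error simulations
#'
#' Formulates the open exchange condition: unconstrained uptake for a
#' configurable list of inorganic ions, limited uptake (lower bound -1, in
#' arbitrary units) for every other metabolite with an exchange reaction,
#' and unconstrained secretion throughout.
#'
#' @param network `"metabolic_network"`.
#' @param ion_mids metabolite keys (`id[compartment]`) of the freely
#'   imported inorganic ions; defaults to a 12-ion configuration of common
#'   inorganic species, intersected with the network's exchangeable
#'   metabolites only when `ion_mids` is left at its default. Explicitly
#'   supplied ions must be exchangeable.
#' @return `"media_constraints"` with label `"open_exchange"` covering
#'   every exchange reaction of the network.
#' @export
open_exchange_media <- function(network, ion_mids = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  ex <- exchange_reactions(network)
  default_ions <- is.null(ion_mids)
  if (default_ions) {
    # default 12-ion configuration: common inorganic ions
    ion_base <- c("h", "h2o", "pi", "o2", "co2", "na1", "k", "cl", "ca2",
                  "mg2", "fe2", "so4")
    ion_mids <- ex$mid[sub("\\[.*\\]$", "", ex$mid) %in% ion_base]
  } else {
    miss <- setdiff(ion_mids, ex$mid)
    if (length(miss)) {
      stop("ion metabolite(s) without exchange reactions: ",
           paste(miss, collapse = ", "))
    }
  }
  is_ion <- ex$mid %in% ion_mids
  media_constraints(
    data.frame(reaction = ex$rxn,
               lb = ifelse(is_ion, -Inf, -1),
               ub = Inf, stringsAsFactors = FALSE),
    label = "open_exchange")
}

#' Reactions disabled by loss of a gene set
#'
#' A reaction is affected when its GPR rule evaluates to `FALSE` with the
#' given genes absent and every other gene present. Non-enzymatic
#' reactions are never affected.
#'
#' @param network `"metabolic_network"`.
#' @param genes character vector of lost (causal) gene ids.
#' @return character vector of affected reaction ids.
#' @export
affected_reactions <- function(network, genes) {
  stopifnot(inherits(network, "metabolic_network"))
  miss <- setdiff(genes, network$genes)
  if (length(miss)) stop("gene(s) not in network: ", paste(miss, collapse = ", "))
  absent <- stats::setNames(rep(FALSE, length(genes)), genes)
  hit <- vapply(network$rxns$id, function(r) {
    !gpr_eval(network$gpr[[r]], absent, default = TRUE)
  }, NA)
  network$rxns$id[hit]
}

#' An inborn-error-of-metabolism case
#'
#' @param id case identifier (disorder name).
#' @param genes causal gene ids (at least one).
#' @param biomarkers data.frame with columns `mid` (metabolite key of the
#'   biomarker's exchange metabolite) and `direction` in
#'   `{elevated, reduced}` (at least one row).
#' @return object of class `"iem_case"`.
#' @export
iem_case <- function(id, genes, biomarkers) {
  stopifnot(length(genes) >= 1, is.data.frame(biomarkers),
            all(c("mid", "direction") %in% names(biomarkers)),
            nrow(biomarkers) >= 1,
            all(biomarkers$direction %in% c("elevated", "reduced")))
  structure(list(id = id, genes = genes,
                 biomarkers = biomarkers[c("mid", "direction")]),
            class = "iem_case")
}

#' Read IEM cases from a tab-delimited file
#'
#' Columns: `iem_id`, `genes` (semicolon-separated), `biomarker`
#' (metabolite key), `direction`; one row per (case, biomarker) pair.
#'
#' @param path file path.
#' @return list of `"iem_case"`.
#' @export
read_iem_cases <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("iem_id", "genes", "biomarker", "direction") %in% names(df)))
  lapply(split(df, df$iem_id), function(d) {
    iem_case(d$iem_id[1], strsplit(d$genes[1], ";", fixed = TRUE)[[1]],
             data.frame(mid = d$biomarker, direction = d$direction,
                        stringsAsFactors = FALSE))
  })
}

#' Predict biomarker shifts for one IEM case
#'
#' Simulates the healthy condition by forcing each reaction associated
#' with the causal genes to at least 90% of its maximum feasible flux
#' under open-exchange conditions (for reversible reactions, the direction
#' with the larger absolute FBA optimum), and the disease condition by
#' closing those reactions. Biomarker exchange reactions are then compared
#' between conditions by flux variability: with healthy range
#' `[min_h, max_h]` and disease range `[min_d, max_d]`, the call is
#' elevated when `(min_d + max_d) - (min_h + max_h)` exceeds the tolerance
#' `tau = 1e-6 * max(1, |max_h|)`, reduced when below `-tau`, else
#' unchanged.
#'
#' @param network `"metabolic_network"`.
#' @param case `"iem_case"`.
#' @param media open-exchange `"media_constraints"`; defaults to
#'   [open_exchange_media()] on the network.
#' @param forcing_fraction fraction of the maximum flux forced in the
#'   healthy condition (default 0.9).
#' @param simultaneous force all affected reactions at once (default) or,
#'   if `FALSE`, evaluate biomarkers per affected reaction and combine by
#'   majority of non-unchanged calls.
#' @return list of class `"iem_prediction"`: `case`, `affected`, `calls`
#'   (data.frame: `mid`, `exchange`, `expected`, `call`, `correct`,
#'   healthy/disease ranges), `status` (`"ok"` or `"unevaluable"`).
#' @export
predict_iem <- function(network, case, media = NULL, forcing_fraction = 0.9,
                        simultaneous = TRUE) {
  stopifnot(inherits(network, "metabolic_network"), inherits(case, "iem_case"))
  if (is.null(media)) media <- open_exchange_media(network)
  net <- apply_media(network, media)
  aff <- affected_reactions(net, case$genes)
  ex <- exchange_reactions(net)
  bm <- case$biomarkers
  bm$exchange <- ex$rxn[match(bm$mid, ex$mid)]
  if (anyNA(bm$exchange)) {
    stop("biomarker(s) without exchange reactions: ",
         paste(bm$mid[is.na(bm$exchange)], collapse = ", "))
  }
  unevaluable <- function() {
    calls <- data.frame(mid = bm$mid, exchange = bm$exchange,
                        expected = bm$direction, call = NA_character_,
                        correct = NA, stringsAsFactors = FALSE)
    structure(list(case = case$id, affected = aff, calls = calls,
                   status = "unevaluable"), class = "iem_prediction")
  }
  force_one <- function(net, rxn) {
    j <- match(rxn, net$rxns$id)
    obj <- numeric(ncol(net$S)); obj[j] <- 1
    hi <- solve_lp(net$S, net$rxns$lb, net$rxns$ub, obj, maximize = TRUE)
    lo <- solve_lp(net$S, net$rxns$lb, net$rxns$ub, obj, maximize = FALSE)
    vmax <- if (hi$status == "optimal") hi$objective else 0
    vmin <- if (lo$status == "optimal") lo$objective else 0
    # force the direction with the larger |FBA optimum|
    if (abs(vmax) >= abs(vmin)) {
      if (vmax <= LP_TOL) return(net)  # carries no flux; nothing to force
      set_bounds(net, rxn, lb = forcing_fraction * vmax)
    } else {
      set_bounds(net, rxn, ub = forcing_fraction * vmin)
    }
  }
  compare_ranges <- function(healthy, disease) {
    mapply(function(min_h, max_h, min_d, max_d) {
      if (anyNA(c(min_h, max_h, min_d, max_d))) return(NA_character_)
      tau <- 1e-6 * max(1, abs(max_h))
      delta <- (min_d + max_d) - (min_h + max_h)
      if (delta > tau) "elevated" else if (delta < -tau) "reduced" else "unchanged"
    }, healthy$min_flux, healthy$max_flux, disease$min_flux, disease$max_flux)
  }
  run_condition <- function(net) {
    ok <- tryCatch(fva(net, bm$exchange), error = function(e) NULL)
    ok
  }
  net_disease <- set_bounds(net, aff, lb = 0, ub = 0)
  if (simultaneous || length(aff) <= 1L) {
    net_healthy <- net
    for (r in aff) net_healthy <- force_one(net_healthy, r)
    healthy <- run_condition(net_healthy)
    if (is.null(healthy)) return(unevaluable())
    disease <- run_condition(net_disease)
    if (is.null(disease)) return(unevaluable())
    bm$call <- compare_ranges(healthy, disease)
    bm <- cbind(bm, stats::setNames(healthy[c("min_flux", "max_flux")],
                                    c("min_healthy", "max_healthy")),
                stats::setNames(disease[c("min_flux", "max_flux")],
                                c("min_disease", "max_disease")))
  } else {
    votes <- matrix(NA_character_, nrow(bm), length(aff))
    disease <- run_condition(net_disease)
    if (is.null(disease)) return(unevaluable())
    for (k in seq_along(aff)) {
      healthy <- run_condition(force_one(net, aff[k]))
      if (is.null(healthy)) return(unevaluable())
      votes[, k] <- compare_ranges(healthy, disease)
    }
    bm$call <- apply(votes, 1, function(v) {
      v <- v[!is.na(v) & v != "unchanged"]
      if (!length(v)) return("unchanged")
      names(sort(base::table(v), decreasing = TRUE))[1]
    })
    bm$min_healthy <- bm$max_healthy <- NA_real_
    bm$min_disease <- bm$max_disease <- NA_real_
  }
  bm$expected <- bm$direction
  bm$correct <- bm$call == bm$expected
  calls <- bm[c("mid", "exchange", "expected", "call", "correct",
                "min_healthy", "max_healthy", "min_disease", "max_disease")]
  rownames(calls) <- NULL
  structure(list(case = case$id, affected = aff, calls = calls, status = "ok"),
            class = "iem_prediction")
}

#' Summarize IEM predictions in a sensitivity table
#'
#' @param predictions list of `"iem_prediction"` (one per case).
#' @return list of class `"iem_evaluation"`: `by_direction` data.frame
#'   (`direction`, `n`, `correct`, `sensitivity` in percent), `total_n`,
#'   `total_correct`, `total_sensitivity` (percent), `unevaluable` (case
#'   ids).
#' @export
evaluate_iem <- function(predictions) {
  stopifnot(length(predictions) >= 1)
  all_calls <- do.call(rbind, lapply(predictions, function(p) {
    if (p$status != "ok") return(NULL)
    p$calls[c("expected", "correct")]
  }))
  unev <- vapply(predictions, function(p) p$status != "ok", NA)
  if (is.null(all_calls) || !nrow(all_calls)) {
    stop("no evaluable IEM predictions")
  }
  by_dir <- do.call(rbind, lapply(c("elevated", "reduced"), function(d) {
    sub <- all_calls[all_calls$expected == d, ]
    data.frame(direction = d, n = nrow(sub),
               correct = sum(sub$correct, na.rm = TRUE),
               sensitivity = if (nrow(sub)) 100 * sum(sub$correct, na.rm = TRUE) / nrow(sub)
               else NA_real_, stringsAsFactors = FALSE)
  }))
  structure(list(
    by_direction = by_dir,
    total_n = nrow(all_calls),
    total_correct = sum(all_calls$correct, na.rm = TRUE),
    total_sensitivity = 100 * sum(all_calls$correct, na.rm = TRUE) / nrow(all_calls),
    unevaluable = vapply(predictions[unev], `[[`, "", "case")),
    class = "iem_evaluation")
}

#' @export
print.iem_evaluation <- function(x, ...) {
  cat("IEM biomarker sensitivity\n")
  for (i in seq_len(nrow(x$by_direction))) {
    d <- x$by_direction[i, ]
    cat(sprintf("  %-9s %3d of %3d (%.1f%%)\n", d$direction, d$correct, d$n,
                d$sensitivity))
  }
  cat(sprintf("  total     %3d of %3d (%.1f%%)\n", x$total_correct, x$total_n,
              x$total_sensitivity))
  if (length(x$unevaluable)) {
    cat("  unevaluable:", paste(x$unevaluable, collapse = ", "), "\n")
  }
  invisible(x)
}
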