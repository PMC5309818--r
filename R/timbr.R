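#' Significance-filter an expression change table
#'
#' Sets `log2fc` to exactly 0 for genes whose FDR-adjusted q-value is at or
#' above the threshold; significant changes pass through unchanged.
#'
#' @param expr data.frame with columns `gene`, `log2fc`, `qvalue`.
#' @param q_threshold FDR threshold (default 0.1; `q < threshold` is
#'   significant).
#' @return the table with insignificant `log2fc` zeroed.
#' @export
filter_significant <- function(expr, q_threshold = 0.1) {
  stopifnot(is.data.frame(expr),
            all(c("gene", "log2fc", "qvalue") %in% names(expr)))
  if (any(expr$qvalue < 0 | expr$qvalue > 1, na.rm = TRUE)) {
    stop("qvalue outside [0, 1]")
  }
  insig <- is.na(expr$qvalue) | expr$qvalue >= q_threshold
  expr$log2fc[insig] <- 0
  expr
}

#' Is a compound's expression response suitable for model integration?
#'
#' A compound qualifies when its significant genes cover at least
#' `min_fraction` of the model gene set (model genes also present on the
#' expression platform). The boundary is inclusive ("at least 1%").
#'
#' @param expr expression table (`gene`, `log2fc`, `qvalue`).
#' @param model_gene_set character vector of model genes on the platform.
#' @param q_threshold significance threshold.
#' @param min_fraction minimum affected fraction (default 0.01).
#' @return list with `suitable` (logical), `n_affected`, `fraction`.
#' @export
compound_suitability <- function(expr, model_gene_set, q_threshold = 0.1,
                                 min_fraction = 0.01) {
  stopifnot(is.data.frame(expr))
  if (!length(model_gene_set)) stop("empty model gene set")
  sig <- expr$gene[!is.na(expr$qvalue) & expr$qvalue < q_threshold]
  n <- length(intersect(sig, model_gene_set))
  frac <- n / length(model_gene_set)
  list(suitable = frac >= min_fraction, n_affected = n, fraction = frac)
}

#' Summarize gene expression changes through a GPR rule
#'
#' Recursive tree evaluation of a significance-filtered log2 fold-change
#' vector: an `OR` node (isozymes) takes the arithmetic mean of its
#' children, so one changed isozyme is diluted by unaffected partners; an
#' `AND` node (complex subunits) takes the child with the largest absolute
#' value (ties broken toward the positive value, then the first child); a
#' leaf contributes its log2 fold change, with genes absent from the data
#' contributing 0.
#'
#' @param rule `"gpr"` object or `NULL`.
#' @param log2fc named numeric vector of (already filtered) log2 fold
#'   changes.
#' @return summarized value `r` (0 for the empty rule).
#' @export
summarize_gpr <- function(rule, log2fc) {
  if (is.null(rule)) return(0)
  rec <- function(node) {
    if (node$op == "gene") {
      v <- log2fc[node$id]
      return(if (is.na(v)) 0 else unname(v))
    }
    vals <- vapply(node$args, rec, 0)
    if (node$op == "or") return(mean(vals))
    mx <- max(abs(vals))
    cand <- vals[abs(vals) == mx]
    if (any(cand > 0)) cand[cand > 0][1] else cand[1]
  }
  rec(unclass(rule))
}

#' Per-reaction expression summaries for a network
#'
#' @param network `"metabolic_network"`.
#' @param expr expression table (`gene`, `log2fc`, `qvalue`); pass the
#'   platform table, filtering is applied here.
#' @param q_threshold significance threshold for [filter_significant()].
#' @return data.frame with `reaction`, `r` (summarized log2 value) and
#'   `data_status` in `{summarized, no_gpr, no_data}`. `no_data` marks
#'   gene-associated reactions none of whose genes are on the platform.
#' @export
reaction_summaries <- function(network, expr, q_threshold = 0.1) {
  stopifnot(inherits(network, "metabolic_network"))
  expr <- filter_significant(expr, q_threshold)
  fc <- stats::setNames(expr$log2fc, expr$gene)
  platform <- expr$gene
  res <- lapply(network$rxns$id, function(rid) {
    rule <- network$gpr[[rid]]
    if (is.null(rule)) return(list(r = 0, status = "no_gpr"))
    gs <- gpr_genes(rule)
    if (!any(gs %in% platform)) return(list(r = 0, status = "no_data"))
    list(r = summarize_gpr(rule, fc), status = "summarized")
  })
  data.frame(reaction = network$rxns$id,
             r = vapply(res, `[[`, 0, "r"),
             data_status = vapply(res, `[[`, "", "status"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default reaction weights for weighted flux minimization
#'
#' Biochemical reactions weigh 1 and transport reactions 2 (exchange
#' reactions, boundary transport by construction, also 2); the weight is
#' doubled for reactions with no gene association or no expression data.
#' Both split directions of a reversible reaction share the weight, since
#' expression carries no directionality.
#'
#' @param irrev `"irreversible_network"`.
#' @param summaries output of [reaction_summaries()] for the source network.
#' @return named numeric vector, one weight per irreversible column.
#' @export
default_weights <- function(irrev, summaries) {
  stopifnot(inherits(irrev, "irreversible_network"))
  net <- irrev$network
  kind <- stats::setNames(net$rxns$kind, net$rxns$id)
  status <- stats::setNames(summaries$data_status, summaries$reaction)
  w_rxn <- ifelse(kind == "biochemical", 1, 2)
  dbl <- status[names(w_rxn)] %in% c("no_gpr", "no_data")
  w_rxn[dbl] <- 2 * w_rxn[dbl]
  stats::setNames(unname(w_rxn[irrev$cols$rxn]), irrev$cols$col)
}

#' Treatment and control weights from a summarized expression value
#'
#' The summarized log2 value `r` is inverse-log transformed to a fold
#' change `2^r`; control weights are the default weights multiplied by the
#' fold change and treatment weights are the default weights divided by
#' it, so upregulated reactions cost less under treatment and more under
#' control (and vice versa). The two transforms are reciprocal:
#' `w_control * w_treatment = w_default^2`.
#'
#' @param w_default default weight(s).
#' @param r summarized log2 value(s), recycled against `w_default`.
#' @return list with `w_treatment`, `w_control`.
#' @export
timbr_weights <- function(w_default, r) {
  stopifnot(all(is.finite(r)), all(w_default > 0))
  fold <- 2^r
  list(w_treatment = w_default / fold, w_control = w_default * fold)
}

#' Minimum forced production rate for a metabolite
#'
#' The production requirement is 90% of the maximum possible secretion
#' rate (by flux variability under the given constraints) or 100 flux
#' units (fmol per cell per hour on the physiological scale), whichever is
#' smaller. Metabolites whose maximum secretion is at tolerance are
#' unproducible and skipped.
#'
#' @param network `"metabolic_network"` (media already applied).
#' @param exchange_rxn id of the metabolite's exchange reaction.
#' @param cap absolute production cap (default 100).
#' @param fraction fraction of the maximum secretion rate (default 0.9).
#' @return list with `min_rate` (`NA` if unproducible), `v_max`,
#'   `status` in `{ok, skipped_unproducible}`.
#' @export
production_bound <- function(network, exchange_rxn, cap = 100, fraction = 0.9) {
  stopifnot(inherits(network, "metabolic_network"))
  j <- match(exchange_rxn, network$rxns$id)
  if (is.na(j) || network$rxns$kind[j] != "exchange") {
    stop("not an exchange reaction: ", exchange_rxn)
  }
  obj <- numeric(ncol(network$S)); obj[j] <- 1
  hi <- solve_lp(network$S, network$rxns$lb, network$rxns$ub, obj,
                 maximize = TRUE)
  v_max <- if (hi$status == "optimal") hi$objective else
    if (hi$status == "unbounded") Inf else 0
  if (v_max <= LP_TOL) {
    return(list(min_rate = NA_real_, v_max = v_max,
                status = "skipped_unproducible"))
  }
  list(min_rate = min(cap, fraction * v_max), v_max = v_max, status = "ok")
}

#' Raw production score from treatment and control demands
#'
#' Symmetric relative difference of the two global network demands,
#' `(d_control - d_treatment) / (d_control + d_treatment)`: positive when
#' the treatment-weighted network produces the metabolite more cheaply
#' than the control-weighted network (expression changes consistent with
#' production), bounded in `(-1, 1)`, and antisymmetric under swapping the
#' conditions.
#'
#' @param demand_treatment,demand_control positive weighted-flux demands.
#' @return raw production score.
#' @export
raw_production_score <- function(demand_treatment, demand_control) {
  if (any(!is.finite(demand_treatment)) || any(!is.finite(demand_control)) ||
      any(demand_treatment <= 0) || any(demand_control <= 0)) {
    stop("demands must be positive and finite")
  }
  (demand_control - demand_treatment) / (demand_control + demand_treatment)
}

#' z-normalize raw production scores
#'
#' Centers and scales with the sample standard deviation (n-1 denominator)
#' over the scored metabolites. A zero-variance vector returns all zeros
#' with a warning.
#'
#' @param raw numeric vector of raw scores (length >= 2).
#' @return z-scores with mean 0 and unit sample sd.
#' @export
normalize_scores <- function(raw) {
  stopifnot(is.numeric(raw))
  if (length(raw) < 2) stop("need at least two scored metabolites")
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    warning("zero variance across raw production scores; all z-scores set to 0")
    return(rep(0, length(raw)))
  }
  (raw - mean(raw)) / s
}

#' Transcriptionally inferred metabolic biomarker response (TIMBR)
#'
#' Fits TIMBR production scores for every exchangeable metabolite of a
#' network given one compound's differential expression table. The
#' pipeline: (1) zero insignificant log2 fold changes; (2) summarize
#' changes through each reaction's GPR (isozymes averaged, complex
#' subunits by largest absolute value); (3) build treatment and control
#' weight vectors around kind-based default weights on the irreversible
#' network; (4) for each metabolite, force secretion at
#' `min(cap, 0.9 * max secretion)` and minimize the weighted flux sum under
#' each condition (the global network demands); (5) score
#' `(d_control - d_treatment)/(d_control + d_treatment)` and z-normalize
#' across scored metabolites.
#'
#' @param network `"metabolic_network"`.
#' @param expr expression table with columns `gene`, `log2fc`, `qvalue`.
#' @param media optional `"media_constraints"` (typically the relaxed
#'   physiological set); used both for the secretion-capacity FVA and
#'   inside the weighted minimization.
#' @param metabolites optional character vector of exchange reaction ids to
#'   score (default: all exchange reactions).
#' @param q_threshold significance threshold (default 0.1).
#' @param cap,fraction see [production_bound()].
#' @param compound,organism metadata strings carried into the result.
#' @return object of class `"timbr"`: list with `scores` (data.frame:
#'   `exchange`, `metabolite`, `name`, `v_max`, `min_rate`,
#'   `demand_treatment`, `demand_control`, `raw_score`, `production_score`,
#'   `status`), `summaries`, `weights` (data.frame per irreversible
#'   column), `compound`, `organism`, `call`.
#' @seealso [compare_production_scores()], [classify_predictions()]
#' @export
timbr <- function(network, expr, media = NULL, metabolites = NULL,
                  q_threshold = 0.1, cap = 100, fraction = 0.9,
                  compound = NA_character_, organism = NA_character_) {
  stopifnot(inherits(network, "metabolic_network"))
  net <- apply_media(network, media)
  summaries <- reaction_summaries(net, expr, q_threshold)
  irrev <- make_irreversible(net)
  w_def <- default_weights(irrev, summaries)
  r_rxn <- stats::setNames(summaries$r, summaries$reaction)
  r_col <- unname(r_rxn[irrev$cols$rxn])
  ws <- timbr_weights(w_def, r_col)

  ex <- exchange_reactions(net)
  if (is.null(metabolites)) metabolites <- ex$rxn
  miss <- setdiff(metabolites, ex$rxn)
  if (length(miss)) stop("not exchange reactions: ", paste(miss, collapse = ", "))

  rows <- lapply(metabolites, function(rx) {
    i <- match(rx, ex$rxn)
    met_mid <- ex$mid[i]
    met_name <- net$mets$name[match(met_mid, net$mets$mid)]
    base <- list(exchange = rx, metabolite = met_mid, name = met_name,
                 v_max = NA_real_, min_rate = NA_real_,
                 demand_treatment = NA_real_, demand_control = NA_real_,
                 raw_score = NA_real_, production_score = NA_real_)
    pb <- production_bound(net, rx, cap = cap, fraction = fraction)
    base$v_max <- pb$v_max
    if (pb$status != "ok") { base$status <- pb$status; return(base) }
    base$min_rate <- pb$min_rate
    # forced column: the secretion (forward) direction of the exchange
    fcol <- irrev$cols$col[irrev$cols$rxn == rx & irrev$cols$dir == 1]
    dt <- min_weighted_flux(irrev, ws$w_treatment, fcol, pb$min_rate)
    dc <- min_weighted_flux(irrev, ws$w_control, fcol, pb$min_rate)
    if (dt$status != "optimal" || dc$status != "optimal") {
      base$status <- "infeasible"; return(base)
    }
    base$demand_treatment <- dt$demand
    base$demand_control <- dc$demand
    base$raw_score <- raw_production_score(dt$demand, dc$demand)
    base$status <- "scored"
    base
  })
  scores <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  scored <- scores$status == "scored"
  if (sum(scored) >= 2) {
    scores$production_score[scored] <- normalize_scores(scores$raw_score[scored])
  }
  structure(list(
    scores = scores, summaries = summaries,
    weights = data.frame(col = irrev$cols$col, rxn = irrev$cols$rxn,
                         w_default = unname(w_def), r = r_col,
                         w_treatment = unname(ws$w_treatment),
                         w_control = unname(ws$w_control),
                         stringsAsFactors = FALSE),
    compound = compound, organism = organism,
    q_threshold = q_threshold, cap = cap, fraction = fraction,
    media_label = if (is.null(media)) NA_character_ else media$label,
    call = match.call()), class = "timbr")
}

#' @export
print.timbr <- function(x, ...) {
  sc <- x$scores
  cat("TIMBR production scores",
      if (!is.na(x$compound)) paste0(" [", x$compound,
                                     if (!is.na(x$organism))
                                       paste0(", ", x$organism), "]"),
      ": ", sum(sc$status == "scored"), " scored of ", nrow(sc),
      " exchangeable metabolites\n", sep = "")
  ord <- order(-sc$production_score, na.last = TRUE)
  top <- utils::head(sc[ord, c("metabolite", "raw_score", "production_score",
                               "status")], 8)
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.timbr <- function(object, ...) {
  sc <- object$scores
  structure(list(
    n_metabolites = nrow(sc),
    n_scored = sum(sc$status == "scored"),
    n_skipped = sum(sc$status == "skipped_unproducible"),
    n_infeasible = sum(sc$status == "infeasible"),
    top = sc[order(-sc$production_score, na.last = TRUE), ][1, ],
    bottom = sc[order(sc$production_score, na.last = TRUE), ][1, ],
    compound = object$compound, organism = object$organism),
    class = "summary.timbr")
}

#' @export
print.summary.timbr <- function(x, ...) {
  cat("TIMBR fit: ", x$n_scored, " scored, ", x$n_skipped, " unproducible, ",
      x$n_infeasible, " infeasible (of ", x$n_metabolites, ")\n", sep = "")
  cat("  highest: ", x$top$metabolite, " (", format(x$top$production_score,
                                                    digits = 3), ")\n", sep = "")
  cat("  lowest:  ", x$bottom$metabolite, " (", format(x$bottom$production_score,
                                                       digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.timbr <- function(object, ...) {
  sc <- object$scores
  stats::setNames(sc$production_score, sc$metabolite)
}

#' @export
plot.timbr <- function(x, ...) {
  sc <- x$scores[x$scores$status == "scored", ]
  sc <- sc[order(sc$production_score), ]
  graphics::barplot(sc$production_score, names.arg = sc$metabolite,
                    horiz = TRUE, las = 1,
                    xlab = "production score (z)",
                    main = if (!is.na(x$compound)) x$compound else "TIMBR", ...)
  invisible(x)
}

#' Correlate production scores between two species
#'
#' Pearson correlation of paired production scores (per compound across
#' shared metabolites, or per metabolite across compounds), with
#' Benjamini-Hochberg adjustment across the family and a three-way class:
#' `positive` / `negative` when the adjusted q-value is below `fdr`, else
#' `uncorrelated`.
#'
#' @param scores_a,scores_b either named numeric vectors (one comparison)
#'   or matrices/data.frames with metabolites in rows and compounds in
#'   columns (one comparison per column).
#' @param fdr FDR threshold for classification (default 0.1).
#' @return data.frame with `compound`, `n`, `r`, `p`, `q`, `class`.
#' @export
compare_production_scores <- function(scores_a, scores_b, fdr = 0.1) {
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1, dimnames = list(names(x), "scores"))
    else as.matrix(x)
  }
  A <- as_mat(scores_a); B <- as_mat(scores_b)
  shared_rows <- intersect(rownames(A), rownames(B))
  shared_cols <- intersect(colnames(A), colnames(B))
  if (!length(shared_rows) || !length(shared_cols)) {
    stop("no shared metabolites/compounds between the two score sets")
  }
  rows <- lapply(shared_cols, function(cc) {
    a <- A[shared_rows, cc]; b <- B[shared_rows, cc]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) {
      return(data.frame(compound = cc, n = sum(ok), r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
    data.frame(compound = cc, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$class <- ifelse(is.na(out$q) | out$q >= fdr, "uncorrelated",
                      ifelse(out$r > 0, "positive", "negative"))
  out
}

#' Call elevated / reduced / unchanged from production scores
#'
#' A metabolite is called elevated when its score is at or above the upper
#' quantile of the scored set and reduced at or below the lower quantile
#' (boundaries inclusive: "top or bottom 25%"); otherwise unchanged.
#'
#' @param scores named numeric vector of production scores.
#' @param lower_q,upper_q quantile probabilities (defaults 0.25 / 0.75).
#' @return named character vector of calls.
#' @export
classify_predictions <- function(scores, lower_q = 0.25, upper_q = 0.75) {
  stopifnot(is.numeric(scores), lower_q < upper_q)
  qs <- stats::quantile(scores, c(lower_q, upper_q), na.rm = TRUE, names = FALSE)
  out <- ifelse(scores >= qs[2], "elevated",
                ifelse(scores <= qs[1], "reduced", "unchanged"))
  stats::setNames(out, names(scores))
}

#' Evaluate calls against experimental truth
#'
#' Builds the 2x2 confusion table with positives = experimentally changed
#' metabolites (truth elevated or reduced) and predicted-positives = called
#' elevated or reduced, and reports sensitivity, specificity (as
#' percentages) and Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#'
#' @param calls named character vector in `{elevated, reduced, unchanged}`.
#' @param truth named character vector in the same alphabet; metabolites
#'   are matched by name.
#' @return list of class `"call_evaluation"`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity` (percent), `mcc` (`NA` when the
#'   denominator is 0), `direction_agreement` (fraction of true positives
#'   whose direction matches).
#' @export
evaluate_calls <- function(calls, truth) {
  shared <- intersect(names(calls), names(truth))
  if (!length(shared)) stop("calls and truth share no metabolites")
  calls <- calls[shared]; truth <- truth[shared]
  lv <- c("elevated", "reduced", "unchanged")
  stopifnot(all(calls %in% lv), all(truth %in% lv))
  pos <- truth != "unchanged"
  pred <- calls != "unchanged"
  tp <- sum(pos & pred); fp <- sum(!pos & pred)
  tn <- sum(!pos & !pred); fn <- sum(pos & !pred)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    mcc = mcc,
    direction_agreement = if (tp > 0)
      mean(calls[pos & pred] == truth[pos & pred]) else NA_real_),
    class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat(sprintf("calls vs truth: TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.0f%%, specificity %.0f%%, MCC %.2f\n",
              x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}
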