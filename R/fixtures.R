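#' Specification for a deterministic toy network
#'
#' Fixture networks emulate the structure of a compartmentalized
#' genome-scale model at toy size: per pathway, an uptake exchange, an
#' extracellular-to-cytosol transport, a chain of gene-associated
#' biochemical conversions, a secretion transport and exchange, plus a
#' biomass sink consuming every pathway product. Flux units mirror the
#' physiological fmol per cell per hour scale, with uptake bounds around
#' 10 so the `min(100, 0.9 * v_max)` production cap exercises both
#' branches across fixtures.
#'
#' @param seed integer; the same seed yields a byte-identical fixture.
#' @param n_pathways number of parallel pathways (>= 1).
#' @param pathway_length internal conversions per pathway (>= 1).
#' @param fraction_reversible probability that an internal conversion is
#'   reversible.
#' @param gpr_profile probability weights for the GPR shapes
#'   `single`, `isozyme` (`A or B`), `complex` (`A and B`), `nested`
#'   (`(A or B) and C`).
#' @param uptake_bound uptake capacity per pathway (flux units).
#' @return object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_pathways = 2L, pathway_length = 3L,
                         fraction_reversible = 0.3,
                         gpr_profile = c(single = 0.4, isozyme = 0.3,
                                         complex = 0.2, nested = 0.1),
                         uptake_bound = 10) {
  if (n_pathways < 1) stop("degenerate fixture: need at least one pathway")
  stopifnot(pathway_length >= 1, fraction_reversible >= 0,
            fraction_reversible <= 1, uptake_bound > 0,
            all(c("single", "isozyme", "complex", "nested") %in%
                  names(gpr_profile)))
  structure(list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
                 pathway_length = as.integer(pathway_length),
                 fraction_reversible = fraction_reversible,
                 gpr_profile = gpr_profile / sum(gpr_profile),
                 uptake_bound = uptake_bound), class = "fixture_spec")
}

# run code with a private, restorable RNG stream
with_fixture_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a deterministic toy metabolic network
#'
#' @param spec `"fixture_spec"`.
#' @return `"metabolic_network"` with compartments `e` (extracellular) and
#'   `c` (cytosol), one uptake exchange / internal chain / secretion
#'   exchange per pathway, and a `biomass` objective consuming every
#'   pathway product. Internal reactions carry GPRs drawn from the
#'   spec's profile with genes unique to each reaction.
#' @examples
#' net <- toy_network(fixture_spec(seed = 1))
#' net
#' @export
toy_network <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_rng(spec$seed, {
    rows <- list()
    add <- function(id, equation, gpr = "", lb = 0, ub = 1000, subsystem = "") {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, equation = equation, gpr = gpr, lb = lb, ub = ub,
        subsystem = subsystem, stringsAsFactors = FALSE)
    }
    make_gpr <- function(rxn_id) {
      shape <- sample(names(spec$gpr_profile), 1, prob = spec$gpr_profile)
      g <- function(k) paste0("g_", rxn_id, "_", k)
      switch(shape,
             single = g(1),
             isozyme = paste0(g(1), " or ", g(2)),
             complex = paste0(g(1), " and ", g(2)),
             nested = paste0("(", g(1), " or ", g(2), ") and ", g(3)))
    }
    products <- character(spec$n_pathways)
    for (p in seq_len(spec$n_pathways)) {
      a <- sprintf("a%d", p)
      add(sprintf("EX_%s", a), sprintf("%s[e] <=>", a),
          lb = -spec$uptake_bound, ub = 1000, subsystem = "exchange")
      tid <- sprintf("T_%s", a)
      add(tid, sprintf("%s[e] => %s[c]", a, a), gpr = make_gpr(tid),
          subsystem = "transport")
      prev <- sprintf("%s[c]", a)
      for (k in seq_len(spec$pathway_length)) {
        mid <- if (k < spec$pathway_length) sprintf("m%d_%d[c]", p, k)
        else sprintf("p%d[c]", p)
        rid <- sprintf("R%d_%d", p, k)
        rev <- stats::runif(1) < spec$fraction_reversible
        add(rid, sprintf("%s %s %s", prev, if (rev) "<=>" else "=>", mid),
            gpr = make_gpr(rid), lb = if (rev) -1000 else 0,
            subsystem = sprintf("pathway_%d", p))
        prev <- mid
      }
      prod <- sprintf("p%d", p)
      tout <- sprintf("T_%s", prod)
      add(tout, sprintf("%s[c] => %s[e]", prod, prod), gpr = make_gpr(tout),
          subsystem = "transport")
      add(sprintf("EX_%s", prod), sprintf("%s[e] <=>", prod),
          lb = 0, ub = 1000, subsystem = "exchange")
      products[p] <- prod
    }
    add("biomass", paste0(
      paste(sprintf("0.5 %s[c]", products), collapse = " + "), " => bm[c]"),
      subsystem = "biomass")
    add("EX_bm", "bm[c] <=>", lb = 0, ub = 1000, subsystem = "exchange")
    metabolic_network(
      do.call(rbind, rows),
      compartments = c(e = "extracellular", c = "cytosol"),
      objective = "biomass",
      id = sprintf("toy_seed%d", spec$seed))
  })
}

#' Generate a species-delta pair of networks
#'
#' Two networks sharing every metabolite, reaction and exchange except for
#' `delta` reactions present only in network A — the pattern of a
#' species-specific enzyme (e.g. a degradation step present in one species
#' only). Transport and exchange for any delta product named in
#' `delta_product` are added to both networks so the pair shares an
#' exchange namespace and differs only in the producing reaction.
#'
#' @param spec `"fixture_spec"`.
#' @param delta data.frame of reaction rows (`id`, `equation`, and
#'   optionally `gpr`, `lb`, `ub`, `subsystem`) present only in network A.
#'   The default converts the first pathway product into a new
#'   extracellular-exported metabolite `d1` via a gene-associated step.
#' @return list with `a`, `b` (`"metabolic_network"`) and `delta_ids`.
#' @export
paired_networks <- function(spec = fixture_spec(), delta = NULL) {
  base <- toy_network(spec)
  tab <- reaction_table(base)
  tab$kind <- NULL
  if (is.null(delta)) {
    delta <- data.frame(id = "R_delta", equation = "p1[c] => d1[c]",
                        gpr = "g_delta_1", lb = 0, ub = 1000,
                        subsystem = "species_delta", stringsAsFactors = FALSE)
    shared_extra <- data.frame(
      id = c("T_d1", "EX_d1"), equation = c("d1[c] => d1[e]", "d1[e] <=>"),
      gpr = c("", ""), lb = c(0, 0), ub = c(1000, 1000),
      subsystem = c("transport", "exchange"), stringsAsFactors = FALSE)
    tab <- rbind(tab, shared_extra)
  }
  if (nrow(delta) == 0L) stop("empty species delta")
  for (col in c("gpr", "subsystem")) if (!col %in% names(delta)) delta[[col]] <- ""
  if (!"lb" %in% names(delta)) delta$lb <- 0
  if (!"ub" %in% names(delta)) delta$ub <- 1000
  clash <- intersect(delta$id, tab$id)
  if (length(clash)) stop("delta reaction id(s) collide with shared ids: ",
                          paste(clash, collapse = ", "))
  mk <- function(t, suffix) metabolic_network(
    t, compartments = base$compartments, objective = base$objective,
    id = paste0(base$id, suffix))
  list(a = mk(rbind(tab, delta[names(tab)]), "_A"),
       b = mk(tab, "_B"),
       delta_ids = delta$id)
}

#' Plant a directional expression signal on one pathway
#'
#' Builds a differential-expression table in which every gene on one
#' minimal producing pathway of the target metabolite carries a
#' significant log2 fold change of `+/- effect` (q = 0.01) and every other
#' network gene carries an insignificant background draw
#' `Normal(0, background_sd)` with q = 0.5. Used for parameter-recovery
#' checks: an upregulated pathway must rank its product's production score
#' first, a downregulated one last.
#'
#' @param network `"metabolic_network"` (a fixture).
#' @param target_mid metabolite key of the target (e.g. `"p1[e]"`).
#' @param direction `"up"` or `"down"`.
#' @param effect planted |log2 fold change| (default 2).
#' @param background_sd sd of the insignificant background (default 0.25).
#' @param seed RNG seed for the background draws.
#' @return data.frame with `gene`, `log2fc`, `qvalue`; attribute
#'   `pathway_reactions` lists the planted reactions.
#' @export
planted_expression <- function(network, target_mid, direction = c("up", "down"),
                               effect = 2, background_sd = 0.25, seed = 1L) {
  stopifnot(inherits(network, "metabolic_network"))
  direction <- match.arg(direction)
  path_rxns <- producing_pathway(network, target_mid)
  if (is.null(path_rxns)) stop("target unreachable from any uptake: ", target_mid)
  path_genes <- sort(unique(unlist(lapply(network$gpr[path_rxns], gpr_genes))))
  if (!length(path_genes)) {
    stop("no gene-associated reactions on the pathway to ", target_mid)
  }
  other <- setdiff(network$genes, path_genes)
  with_fixture_rng(seed, {
    out <- rbind(
      data.frame(gene = path_genes,
                 log2fc = if (direction == "up") effect else -effect,
                 qvalue = 0.01, stringsAsFactors = FALSE),
      if (length(other)) data.frame(
        gene = other, log2fc = stats::rnorm(length(other), 0, background_sd),
        qvalue = 0.5, stringsAsFactors = FALSE))
    rownames(out) <- NULL
    attr(out, "pathway_reactions") <- path_rxns
    out
  })
}

# breadth-first search for a minimal chain of reactions producing the
# target metabolite from any uptaken (exchange lb < 0) metabolite
producing_pathway <- function(network, target_mid) {
  if (!target_mid %in% network$mets$mid) stop("unknown metabolite: ", target_mid)
  ex <- exchange_reactions(network)
  seeds <- ex$mid[network$rxns$lb[match(ex$rxn, network$rxns$id)] < 0]
  if (!length(seeds)) return(NULL)
  S <- network$S
  rid <- network$rxns$id
  # edges met -> met through a reaction consuming one and producing the other
  prev_rxn <- stats::setNames(rep(NA_character_, nrow(S)), rownames(S))
  prev_met <- prev_rxn
  visited <- rownames(S) %in% seeds
  queue <- seeds
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    i <- match(cur, rownames(S))
    consuming <- which(S[i, ] < 0)
    rev_prod <- which(S[i, ] > 0 & network$rxns$lb < 0)
    for (j in unique(c(consuming, rev_prod))) {
      sign <- if (S[i, j] < 0) 1 else -1  # direction that consumes cur
      prods <- which(sign * S[, j] > 0)
      for (k in prods) {
        mid <- rownames(S)[k]
        if (!visited[k]) {
          visited[k] <- TRUE
          prev_rxn[mid] <- rid[j]
          prev_met[mid] <- cur
          queue <- c(queue, mid)
        }
      }
    }
    if (visited[match(target_mid, rownames(S))]) break
  }
  if (!visited[match(target_mid, rownames(S))]) return(NULL)
  path <- character(0)
  cur <- target_mid
  while (!is.na(prev_rxn[cur])) {
    path <- c(prev_rxn[[cur]], path)
    cur <- prev_met[[cur]]
  }
  unique(path)
}
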