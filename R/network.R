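#' Build a compartmentalized metabolic network
#'
#' Constructs a `"metabolic_network"` from a reaction table in the common
#' spreadsheet dialect: one row per reaction with an equation string,
#' a GPR string, flux bounds and a subsystem. Metabolites are written as
#' `id[compartment]` tokens with optional leading stoichiometric
#' coefficients; `"=>"` marks an irreversible reaction and `"<=>"` a
#' reversible one. An empty product (or substrate) side gives a boundary
#' (exchange) reaction, e.g. `"glc[e] <=>"`.
#'
#' The stoichiometric matrix `S` has one row per metabolite and one column
#' per reaction; negative coefficients are consumed, positive produced.
#' For an exchange reaction written with its metabolite on the left,
#' positive flux is secretion and negative flux is uptake (the usual
#' convention for `EX_` reactions).
#'
#' @param reactions data.frame with columns `id`, `equation`, and optionally
#'   `gpr` (default none), `lb`/`ub` (defaults `-1000/1000` for reversible,
#'   `0/1000` for irreversible), `subsystem`, `name`.
#' @param compartments named character vector mapping compartment ids to
#'   names; defaults to the compartments mentioned in the equations.
#' @param metabolite_names optional named character vector, metabolite key
#'   (`id[comp]`) to display name.
#' @param objective reaction id to use as the default objective (e.g. a
#'   biomass reaction), or `NA`.
#' @param id model identifier.
#' @return object of class `"metabolic_network"`: a list with elements
#'   `id`, `compartments`, `mets` (data.frame: `mid`, `id`, `name`,
#'   `compartment`), `rxns` (data.frame: `id`, `name`, `lb`, `ub`,
#'   `subsystem`, `kind`), `gpr` (named list of parsed rules), `S`
#'   (sparse `dgCMatrix`), `genes`, `objective`.
#' @examples
#' net <- metabolic_network(data.frame(
#'   id = c("EX_a", "T_a", "R1", "EX_b"),
#'   equation = c("a[e] <=>", "a[e] => a[c]", "a[c] => b[e]", "b[e] <=>"),
#'   gpr = c("", "", "G1 or G2", ""),
#'   lb = c(-10, 0, 0, 0), ub = c(1000, 1000, 1000, 1000)))
#' net
#' @export
metabolic_network <- function(reactions, compartments = NULL,
                              metabolite_names = NULL, objective = NA_character_,
                              id = "model") {
  stopifnot(is.data.frame(reactions), all(c("id", "equation") %in% names(reactions)))
  rid <- as.character(reactions$id)
  if (anyDuplicated(rid)) {
    stop("duplicate reaction ids: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  n <- length(rid)
  eqs <- lapply(as.character(reactions$equation), parse_equation)
  rev_eq <- vapply(eqs, `[[`, NA, "reversible")
  lb <- if ("lb" %in% names(reactions)) as.numeric(reactions$lb) else ifelse(rev_eq, -1000, 0)
  ub <- if ("ub" %in% names(reactions)) as.numeric(reactions$ub) else rep(1000, n)
  if (any(is.na(lb)) || any(is.na(ub))) stop("missing flux bounds")
  if (any(lb > ub)) {
    stop("lb > ub for reaction(s): ", paste(rid[lb > ub], collapse = ", "))
  }
  gpr_txt <- if ("gpr" %in% names(reactions)) as.character(reactions$gpr) else rep("", n)
  gpr_txt[is.na(gpr_txt)] <- ""
  gprs <- lapply(gpr_txt, parse_gpr)
  names(gprs) <- rid

  # metabolite universe and sparse S
  all_mids <- sort(unique(unlist(lapply(eqs, function(e) names(e$stoich)))))
  if (length(all_mids) == 0L) stop("network has no metabolites")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) {
    st <- eqs[[j]]$stoich
    if (length(st) == 0L) stop("reaction with zero metabolites: ", rid[j])
    ii <- c(ii, match(names(st), all_mids))
    jj <- c(jj, rep(j, length(st)))
    xx <- c(xx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(all_mids), n),
                            dimnames = list(all_mids, rid))

  comp_of <- sub("^.*\\[(.*)\\]$", "\\1", all_mids)
  base_id <- sub("\\[.*\\]$", "", all_mids)
  if (is.null(compartments)) {
    u <- sort(unique(comp_of))
    compartments <- stats::setNames(u, u)
  }
  undecl <- setdiff(comp_of, names(compartments))
  if (length(undecl)) {
    stop("metabolites reference undeclared compartment(s): ",
         paste(unique(undecl), collapse = ", "))
  }
  mname <- base_id
  if (!is.null(metabolite_names)) {
    hit <- all_mids %in% names(metabolite_names)
    mname[hit] <- metabolite_names[all_mids[hit]]
  }
  mets <- data.frame(mid = all_mids, id = base_id, name = mname,
                     compartment = comp_of, stringsAsFactors = FALSE)

  rxns <- data.frame(
    id = rid,
    name = if ("name" %in% names(reactions)) as.character(reactions$name) else rid,
    lb = lb, ub = ub,
    subsystem = if ("subsystem" %in% names(reactions))
      as.character(reactions$subsystem) else rep("", n),
    kind = NA_character_, stringsAsFactors = FALSE)

  net <- structure(list(
    id = id, compartments = compartments, mets = mets, rxns = rxns,
    gpr = gprs, S = S,
    genes = sort(unique(unlist(lapply(gprs, gpr_genes)))),
    objective = objective), class = "metabolic_network")
  net$rxns$kind <- classify_reaction_kind(net)
  if (!is.na(objective) && !objective %in% rid) {
    stop("objective reaction not in network: ", objective)
  }
  net
}

# "2 a[c] + b[c] => c[c]" -> list(stoich = named numeric, reversible = logical)
parse_equation <- function(eq) {
  stopifnot(length(eq) == 1L, !is.na(eq))
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>"
  else if (grepl("=>", eq, fixed = TRUE)) "=>"
  else stop("malformed equation (no '=>' or '<=>'): ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("malformed equation: ", eq)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (!nzchar(tm)) stop("malformed equation term in: ", txt)
      m <- regmatches(tm, regexec(
        "^([0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?[[:space:]]+)?([^][[:space:]]+\\[[^]]+\\])$", tm))[[1]]
      if (length(m) == 0L) stop("malformed metabolite token '", tm,
                                "' (expected '[coef] id[compartment]')")
      coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      mid <- m[4]
      out[mid] <- (if (is.na(out[mid])) 0 else out[mid]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (mid in names(rhs)) st[mid] <- (if (is.na(st[mid])) 0 else st[mid]) + rhs[mid]
  # same metabolite on both sides is kept as written (net coefficient);
  # drop only exact zero cancellations
  st <- st[st != 0]
  if (length(st) == 0L) stop("equation cancels to nothing: ", eq)
  list(stoich = st, reversible = arrow == "<=>")
}

# reaction -> equation string (canonical: substrates sorted, coefs trimmed)
format_equation <- function(net, rxn_id) {
  col <- net$S[, rxn_id]
  nz <- which(col != 0)
  fmt <- function(idx) {
    if (!length(idx)) return("")
    cf <- abs(col[idx])
    tok <- rownames(net$S)[idx]
    paste(ifelse(cf == 1, tok, paste(format(cf, trim = TRUE, digits = 12), tok)),
          collapse = " + ")
  }
  arrow <- if (net$rxns$lb[match(rxn_id, net$rxns$id)] < 0) "<=>" else "=>"
  paste(fmt(nz[col[nz] < 0]), arrow, fmt(nz[col[nz] > 0]))
}

#' Classify reactions as exchange, transport, or biochemical
#'
#' An exchange reaction is a single-metabolite boundary reaction; a
#' transport reaction spans at least two compartments; everything else is
#' biochemical. A reaction that both transports and transforms is
#' classified transport (compartment span takes priority), so that each
#' reaction has the single kind needed for default TIMBR weights.
#'
#' @param network `"metabolic_network"`.
#' @return character vector of kinds, one per reaction, in network order.
#' @export
classify_reaction_kind <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  comp <- network$mets$compartment
  vapply(seq_len(ncol(network$S)), function(j) {
    nz <- which(network$S[, j] != 0)
    if (length(nz) == 0L) stop("reaction with zero metabolites: ",
                               colnames(network$S)[j])
    if (length(nz) == 1L) return("exchange")
    if (length(unique(comp[nz])) >= 2L) return("transport")
    "biochemical"
  }, "")
}

#' Reactions of a network as a table
#'
#' @param network `"metabolic_network"`.
#' @return data.frame with `id`, `equation`, `gpr`, `lb`, `ub`,
#'   `subsystem`, `kind` (the spreadsheet dialect plus the derived kind).
#' @export
reaction_table <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  data.frame(
    id = network$rxns$id,
    equation = vapply(network$rxns$id, function(r) format_equation(network, r), ""),
    gpr = vapply(network$gpr, deparse_gpr, ""),
    lb = network$rxns$lb, ub = network$rxns$ub,
    subsystem = network$rxns$subsystem, kind = network$rxns$kind,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Split reversible reactions into forward/reverse columns
#'
#' Converts a network into its irreversible form: every reaction with a
#' negative lower bound contributes a forward and a reverse column with
#' non-negative bounds; the reverse column is the negated stoichiometry.
#' A source reaction with bounds `[-a, b]` yields forward bounds
#' `[max(0, -a's counterpart)...]`, concretely forward `[max(0,lb), max(0,ub)]`
#' and reverse `[max(0,-ub), max(0,-lb)]`, which also preserves forced
#' negative flux. Net flux `v = v_fwd - v_rev` reproduces any feasible flux
#' of the source network and vice versa.
#'
#' @param network `"metabolic_network"`.
#' @return object of class `"irreversible_network"`: list with `S`, `lb`,
#'   `ub` (per column), `cols` (data.frame: `col`, `rxn`, `dir` in
#'   `{1,-1}`), `mets`, `network` (the source).
#' @export
make_irreversible <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  rid <- network$rxns$id
  rev <- network$rxns$lb < 0
  cols <- list(); lb <- numeric(0); ub <- numeric(0)
  Scols <- list()
  for (j in seq_along(rid)) {
    sj <- network$S[, j, drop = FALSE]
    if (!rev[j]) {
      cols[[length(cols) + 1L]] <- data.frame(col = rid[j], rxn = rid[j], dir = 1)
      lb <- c(lb, network$rxns$lb[j]); ub <- c(ub, network$rxns$ub[j])
      Scols[[length(Scols) + 1L]] <- sj
    } else {
      l <- network$rxns$lb[j]; u <- network$rxns$ub[j]
      cols[[length(cols) + 1L]] <- data.frame(col = paste0(rid[j], "_f"),
                                              rxn = rid[j], dir = 1)
      lb <- c(lb, max(0, l)); ub <- c(ub, max(0, u))
      Scols[[length(Scols) + 1L]] <- sj
      cols[[length(cols) + 1L]] <- data.frame(col = paste0(rid[j], "_b"),
                                              rxn = rid[j], dir = -1)
      lb <- c(lb, max(0, -u)); ub <- c(ub, max(0, -l))
      Scols[[length(Scols) + 1L]] <- -sj
    }
  }
  cols <- do.call(rbind, cols)
  S <- do.call(cbind, Scols)
  colnames(S) <- cols$col
  structure(list(S = S, lb = lb, ub = ub, cols = cols,
                 mets = rownames(S), network = network),
            class = "irreversible_network")
}

#' Map an irreversible flux assignment back to net source fluxes
#'
#' @param irrev `"irreversible_network"`.
#' @param flux numeric vector, one value per irreversible column.
#' @return named numeric vector of net fluxes over source reaction ids.
#' @export
net_flux <- function(irrev, flux) {
  stopifnot(inherits(irrev, "irreversible_network"),
            length(flux) == nrow(irrev$cols))
  signed <- flux * irrev$cols$dir
  tapply(signed, irrev$cols$rxn, sum)[irrev$network$rxns$id]
}

#' Model statistics in the style of a reconstruction comparison table
#'
#' Counts genes and reactions, and splits gene-associated (enzymatic)
#' reactions into isozymic (GPR contains an `OR`), enzyme-complex (GPR
#' contains an `AND`) and the rest; reports the mean number of distinct
#' genes per enzymatic reaction. Given a second network, also reports the
#' fraction of gene-associated reactions (shared by id, enzymatic in at
#' least one) that carry gene annotations in both networks.
#'
#' @param network `"metabolic_network"`.
#' @param paired optional second `"metabolic_network"` for the cross-species
#'   fraction.
#' @return list of class `"network_stats"`.
#' @export
network_stats <- function(network, paired = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  gprs <- network$gpr
  enz <- !vapply(gprs, is.null, NA)
  sizes <- vapply(gprs[enz], gpr_size, 0L)
  out <- list(
    id = network$id,
    genes = length(network$genes),
    reactions = nrow(network$rxns),
    metabolites = nrow(network$mets),
    enzymatic = sum(enz),
    non_enzymatic = sum(!enz),
    isozymic = sum(vapply(gprs, gpr_has_op, NA, op = "or")),
    enzyme_complex = sum(vapply(gprs, gpr_has_op, NA, op = "and")),
    mean_gpr_size = if (any(enz)) mean(sizes) else NA_real_)
  if (!is.null(paired)) {
    stopifnot(inherits(paired, "metabolic_network"))
    shared <- intersect(network$rxns$id, paired$rxns$id)
    e1 <- !vapply(network$gpr[shared], is.null, NA)
    e2 <- !vapply(paired$gpr[shared], is.null, NA)
    any_enz <- e1 | e2
    out$shared_reactions <- length(shared)
    out$both_species_fraction <-
      if (any(any_enz)) sum(e1 & e2) / sum(any_enz) else NA_real_
  }
  class(out) <- "network_stats"
  out
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Model statistics: ", x$id, "\n", sep = "")
  cat(sprintf("  genes            %6d\n", x$genes))
  cat(sprintf("  metabolites      %6d\n", x$metabolites))
  cat(sprintf("  reactions        %6d\n", x$reactions))
  cat(sprintf("    enzymatic      %6d\n", x$enzymatic))
  cat(sprintf("    isozymic       %6d\n", x$isozymic))
  cat(sprintf("    enzyme complex %6d\n", x$enzyme_complex))
  cat(sprintf("    non-enzymatic  %6d\n", x$non_enzymatic))
  cat(sprintf("  mean GPR size    %8.2f\n", x$mean_gpr_size))
  if (!is.null(x$both_species_fraction)) {
    cat(sprintf("  gene-associated reactions annotated in both networks: %.1f%%\n",
                100 * x$both_species_fraction))
  }
  invisible(x)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$id, ": ",
      nrow(x$rxns), " reactions, ", nrow(x$mets), " metabolites, ",
      length(x$genes), " genes, ",
      length(x$compartments), " compartments\n", sep = "")
  if (!is.na(x$objective)) cat("  objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_network <- function(object, ...) network_stats(object)

#' Exchange reactions of a network
#'
#' @param network `"metabolic_network"`.
#' @return data.frame with `rxn` (exchange reaction id), `mid` (the single
#'   boundary metabolite key) and `coef` (its stoichiometric coefficient).
#' @export
exchange_reactions <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  idx <- which(network$rxns$kind == "exchange")
  if (!length(idx)) {
    return(data.frame(rxn = character(0), mid = character(0), coef = numeric(0)))
  }
  mids <- vapply(idx, function(j) rownames(network$S)[which(network$S[, j] != 0)], "")
  coefs <- vapply(idx, function(j) network$S[which(network$S[, j] != 0), j], 0)
  data.frame(rxn = network$rxns$id[idx], mid = mids, coef = coefs,
             stringsAsFactors = FALSE, row.names = NULL)
}

# internal: replace bounds for named reactions, returning the network
set_bounds <- function(network, rxn_ids, lb = NULL, ub = NULL) {
  j <- match(rxn_ids, network$rxns$id)
  if (anyNA(j)) stop("unknown reaction(s): ", paste(rxn_ids[is.na(j)], collapse = ", "))
  if (!is.null(lb)) network$rxns$lb[j] <- lb
  if (!is.null(ub)) network$rxns$ub[j] <- ub
  if (any(network$rxns$lb[j] > network$rxns$ub[j])) stop("lb > ub after update")
  network
}
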