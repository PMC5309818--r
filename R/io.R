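#' Read / write a model in the tabular spreadsheet dialect
#'
#' The tabular dialect is a UTF-8 tab-delimited file with a header row and
#' one reaction per line: columns `id`, `equation`, `gpr`, `lb`, `ub`,
#' `subsystem` (and optionally `objective`, a logical marking the objective
#' reaction). Metabolites are `id[compartment]` tokens; `"=>"` is
#' irreversible and `"<=>"` reversible.
#'
#' @param path file path.
#' @return `read_table_model()` returns a `"metabolic_network"`.
#' @seealso [read_sbml()] for SBML Level 3 + FBC I/O.
#' @export
read_table_model <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "", comment.char = "#")
  need <- c("id", "equation")
  if (!all(need %in% names(df))) {
    stop("table model must have columns 'id' and 'equation'; found: ",
         paste(names(df), collapse = ", "))
  }
  obj <- NA_character_
  if ("objective" %in% names(df)) {
    flag <- as.logical(df$objective)
    if (sum(flag, na.rm = TRUE) == 1L) obj <- df$id[which(flag)]
  }
  metabolic_network(df, objective = obj,
                    id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_table_model
#' @param network `"metabolic_network"` to write.
#' @export
write_table_model <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  tab <- reaction_table(network)
  tab$kind <- NULL
  tab$objective <- !is.na(network$objective) & tab$id == network$objective
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# ---- SBML Level 3 Version 1 with the FBC version 2 package -----------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds must match [A-Za-z_][A-Za-z0-9_]*; model/metabolite/gene ids are
# restricted to that alphabet (checked on write) and namespaced with the
# usual M_/R_/G_ prefixes.
sbml_check_id <- function(ids, what) {
  bad <- ids[!grepl("^[A-Za-z0-9_]+$", ids)]
  if (length(bad)) {
    stop("cannot serialize ", what, " id(s) to SBML (use [A-Za-z0-9_]): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ids
}

#' Write a network as SBML Level 3 (FBC version 2)
#'
#' Emits compartments, species, per-reaction flux bound parameters,
#' gene products, nested FBC gene-product associations for GPR rules, and
#' the active objective when one is set. Subsystems are stored in the
#' reaction `notes` block (`SUBSYSTEM: ...`), the convention used by COBRA
#' readers.
#'
#' @param network `"metabolic_network"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  mids <- network$mets$mid
  m_sid <- paste0("M_", sbml_check_id(network$mets$id, "metabolite"), "_",
                  sbml_check_id(network$mets$compartment, "compartment"))
  r_sid <- paste0("R_", sbml_check_id(network$rxns$id, "reaction"))
  g_sid <- paste0("G_", sbml_check_id(network$genes, "gene"))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) {
    x <- ifelse(is.infinite(x), sign(x) * 1e6, x)
    format(x, trim = TRUE, digits = 15, scientific = FALSE)
  }
  out <- character(0)
  w <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(gsub("[^A-Za-z0-9_]", "_", network$id)),
    '" name="', esc(network$id), '" fbc:strict="true">')

  w('    <listOfCompartments>')
  for (k in seq_along(network$compartments)) {
    w('      <compartment id="', sbml_check_id(names(network$compartments)[k],
                                               "compartment"),
      '" name="', esc(network$compartments[[k]]), '" constant="true"/>')
  }
  w('    </listOfCompartments>')

  w('    <listOfSpecies>')
  for (k in seq_along(mids)) {
    w('      <species id="', m_sid[k], '" name="', esc(network$mets$name[k]),
      '" compartment="', sbml_check_id(network$mets$compartment[k], "compartment"),
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>')
  }
  w('    </listOfSpecies>')

  # one parameter per distinct bound value
  vals <- sort(unique(c(ifelse(is.infinite(network$rxns$lb), -1e6, network$rxns$lb),
                        ifelse(is.infinite(network$rxns$ub), 1e6, network$rxns$ub))))
  pid <- stats::setNames(paste0("par_", seq_along(vals)), num(vals))
  w('    <listOfParameters>')
  for (k in seq_along(vals)) {
    w('      <parameter id="par_', k, '" value="', num(vals[k]),
      '" constant="true"/>')
  }
  w('    </listOfParameters>')

  gpr_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (node$op == "gene") {
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_', node$id, '"/>'))
    }
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(node$args, gpr_xml, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }

  w('    <listOfReactions>')
  for (j in seq_len(nrow(network$rxns))) {
    lbv <- network$rxns$lb[j]; ubv <- network$rxns$ub[j]
    w('      <reaction id="', r_sid[j], '" name="', esc(network$rxns$name[j]),
      '" reversible="', if (lbv < 0) "true" else "false",
      '" fast="false" fbc:lowerFluxBound="', pid[[num(lbv)]],
      '" fbc:upperFluxBound="', pid[[num(ubv)]], '">')
    if (nzchar(network$rxns$subsystem[j])) {
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>SUBSYSTEM: ',
        esc(network$rxns$subsystem[j]), '</p></body></notes>')
    }
    rule <- network$gpr[[j]]
    if (!is.null(rule)) {
      w('        <fbc:geneProductAssociation>')
      for (line in gpr_xml(unclass(rule), 10)) w(line)
      w('        </fbc:geneProductAssociation>')
    }
    col <- network$S[, j]
    nzi <- which(col != 0)
    subs <- nzi[col[nzi] < 0]; prods <- nzi[col[nzi] > 0]
    if (length(subs)) {
      w('        <listOfReactants>')
      for (k in subs) w('          <speciesReference species="', m_sid[k],
                        '" stoichiometry="', num(abs(col[k])), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prods)) {
      w('        <listOfProducts>')
      for (k in prods) w('          <speciesReference species="', m_sid[k],
                         '" stoichiometry="', num(col[k]), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')

  if (length(network$genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (k in seq_along(network$genes)) {
      w('      <fbc:geneProduct fbc:id="', g_sid[k], '" fbc:label="',
        esc(network$genes[k]), '"/>')
    }
    w('    </fbc:listOfGeneProducts>')
  }
  if (!is.na(network$objective)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    w('          <fbc:fluxObjective fbc:reaction="R_',
      network$objective, '" fbc:coefficient="1"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read an SBML Level 3 (FBC) model
#'
#' Parses compartments, species, reactions with FBC flux bounds and
#' gene-product associations, the `SUBSYSTEM` notes convention, and the
#' active FBC objective. Gene products are reported by their `fbc:label`.
#'
#' @param path SBML file path.
#' @return `"metabolic_network"`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)

  attr1 <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    if (is.na(v)) NULL else v
  }
  comps <- xml2::xml_find_all(model, ".//s:listOfCompartments/s:compartment", ns)
  comp_ids <- xml2::xml_attr(comps, "id")
  comp_names <- xml2::xml_attr(comps, "name")
  comp_names[is.na(comp_names)] <- comp_ids[is.na(comp_names)]
  compartments <- stats::setNames(comp_names, comp_ids)

  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  sp_sid <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  sp_name <- xml2::xml_attr(sp, "name")
  # strip M_ prefix and _<compartment> suffix where present
  sp_id <- sp_sid
  sp_id <- ifelse(startsWith(sp_id, "M_"), substring(sp_id, 3), sp_id)
  suff <- paste0("_", sp_comp)
  has_suff <- substring(sp_id, nchar(sp_id) - nchar(suff) + 1) == suff
  sp_id <- ifelse(has_suff, substring(sp_id, 1, nchar(sp_id) - nchar(suff)), sp_id)
  sp_mid <- stats::setNames(paste0(sp_id, "[", sp_comp, "]"), sp_sid)
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]

  pars <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(model, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabel <- stats::setNames(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id"))
  na_lab <- is.na(glabel)
  glabel[na_lab] <- sub("^G_", "", names(glabel)[na_lab])

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- if (ref %in% names(glabel)) glabel[[ref]] else sub("^G_", "", ref)
      return(list(op = "gene", id = lab))
    }
    kids <- xml2::xml_children(node)
    list(op = nm, args = lapply(kids, parse_assoc))
  }

  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  rows <- vector("list", length(rx))
  gprs <- vector("list", length(rx))
  stoich <- vector("list", length(rx))
  for (j in seq_along(rx)) {
    node <- rx[[j]]
    sid <- xml2::xml_attr(node, "id")
    id <- sub("^R_", "", sid)
    lbp <- attr1(node, "lowerFluxBound"); ubp <- attr1(node, "upperFluxBound")
    lb <- if (!is.null(lbp) && lbp %in% names(parval)) parval[[lbp]] else
      if (identical(xml2::xml_attr(node, "reversible"), "true")) -1000 else 0
    ub <- if (!is.null(ubp) && ubp %in% names(parval)) parval[[ubp]] else 1000
    refs <- function(xp, sign) {
      srefs <- xml2::xml_find_all(node, xp, ns)
      if (!length(srefs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(srefs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, sp_mid[xml2::xml_attr(srefs, "species")])
    }
    lhs <- refs("./s:listOfReactants/s:speciesReference", -1)
    rhs <- refs("./s:listOfProducts/s:speciesReference", +1)
    st <- c(lhs, rhs)
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    stoich[[j]] <- st
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gprs[j] <- list(if (inherits(assoc, "xml_missing")) NULL else
      gpr_canonicalize(parse_assoc(xml2::xml_child(assoc))))
    note <- xml2::xml_find_first(node, ".//s:notes//*[contains(text(),'SUBSYSTEM:')]", ns)
    subsystem <- if (inherits(note, "xml_missing")) "" else
      trimws(sub("^.*SUBSYSTEM:", "", xml2::xml_text(note)))
    nm <- xml2::xml_attr(node, "name")
    rows[[j]] <- data.frame(id = id, name = if (is.na(nm)) id else nm,
                            lb = lb, ub = ub, subsystem = subsystem,
                            stringsAsFactors = FALSE)
  }
  rxdf <- do.call(rbind, rows)

  obj <- NA_character_
  fo <- xml2::xml_find_first(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (!inherits(fo, "xml_missing")) {
    obj <- sub("^R_", "", xml2::xml_attr(fo, "reaction"))
  }

  # assemble via equation strings so everything funnels through one constructor
  eqs <- vapply(seq_along(stoich), function(j) {
    st <- stoich[[j]]
    lhs <- st[st < 0]; rhs <- st[st > 0]
    side <- function(s) paste(
      ifelse(abs(s) == 1, names(s),
             paste(format(abs(s), trim = TRUE, digits = 12), names(s))),
      collapse = " + ")
    paste(side(lhs), if (rxdf$lb[j] < 0) "<=>" else "=>", side(rhs))
  }, "")
  rxdf$equation <- eqs
  rxdf$gpr <- vapply(gprs, deparse_gpr, "")
  mn <- stats::setNames(sp_name, sp_mid)
  net <- metabolic_network(rxdf, compartments = compartments,
                           metabolite_names = mn, objective = obj,
                           id = {
                             nmm <- xml2::xml_attr(model, "name")
                             if (is.na(nmm)) xml2::xml_attr(model, "id") else nmm
                           })
  net
}
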