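#' Consensus orthology tables
#'
#' Orthology annotations between a source species (e.g. human) and a target
#' species (e.g. rat) are aggregated across five genomics databases (RGD,
#' Homologene, Ensembl, KEGG, UniProt). Each (human, rat) pair carries one
#' presence flag per database; its database score is the number of
#' databases annotating the pair (1-5). Optional per-gene ordinal
#' confidence scores (derived upstream from protein-level evidence and
#' annotation scores) are consumed as supplied, not recomputed.
#'
#' @name orthology
NULL

ORTHOLOGY_SOURCES <- c("RGD", "Homologene", "Ensembl", "KEGG", "UniProt")

#' Aggregate per-database orthologue pair lists
#'
#' @param tables either a named list of data.frames (one per source, each
#'   with columns `human_gene`, `rat_gene`) or a single long data.frame
#'   with columns `human_gene`, `rat_gene`, `source`.
#' @param conf optional data.frame of per-gene confidence scores with
#'   columns `gene`, `conf`; matched against both human and rat gene ids.
#' @return object of class `"orthology_table"`: data.frame with
#'   `human_gene`, `rat_gene`, one logical column per source, `db_score`,
#'   `human_conf`, `rat_conf` (`NA` when unsupplied), `rank` (`NA` until
#'   [rank_orthologs()]).
#' @export
aggregate_pairs <- function(tables, conf = NULL) {
  if (is.data.frame(tables)) {
    stopifnot(all(c("human_gene", "rat_gene", "source") %in% names(tables)))
    long <- tables
  } else {
    stopifnot(is.list(tables), !is.null(names(tables)))
    long <- do.call(rbind, lapply(names(tables), function(src) {
      t <- tables[[src]]
      stopifnot(all(c("human_gene", "rat_gene") %in% names(t)))
      data.frame(human_gene = as.character(t$human_gene),
                 rat_gene = as.character(t$rat_gene), source = src,
                 stringsAsFactors = FALSE)
    }))
  }
  bad <- setdiff(unique(long$source), ORTHOLOGY_SOURCES)
  if (length(bad)) {
    stop("unknown orthology source(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(ORTHOLOGY_SOURCES, collapse = ", "), ")")
  }
  key <- paste(long$human_gene, long$rat_gene, sep = "\r")
  pairs <- long[!duplicated(key), c("human_gene", "rat_gene")]
  for (src in ORTHOLOGY_SOURCES) {
    src_keys <- key[long$source == src]
    pairs[[src]] <- paste(pairs$human_gene, pairs$rat_gene, sep = "\r") %in% src_keys
  }
  pairs$db_score <- rowSums(pairs[ORTHOLOGY_SOURCES])
  lookup_conf <- function(genes) {
    if (is.null(conf)) return(rep(NA_real_, length(genes)))
    stopifnot(all(c("gene", "conf") %in% names(conf)))
    conf$conf[match(genes, conf$gene)]
  }
  pairs$human_conf <- lookup_conf(pairs$human_gene)
  pairs$rat_conf <- lookup_conf(pairs$rat_gene)
  pairs$rank <- NA_integer_
  pairs <- pairs[order(pairs$human_gene, pairs$rat_gene, method = "radix"), ]
  rownames(pairs) <- NULL
  class(pairs) <- c("orthology_table", "data.frame")
  pairs
}

#' Read a pre-aggregated orthology table
#'
#' Tab-delimited with header: either the long layout
#' (`human_gene`, `rat_gene`, `source`) or the wide layout with five logical
#' flag columns named after the sources.
#'
#' @param path file path.
#' @return `"orthology_table"`.
#' @export
read_orthology <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if ("source" %in% names(df)) return(aggregate_pairs(df))
  stopifnot(all(c("human_gene", "rat_gene") %in% names(df)))
  missing <- setdiff(ORTHOLOGY_SOURCES, names(df))
  if (length(missing)) stop("wide orthology table missing flag column(s): ",
                            paste(missing, collapse = ", "))
  long <- do.call(rbind, lapply(ORTHOLOGY_SOURCES, function(src) {
    hit <- which(as.logical(df[[src]]))
    data.frame(human_gene = df$human_gene[hit], rat_gene = df$rat_gene[hit],
               source = rep(src, length(hit)), stringsAsFactors = FALSE)
  }))
  tab <- aggregate_pairs(long)
  for (col in c("human_conf", "rat_conf")) {
    if (col %in% names(df)) {
      tab[[col]] <- df[[col]][match(paste(tab$human_gene, tab$rat_gene),
                                    paste(df$human_gene, df$rat_gene))]
    }
  }
  tab
}

#' Drop promiscuous human genes
#'
#' Human genes annotated to `max_orthologs` or more rat orthologues are
#' removed entirely (all of their pairs), to avoid inferring function from
#' nonspecific annotations. The boundary is inclusive: at the default of
#' 10, a human gene with exactly ten rat partners is dropped.
#'
#' @param table `"orthology_table"`.
#' @param max_orthologs integer `>= 1`.
#' @return filtered `"orthology_table"`.
#' @export
exclude_promiscuous <- function(table, max_orthologs = 10) {
  stopifnot(inherits(table, "orthology_table"))
  if (!is.numeric(max_orthologs) || max_orthologs < 1) {
    stop("max_orthologs must be >= 1")
  }
  counts <- base::table(factor(table$human_gene))
  drop <- names(counts)[counts >= max_orthologs]
  out <- table[!table$human_gene %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank rat orthologues within each human gene
#'
#' Within each human gene, pairs are ranked by database score (descending),
#' then rat-gene confidence (descending, missing = lowest), then rat gene
#' id (ascending) as a deterministic final tie-break.
#'
#' @param table `"orthology_table"`.
#' @return the table with `rank` filled in (a permutation of `1..k` within
#'   each human gene).
#' @export
rank_orthologs <- function(table) {
  stopifnot(inherits(table, "orthology_table"))
  conf <- table$rat_conf
  conf[is.na(conf)] <- -Inf
  ord <- order(table$human_gene, -table$db_score, -conf, table$rat_gene,
               method = "radix")
  rk <- integer(nrow(table))
  rk[ord] <- stats::ave(seq_along(ord), table$human_gene[ord],
                        FUN = seq_along)
  table$rank <- rk
  table
}

#' Consensus filter on a ranked orthology table
#'
#' Keeps pairs annotated in at least `min_dbs` databases with rank at most
#' `max_rank` within their human gene (the "at least 2 of 5 databases, at
#' most 2 orthologues per human gene" consensus subset at the defaults).
#' Ranks are computed on the full post-promiscuity table before the
#' database-score cut.
#'
#' @param table `"orthology_table"` (ranked; if `rank` is all `NA` it is
#'   ranked first).
#' @param min_dbs minimum database score.
#' @param max_rank maximum within-gene rank.
#' @return filtered `"orthology_table"`.
#' @export
filter_consensus <- function(table, min_dbs = 2, max_rank = 2) {
  stopifnot(inherits(table, "orthology_table"))
  if (all(is.na(table$rank))) table <- rank_orthologs(table)
  out <- table[table$db_score >= min_dbs & table$rank <= max_rank, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a GPR rule between species through an orthology table
#'
#' Each source (human) gene leaf is replaced by the `OR` of its retained
#' target (rat) orthologues. A leaf with no orthologue is dropped: inside
#' an `OR` node the remaining isozymes stand (`isozyme_dropped`); inside an
#' `AND` node the complex degrades gracefully to its mapped subunits and
#' the loss is flagged (`broken_complex`). A rule whose every leaf is
#' unmapped becomes the empty rule and is flagged `orphaned` for manual
#' review. No loss is silent.
#'
#' @param rule `"gpr"` object or `NULL`.
#' @param table filtered `"orthology_table"`.
#' @return list with `rule` (translated GPR or `NULL`), `events`
#'   (character subset of `c("isozyme_dropped", "broken_complex",
#'   "orphaned")`), `unmapped` (source genes without orthologues).
#' @export
translate_gpr <- function(rule, table) {
  stopifnot(inherits(table, "orthology_table"))
  if (is.null(rule)) return(list(rule = NULL, events = character(0),
                                 unmapped = character(0)))
  map <- split(table$rat_gene, table$human_gene)
  events <- character(0)
  unmapped <- character(0)
  rec <- function(node, parent_op) {
    if (node$op == "gene") {
      rats <- map[[node$id]]
      if (is.null(rats) || !length(rats)) {
        unmapped <<- c(unmapped, node$id)
        if (parent_op == "and") events <<- c(events, "broken_complex")
        else if (parent_op == "or") events <<- c(events, "isozyme_dropped")
        return(NULL)
      }
      if (length(rats) == 1L) return(list(op = "gene", id = rats))
      return(list(op = "or",
                  args = lapply(rats, function(g) list(op = "gene", id = g))))
    }
    kids <- Filter(Negate(is.null),
                   lapply(node$args, rec, parent_op = node$op))
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(op = node$op, args = kids)
  }
  new_rule <- rec(unclass(rule), parent_op = "top")
  if (is.null(new_rule)) {
    return(list(rule = NULL, events = unique(c(events, "orphaned")),
                unmapped = unique(unmapped)))
  }
  list(rule = gpr_canonicalize(new_rule), events = unique(events),
       unmapped = unique(unmapped))
}

#' Translate every GPR of a network
#'
#' Applies [translate_gpr()] reaction by reaction, producing a draft
#' network for the target species plus a translation report.
#'
#' @param network source-species `"metabolic_network"`.
#' @param table filtered `"orthology_table"`.
#' @param id id for the translated network.
#' @return list with `network` (translated draft) and `report` (data.frame:
#'   `reaction`, `event` in `{ok, isozyme_dropped, broken_complex,
#'   orphaned}`, `unmapped` semicolon-joined).
#' @export
translate_model <- function(network, table, id = paste0(network$id, "_translated")) {
  stopifnot(inherits(network, "metabolic_network"))
  rows <- list()
  gprs <- network$gpr
  for (r in network$rxns$id) {
    tr <- translate_gpr(gprs[[r]], table)
    gprs[[r]] <- tr$rule
    ev <- if ("orphaned" %in% tr$events) "orphaned"
    else if ("broken_complex" %in% tr$events) "broken_complex"
    else if ("isozyme_dropped" %in% tr$events) "isozyme_dropped"
    else "ok"
    rows[[r]] <- data.frame(reaction = r, event = ev,
                            unmapped = paste(tr$unmapped, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  tab <- reaction_table(network)
  tab$gpr <- vapply(gprs[tab$id], deparse_gpr, "")
  net <- metabolic_network(tab, compartments = network$compartments,
                           metabolite_names = stats::setNames(
                             network$mets$name, network$mets$mid),
                           objective = network$objective, id = id)
  list(network = net, report = do.call(rbind, c(rows, make.row.names = FALSE)))
}
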