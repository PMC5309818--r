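make_long <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(human_gene = r[[1]], rat_gene = r[[2]], source = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

test_that("aggregation sets database flags and scores", {
  tab <- aggregate_pairs(make_long(
    list("H1", "R1", "RGD"), list("H1", "R1", "KEGG"),
    list("H1", "R2", "Ensembl"),
    list("H2", "R3", "RGD"), list("H2", "R3", "Homologene"),
    list("H2", "R3", "Ensembl"), list("H2", "R3", "KEGG"),
    list("H2", "R3", "UniProt")))
  expect_equal(nrow(tab), 3)
  score <- stats::setNames(tab$db_score, paste(tab$human_gene, tab$rat_gene))
  expect_equal(unname(score["H1 R1"]), 2)
  expect_equal(unname(score["H1 R2"]), 1)
  expect_equal(unname(score["H2 R3"]), 5)
  expect_error(aggregate_pairs(make_long(list("H", "R", "MyDB"))),
               "unknown orthology source")
})

test_that("promiscuous human genes are dropped at the inclusive boundary", {
  rows <- c(lapply(1:10, function(i) list("Hbig", paste0("R", i), "RGD")),
            lapply(1:9, function(i) list("Hok", paste0("Q", i), "RGD")))
  tab <- aggregate_pairs(do.call(make_long, rows))
  out <- exclude_promiscuous(tab, max_orthologs = 10)
  expect_false("Hbig" %in% out$human_gene)   # exactly ten partners: dropped
  expect_equal(sum(out$human_gene == "Hok"), 9)  # nine partners: retained
  expect_error(exclude_promiscuous(tab, 0), "max_orthologs")
  # brute-force oracle over a random table
  set.seed(5)
  big <- aggregate_pairs(data.frame(
    human_gene = sample(paste0("H", 1:12), 250, replace = TRUE),
    rat_gene = sample(paste0("R", 1:60), 250, replace = TRUE),
    source = sample(c("RGD", "KEGG", "Ensembl"), 250, replace = TRUE),
    stringsAsFactors = FALSE))
  keep <- vapply(split(big$human_gene, big$human_gene), length, 0L) < 10
  expect_setequal(unique(exclude_promiscuous(big)$human_gene),
                  names(keep)[keep])
})

test_that("ranking orders by database score, confidence, then rat id", {
  tab <- aggregate_pairs(
    make_long(list("H1", "Rb", "RGD"), list("H1", "Rb", "KEGG"),
              list("H1", "Rb", "Ensembl"), list("H1", "Ra", "RGD"),
              list("H1", "Rc", "RGD"), list("H1", "Rd", "RGD")),
    conf = data.frame(gene = c("Rc", "Rd", "Ra"), conf = c(5, 2, 2)))
  rk <- rank_orthologs(tab)
  ranks <- stats::setNames(rk$rank, rk$rat_gene)
  expect_equal(unname(ranks["Rb"]), 1L)  # db score 3 beats score-1 pairs
  expect_equal(unname(ranks["Rc"]), 2L)  # conf 5 beats conf 2
  expect_equal(unname(ranks["Ra"]), 3L)  # conf tie: lexicographic rat id
  expect_equal(unname(ranks["Rd"]), 4L)
  expect_setequal(rk$rank[rk$human_gene == "H1"], 1:4)
})

test_that("consensus filter matches a brute-force filter and is monotone", {
  set.seed(11)
  long <- data.frame(
    human_gene = sample(paste0("H", 1:20), 300, replace = TRUE),
    rat_gene = sample(paste0("R", 1:40), 300, replace = TRUE),
    source = sample(c("RGD", "Homologene", "Ensembl", "KEGG", "UniProt"),
                    300, replace = TRUE),
    stringsAsFactors = FALSE)
  tab <- rank_orthologs(exclude_promiscuous(aggregate_pairs(long)))
  out <- filter_consensus(tab, min_dbs = 2, max_rank = 2)
  brute <- tab[tab$db_score >= 2 & tab$rank <= 2, ]
  expect_setequal(paste(out$human_gene, out$rat_gene),
                  paste(brute$human_gene, brute$rat_gene))
  # single-database pairs never survive the default filter
  expect_true(all(out$db_score >= 2))
  # monotonicity: tightening either knob never adds pairs
  key <- function(t) paste(t$human_gene, t$rat_gene)
  expect_true(all(key(filter_consensus(tab, 3, 2)) %in% key(out)))
  expect_true(all(key(filter_consensus(tab, 2, 1)) %in% key(out)))
})

test_that("GPR translation expands, degrades, and orphans as specified", {
  tab <- aggregate_pairs(make_long(
    list("H1", "R1", "RGD"), list("H1", "R1", "KEGG"),
    list("H2", "R2", "RGD"), list("H2", "R2", "KEGG"),
    list("H2", "R3", "RGD"), list("H2", "R3", "KEGG")))
  tab <- filter_consensus(rank_orthologs(tab))
  # OR expansion: H1 -> {R1}, H2 -> {R2, R3}
  tr <- translate_gpr(parse_gpr("H1 or H2"), tab)
  expect_equal(deparse_gpr(tr$rule), "R1 or R2 or R3")
  expect_length(tr$events, 0)
  # broken complex degrades to the mapped subunit
  tr2 <- translate_gpr(parse_gpr("H1 and Hmissing"), tab)
  expect_equal(deparse_gpr(tr2$rule), "R1")
  expect_equal(tr2$events, "broken_complex")
  expect_equal(tr2$unmapped, "Hmissing")
  # truth-table equivalence of the degraded rule under the stated policy:
  # the unmapped subunit is treated as satisfied
  for (r1 in c(TRUE, FALSE)) {
    expect_equal(gpr_eval(tr2$rule, c(R1 = r1)),
                 gpr_eval(parse_gpr("R1 and TRUEGENE"),
                          c(R1 = r1, TRUEGENE = TRUE)))
  }
  # fully unmapped rule becomes the empty rule with an orphan flag
  tr3 <- translate_gpr(parse_gpr("Hx"), tab)
  expect_null(tr3$rule)
  expect_true("orphaned" %in% tr3$events)
  # translation never invents genes
  tr4 <- translate_gpr(parse_gpr("(H1 and H2) or Hx"), tab)
  expect_true(all(gpr_genes(tr4$rule) %in% tab$rat_gene))
})

test_that("one-to-one tables preserve GPR size; model translation reports", {
  tab <- aggregate_pairs(make_long(
    list("H1", "R1", "RGD"), list("H1", "R1", "KEGG"),
    list("H2", "R2", "RGD"), list("H2", "R2", "KEGG"),
    list("H3", "R3", "RGD"), list("H3", "R3", "KEGG")))
  tab <- filter_consensus(rank_orthologs(tab))
  for (text in c("H1", "H1 or H2", "H1 and H2", "(H1 or H2) and H3")) {
    tr <- translate_gpr(parse_gpr(text), tab)
    expect_equal(gpr_size(tr$rule), gpr_size(parse_gpr(text)))
  }
  net <- metabolic_network(data.frame(
    id = c("R1", "R2", "R3", "R4"),
    equation = c("a[c] =>", "a[c] => b[c]", "b[c] => d[c]", "d[c] =>"),
    gpr = c("H1 or H2", "H1 and Hmiss", "Hmiss", "")))
  res <- translate_model(net, tab)
  events <- stats::setNames(res$report$event, res$report$reaction)
  expect_equal(unname(events[c("R1", "R2", "R3", "R4")]),
               c("ok", "broken_complex", "orphaned", "ok"))
  expect_equal(deparse_gpr(res$network$gpr[["R1"]]), "R1 or R2")
  expect_null(res$network$gpr[["R3"]])
})

test_that("orthology tables survive a wide-format file round trip", {
  tab <- aggregate_pairs(make_long(
    list("H1", "R1", "RGD"), list("H1", "R1", "UniProt"),
    list("H2", "R2", "Ensembl")))
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_orthology(tmp)
  expect_equal(back$db_score, tab$db_score)
  expect_equal(back$human_gene, tab$human_gene)
  expect_equal(back$rat_gene, tab$rat_gene)
  unlink(tmp)
})
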