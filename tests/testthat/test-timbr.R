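test_that("significance filtering zeroes insignificant fold changes", {
  expr <- data.frame(gene = c("A", "B", "C"), log2fc = c(2, 2, -1),
                     qvalue = c(0.5, 0.05, 0.1))
  out <- filter_significant(expr)
  expect_equal(out$log2fc, c(0, 2, 0))  # q = 0.1 is not < 0.1
  # vectorized filter matches a row-wise loop oracle
  set.seed(3)
  big <- data.frame(gene = paste0("g", 1:200),
                    log2fc = stats::rnorm(200), qvalue = stats::runif(200))
  loop <- big$log2fc
  for (i in seq_len(nrow(big))) if (big$qvalue[i] >= 0.1) loop[i] <- 0
  expect_equal(filter_significant(big)$log2fc, loop)
  expect_error(filter_significant(data.frame(gene = "A", log2fc = 1,
                                             qvalue = 2)), "qvalue")
})

test_that("compound suitability uses an inclusive 1% boundary", {
  genes <- paste0("g", 1:2000)
  mk_expr <- function(n_sig) data.frame(
    gene = genes, log2fc = 1,
    qvalue = c(rep(0.01, n_sig), rep(0.9, 2000 - n_sig)))
  expect_false(compound_suitability(mk_expr(10), genes)$suitable)   # 0.5%
  expect_true(compound_suitability(mk_expr(20), genes)$suitable)    # 1.0%
  expect_error(compound_suitability(mk_expr(10), character(0)), "empty")
})

test_that("GPR summarization averages isozymes and max-abs complexes", {
  fc <- c(A = 1, B = 0, C = -0.5, D = -2, E = 0.5)
  expect_equal(summarize_gpr(parse_gpr("A or B"), fc), 0.5)
  expect_equal(summarize_gpr(parse_gpr("E and D"), fc), -2)
  # nested: max-abs(mean(2, 0), -0.5) = +1
  fc2 <- c(A = 2, B = 0, C = -0.5)
  expect_equal(summarize_gpr(parse_gpr("(A or B) and C"), fc2), 1)
  # ties broken toward the positive value
  expect_equal(summarize_gpr(parse_gpr("A and Z"), c(A = 1, Z = -1)), 1)
  # absent genes contribute zero; empty rule summarizes to zero
  expect_equal(summarize_gpr(parse_gpr("A or Q"), c(A = 1)), 0.5)
  expect_equal(summarize_gpr(NULL, fc), 0)
})

test_that("per-reaction summaries separate no_gpr from no_data", {
  net <- metabolic_network(data.frame(
    id = c("R1", "R2", "R3"),
    equation = c("a[c] =>", "a[c] => b[c]", "b[c] =>"),
    gpr = c("", "Gup", "Goff")))
  expr <- data.frame(gene = "Gup", log2fc = 1.5, qvalue = 0.01)
  sm <- reaction_summaries(net, expr)
  expect_equal(sm$data_status, c("no_gpr", "summarized", "no_data"))
  expect_equal(sm$r, c(0, 1.5, 0))
})

test_that("default weights follow kind and data availability", {
  net <- metabolic_network(data.frame(
    id = c("EX", "TRN", "BIO", "BND"),
    equation = c("a[e] <=>", "a[e] => a[c]", "a[c] => b[c]", "b[c] => d[c]"),
    gpr = c("", "Gt", "Gb", "Goff"),
    lb = c(-10, 0, 0, 0), ub = rep(10, 4)))
  expr <- data.frame(gene = c("Gt", "Gb"), log2fc = c(0, 0), qvalue = c(1, 1))
  irr <- make_irreversible(net)
  w <- default_weights(irr, reaction_summaries(net, expr))
  # exchange: transport default 2, no GPR -> 4 (both split directions)
  expect_equal(unname(w[c("EX_f", "EX_b")]), c(4, 4))
  expect_equal(unname(w["TRN"]), 2)   # gene-associated transport with data
  expect_equal(unname(w["BIO"]), 1)   # gene-associated biochemical with data
  expect_equal(unname(w["BND"]), 2)   # biochemical, genes off-platform -> doubled
})

test_that("treatment/control weights are reciprocal around the default", {
  tw <- timbr_weights(1, 1)
  expect_equal(tw$w_treatment, 0.5)
  expect_equal(tw$w_control, 2)
  tw0 <- timbr_weights(3, 0)
  expect_equal(tw0$w_treatment, 3); expect_equal(tw0$w_control, 3)
  tw2 <- timbr_weights(2, -1)
  expect_equal(tw2$w_treatment, 4); expect_equal(tw2$w_control, 1)
  set.seed(8)
  w <- stats::runif(1000, 0.1, 10)
  r <- stats::rnorm(1000, 0, 3)
  ws <- timbr_weights(w, r)
  expect_equal(ws$w_control * ws$w_treatment, w^2, tolerance = 1e-12)
})

test_that("production bound takes the smaller of the cap and 90% capacity", {
  # v_max = 50 -> 45; with a small cap the cap binds; blocked -> skipped
  net <- metabolic_network(data.frame(
    id = c("EX_a", "R", "EX_b", "EX_z"),
    equation = c("a[e] <=>", "a[e] => b[e]", "b[e] <=>", "z[e] <=>"),
    lb = c(-50, 0, 0, 0), ub = c(1000, 1000, 1000, 1000)))
  pb <- production_bound(net, "EX_b")
  expect_equal(pb$min_rate, 45)
  pb2 <- production_bound(net, "EX_b", cap = 20)
  expect_equal(pb2$min_rate, 20)
  pb3 <- production_bound(net, "EX_z")
  expect_equal(pb3$status, "skipped_unproducible")
  expect_error(production_bound(net, "R"), "exchange")
})

test_that("raw production scores are the symmetric relative demand difference", {
  expect_equal(raw_production_score(5, 5), 0)
  expect_equal(raw_production_score(1, 3), 0.5)  # treatment a third of control
  expect_equal(raw_production_score(3, 1), -raw_production_score(1, 3))
  expect_error(raw_production_score(0, 1), "positive")
})

test_that("z-normalization has the documented moments and edge cases", {
  expect_equal(normalize_scores(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- stats::rnorm(50)
  z <- normalize_scores(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_warning(z0 <- normalize_scores(rep(2, 5)), "zero variance")
  expect_equal(z0, rep(0, 5))
  expect_error(normalize_scores(1), "at least two")
})

test_that("null expression yields equal demands and all-zero raw scores", {
  net <- toy_network(fixture_spec(seed = 4, n_pathways = 2))
  expr <- data.frame(gene = net$genes, log2fc = stats::rnorm(length(net$genes)),
                     qvalue = 0.9)  # nothing significant
  expect_warning(fit <- timbr(net, expr), "zero variance")
  sc <- fit$scores[fit$scores$status == "scored", ]
  expect_gt(nrow(sc), 1)
  expect_equal(sc$demand_treatment, sc$demand_control, tolerance = 1e-9)
  expect_equal(sc$raw_score, rep(0, nrow(sc)), tolerance = 1e-9)
})

test_that("planted up/down regulation moves the target to the extremes", {
  spec <- fixture_spec(seed = 10, n_pathways = 3, pathway_length = 2)
  net <- toy_network(spec)
  for (dir in c("up", "down")) {
    expr <- planted_expression(net, "p2[e]", dir, seed = 21)
    fit <- timbr(net, expr, compound = paste0("planted_", dir))
    sc <- fit$scores[fit$scores$status == "scored", ]
    target <- sc$production_score[sc$exchange == "EX_p2"]
    others <- sc$production_score[sc$exchange != "EX_p2"]
    if (dir == "up") expect_true(all(target > others))
    else expect_true(all(target < others))
  }
})

test_that("scores are invariant to uniform scaling of default weights", {
  net <- toy_network(fixture_spec(seed = 12, n_pathways = 2))
  irr <- make_irreversible(net)
  expr <- planted_expression(net, "p1[e]", "up", seed = 2)
  sm <- reaction_summaries(net, expr)
  w_def <- default_weights(irr, sm)
  r_col <- stats::setNames(sm$r, sm$reaction)[irr$cols$rxn]
  demand_for <- function(wd) {
    ws <- timbr_weights(wd, unname(r_col))
    dt <- min_weighted_flux(irrev = irr, ws$w_treatment, "EX_p1", 5)
    dc <- min_weighted_flux(irrev = irr, ws$w_control, "EX_p1", 5)
    raw_production_score(dt$demand, dc$demand)
  }
  expect_equal(demand_for(w_def), demand_for(7 * w_def), tolerance = 1e-9)
})

test_that("demand equals brute-force path enumeration on acyclic fixtures", {
  # two disjoint routes with hand-enumerable costs; forcing below both
  # route capacities so the optimum runs entirely down the cheaper path
  net <- two_path_network()
  irr <- make_irreversible(net)
  set.seed(9)
  for (rep in 1:10) {
    w <- stats::setNames(stats::runif(ncol(irr$S), 0.2, 3), colnames(irr$S))
    rate <- stats::runif(1, 1, 15)
    shared <- c("EX_a_b", "T_a", "T_b", "EX_b")
    cost1 <- sum(w[c(shared, "P1a", "P1b")])
    cost2 <- sum(w[c(shared, "P2a", "P2b")])
    oracle <- rate * min(cost1, cost2)
    got <- min_weighted_flux(irr, w, "EX_b", rate)
    expect_equal(got$demand, oracle, tolerance = 1e-6)
  }
})

test_that("species score comparison classifies correlation directions", {
  set.seed(14)
  base <- stats::rnorm(30)
  A <- cbind(same = base, anti = base, noise = base)
  B <- cbind(same = base + stats::rnorm(30, 0, 0.1),
             anti = -base + stats::rnorm(30, 0, 0.1),
             noise = stats::rnorm(30))
  rownames(A) <- rownames(B) <- paste0("m", 1:30)
  out <- compare_production_scores(A, B, fdr = 0.1)
  cls <- stats::setNames(out$class, out$compound)
  expect_equal(unname(cls["same"]), "positive")
  expect_equal(unname(cls["anti"]), "negative")
  expect_equal(unname(cls["noise"]), "uncorrelated")
  # identical and negated vectors give |r| = 1
  v <- stats::setNames(stats::rnorm(10), paste0("m", 1:10))
  one <- compare_production_scores(v, v)
  expect_equal(one$r, 1)
  neg <- compare_production_scores(v, -v)
  expect_equal(neg$r, -1)
  # too few pairs is reported, not computed
  short <- stats::setNames(1:2, c("a", "b"))
  expect_true(is.na(compare_production_scores(short, short)$r))
})

test_that("quantile calls and confusion-matrix evaluation behave as stated", {
  scores <- stats::setNames(c(3, 2.5, 1.8, -2.2, 0, 0.1, -0.1, 0.2, -0.3,
                              2.1, -1.9), paste0("m", 1:11))
  calls <- classify_predictions(scores)
  expect_equal(unname(calls["m1"]), "elevated")
  expect_equal(unname(calls["m4"]), "reduced")
  expect_equal(unname(calls["m5"]), "unchanged")
  # inclusive boundaries
  sc2 <- stats::setNames(c(1, 2, 3, 4), letters[1:4])
  c2 <- classify_predictions(sc2)
  expect_equal(unname(c2[c("a", "d")]), c("reduced", "elevated"))
  # perfect calls give MCC 1; all-unchanged calls give sensitivity 0
  truth <- c(m1 = "elevated", m2 = "reduced", m3 = "unchanged", m4 = "unchanged")
  perfect <- evaluate_calls(truth, truth)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$sensitivity, 100)
  nothing <- evaluate_calls(
    stats::setNames(rep("unchanged", 4), names(truth)), truth)
  expect_equal(nothing$sensitivity, 0)
  # degenerate table has undefined MCC, reported as NA
  all_pos <- evaluate_calls(c(m1 = "elevated"), c(m1 = "elevated"))
  expect_true(is.na(all_pos$mcc))
})

test_that("the fitted object supports the standard S3 generics", {
  net <- toy_network(fixture_spec(seed = 1, n_pathways = 2))
  expr <- planted_expression(net, "p1[e]", "up", seed = 3)
  fit <- timbr(net, expr, compound = "demo")
  expect_s3_class(fit, "timbr")
  co <- coef(fit)
  expect_true(is.numeric(co) && !is.null(names(co)))
  expect_output(print(fit), "TIMBR production scores")
  expect_output(print(summary(fit)), "highest")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
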