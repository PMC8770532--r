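# summative-record stub keyed by EC
summ_stub <- function(ec, lfc, p) {
  data.frame(group = ec, n_isoforms = 1L, log2fc = lfc, p_value = p,
             n_significant_isoforms = 0L, reg_class = "unchanged",
             discordant = FALSE, stringsAsFactors = FALSE)
}

dec_stub <- function(id, lfc, p) {
  data.frame(compound_id = id, log2fc = lfc, p_value = p,
             reg_class = "unchanged", stringsAsFactors = FALSE)
}

test_that("built-in graphs carry exactly the expected EC inventory", {
  g <- builtin_pathway_graphs()
  expect_setequal(g$EMP_upper$enzymes$ec,
                  c("5.3.1.9", "3.1.3.11", "4.1.2.13", "5.3.1.1"))
  expect_setequal(g$ED$enzymes$ec[!g$ED$enzymes$absent_from_transcriptome],
                  c("2.7.1.12", "1.1.1.49", "3.1.1.31"))
  expect_setequal(g$ED$enzymes$ec[g$ED$enzymes$absent_from_transcriptome],
                  c("1.1.5.2", "4.1.2.14", "4.2.1.12"))
  expect_setequal(g$OPP$enzymes$ec[!g$OPP$enzymes$shared],
                  c("1.1.1.44", "5.1.3.1", "5.3.1.6", "2.2.1.1", "2.2.1.2",
                    "2.7.1.15"))
  expect_setequal(g$OPP$enzymes$ec[g$OPP$enzymes$shared],
                  c("1.1.1.49", "3.1.1.31"))
  expect_setequal(g$EMP_lower$enzymes$ec,
                  c("1.2.1.12", "2.7.2.3", "4.2.1.11", "2.7.1.40"))
  expect_true("2.4.1.242" %in% g$starch_biosynthesis$enzymes$ec)
  # edges connect compounds through enzymes
  expect_true(all(c(g$OPP$edges$from, g$OPP$edges$to) %in%
                    c(g$OPP$enzymes$ec, g$OPP$compounds)))
})

test_that("enzyme calls apply the summative tri-state thresholds", {
  g <- builtin_pathway_graphs()$EMP_upper
  summ <- rbind(summ_stub("5.3.1.9", 1.5, 0.01),    # 2.83-fold -> significant
                summ_stub("3.1.3.11", 0.3, 0.5),    # 1.23-fold -> moderate
                summ_stub("4.1.2.13", 0.1, 0.9))    # -> unchanged
  calls <- call_enzymes(g, summ)
  expect_equal(calls$grade[calls$node == "5.3.1.9"], "significant")
  expect_equal(calls$direction[calls$node == "5.3.1.9"], "up")
  expect_equal(calls$grade[calls$node == "3.1.3.11"], "moderate")
  expect_equal(calls$grade[calls$node == "4.1.2.13"], "unchanged")
  expect_equal(calls$direction[calls$node == "4.1.2.13"], "none")
  expect_equal(calls$grade[calls$node == "5.3.1.1"], "missing")   # no record
  # large fold but p above threshold is only moderate
  calls2 <- call_enzymes(g, summ_stub("5.3.1.9", 1.5, 0.2))
  expect_equal(calls2$grade[calls2$node == "5.3.1.9"], "moderate")
})

test_that("metabolite calls use the compound thresholds", {
  g <- builtin_pathway_graphs()$EMP_upper
  decs <- rbind(dec_stub("glucose", 4, 0.001),                # 16-fold sig up
                dec_stub("fructose-6-phosphate", log2(1.25), 0.5),  # moderate
                dec_stub("glucose-6-phosphate", 0.1, 0.9))
  calls <- call_metabolites(g, decs)
  expect_equal(calls$grade[calls$node == "glucose"], "significant")
  expect_equal(calls$grade[calls$node == "fructose-6-phosphate"], "moderate")
  expect_equal(calls$direction[calls$node == "fructose-6-phosphate"], "up")
  expect_equal(calls$grade[calls$node == "glucose-6-phosphate"], "unchanged")
  expect_equal(calls$grade[calls$node == "glyceraldehyde-3-phosphate"],
               "missing")
})

# Direction calls of the published Fig-5-style comparison: OPP with five
# of six core enzymes up, EMP-upper partly down, ED mixed, EMP-lower
# mixed with the discordant PGK.
fig5_summative <- function() {
  rbind(
    # EMP upper: GPI, FBP unchanged; FBPAL moderate down; TPI significant down
    summ_stub("5.3.1.9", 0.05, 0.8), summ_stub("3.1.3.11", -0.1, 0.7),
    summ_stub("4.1.2.13", -0.4, 0.2), summ_stub("5.3.1.1", -1.4, 0.01),
    # ED: GCK moderate down; GPDH, PGCL moderate up
    summ_stub("2.7.1.12", -0.5, 0.3), summ_stub("1.1.1.49", 0.4, 0.2),
    summ_stub("3.1.1.31", 0.5, 0.15),
    # OPP core: five up (mix of significant and moderate), RBPI unchanged
    summ_stub("1.1.1.44", 1.6, 0.01), summ_stub("5.1.3.1", 0.5, 0.2),
    summ_stub("5.3.1.6", 0.05, 0.9), summ_stub("2.2.1.1", 1.2, 0.04),
    summ_stub("2.2.1.2", 0.4, 0.3), summ_stub("2.7.1.15", 1.1, 0.03),
    # EMP lower: GAPDH sig down, PGK moderate down (discordant), PPH
    # moderate down, PK unchanged
    summ_stub("1.2.1.12", -1.2, 0.02), summ_stub("2.7.2.3", -0.4, 0.3),
    summ_stub("4.2.1.11", -0.3, 0.4), summ_stub("2.7.1.40", -0.1, 0.8))
}

test_that("route verdicts reproduce the OPP-preference fixture", {
  graphs <- builtin_pathway_graphs()
  summ <- fig5_summative()
  decs <- rbind(dec_stub("glucose", log2(1.3), 0.2),
                dec_stub("gluconate", -log2(1.5), 0.1),
                dec_stub("xylulose-5-phosphate", log2(1.4), 0.1),
                dec_stub("fructose-6-phosphate", log2(1.3), 0.2),
                dec_stub("glycerate-3-phosphate", 2.2, 0.005))
  routes <- c("EMP_upper", "ED", "OPP", "EMP_lower")
  verdicts <- lapply(graphs[routes], function(g) {
    evaluate_route(g, call_enzymes(g, summ), call_metabolites(g, decs))
  })
  opp <- verdicts$OPP
  expect_equal(opp$n_enzymes, 6L)
  expect_equal(opp$m_same, 5L)
  expect_equal(opp$direction, "up")
  expect_equal(opp$p_value, 1.74e-07, tolerance = 0.005)
  expect_true(all(c("xylulose-5-phosphate", "fructose-6-phosphate") %in%
                    opp$supporting_metabolites))
  # ED counts exclude the three ECs absent from the transcriptome
  expect_equal(verdicts$ED$n_enzymes, 3L)
  # EMP upper: 2 of 4 down
  expect_equal(verdicts$EMP_upper$m_same, 2L)
  expect_equal(verdicts$EMP_upper$direction, "down")

  cmp <- compare_routes(verdicts)
  expect_equal(cmp$table$pathway[cmp$table$preferred], "OPP")
  expect_equal(sum(cmp$table$preferred), 1L)
  expect_length(cmp$report, 4L)
})

test_that("a null fixture prefers no route and ties break by name", {
  graphs <- builtin_pathway_graphs()
  flat <- rbind(summ_stub("5.3.1.9", 0, 1), summ_stub("3.1.3.11", 0, 1),
                summ_stub("4.1.2.13", 0, 1), summ_stub("5.3.1.1", 0, 1),
                summ_stub("1.1.1.44", 0, 1), summ_stub("5.1.3.1", 0, 1),
                summ_stub("5.3.1.6", 0, 1), summ_stub("2.2.1.1", 0, 1),
                summ_stub("2.2.1.2", 0, 1), summ_stub("2.7.1.15", 0, 1))
  v1 <- evaluate_route(graphs$EMP_upper,
                       call_enzymes(graphs$EMP_upper, flat))
  v2 <- evaluate_route(graphs$OPP, call_enzymes(graphs$OPP, flat))
  expect_equal(v1$m_same, 0L)
  expect_equal(v1$p_value, 1)
  cmp <- compare_routes(list(v1, v2))
  expect_equal(sum(cmp$table$preferred), 0L)

  # identical verdicts: deterministic alphabetical tie-break
  va <- evaluate_route(graphs$OPP, call_enzymes(graphs$OPP, fig5_summative()))
  vb <- va; vb$pathway <- "AAA_clone"
  cmp2 <- compare_routes(list(va, vb))
  expect_equal(cmp2$table$pathway[cmp2$table$preferred], "AAA_clone")
})

test_that("evaluate_route is invariant to node order and warns on no data", {
  g <- builtin_pathway_graphs()$OPP
  calls <- call_enzymes(g, fig5_summative())
  v1 <- evaluate_route(g, calls)
  v2 <- evaluate_route(g, calls[rev(seq_len(nrow(calls))), ])
  expect_equal(v1$p_value, v2$p_value)
  expect_equal(v1$m_same, v2$m_same)
  none <- call_enzymes(g, summ_stub("9.9.9.9", 0, 1))
  expect_warning(v0 <- evaluate_route(g, none), "no enzyme")
  expect_equal(v0$p_value, 1)
})

test_that("GSR function report combines enrichment with direction consistency", {
  # nitrogen-metabolism-like pathway: 8 GSR genes, 6 positively correlated
  gsr <- data.frame(
    gene_id = sprintf("g%02d", 1:12),
    lfc_L2H_vs_LL = c(rep(3, 6), rep(-3, 2), rep(3, 4)),
    lfc_H2L_vs_HH = c(rep(-3, 6), rep(3, 2), rep(-3, 4)),
    lfc_HH_vs_LL = c(rep(3, 6), rep(-3, 2), rep(3, 4)),
    classification = c(rep("positive_gsr", 6), rep("negative_gsr", 2),
                       rep("positive_gsr", 4)),
    rank_score = 3, stringsAsFactors = FALSE)
  map <- structure(list(
    nm = list(name = "nitrogen-like", members = sprintf("g%02d", 1:8)),
    th = list(name = "thiamine-like", members = sprintf("g%02d", 9:12)),
    s1 = list(name = "singleton", members = "g01")),
    class = "pathway_map")
  rep_ <- gsr_function_report(gsr, map, N = 9277)
  nm <- rep_[rep_$pathway_id == "nm", ]
  expect_equal(nm$n_genes_gsr, 8L)
  expect_equal(nm$m_same, 6L)
  expect_equal(nm$direction, "up")
  expect_equal(nm$consistency_p, 3.9e-10, tolerance = 0.02)
  th <- rep_[rep_$pathway_id == "th", ]
  expect_equal(th$consistency_p, 1.5e-05, tolerance = 0.02)
  s1 <- rep_[rep_$pathway_id == "s1", ]
  expect_equal(s1$consistency_p, 0.5)   # Binomial(1, 1/2)
})

test_that("pipeline on planted routes prefers OPP end to end", {
  # plant all OPP core enzymes up and all EMP-upper enzymes down in a
  # synthetic experiment, then run counts -> summative -> calls -> verdicts
  set.seed(42)
  n_bg <- 300L
  opp_ecs <- c("1.1.1.44", "5.1.3.1", "5.3.1.6", "2.2.1.1", "2.2.1.2",
               "2.7.1.15")
  emp_ecs <- c("5.3.1.9", "3.1.3.11", "4.1.2.13", "5.3.1.1")
  ecs <- c(opp_ecs, emp_ecs)
  n <- n_bg + length(ecs)
  mu <- rlnorm(n, log(200), 0.5)
  eff <- rep(1, n)
  eff[n_bg + seq_along(opp_ecs)] <- 8     # up in HH
  eff[n_bg + length(opp_ecs) + seq_along(emp_ecs)] <- 1 / 8
  draw <- function(m) rnbinom(n, size = 20, mu = m)
  counts_a <- cbind(draw(mu), draw(mu), draw(mu))
  counts_b <- cbind(draw(mu * eff), draw(mu * eff), draw(mu * eff))
  rownames(counts_a) <- rownames(counts_b) <-
    c(sprintf("bg%03d", seq_len(n_bg)), paste0("enz_", ecs))
  mat <- two_cond_matrix(counts_a, counts_b)
  ann <- data.frame(gene_id = rownames(counts_a),
                    product = "x", isoform_group = NA_character_,
                    stringsAsFactors = FALSE)
  ann$ec_numbers <- c(replicate(n_bg, character(0), simplify = FALSE),
                      as.list(ecs))
  ann$pathway_ids <- replicate(n, character(0), simplify = FALSE)
  summ <- summative_call(mat, ann, "ec", "LL", "HH")
  graphs <- builtin_pathway_graphs()
  verdicts <- lapply(graphs[c("EMP_upper", "OPP")], function(g) {
    evaluate_route(g, call_enzymes(g, summ))
  })
  cmp <- compare_routes(verdicts)
  expect_equal(cmp$table$pathway[cmp$table$preferred], "OPP")
  expect_equal(cmp$table$m_same[cmp$table$pathway == "OPP"], 6L)
  expect_equal(cmp$table$direction[cmp$table$pathway == "EMP_upper"], "down")
})
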