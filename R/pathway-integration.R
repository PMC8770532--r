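#' Built-in glucose-assimilation and starch pathway graphs
#'
#' The five candidate routes examined when asking how supplemented
#' glucose is assimilated: the upper and lower halves of
#' Embden-Meyerhof-Parnas glycolysis (EMP), the Entner-Doudoroff (ED)
#' pathway, the oxidative pentose phosphate (OPP) pathway, and starch
#' biosynthesis. Enzyme nodes are EC numbers; some ED enzymes are
#' flagged absent (not found in the transcriptome) and the two
#' glucose-6-phosphate entry enzymes shared between ED and OPP are
#' flagged shared on the OPP graph so they do not count toward the
#' OPP consistency statistic. Compound nodes carry the directed
#' compound -> enzyme -> compound chain of each route.
#'
#' @return Named list of \code{pathway_graph} objects
#'   (\code{EMP_upper}, \code{ED}, \code{OPP}, \code{EMP_lower},
#'   \code{starch_biosynthesis}), each a list with \code{name},
#'   \code{enzymes} (data.frame \code{ec}, \code{label},
#'   \code{absent_from_transcriptome}, \code{shared}),
#'   \code{compounds} (character) and \code{edges} (data.frame
#'   \code{from}, \code{to}).
#' @export
builtin_pathway_graphs <- function() {
  g <- function(name, enzymes, compounds, edges) {
    structure(list(name = name, enzymes = enzymes, compounds = compounds,
                   edges = edges), class = "pathway_graph")
  }
  enz <- function(ec, label, absent = FALSE, shared = FALSE) {
    data.frame(ec = ec, label = label,
               absent_from_transcriptome = absent, shared = shared,
               stringsAsFactors = FALSE)
  }
  edges <- function(...) {
    chain <- c(...)
    data.frame(from = chain[-length(chain)], to = chain[-1L],
               stringsAsFactors = FALSE)
  }

  list(
    EMP_upper = g("EMP_upper",
      rbind(enz("5.3.1.9",  "glucose-6-phosphate isomerase (GPI)"),
            enz("3.1.3.11", "fructose-bisphosphatase (FBP)"),
            enz("4.1.2.13", "fructose-bisphosphate aldolase (FBPAL)"),
            enz("5.3.1.1",  "triose-phosphate isomerase (TPI)")),
      c("glucose", "glucose-6-phosphate", "fructose-6-phosphate",
        "fructose-1,6-bisphosphate", "glyceraldehyde-3-phosphate",
        "dihydroxyacetone-phosphate"),
      edges("glucose-6-phosphate", "5.3.1.9", "fructose-6-phosphate",
            "3.1.3.11", "fructose-1,6-bisphosphate",
            "4.1.2.13", "dihydroxyacetone-phosphate",
            "5.3.1.1", "glyceraldehyde-3-phosphate")),

    ED = g("ED",
      rbind(enz("1.1.5.2",  "quinoprotein glucose dehydrogenase", absent = TRUE),
            enz("2.7.1.12", "gluconokinase (GCK)"),
            enz("1.1.1.49", "glucose-6-phosphate dehydrogenase (GPDH)"),
            enz("3.1.1.31", "6-phosphogluconolactonase (PGCL)"),
            enz("4.2.1.12", "phosphogluconate dehydratase", absent = TRUE),
            enz("4.1.2.14", "KDPG aldolase", absent = TRUE)),
      c("glucose", "gluconate", "6-phosphogluconate",
        "glucose-6-phosphate", "gluconolactone-6-phosphate",
        "2-keto-3-deoxy-6-phosphogluconate", "pyruvate",
        "glyceraldehyde-3-phosphate"),
      rbind(edges("glucose", "1.1.5.2", "gluconate",
                  "2.7.1.12", "6-phosphogluconate",
                  "4.2.1.12", "2-keto-3-deoxy-6-phosphogluconate",
                  "4.1.2.14", "pyruvate"),
            edges("glucose-6-phosphate", "1.1.1.49",
                  "gluconolactone-6-phosphate", "3.1.1.31",
                  "6-phosphogluconate"))),

    OPP = g("OPP",
      rbind(enz("1.1.1.49", "glucose-6-phosphate dehydrogenase (GPDH)", shared = TRUE),
            enz("3.1.1.31", "6-phosphogluconolactonase (PGCL)", shared = TRUE),
            enz("1.1.1.44", "phosphogluconate dehydrogenase (PGCDH)"),
            enz("5.1.3.1",  "ribulose-phosphate 3-epimerase (RBPE)"),
            enz("5.3.1.6",  "ribose-5-phosphate isomerase (RBPI)"),
            enz("2.2.1.1",  "transketolase (TKT)"),
            enz("2.2.1.2",  "transaldolase (TAL)"),
            enz("2.7.1.15", "ribokinase (RBK)")),
      c("glucose-6-phosphate", "gluconolactone-6-phosphate",
        "6-phosphogluconate", "ribulose-5-phosphate",
        "ribose-5-phosphate", "xylulose-5-phosphate", "ribose",
        "sedoheptulose-7-phosphate", "fructose-6-phosphate",
        "glyceraldehyde-3-phosphate"),
      rbind(edges("glucose-6-phosphate", "1.1.1.49",
                  "gluconolactone-6-phosphate", "3.1.1.31",
                  "6-phosphogluconate", "1.1.1.44", "ribulose-5-phosphate",
                  "5.1.3.1", "xylulose-5-phosphate",
                  "2.2.1.1", "sedoheptulose-7-phosphate",
                  "2.2.1.2", "fructose-6-phosphate"),
            edges("ribulose-5-phosphate", "5.3.1.6", "ribose-5-phosphate"),
            edges("ribose", "2.7.1.15", "ribose-5-phosphate"))),

    EMP_lower = g("EMP_lower",
      rbind(enz("1.2.1.12", "glyceraldehyde-3-phosphate dehydrogenase (GAPDH)"),
            enz("2.7.2.3",  "phosphoglycerate kinase (PGK)"),
            enz("4.2.1.11", "phosphopyruvate hydratase (PPH)"),
            enz("2.7.1.40", "pyruvate kinase (PK)")),
      c("glyceraldehyde-3-phosphate", "glycerate-1,3-bisphosphate",
        "glycerate-3-phosphate", "glycerate-2-phosphate",
        "phosphoenolpyruvate", "pyruvate"),
      edges("glyceraldehyde-3-phosphate", "1.2.1.12",
            "glycerate-1,3-bisphosphate", "2.7.2.3",
            "glycerate-3-phosphate", "4.2.1.11",
            "phosphoenolpyruvate", "2.7.1.40", "pyruvate")),

    starch_biosynthesis = g("starch_biosynthesis",
      rbind(enz("5.4.2.2",   "phosphoglucomutase (PGM)"),
            enz("2.7.7.27",  "glucose-1-phosphate adenylyltransferase (AGPase)"),
            enz("2.4.1.242", "granule-bound starch synthase (GBSS)"),
            enz("2.4.1.21",  "starch synthase (SS)"),
            enz("2.4.1.18",  "1,4-alpha-glucan branching enzyme (BE)")),
      c("glucose-6-phosphate", "glucose-1-phosphate", "ADP-glucose",
        "amylose", "amylopectin"),
      rbind(edges("glucose-6-phosphate", "5.4.2.2", "glucose-1-phosphate",
                  "2.7.7.27", "ADP-glucose", "2.4.1.242", "amylose"),
            edges("ADP-glucose", "2.4.1.21", "amylopectin"),
            edges("amylose", "2.4.1.18", "amylopectin")))
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph:", x$name, "-", nrow(x$enzymes), "enzymes,",
      length(x$compounds), "compounds\n")
  invisible(x)
}

# shared tri-state grading
.grade <- function(lfc, p, sig_fold, sig_p, moderate_fold) {
  sig <- is.finite(lfc) & abs(lfc) > log2(sig_fold) & p < sig_p
  mod <- !sig & is.finite(lfc) & abs(lfc) > log2(moderate_fold)
  grade <- ifelse(sig, "significant", ifelse(mod, "moderate", "unchanged"))
  direction <- ifelse(grade == "unchanged", "none",
                      ifelse(lfc > 0, "up", "down"))
  list(grade = grade, direction = direction)
}

#' Tri-state regulation calls for the enzymes of a pathway graph
#'
#' Grades each EC node from its summative (isoform-summed) transcript
#' record: significant when the summative fold exceeds
#' \code{summative_fold} with p < \code{summative_p}, moderate when it
#' exceeds \code{moderate_fold}, unchanged otherwise; ECs without a
#' summative record, or flagged absent from the transcriptome, are
#' graded missing.
#'
#' @param graph A \code{pathway_graph}.
#' @param summative [summative_call()] output keyed by EC
#'   (\code{group_key = "ec"}).
#' @param config An [analysis_config()].
#' @return data.frame: \code{node} (EC), \code{grade}, \code{direction},
#'   \code{shared}, \code{discordant}, \code{source}.
#' @export
call_enzymes <- function(graph, summative, config = analysis_config()) {
  stopifnot(inherits(graph, "pathway_graph"))
  idx <- match(graph$enzymes$ec, summative$group)
  lfc <- summative$log2fc[idx]
  p <- summative$p_value[idx]
  gr <- .grade(lfc, p, config$summative_fold, config$summative_p,
               config$moderate_fold)
  missing <- is.na(idx) | graph$enzymes$absent_from_transcriptome
  data.frame(node = graph$enzymes$ec,
             grade = ifelse(missing, "missing", gr$grade),
             direction = ifelse(missing, "none", gr$direction),
             shared = graph$enzymes$shared,
             discordant = ifelse(missing, FALSE,
                                 summative$discordant[idx]),
             source = "summative_transcript",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tri-state regulation calls for the metabolites of a pathway graph
#'
#' Same tri-state logic as [call_enzymes()], with the differential-
#' compound thresholds (\code{dec_fold}, \code{dec_p}) for the
#' significant grade and \code{moderate_fold} for moderate; compounds
#' not present in the DEC table are graded missing.
#'
#' @param graph A \code{pathway_graph}.
#' @param decs [call_decs()] output whose \code{compound_id} values use
#'   the graph's compound names (map instrument ids beforehand, e.g.
#'   via [ppm_match()]).
#' @param config An [analysis_config()].
#' @return data.frame: \code{node}, \code{grade}, \code{direction},
#'   \code{source}.
#' @export
call_metabolites <- function(graph, decs, config = analysis_config()) {
  stopifnot(inherits(graph, "pathway_graph"))
  idx <- match(graph$compounds, decs$compound_id)
  gr <- .grade(decs$log2fc[idx], decs$p_value[idx],
               config$dec_fold, config$dec_p, config$moderate_fold)
  missing <- is.na(idx)
  data.frame(node = graph$compounds,
             grade = ifelse(missing, "missing", gr$grade),
             direction = ifelse(missing, "none", gr$direction),
             source = "metabolite",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Direction-consistency verdict for one candidate route
#'
#' N is the number of core (non-missing, non-shared) enzyme nodes with
#' data; M is the larger same-direction count among up and down,
#' counting both significant and moderate grades; the consistency
#' p-value is [pathway_consistency()] on (N, M). Pathway metabolites
#' with data are partitioned into supporting (same direction as the
#' enzyme majority) and conflicting (opposite direction); they inform
#' interpretation but do not enter the p-value.
#'
#' @param graph A \code{pathway_graph}.
#' @param enzyme_calls [call_enzymes()] output for the graph.
#' @param metabolite_calls Optional [call_metabolites()] output.
#' @return List of class \code{route_verdict}: \code{pathway},
#'   \code{n_enzymes}, \code{m_same}, \code{direction}, \code{p_value},
#'   \code{supporting_metabolites}, \code{conflicting_metabolites},
#'   \code{preferred} (set by [compare_routes()]).
#' @export
evaluate_route <- function(graph, enzyme_calls, metabolite_calls = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  core <- enzyme_calls[!enzyme_calls$shared & enzyme_calls$grade != "missing", ,
                       drop = FALSE]
  n <- nrow(core)
  active <- core$grade %in% c("significant", "moderate")
  n_up <- sum(active & core$direction == "up")
  n_down <- sum(active & core$direction == "down")
  if (n == 0L) {
    warning("route ", graph$name, " has no enzyme with data")
    m <- 0L; dir <- "none"
  } else if (n_up == 0L && n_down == 0L) {
    m <- 0L; dir <- "none"
  } else if (n_up >= n_down) {   # deterministic tie-break toward up
    m <- n_up; dir <- "up"
  } else {
    m <- n_down; dir <- "down"
  }
  cons <- pathway_consistency(n, m, if (dir == "none") "none" else dir)
  supp <- conf <- character(0)
  if (!is.null(metabolite_calls) && dir != "none") {
    has <- metabolite_calls$grade %in% c("significant", "moderate")
    supp <- metabolite_calls$node[has & metabolite_calls$direction == dir]
    conf <- metabolite_calls$node[has & metabolite_calls$direction != dir]
  }
  structure(list(pathway = graph$name, n_enzymes = n, m_same = m,
                 direction = dir, p_value = cons$p_value,
                 supporting_metabolites = supp,
                 conflicting_metabolites = conf,
                 preferred = FALSE),
            class = "route_verdict")
}

#' @export
print.route_verdict <- function(x, ...) {
  cat(sprintf("%s: %d of %d enzymes co-directional (%s), p = %.3g%s\n",
              x$pathway, x$m_same, x$n_enzymes, x$direction, x$p_value,
              if (x$preferred) " [preferred]" else ""))
  invisible(x)
}

#' Compare route verdicts and mark the preferred route
#'
#' The preferred route is the verdict with direction up and the
#' smallest consistency p-value below 0.05; ties are broken by larger
#' M, then alphabetical pathway name. When no upregulated route reaches
#' p < 0.05 none is preferred.
#'
#' @param verdicts List of \code{route_verdict} objects (>= 2).
#' @return List with \code{verdicts} (preferred flag set),
#'   \code{table} (one row per route) and \code{report} (character,
#'   one neutral line per route).
#' @export
compare_routes <- function(verdicts) {
  if (length(verdicts) < 2L) stop("compare_routes needs >= 2 verdicts")
  tab <- do.call(rbind, lapply(verdicts, function(v) {
    data.frame(pathway = v$pathway, n_enzymes = v$n_enzymes,
               m_same = v$m_same, direction = v$direction,
               p_value = v$p_value, stringsAsFactors = FALSE)
  }))
  cand <- which(tab$direction == "up" & tab$p_value < 0.05)
  pref <- NA_integer_
  if (length(cand) > 0L) {
    ord <- cand[order(tab$p_value[cand], -tab$m_same[cand],
                      tab$pathway[cand])]
    pref <- ord[[1L]]
  }
  tab$preferred <- seq_len(nrow(tab)) == ifelse(is.na(pref), 0L, pref)
  for (i in seq_along(verdicts)) verdicts[[i]]$preferred <- tab$preferred[[i]]
  report <- sprintf("%s: %d of %d enzymes co-directional (%s), p = %.3g%s",
                    tab$pathway, tab$m_same, tab$n_enzymes, tab$direction,
                    tab$p_value,
                    ifelse(tab$preferred, " [preferred]", ""))
  list(verdicts = verdicts, table = tab, report = report)
}

#' Enrichment plus direction consistency of GSR genes per pathway
#'
#' For every pathway in the map: binomial enrichment of the GSR set,
#' then — for the GSR genes inside the pathway — the count in the
#' majority response direction (positive_gsr = up, negative_gsr =
#' down) and the [pathway_consistency()] p-value on (N genes with
#' monotonic class, M in majority direction).
#'
#' @param gsr_records GSR records from [identify_gsr()].
#' @param map A \code{pathway_map}.
#' @param N Transcriptome size.
#' @return data.frame: enrichment columns plus \code{n_genes_gsr},
#'   \code{m_same}, \code{direction}, \code{consistency_p}.
#' @export
gsr_function_report <- function(gsr_records, map, N) {
  mono <- gsr_records[gsr_records$classification != "non_monotonic", ,
                      drop = FALSE]
  enr <- pathway_enrichment(mono$gene_id, map, N)
  extra <- t(vapply(enr$pathway_id, function(id) {
    inside <- mono[mono$gene_id %in% map[[id]]$members, , drop = FALSE]
    n_up <- sum(inside$classification == "positive_gsr")
    n_down <- sum(inside$classification == "negative_gsr")
    m <- max(n_up, n_down)
    n <- nrow(inside)
    p <- if (n == 0L) 1 else pathway_consistency(n, m)$p_value
    c(n, m, if (n_up >= n_down) 1 else -1, p)
  }, numeric(4)))
  enr$n_genes_gsr <- as.integer(extra[, 1L])
  enr$m_same <- as.integer(extra[, 2L])
  enr$direction <- ifelse(enr$n_genes_gsr == 0L, "none",
                          ifelse(extra[, 3L] > 0, "up", "down"))
  enr$consistency_p <- extra[, 4L]
  enr
}
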