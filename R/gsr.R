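#' Run the three standard comparisons of the reciprocal-shift design
#'
#' Calls DEGs for L2H vs LL, H2L vs HH, and HH vs LL (in each case the
#' second-named condition over the first, so a positive log2fc in
#' L2H_vs_LL or HH_vs_LL means higher expression at the higher target
#' glucose level).
#'
#' @param matrix A [count_matrix()] containing all four conditions.
#' @param config An [analysis_config()].
#' @return Named list of three [call_degs()] data.frames:
#'   \code{L2H_vs_LL}, \code{H2L_vs_HH}, \code{HH_vs_LL}.
#' @export
build_comparisons <- function(matrix, config = analysis_config()) {
  missing <- setdiff(CONDITION_LABELS, unique(matrix$sample_meta$condition))
  if (length(missing) > 0L)
    stop("missing condition(s): ", paste(missing, collapse = ", "))
  list(
    L2H_vs_LL = call_degs(matrix, "LL", "L2H", config),
    H2L_vs_HH = call_degs(matrix, "HH", "H2L", config),
    HH_vs_LL  = call_degs(matrix, "LL", "HH", config)
  )
}

is_significant <- function(reg_class) {
  reg_class %in% c("significant_up", "significant_down")
}

#' Identify glucose-specific responsive (GSR) genes
#'
#' The common set is every gene significant in BOTH shift comparisons
#' (L2H vs LL and H2L vs HH). A common gene is classified
#' \code{positive_gsr} when its expression rises after the shift into
#' high glucose and falls after the shift into low glucose (log2fc
#' L2H_vs_LL > 0 and H2L_vs_HH < 0), \code{negative_gsr} for the
#' mirrored signs, and \code{non_monotonic} otherwise. A gene that is
#' additionally significant in the steady-state HH vs LL contrast must
#' agree in sign with its L2H_vs_LL response, else it is demoted to
#' \code{non_monotonic}. The monotonic genes are the GSR set: their
#' transcription correlates (positively or negatively) with the glucose
#' supplementation level.
#'
#' @param deg_lists The list returned by [build_comparisons()].
#' @param config An [analysis_config()].
#' @return List with \code{records} (data.frame: \code{gene_id}, the
#'   three log2fc columns, \code{classification}, \code{rank_score} =
#'   |log2fc HH vs LL|) covering the common set, and \code{venn}
#'   summary from [venn_summary()].
#' @export
identify_gsr <- function(deg_lists, config = analysis_config()) {
  stopifnot(all(c("L2H_vs_LL", "H2L_vs_HH", "HH_vs_LL") %in% names(deg_lists)))
  a <- deg_lists$L2H_vs_LL; b <- deg_lists$H2L_vs_HH; c_ <- deg_lists$HH_vs_LL
  if (!identical(a$gene_id, b$gene_id) || !identical(a$gene_id, c_$gene_id))
    stop("comparison tables cover different gene universes")

  sig_a <- is_significant(a$reg_class)
  sig_b <- is_significant(b$reg_class)
  sig_c <- is_significant(c_$reg_class)
  common <- sig_a & sig_b

  lfc_a <- a$log2fc; lfc_b <- b$log2fc; lfc_c <- c_$log2fc
  cls <- ifelse(lfc_a > 0 & lfc_b < 0, "positive_gsr",
         ifelse(lfc_a < 0 & lfc_b > 0, "negative_gsr", "non_monotonic"))
  # steady-state contrast, when itself significant, must agree in sign
  disagree <- sig_c & sign(lfc_c) != sign(lfc_a)
  cls[disagree] <- "non_monotonic"

  records <- data.frame(
    gene_id = a$gene_id[common],
    lfc_L2H_vs_LL = lfc_a[common],
    lfc_H2L_vs_HH = lfc_b[common],
    lfc_HH_vs_LL = lfc_c[common],
    classification = cls[common],
    rank_score = abs(lfc_c[common]),
    stringsAsFactors = FALSE)

  venn <- venn_summary(a$gene_id[sig_a], b$gene_id[sig_b], c_$gene_id[sig_c],
                       n_monotonic = sum(records$classification != "non_monotonic"))
  list(records = records, venn = venn)
}

#' Venn summary of the three DEG sets
#'
#' Set sizes, all seven intersection cells, the size of the common
#' shift set, the number of monotonic genes and the monotonic
#' percentage (reported to one decimal place).
#'
#' @param set_l2h,set_h2l,set_hh Character vectors of significant gene
#'   ids in L2H vs LL, H2L vs HH, HH vs LL.
#' @param n_monotonic Number of common-set genes classified monotonic.
#' @return List of counts; \code{monotonic_percent} is
#'   \code{100 * n_monotonic / n_common_shift} rounded to 1 decimal.
#' @export
venn_summary <- function(set_l2h, set_h2l, set_hh, n_monotonic) {
  in_ab <- intersect(set_l2h, set_h2l)
  in_abc <- intersect(in_ab, set_hh)
  n_common <- length(in_ab)
  if (n_monotonic > n_common)
    stop("n_monotonic exceeds the common-set size")
  list(
    n_L2H_vs_LL = length(set_l2h),
    n_H2L_vs_HH = length(set_h2l),
    n_HH_vs_LL = length(set_hh),
    n_only_L2H = length(setdiff(setdiff(set_l2h, set_h2l), set_hh)),
    n_only_H2L = length(setdiff(setdiff(set_h2l, set_l2h), set_hh)),
    n_only_HH = length(setdiff(setdiff(set_hh, set_l2h), set_h2l)),
    n_L2H_H2L_only = length(setdiff(in_ab, set_hh)),
    n_L2H_HH_only = length(setdiff(intersect(set_l2h, set_hh), set_h2l)),
    n_H2L_HH_only = length(setdiff(intersect(set_h2l, set_hh), set_l2h)),
    n_all_three = length(in_abc),
    n_common_shift = n_common,
    n_monotonic = n_monotonic,
    monotonic_percent = if (n_common > 0) round(100 * n_monotonic / n_common, 1) else NA_real_
  )
}

#' Top-N most up- or downregulated GSR genes
#'
#' Ranks \code{positive_gsr} records (direction \code{"up"}) or
#' \code{negative_gsr} records (\code{"down"}) by descending
#' \code{rank_score} (|log2fc| of the steady-state HH vs LL contrast);
#' ties broken by lexicographic gene id.
#'
#' @param records GSR records data.frame from [identify_gsr()].
#' @param direction \code{"up"} or \code{"down"}.
#' @param n Maximum list length.
#' @return Character vector of at most \code{n} gene ids.
#' @export
rank_top <- function(records, direction = c("up", "down"), n = 10L) {
  direction <- match.arg(direction)
  stopifnot(n >= 1L)
  want <- if (direction == "up") "positive_gsr" else "negative_gsr"
  sub <- records[records$classification == want, , drop = FALSE]
  if (nrow(sub) == 0L) return(character(0))
  ord <- order(-sub$rank_score, sub$gene_id)
  utils::head(sub$gene_id[ord], n)
}
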