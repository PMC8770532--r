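#' Exact binomial upper tail
#'
#' \code{P(X >= k)} for \code{X ~ Binomial(n, p)}, computed with the
#' numerically stable distribution routine (no normal or Poisson
#' approximation).
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials.
#' @param p Success probability in [0, 1].
#' @return Upper-tail probability; 1 when k = 0.
#' @export
binomial_upper_tail <- function(k, n, p) {
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Binomial pathway enrichment over a gene subset
#'
#' For each pathway with K member genes in a transcriptome of N genes,
#' k of which fall in a subset of n genes (e.g. the GSR set): log2
#' fold-enrichment \code{log2(k*N/(K*n))} and the exact binomial
#' upper-tail p-value of observing >= k pathway members among n trials
#' with success probability K/N. Pathways without overlap (k = 0) are
#' reported with p = 1 and undefined (NA) fold-enrichment. A
#' BH-adjusted column is added for convenience; the primary statistic
#' is the raw binomial p.
#'
#' @param subset Character vector of gene ids (the tested subset).
#' @param map A \code{pathway_map} from [read_pathway_map()] or
#'   [simulate_pathway_map()].
#' @param N Transcriptome size (>= length of subset).
#' @param universe Optional character vector of all transcriptome gene
#'   ids; when given, subset members outside it are an error and
#'   pathway memberships are intersected with it.
#' @return data.frame sorted by ascending p-value with columns
#'   \code{pathway_id}, \code{name}, \code{K}, \code{k}, \code{n},
#'   \code{N}, \code{fc_log2}, \code{p_value}, \code{q_value}.
#' @export
pathway_enrichment <- function(subset, map, N, universe = NULL) {
  subset <- unique(as.character(subset))
  n <- length(subset)
  if (N < n) stop("transcriptome size N must be >= subset size")
  if (!is.null(universe)) {
    outside <- setdiff(subset, universe)
    if (length(outside) > 0L)
      stop("subset gene(s) absent from transcriptome universe: ",
           paste(utils::head(outside, 5L), collapse = ", "))
  }
  rows <- lapply(names(map), function(id) {
    members <- map[[id]]$members
    if (!is.null(universe)) members <- intersect(members, universe)
    K <- length(members)
    k <- length(intersect(members, subset))
    p <- if (k == 0L) 1 else binomial_upper_tail(k, n, K / N)
    fc <- if (k > 0L) log2(k * N / (K * n)) else NA_real_
    data.frame(pathway_id = id, name = map[[id]]$name, K = K, k = k,
               n = n, N = N, fc_log2 = fc, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway_id = character(0), name = character(0),
                      K = integer(0), k = integer(0), n = integer(0),
                      N = integer(0), fc_log2 = numeric(0),
                      p_value = numeric(0), q_value = numeric(0))
    return(out)
  }
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway direction-consistency test
#'
#' If M of the N enzymes in a pathway are regulated in the same
#' direction, the chance of any one enzyme landing in one given
#' direction pattern of M co-directional changes is taken as 2^-M; the
#' consistency p-value is the exact binomial upper tail
#' \code{P(X >= M)} for \code{X ~ Binomial(N, 2^-M)}. A small p
#' indicates coordinated transcriptional regulation of the pathway.
#'
#' @param n_enzymes N, enzymes considered (with data).
#' @param m_same M, enzymes sharing the majority direction.
#' @param direction \code{"up"}, \code{"down"}, or \code{"none"}.
#' @return List of class \code{consistency_result}: \code{n_enzymes},
#'   \code{m_same}, \code{direction}, \code{p_success} (2^-M),
#'   \code{p_value}.
#' @export
pathway_consistency <- function(n_enzymes, m_same,
                                direction = c("up", "down", "none")) {
  direction <- match.arg(direction)
  if (m_same < 0 || m_same > n_enzymes)
    stop("m_same must satisfy 0 <= m_same <= n_enzymes")
  p_success <- 2^-m_same
  p <- if (m_same == 0) 1 else binomial_upper_tail(m_same, n_enzymes, p_success)
  structure(list(n_enzymes = n_enzymes, m_same = m_same,
                 direction = direction, p_success = p_success,
                 p_value = p),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("%d of %d enzymes co-directional (%s), p = %.3g\n",
              x$m_same, x$n_enzymes, x$direction, x$p_value))
  invisible(x)
}
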