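#' Transcripts-per-million normalization
#'
#' TPM for gene g in one sample is \code{1e6 * (c_g/L_g) / sum_j
#' (c_j/L_j)} with c the read count and L the effective length in
#' nucleotides; every sample column sums to one million.
#'
#' @param matrix A [count_matrix()].
#' @return Numeric matrix of TPM values with the same dimnames.
#' @export
compute_tpm <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  rates <- matrix$counts / matrix$effective_lengths
  denom <- colSums(rates)
  zero <- denom == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(matrix$counts)[zero], collapse = ", "))
  sweep(rates, 2L, denom, "/") * 1e6
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; input order preserved. Thin wrapper around
#' \code{stats::p.adjust(method = "BH")} with input validation.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Method-of-moments common dispersion estimate
#'
#' For each gene, within-condition sample mean m and variance s^2 of
#' library-size-scaled counts give a per-gene moment estimate
#' \code{max(0, (s^2 - m)/m^2)} of the NB dispersion phi (variance =
#' mu + phi*mu^2); estimates from the two conditions are averaged and
#' the common phi is the median over genes whose scaled mean is >= 5
#' (low counts destabilize moment estimates).
#'
#' @param matrix A [count_matrix()].
#' @param conditions Character vector of two condition labels.
#' @return Non-negative scalar dispersion estimate.
#' @export
estimate_dispersion <- function(matrix, conditions) {
  stopifnot(inherits(matrix, "count_matrix"), length(conditions) == 2L)
  check_replicates(matrix, conditions, min_rep = 2L)
  lib <- colSums(matrix$counts)
  sf <- lib / exp(mean(log(lib)))
  scaled <- sweep(matrix$counts, 2L, sf, "/")
  per_cond <- vapply(conditions, function(cond) {
    idx <- condition_samples(matrix, cond)
    m <- rowMeans(scaled[, idx, drop = FALSE])
    v <- apply(scaled[, idx, drop = FALSE], 1L, stats::var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }, numeric(nrow(matrix$counts)))
  per_cond <- base::matrix(per_cond, nrow = nrow(matrix$counts))
  raw <- rowMeans(per_cond, na.rm = TRUE)
  idx_all <- unlist(lapply(conditions, condition_samples, mat = matrix))
  keep <- rowMeans(scaled[, idx_all, drop = FALSE]) >= 5 & is.finite(raw)
  if (!any(keep)) return(0)
  max(0, stats::median(pmax(0, raw[keep])))
}

#' Conditional negative-binomial exact test for two groups of counts
#'
#' Counts are scaled to a common library size using the supplied size
#' factors, summed within group, and tested conditionally on the total:
#' under the null the group-A total given the grand total follows the
#' conditional distribution of two NB convolutions (group of n
#' replicates with common dispersion phi has an NB total with size
#' n/phi). The two-sided p-value sums the probabilities of all outcomes
#' no more probable than the observed one (ties included). With phi = 0
#' this reduces to the exact binomial split of the total with
#' probability nA/(nA+nB).
#'
#' @param counts_a,counts_b Non-negative integer replicate counts.
#' @param phi Common NB dispersion (>= 0; variance = mu + phi*mu^2).
#' @param size_factors Positive scaling factors, one per sample in the
#'   order \code{c(counts_a, counts_b)}; defaults to all 1.
#' @return Two-sided exact p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, phi, size_factors = NULL) {
  if (length(counts_a) == 0L || length(counts_b) == 0L)
    stop("both groups must be non-empty")
  if (!is.finite(phi) || phi < 0) stop("dispersion phi must be >= 0")
  n_a <- length(counts_a); n_b <- length(counts_b)
  if (is.null(size_factors)) size_factors <- rep(1, n_a + n_b)
  if (length(size_factors) != n_a + n_b || any(size_factors <= 0))
    stop("size_factors must be positive, one per sample")
  sf <- size_factors / exp(mean(log(size_factors)))
  s_a <- round(sum(counts_a / sf[seq_len(n_a)]))
  s_b <- round(sum(counts_b / sf[n_a + seq_len(n_b)]))
  .nb_exact_p(s_a, s_b, n_a, n_b, phi)
}

# Conditional exact p for pre-summed, pre-scaled group totals.
.nb_exact_p <- function(s_a, s_b, n_a, n_b, phi) {
  total <- s_a + s_b
  if (total == 0) return(1)
  x <- 0:total
  if (phi == 0) {
    f <- stats::dbinom(x, total, n_a / (n_a + n_b))
  } else {
    mu <- total / (n_a + n_b)
    f <- stats::dnbinom(x, size = n_a / phi, mu = n_a * mu) *
      stats::dnbinom(total - x, size = n_b / phi, mu = n_b * mu)
    f <- f / sum(f)
  }
  obs <- f[s_a + 1L]
  min(1, sum(f[f <= obs * (1 + 1e-10)]))
}

#' Call differentially expressed genes between two conditions
#'
#' Per gene: mean TPM per condition, log2 fold-change of condition B
#' over condition A with a pseudocount added to both means, exact NB
#' p-value on the replicate counts (common dispersion estimated from
#' the two conditions unless supplied), BH q-value, and a tri-state
#' regulation class: \code{significant_up}/\code{significant_down} when
#' the fold-change exceeds \code{deg_fold} and q < \code{deg_fdr};
#' otherwise \code{moderate_up}/\code{moderate_down} when the
#' fold-change exceeds \code{moderate_fold}; otherwise
#' \code{unchanged}.
#'
#' @param matrix A [count_matrix()].
#' @param cond_a,cond_b Condition labels; the log2 fold-change is B
#'   over A.
#' @param config An [analysis_config()].
#' @param dispersion Optional fixed common dispersion; estimated by
#'   [estimate_dispersion()] when NULL.
#' @param fold,p_threshold,use_fdr Override the significance rule:
#'   defaults are \code{deg_fold} / \code{deg_fdr} on the q-value; the
#'   summative caller reuses this routine with \code{summative_fold} /
#'   \code{summative_p} on the raw p-value.
#' @return data.frame with one row per gene: \code{gene_id},
#'   \code{comparison}, \code{mean_a}, \code{mean_b}, \code{log2fc},
#'   \code{p_value}, \code{q_value}, \code{reg_class}.
#' @export
call_degs <- function(matrix, cond_a, cond_b, config = analysis_config(),
                      dispersion = NULL, fold = config$deg_fold,
                      p_threshold = config$deg_fdr, use_fdr = TRUE) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (identical(cond_a, cond_b))
    stop("cannot compare condition ", cond_a, " with itself")
  check_replicates(matrix, c(cond_a, cond_b), min_rep = 2L)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(matrix, c(cond_a, cond_b))

  idx_a <- condition_samples(matrix, cond_a)
  idx_b <- condition_samples(matrix, cond_b)
  tpm <- compute_tpm(matrix)
  mean_a <- rowMeans(tpm[, idx_a, drop = FALSE])
  mean_b <- rowMeans(tpm[, idx_b, drop = FALSE])
  pc <- config$pseudocount
  log2fc <- log2((mean_b + pc) / (mean_a + pc))

  lib <- colSums(matrix$counts)[c(idx_a, idx_b)]
  sf <- lib / exp(mean(log(lib)))
  n_a <- length(idx_a); n_b <- length(idx_b)
  sc <- sweep(matrix$counts[, c(idx_a, idx_b), drop = FALSE], 2L, sf, "/")
  s_a <- round(rowSums(sc[, seq_len(n_a), drop = FALSE]))
  s_b <- round(rowSums(sc[, n_a + seq_len(n_b), drop = FALSE]))
  p <- vapply(seq_len(nrow(sc)), function(i) {
    .nb_exact_p(s_a[[i]], s_b[[i]], n_a, n_b, dispersion)
  }, numeric(1))
  q <- bh_fdr(p)

  crit <- if (use_fdr) q else p
  sig <- abs(log2fc) > log2(fold) & crit < p_threshold
  mod <- !sig & abs(log2fc) > log2(config$moderate_fold)
  reg_class <- ifelse(sig, ifelse(log2fc > 0, "significant_up", "significant_down"),
               ifelse(mod, ifelse(log2fc > 0, "moderate_up", "moderate_down"),
                      "unchanged"))
  data.frame(gene_id = rownames(matrix$counts),
             comparison = paste0(cond_b, "_vs_", cond_a),
             mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
             p_value = p, q_value = q, reg_class = reg_class,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summative (isoform-group) differential calls
#'
#' Counts of all isoforms sharing a grouping key (isoform group or EC
#' number) are summed per sample before testing, so each enzyme is
#' tested as one unit; significance uses the summative thresholds
#' (fold > \code{summative_fold}, raw p < \code{summative_p}) and the
#' moderate grade uses \code{moderate_fold}. A group is flagged
#' discordant when the summative direction opposes the majority
#' direction of its individually significant isoforms (individual
#' significance at the DEG thresholds) — the situation seen when one
#' highly abundant isoform masks several regulated ones.
#'
#' @param matrix A [count_matrix()].
#' @param annotation Annotation data.frame as from [read_annotation()].
#' @param group_key \code{"isoform_group"} or \code{"ec"}; with
#'   \code{"ec"} a multi-EC gene contributes to every one of its ECs.
#' @param cond_a,cond_b Condition labels (log2fc is B over A).
#' @param config An [analysis_config()].
#' @param deg_records Optional precomputed [call_degs()] table for the
#'   same comparison, used for the per-isoform significance counts.
#' @return data.frame with one row per group: \code{group},
#'   \code{n_isoforms}, \code{log2fc}, \code{p_value},
#'   \code{n_significant_isoforms}, \code{reg_class}, \code{discordant}.
#' @export
summative_call <- function(matrix, annotation,
                           group_key = c("isoform_group", "ec"),
                           cond_a, cond_b, config = analysis_config(),
                           deg_records = NULL) {
  group_key <- match.arg(group_key)
  stopifnot(inherits(matrix, "count_matrix"))
  ann <- annotation[annotation$gene_id %in% rownames(matrix$counts), ,
                    drop = FALSE]
  groups <- if (group_key == "ec") {
    memb <- data.frame(
      gene_id = rep(ann$gene_id, lengths(ann$ec_numbers)),
      group = unlist(ann$ec_numbers),
      stringsAsFactors = FALSE)
    split(memb$gene_id, memb$group)
  } else {
    keep <- !is.na(ann$isoform_group) & nzchar(ann$isoform_group)
    split(ann$gene_id[keep], ann$isoform_group[keep])
  }
  if (length(groups) == 0L)
    stop("no gene carries a non-empty '", group_key, "' annotation")

  # dispersion and abundances come from the full gene-level matrix: a
  # grouped matrix is too small for moment estimates and its TPM would
  # renormalize away the groups' relative abundances
  disp <- estimate_dispersion(matrix, c(cond_a, cond_b))
  idx_a <- condition_samples(matrix, cond_a)
  idx_b <- condition_samples(matrix, cond_b)
  tpm <- compute_tpm(matrix)
  lib <- colSums(matrix$counts)[c(idx_a, idx_b)]
  sf <- lib / exp(mean(log(lib)))
  n_a <- length(idx_a); n_b <- length(idx_b)
  pc <- config$pseudocount

  sum_deg <- do.call(rbind, lapply(names(groups), function(gid) {
    g <- groups[[gid]]
    mean_a <- mean(colSums(tpm[g, idx_a, drop = FALSE]))
    mean_b <- mean(colSums(tpm[g, idx_b, drop = FALSE]))
    lfc <- log2((mean_b + pc) / (mean_a + pc))
    sc <- colSums(matrix$counts[g, c(idx_a, idx_b), drop = FALSE]) / sf
    p <- .nb_exact_p(round(sum(sc[seq_len(n_a)])),
                     round(sum(sc[n_a + seq_len(n_b)])), n_a, n_b, disp)
    sig <- abs(lfc) > log2(config$summative_fold) & p < config$summative_p
    mod <- !sig & abs(lfc) > log2(config$moderate_fold)
    data.frame(gene_id = gid, log2fc = lfc, p_value = p,
               reg_class = if (sig) {
                 if (lfc > 0) "significant_up" else "significant_down"
               } else if (mod) {
                 if (lfc > 0) "moderate_up" else "moderate_down"
               } else "unchanged",
               stringsAsFactors = FALSE)
  }))

  if (is.null(deg_records))
    deg_records <- call_degs(matrix, cond_a, cond_b, config,
                             dispersion = disp)
  sig_dir <- stats::setNames(
    ifelse(deg_records$reg_class == "significant_up", 1L,
    ifelse(deg_records$reg_class == "significant_down", -1L, 0L)),
    deg_records$gene_id)

  res <- lapply(names(groups), function(gid) {
    dirs <- sig_dir[groups[[gid]]]
    n_sig <- sum(dirs != 0L)
    maj <- sign(sum(dirs))
    srow <- sum_deg[sum_deg$gene_id == gid, ]
    discordant <- n_sig >= 1L && maj != 0L &&
      sign(srow$log2fc) != 0 && sign(srow$log2fc) != maj
    data.frame(group = gid, n_isoforms = length(groups[[gid]]),
               log2fc = srow$log2fc, p_value = srow$p_value,
               n_significant_isoforms = n_sig,
               reg_class = srow$reg_class, discordant = discordant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
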