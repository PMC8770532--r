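#' Relative-standard-deviation filter for metabolite ions
#'
#' Removes compounds whose RSD (100 * sd / mean of intensities over the
#' designated replicate set) exceeds the threshold; zero-mean compounds
#' are removed with reason "zero mean". Idempotent.
#'
#' @param table A [metabolite_table()].
#' @param rsd_max_percent Threshold in percent (default from the study:
#'   30).
#' @param samples Sample ids to compute the RSD over — by default all
#'   samples; pass the QC-injection ids when a QC schedule exists.
#' @return List with \code{table} (filtered) and \code{removed}
#'   (data.frame \code{compound_id}, \code{rsd}, \code{reason}).
#' @export
rsd_filter <- function(table, rsd_max_percent = 30, samples = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  if (nrow(table$intensities) == 0L)
    return(list(table = table,
                removed = data.frame(compound_id = character(0),
                                     rsd = numeric(0),
                                     reason = character(0))))
  if (is.null(samples)) samples <- colnames(table$intensities)
  sub <- table$intensities[, samples, drop = FALSE]
  if (ncol(sub) < 2L) stop("RSD needs >= 2 replicates")
  m <- rowMeans(sub)
  s <- apply(sub, 1L, stats::sd)
  rsd <- ifelse(m == 0, Inf, 100 * s / m)
  drop <- rsd > rsd_max_percent
  removed <- data.frame(compound_id = rownames(sub)[drop],
                        rsd = rsd[drop],
                        reason = ifelse(m[drop] == 0, "zero mean",
                                        "RSD above threshold"),
                        row.names = NULL, stringsAsFactors = FALSE)
  keep <- which(!drop)
  filtered <- metabolite_table(table$compounds[keep, , drop = FALSE],
                               table$intensities[keep, , drop = FALSE],
                               table$sample_meta)
  list(table = filtered, removed = removed)
}

#' Median normalization of metabolite intensities
#'
#' Scales each sample so its median intensity equals the grand median
#' of all per-sample medians. A light-weight stand-in for
#' injection-order signal-drift correction when no QC schedule is
#' available; pluggable — any matrix-to-matrix normalizer can replace
#' it upstream of [call_decs()].
#'
#' @param table A [metabolite_table()].
#' @return List with \code{table} (normalized) and \code{factors}
#'   (named numeric: the multiplicative factor applied per sample).
#' @export
normalize_median <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  med <- apply(table$intensities, 2L, stats::median)
  target <- stats::median(med)
  factors <- target / med
  norm <- sweep(table$intensities, 2L, factors, "*")
  list(table = metabolite_table(table$compounds, norm, table$sample_meta),
       factors = factors)
}

#' Match an observed mass against candidate theoretical masses
#'
#' A candidate matches when the mass error
#' \code{1e6 * |observed - theoretical| / theoretical} is strictly
#' below \code{ppm_max}.
#'
#' @param observed_mz Observed mass-to-charge in Da (> 0).
#' @param candidates data.frame with columns \code{id} and \code{mass}
#'   (theoretical, Da).
#' @param ppm_max Threshold in ppm (strict less-than; default 10).
#' @return data.frame of matches (\code{id}, \code{mass}, \code{ppm})
#'   sorted by ascending ppm.
#' @export
ppm_match <- function(observed_mz, candidates, ppm_max = 10) {
  if (!is.finite(observed_mz) || observed_mz <= 0)
    stop("observed mass must be positive")
  if (any(candidates$mass <= 0)) stop("theoretical masses must be positive")
  ppm <- 1e6 * abs(observed_mz - candidates$mass) / candidates$mass
  hit <- ppm < ppm_max
  out <- data.frame(id = candidates$id[hit], mass = candidates$mass[hit],
                    ppm = ppm[hit], stringsAsFactors = FALSE)
  out[order(out$ppm), , drop = FALSE]
}

#' Call differentially expressed compounds (high vs low glucose)
#'
#' Welch two-sample t-test on log2 intensities per compound; the log2
#' fold-change is the difference of mean log2 intensities (high over
#' low, i.e. the log ratio of geometric means). Classes: \code{up}
#' when log2fc > log2(dec_fold) and p < dec_p, \code{down} mirrored,
#' else \code{unchanged}.
#'
#' @param table A [metabolite_table()] with conditions low and high,
#'   >= 3 replicates each.
#' @param config An [analysis_config()] (uses \code{dec_fold},
#'   \code{dec_p}).
#' @return data.frame: \code{compound_id}, \code{log2fc},
#'   \code{p_value}, \code{reg_class}.
#' @export
call_decs <- function(table, config = analysis_config()) {
  stopifnot(inherits(table, "metabolite_table"))
  meta <- table$sample_meta
  idx_lo <- which(meta$condition == "low")
  idx_hi <- which(meta$condition == "high")
  if (length(idx_lo) < 3L || length(idx_hi) < 3L)
    stop("call_decs needs >= 3 replicates in each condition")
  logint <- log2(table$intensities)
  res <- t(vapply(seq_len(nrow(logint)), function(i) {
    lo <- logint[i, idx_lo]; hi <- logint[i, idx_hi]
    lfc <- mean(hi) - mean(lo)
    p <- if (stats::sd(lo) == 0 && stats::sd(hi) == 0) {
      if (lfc == 0) 1 else 0
    } else {
      stats::t.test(hi, lo)$p.value
    }
    c(lfc, p)
  }, numeric(2)))
  lfc <- res[, 1L]; p <- res[, 2L]
  reg <- ifelse(lfc > log2(config$dec_fold) & p < config$dec_p, "up",
         ifelse(lfc < -log2(config$dec_fold) & p < config$dec_p, "down",
                "unchanged"))
  data.frame(compound_id = rownames(table$intensities),
             log2fc = lfc, p_value = p, reg_class = reg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal-component QC report of metabolite samples
#'
#' PCA of log2 intensities (samples as observations) as a replicate-
#' agreement check; returns scores and variance explained.
#'
#' @param table A [metabolite_table()].
#' @param n_components Number of PCs to report.
#' @return List with \code{scores} (samples x PCs, with condition
#'   column) and \code{variance_explained} (fractions).
#' @export
metabolite_pca <- function(table, n_components = 2L) {
  stopifnot(inherits(table, "metabolite_table"))
  x <- t(log2(table$intensities))
  keep <- apply(x, 2L, stats::sd) > 0
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- data.frame(sample_id = rownames(x),
                       condition = table$sample_meta$condition,
                       pc$x[, seq_len(k), drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve[seq_len(k)])
}
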