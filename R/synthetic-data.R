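#' Specification of the synthetic reciprocal-shift transcriptome
#'
#' Defaults emulate the study conditions: 9,277 annotated genes
#' quantified in 12 samples (LL, HH, L2H, H2L, triplicate), negative-
#' binomial counts with dispersion 0.1, ~2 million reads per sample,
#' and planted glucose-responsive structure: 1.5% of genes positively
#' and 1.5% negatively correlated with the target glucose level (mean
#' |log2 effect| 3, s.d. 0.5, truncated below at 2 so planted genes
#' exceed the 4-fold calling threshold in expectation), plus 0.6% of
#' genes responding transiently in both shifted samples only (the
#' non-monotonic fraction the GSR filter must reject).
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition.
#' @param library_size_mean Expected total counts per sample.
#' @param library_size_cv Coefficient of variation of library sizes.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi*mu^2).
#' @param frac_positive_gsr,frac_negative_gsr Fractions of genes whose
#'   expected expression scales positively/negatively with the target
#'   glucose level.
#' @param gsr_log2_effect Mean |log2 ratio| between high- and
#'   low-glucose target states for planted GSR genes.
#' @param gsr_effect_sd Standard deviation of the planted effect.
#' @param gsr_effect_min Lower truncation of the planted |effect|.
#' @param frac_shift_only Fraction of genes whose effect applies only
#'   in the shifted conditions (L2H and H2L).
#' @param baseline_sdlog sdlog of the log-normal baseline relative
#'   expression (1.25 puts the median count near 100 at the default
#'   library size).
#' @param rng_seed Integer seed.
#' @return List of class \code{transcriptome_sim_spec}.
#' @export
transcriptome_sim_spec <- function(n_genes = 9277L, n_replicates = 3L,
                                   library_size_mean = 2e6,
                                   library_size_cv = 0.1,
                                   nb_dispersion = 0.1,
                                   frac_positive_gsr = 0.015,
                                   frac_negative_gsr = 0.015,
                                   gsr_log2_effect = 3,
                                   gsr_effect_sd = 0.5,
                                   gsr_effect_min = 2,
                                   frac_shift_only = 0.006,
                                   baseline_sdlog = 1.25,
                                   rng_seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_replicates = as.integer(n_replicates),
               library_size_mean = library_size_mean,
               library_size_cv = library_size_cv,
               nb_dispersion = nb_dispersion,
               frac_positive_gsr = frac_positive_gsr,
               frac_negative_gsr = frac_negative_gsr,
               gsr_log2_effect = gsr_log2_effect,
               gsr_effect_sd = gsr_effect_sd,
               gsr_effect_min = gsr_effect_min,
               frac_shift_only = frac_shift_only,
               baseline_sdlog = baseline_sdlog,
               rng_seed = as.integer(rng_seed))
  fr <- spec$frac_positive_gsr + spec$frac_negative_gsr + spec$frac_shift_only
  if (any(c(spec$frac_positive_gsr, spec$frac_negative_gsr,
            spec$frac_shift_only) < 0) || fr >= 1)
    stop("planted fractions must be non-negative and sum to < 1")
  if (spec$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(spec, class = "transcriptome_sim_spec")
}

# normal truncated below, via inverse CDF so it is seed-deterministic
rtnorm_lower <- function(n, mean, sd, lower) {
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

#' Simulate a reciprocal-shift count matrix with planted ground truth
#'
#' Baseline relative expression is log-normal; for a planted gene the
#' expected count is multiplied by \code{2^(s*e)} in every sample whose
#' condition targets the high glucose level (HH and L2H) — with s = +1
#' for \code{positive_gsr}, -1 for \code{negative_gsr} — while
#' \code{shift_only} genes apply the multiplier in the two shifted
#' conditions (L2H and H2L) irrespective of direction of shift, making
#' them significant in both shift comparisons but with equal signs
#' (non-monotonic). Counts are NB with common dispersion phi. The same
#' seed reproduces the matrix exactly.
#'
#' @param spec A [transcriptome_sim_spec()].
#' @return List with \code{matrix} (a [count_matrix()]) and
#'   \code{truth} (list with data.frame \code{genes}: \code{gene_id},
#'   \code{class} in \{positive_gsr, negative_gsr, shift_only, null\},
#'   \code{effect} = signed planted log2 effect).
#' @export
simulate_transcriptome <- function(spec = transcriptome_sim_spec()) {
  stopifnot(inherits(spec, "transcriptome_sim_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  rel <- stats::rlnorm(n, meanlog = 0, sdlog = spec$baseline_sdlog)
  rel <- rel / sum(rel)

  n_pos <- round(spec$frac_positive_gsr * n)
  n_neg <- round(spec$frac_negative_gsr * n)
  n_shift <- round(spec$frac_shift_only * n)
  planted <- sample.int(n, n_pos + n_neg + n_shift)
  class <- rep("null", n)
  class[planted[seq_len(n_pos)]] <- "positive_gsr"
  class[planted[n_pos + seq_len(n_neg)]] <- "negative_gsr"
  class[planted[n_pos + n_neg + seq_len(n_shift)]] <- "shift_only"

  e <- rtnorm_lower(n, spec$gsr_log2_effect, spec$gsr_effect_sd,
                    spec$gsr_effect_min)
  shift_sign <- sample(c(-1, 1), n, replace = TRUE)
  effect <- ifelse(class == "positive_gsr", e,
            ifelse(class == "negative_gsr", -e,
            ifelse(class == "shift_only", shift_sign * e, 0)))

  conds <- rep(CONDITION_LABELS, each = spec$n_replicates)
  reps <- rep(seq_len(spec$n_replicates), times = length(CONDITION_LABELS))
  sample_ids <- paste0(conds, "_", reps)
  info <- condition_info(conds)
  cv <- spec$library_size_cv
  sdlog_lib <- sqrt(log(1 + cv^2))
  libs <- stats::rlnorm(length(conds),
                        meanlog = log(spec$library_size_mean) - sdlog_lib^2 / 2,
                        sdlog = sdlog_lib)

  counts <- matrix(0, nrow = n, ncol = length(conds),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(conds)) {
    high_target <- info$target_level[[j]] == GLUCOSE_HIGH
    mult <- rep(1, n)
    gsr <- class %in% c("positive_gsr", "negative_gsr")
    if (high_target) mult[gsr] <- 2^effect[gsr]
    if (info$is_shifted[[j]]) {
      so <- class == "shift_only"
      mult[so] <- 2^effect[so]
    }
    mu <- libs[[j]] * rel * mult
    counts[, j] <- if (spec$nb_dispersion == 0) {
      stats::rpois(n, mu)
    } else {
      stats::rnbinom(n, size = 1 / spec$nb_dispersion, mu = mu)
    }
  }

  meta <- data.frame(sample_id = sample_ids, condition = conds,
                     replicate = reps, stringsAsFactors = FALSE)
  truth <- list(genes = data.frame(gene_id = gene_ids, class = class,
                                   effect = effect,
                                   stringsAsFactors = FALSE))
  list(matrix = count_matrix(counts, meta), truth = truth)
}

#' Simulate a pathway map, optionally enriched for planted GSR genes
#'
#' Pathway sizes are uniform in \code{size_range}. In an enriched
#' pathway each member slot is filled from the planted-GSR gene pool
#' with probability \code{min(1, enrich_factor * f)} (f = GSR fraction
#' of the transcriptome) and from the remaining genes otherwise, so the
#' expected GSR overlap is \code{size * min(1, enrich_factor * f)};
#' non-enriched pathways use \code{enrich_factor = 1}, the null
#' expectation K*n/N.
#'
#' @param truth Truth object from [simulate_transcriptome()].
#' @param n_pathways Number of pathways.
#' @param size_range Integer vector (min, max) of pathway sizes.
#' @param n_enriched Number of pathways planted as enriched.
#' @param enrich_factor Sampling enrichment multiplier for GSR genes.
#' @param rng_seed Integer seed.
#' @return List with \code{map} (a \code{pathway_map}) and updated
#'   \code{truth} carrying \code{pathways} (data.frame
#'   \code{pathway_id}, \code{enriched}).
#' @export
simulate_pathway_map <- function(truth, n_pathways = 50L,
                                 size_range = c(10L, 90L),
                                 n_enriched = 5L, enrich_factor = 16,
                                 rng_seed = 1L) {
  genes <- truth$genes
  n_genes <- nrow(genes)
  if (max(size_range) > n_genes)
    stop("size_range max exceeds the number of simulated genes")
  if (n_pathways > 0L && n_enriched > n_pathways)
    stop("n_enriched exceeds n_pathways")
  set.seed(rng_seed)
  gsr_pool <- genes$gene_id[genes$class %in% c("positive_gsr", "negative_gsr")]
  other_pool <- setdiff(genes$gene_id, gsr_pool)
  f <- length(gsr_pool) / n_genes

  map <- list()
  enriched <- logical(n_pathways)
  if (n_pathways > 0L) {
    size_choices <- seq(size_range[[1L]], size_range[[2L]])
    sizes <- size_choices[sample.int(length(size_choices), n_pathways,
                                     replace = TRUE)]
    enriched[seq_len(n_enriched)] <- TRUE
    for (i in seq_len(n_pathways)) {
      eff <- if (enriched[[i]]) enrich_factor else 1
      p_gsr <- min(1, eff * f)
      n_from_gsr <- min(stats::rbinom(1L, sizes[[i]], p_gsr),
                        length(gsr_pool))
      members <- c(sample(gsr_pool, n_from_gsr),
                   sample(other_pool, sizes[[i]] - n_from_gsr))
      id <- sprintf("sp%03d", i)
      map[[id]] <- list(name = paste("Synthetic pathway", i),
                        members = members)
    }
  }
  truth$pathways <- data.frame(
    pathway_id = if (n_pathways > 0L) sprintf("sp%03d", seq_len(n_pathways)) else character(0),
    enriched = enriched, stringsAsFactors = FALSE)
  list(map = structure(map, class = "pathway_map"), truth = truth)
}

#' Simulate a two-condition metabolite intensity table
#'
#' Defaults emulate the study's metabolome: 409 single-ion compounds
#' measured in sextuplicate under low- and high-glucose steady states,
#' with 18% planted as differential (|log2 effect| 3, i.e. 8-fold,
#' above the 4-fold calling threshold) and multiplicative log-normal
#' noise. m/z values are uniform over the instrument's 50-1200 Da scan
#' range.
#'
#' @param n_compounds Number of compounds.
#' @param frac_dec Planted differential fraction in [0, 1]; the planted
#'   count is \code{round(frac_dec * n_compounds)}.
#' @param log2_effect |log2 ratio| of high over low for planted
#'   compounds (sign random per compound).
#' @param noise_sigma sdlog of the multiplicative log-normal noise.
#' @param n_reps Replicates per condition (>= 3).
#' @param rng_seed Integer seed.
#' @return List with \code{table} (a [metabolite_table()]) and
#'   \code{truth} (data.frame \code{compound_id}, \code{is_dec},
#'   \code{effect} = signed log2 effect).
#' @export
simulate_metabolome <- function(n_compounds = 409L, frac_dec = 0.18,
                                log2_effect = 3, noise_sigma = 0.3,
                                n_reps = 6L, rng_seed = 1L) {
  if (frac_dec < 0 || frac_dec > 1) stop("frac_dec must lie in [0, 1]")
  if (n_reps < 3L) stop("n_reps must be >= 3")
  set.seed(rng_seed)
  ids <- sprintf("C%04d", seq_len(n_compounds))
  baseline <- stats::rlnorm(n_compounds, meanlog = log(1e5), sdlog = 1)
  n_dec <- round(frac_dec * n_compounds)
  is_dec <- rep(FALSE, n_compounds)
  is_dec[sample.int(n_compounds, n_dec)] <- TRUE
  effect <- ifelse(is_dec, sample(c(-1, 1), n_compounds, replace = TRUE) *
                     log2_effect, 0)

  conds <- rep(c("low", "high"), each = n_reps)
  reps <- rep(seq_len(n_reps), times = 2L)
  sample_ids <- paste0(conds, "_", reps)
  ints <- matrix(0, n_compounds, length(conds),
                 dimnames = list(ids, sample_ids))
  for (j in seq_along(conds)) {
    mu <- baseline * 2^(effect * (conds[[j]] == "high"))
    ints[, j] <- mu * stats::rlnorm(n_compounds, 0, noise_sigma)
  }

  compounds <- data.frame(compound_id = ids,
                          mz = stats::runif(n_compounds, 50, 1200),
                          rt = stats::runif(n_compounds, 0.5, 15),
                          annotation = NA_character_,
                          stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sample_ids, condition = conds,
                     replicate = reps, stringsAsFactors = FALSE)
  truth <- data.frame(compound_id = ids, is_dec = is_dec, effect = effect,
                      stringsAsFactors = FALSE)
  list(table = metabolite_table(compounds, ints, meta), truth = truth)
}
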