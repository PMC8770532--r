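# Shared in-code fixtures for the test suite.

# A tiny valid count matrix covering all four conditions in duplicate
# or triplicate, with hand-set counts.
tiny_matrix <- function(n_genes = 3L, n_reps = 3L, base = 100L) {
  conds <- rep(CONDITION_LABELS, each = n_reps)
  reps <- rep(seq_len(n_reps), times = 4L)
  ids <- paste0(conds, "_", reps)
  counts <- matrix(base, n_genes, length(conds),
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)), ids))
  meta <- data.frame(sample_id = ids, condition = conds, replicate = reps,
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Two-condition matrix with explicit per-gene counts (list of length-2
# lists: counts in A then B), for exact-test fixtures.
two_cond_matrix <- function(counts_a, counts_b,
                            cond_a = "LL", cond_b = "HH") {
  stopifnot(nrow(counts_a) == nrow(counts_b))
  counts <- cbind(counts_a, counts_b)
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)
  ids <- c(paste0(cond_a, "_", seq_len(n_a)), paste0(cond_b, "_", seq_len(n_b)))
  colnames(counts) <- ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  meta <- data.frame(sample_id = ids,
                     condition = c(rep(cond_a, n_a), rep(cond_b, n_b)),
                     replicate = c(seq_len(n_a), seq_len(n_b)),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Small metabolite table from an intensity matrix (rows = compounds).
tiny_metabolome <- function(intensities, n_reps = ncol(intensities) / 2L,
                            mz = NULL) {
  n <- nrow(intensities)
  ids <- sprintf("C%03d", seq_len(n))
  rownames(intensities) <- ids
  conds <- rep(c("low", "high"), each = n_reps)
  reps <- rep(seq_len(n_reps), 2L)
  colnames(intensities) <- paste0(conds, "_", reps)
  meta <- data.frame(sample_id = colnames(intensities), condition = conds,
                     replicate = reps, stringsAsFactors = FALSE)
  if (is.null(mz)) mz <- seq(100, by = 10, length.out = n)
  compounds <- data.frame(compound_id = ids, mz = mz,
                          rt = seq(1, by = 0.5, length.out = n),
                          stringsAsFactors = FALSE)
  metabolite_table(compounds, intensities, meta)
}

# Independent exact-rational upper-tail oracle: direct term summation
# with choose(); valid for modest n.
binom_upper_oracle <- function(k, n, p) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Independent oracle for the conditional split test at phi = 0:
# enumerate the binomial conditional distribution of the group-A total.
binom_split_oracle <- function(s_a, s_b, n_a, n_b) {
  total <- s_a + s_b
  if (total == 0) return(1)
  f <- choose(total, 0:total) * (n_a / (n_a + n_b))^(0:total) *
    (n_b / (n_a + n_b))^(total:0)
  obs <- f[s_a + 1]
  min(1, sum(f[f <= obs * (1 + 1e-10)]))
}
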