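test_that("TPM matches its definition and normalizes columns to 1e6", {
  mat <- two_cond_matrix(matrix(c(10, 20), 2, 1), matrix(c(10, 20), 2, 1))
  mat$sample_meta$replicate <- c(1L, 1L)
  mat$effective_lengths <- c(g001 = 100, g002 = 400)
  tpm <- compute_tpm(mat)
  # rates (0.1, 0.05) -> (2/3, 1/3) of a million
  expect_equal(tpm[, 1], c(g001 = 666666.6667, g002 = 333333.3333),
               tolerance = 1e-8)
  expect_equal(unname(colSums(tpm)), rep(1e6, 2), tolerance = 1e-6)

  eq <- two_cond_matrix(matrix(10, 2, 2), matrix(c(10, 10, 0, 10), 2, 2))
  tpm2 <- compute_tpm(eq)
  expect_equal(unname(tpm2[, 1]), c(5e5, 5e5))   # equal counts, equal lengths
  expect_equal(tpm2[1, 4], 0)                    # zero count -> zero TPM

  zero <- matrix(c(10, 10, 0, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  zmat <- count_matrix(zero, data.frame(sample_id = c("s1", "s2"),
                                        condition = c("LL", "HH"),
                                        replicate = c(1L, 1L)))
  expect_error(compute_tpm(zmat), "s2")
})

test_that("bh_fdr reproduces the hand step-up and validates input", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  p <- sort(runif(50))
  expect_true(all(diff(bh_fdr(p)) >= 0))   # monotone on sorted input
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dispersion estimator recovers Poisson and NB truth", {
  n <- 2000L
  make <- function(phi, seed) {
    set.seed(seed)
    mu <- rlnorm(n, log(100), 1)
    draw <- function() if (phi == 0) rpois(n, mu) else
      rnbinom(n, size = 1 / phi, mu = mu)
    two_cond_matrix(cbind(draw(), draw(), draw()),
                    cbind(draw(), draw(), draw()))
  }
  expect_lte(estimate_dispersion(make(0, 11), c("LL", "HH")), 0.02)
  phi_hat <- estimate_dispersion(make(0.1, 12), c("LL", "HH"))
  expect_gte(phi_hat, 0.05)
  expect_lte(phi_hat, 0.2)

  const <- two_cond_matrix(matrix(100, 1, 3), matrix(100, 1, 3))
  expect_equal(estimate_dispersion(const, c("LL", "HH")), 0)

  single <- two_cond_matrix(matrix(100, 1, 1), matrix(100, 1, 3))
  expect_error(estimate_dispersion(single, c("LL", "HH")), "replicate")
})

test_that("exact test: identical groups give p = 1, phi=0 is the binomial split", {
  expect_equal(nb_exact_test(c(50, 50), c(50, 50), phi = 0.1), 1)
  expect_equal(nb_exact_test(c(50, 50), c(50, 50), phi = 0), 1)
  # A-total 0 vs B-total 10: two-sided binomial at p = 1/2
  expect_equal(nb_exact_test(c(0, 0), c(4, 6), phi = 0), 2 / 1024)
  expect_error(nb_exact_test(c(1, 2), c(3, 4), phi = -1), "phi")
  expect_error(nb_exact_test(numeric(0), c(1), phi = 0), "non-empty")
})

test_that("exact test at phi = 0 matches the enumeration oracle on seeded cases", {
  set.seed(2024)
  for (case in seq_len(100)) {
    n_a <- sample(2:4, 1); n_b <- sample(2:4, 1)
    a <- rpois(n_a, sample(1:10, 1))
    b <- rpois(n_b, sample(1:10, 1))
    if (sum(a) + sum(b) > 60) next
    expect_equal(nb_exact_test(a, b, phi = 0),
                 binom_split_oracle(sum(a), sum(b), n_a, n_b),
                 tolerance = 1e-12)
  }
})

test_that("exact test p-values are symmetric and valid under the null", {
  set.seed(5)
  # swapping the groups leaves p unchanged
  for (i in 1:20) {
    a <- rpois(3, 50); b <- rpois(3, 50)
    expect_equal(nb_exact_test(a, b, 0.1), nb_exact_test(b, a, 0.1),
                 tolerance = 1e-12)
  }
})

test_that("call_degs classifies by fold and FDR, with correct orientation", {
  set.seed(31)
  n <- 400L
  mu <- rlnorm(n, log(120), 0.8)
  eff <- rep(1, n); eff[1:20] <- 16   # planted 16-fold up in B
  draw <- function(m) rnbinom(n, size = 20, mu = m)
  mat <- two_cond_matrix(cbind(draw(mu), draw(mu), draw(mu)),
                         cbind(draw(mu * eff), draw(mu * eff), draw(mu * eff)))
  deg <- call_degs(mat, "LL", "HH")
  expect_equal(nrow(deg), n)
  expect_true(all(deg$q_value >= deg$p_value))
  planted <- deg$reg_class[1:20]
  expect_gte(mean(planted == "significant_up"), 0.9)
  # null genes controlled
  expect_lte(mean(deg$reg_class[-(1:20)] %in%
                    c("significant_up", "significant_down")), 0.01)
  # swapped comparison negates log2fc, keeps p
  rev <- call_degs(mat, "HH", "LL")
  expect_equal(rev$log2fc, -deg$log2fc, tolerance = 1e-12)
  expect_equal(rev$p_value, deg$p_value, tolerance = 1e-12)
  expect_error(call_degs(mat, "LL", "LL"), "itself")
})

test_that("a gene with identical counts in both conditions is unchanged", {
  # large constant background keeps the TPM composition comparable
  mat <- two_cond_matrix(matrix(c(100, 30, 10000), 3, 3),
                         matrix(c(100, 800, 10000), 3, 3))
  deg <- call_degs(mat, "LL", "HH", dispersion = 0.05)
  expect_equal(deg$reg_class[1], "unchanged")
  expect_equal(deg$reg_class[2], "significant_up")
  expect_equal(deg$reg_class[3], "unchanged")
})

test_that("summative calls sum isoforms and flag the discordant PGK-like case", {
  set.seed(77)
  # 5 isoforms of one enzyme: 4 planted up (+2.5 log2), 1 planted down
  # (-3 log2) with 40x the abundance of the others -> the abundant
  # isoform drags the summative sum down while the majority of
  # individually significant isoforms goes up -> discordant
  n_bg <- 50L
  mu_a <- c(100, 100, 100, 100, 4000, rep(1000, n_bg))
  mu_b <- mu_a * c(2^2.5, 2^2.5, 2^2.5, 2^2.5, 2^-3, rep(1, n_bg))
  n <- length(mu_a)
  draw <- function(m) t(replicate(3, rnbinom(n, size = 50, mu = m)))
  mat <- two_cond_matrix(t(draw(mu_a)), t(draw(mu_b)))
  singleton <- two_cond_matrix(matrix(100, 1, 3), matrix(410, 1, 3))
  ann <- data.frame(gene_id = rownames(mat$counts)[1:5],
                    product = "phosphoglycerate kinase",
                    ec_numbers = "2.7.2.3", pathway_ids = "",
                    isoform_group = "PGK", stringsAsFactors = FALSE)
  ann$ec_numbers <- as.list(ann$ec_numbers)
  ann$pathway_ids <- as.list(rep("", 5))
  summ <- summative_call(mat, ann, "ec", "LL", "HH",
                         analysis_config(), deg_records = NULL)
  expect_equal(summ$n_isoforms, 5L)
  expect_lt(summ$log2fc, 0)
  expect_gte(summ$n_significant_isoforms, 3L)
  expect_true(summ$discordant)

  # singleton group: summative log2fc equals the gene's own log2fc
  ann1 <- data.frame(gene_id = "g001", product = "x",
                     isoform_group = "E1", stringsAsFactors = FALSE)
  ann1$ec_numbers <- list("1.1.1.1"); ann1$pathway_ids <- list(character(0))
  s1 <- summative_call(singleton, ann1, "isoform_group", "LL", "HH")
  d1 <- call_degs(singleton, "LL", "HH")
  expect_equal(s1$log2fc, d1$log2fc)
  expect_false(s1$discordant)

  # all isoforms unchanged -> unchanged, not discordant
  flat <- two_cond_matrix(matrix(100, 3, 3), matrix(100, 3, 3))
  annf <- data.frame(gene_id = rownames(flat$counts), product = "y",
                     isoform_group = "E2", stringsAsFactors = FALSE)
  annf$ec_numbers <- replicate(3, character(0), simplify = FALSE)
  annf$pathway_ids <- replicate(3, character(0), simplify = FALSE)
  sf <- summative_call(flat, annf, "isoform_group", "LL", "HH")
  expect_equal(sf$reg_class, "unchanged")
  expect_false(sf$discordant)
  expect_error(summative_call(flat, annf, "ec", "LL", "HH"), "no gene")
})

test_that("exact test agrees with edgeR's exact test on a seeded matrix", {
  skip_if_not_installed("edgeR")
  set.seed(99)
  n <- 150L
  mu <- rlnorm(n, log(150), 0.7)
  eff <- rep(1, n); eff[1:10] <- 6
  phi <- 0.08
  draw <- function(m) rnbinom(n, size = 1 / phi, mu = m)
  mat <- two_cond_matrix(cbind(draw(mu), draw(mu), draw(mu)),
                         cbind(draw(mu * eff), draw(mu * eff), draw(mu * eff)))
  mine <- call_degs(mat, "LL", "HH", dispersion = phi)
  y <- edgeR::DGEList(counts = mat$counts,
                      group = mat$sample_meta$condition)
  y <- edgeR::calcNormFactors(y, method = "none")
  et <- edgeR::exactTest(y, pair = c("LL", "HH"), dispersion = phi)
  # same ranking and compatible significance at FDR 0.01
  expect_gt(cor(-log10(mine$p_value), -log10(et$table$PValue),
                method = "spearman"), 0.95)
  agree <- (mine$q_value < 0.01) == (p.adjust(et$table$PValue, "BH") < 0.01)
  expect_gte(mean(agree), 0.95)
})
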