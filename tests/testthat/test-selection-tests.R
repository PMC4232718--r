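test_that("chi-square tail handles boundaries and rejects bad input", {
  expect_identical(chi2_sf(0, 1), 1)
  expect_identical(chi2_sf(0, 7), 1)
  expect_error(chi2_sf(-1, 1), ">= 0")
  expect_error(chi2_sf(1, 0), "positive integer")
  ## monotone decreasing in the statistic
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(chi2_sf(x, 3)) < 0))
})

test_that("chi-square tail agrees with a series/continued-fraction oracle", {
  set.seed(71)
  xs <- c(1e-4, 0.5, 2, 10, 48.81, 100, 200, runif(20, 0, 200))
  for (df in c(1L, 2L, 5L, 24L, 30L)) {
    for (x in xs) {
      o <- oracle_chi2_sf(x, df)
      got <- chi2_sf(x, df)
      expect_lt(abs(got - o) / max(o, 1e-300), 1e-10)
    }
  }
})

test_that("lrt statistics reproduce published-style arithmetic", {
  r1 <- lrt_from_loglik(13033.12, 12711.16, df = 1)
  expect_equal(r1$stat, 643.92, tolerance = 1e-12)
  r2 <- lrt_from_loglik(12287.21, 11866.17, df = 1)
  expect_equal(r2$stat, 842.08, tolerance = 1e-12)
  ## identical likelihoods: stat 0, p 1
  r0 <- lrt_from_loglik(100, 100, df = 1)
  expect_identical(r0$stat, 0)
  expect_identical(r0$p, 1)
})

test_that("lrt on fits enforces nesting, df accounting, and convergence notes", {
  tr <- small_tagged_tree()
  sim <- simulate_alignment(tr, omega = 0.4, kappa = 2, n_codons = 120,
                            seed = 72)
  A <- fit_codon_model(sim$alignment, tr, "one_ratio", n_starts = 1)
  B <- fit_codon_model(sim$alignment, tr, "neutral", start = A, n_starts = 1)
  C <- fit_codon_model(sim$alignment, tr, "two_ratio", start = A, n_starts = 1)
  res <- lrt(B, A)
  expect_identical(res$df, 1L)
  expect_gte(res$stat, 0)
  res2 <- lrt(A, C)
  ## manual np audit: C frees one extra omega
  expect_identical(res2$df, C$np - A$np)
  expect_identical(C$np - A$np, 1L)
  expect_error(lrt(A, B), "nested")
  expect_error(lrt(C, A), "nested")
})

test_that("with no tagged foreground the two-ratio model collapses to one-ratio", {
  tr <- read_newick("((A:0.2,B:0.3)AB:0.1,C:0.4)R;", text = TRUE)
  sim <- simulate_alignment(tr, omega = 0.4, kappa = 2, n_codons = 100,
                            seed = 73)
  A <- fit_codon_model(sim$alignment, tr, "one_ratio", n_starts = 1)
  expect_warning(
    C <- fit_codon_model(sim$alignment, tr, "two_ratio", start = A,
                         n_starts = 1),
    "single branch partition")
  expect_equal(C$loglik, A$loglik, tolerance = 1e-6)
})

test_that("the ladder on relaxed-foreground data finds relaxation and keeps nesting order", {
  tr <- small_tagged_tree()
  sim <- simulate_alignment(tr, omega = c(0.26, 0.68), kappa = 2,
                            n_codons = 400, seed = 74)
  lad <- run_ladder(sim$alignment, tr, n_starts = 1)
  f <- lad$fits
  expect_lte(f$B$loglik, f$A$loglik + 1e-6)
  expect_lte(f$A$loglik, f$C$loglik + 1e-6)
  expect_lte(f$C$loglik, f$E$loglik + 1e-6)
  expect_lte(f$D$loglik, f$C$loglik + 1e-6)
  expect_gt(f$C$params$omega1, f$C$params$omega0)  # foreground above background
  expect_lt(lad$tests$A_vs_C$p, 0.05)
  expect_true(lad$verdict %in% c("partially_relaxed", "fully_relaxed"))
  tab <- ladder_table(lad)
  expect_identical(tab$model, c("A", "B", "C", "D", "E"))
  expect_true(all(tab$stat[-1] >= 0))
})

test_that("tagging the whole tree collapses clade model C to its null", {
  tr <- read_newick("((A:0.2,B:0.3)AB:0.1,C:0.4)R;", text = TRUE)
  tr <- tag_branches(tr, c("A", "B", "C"), 1L)
  sim <- simulate_alignment(tr, omega = 0.4, kappa = 2, n_codons = 120,
                            seed = 75)
  null_fit <- fit_codon_model(sim$alignment, tr, "M2a_rel", n_starts = 1)
  alt_fit <- fit_codon_model(sim$alignment, tr, "cladeC", start = null_fit,
                             n_starts = 1)
  expect_equal(alt_fit$loglik, null_fit$loglik, tolerance = 1e-4)
})

test_that("clade test recovers a divergent foreground class", {
  tr <- small_tagged_tree()
  set.seed(76)
  ## third class divergent: background 0.2, foreground above 1
  so_bg <- ifelse(runif(400) < 0.4, 0.05, ifelse(runif(400) < 0.5, 1, 0.2))
  so_fg <- ifelse(so_bg == 0.2, 1.6, so_bg)
  sim <- simulate_alignment(tr, omega = NA, kappa = 2, n_codons = 400,
                            seed = 76, site_omega = so_bg, site_omega_fg = so_fg)
  ct <- run_clade_test(sim$alignment, tr, n_starts = 1)
  expect_gte(ct$test$stat, 0)
  expect_gt(ct$omega3, ct$omega2)
})

test_that("site tests flag planted positively selected sites by NEB posterior", {
  tr8 <- read_newick(paste0("(((A:0.25,B:0.25)n1:0.12,(C:0.25,D:0.25)n2:0.12)",
                            "n5:0.1,((E:0.25,F:0.25)n3:0.12,",
                            "(G:0.25,H:0.25)n4:0.12)n6:0.1)R;"), text = TRUE)
  set.seed(77)
  n <- 2000L
  u <- runif(n)
  so <- ifelse(u < 0.05, 3, ifelse(u < 0.55, 0.05, 1))
  sim <- simulate_alignment(tr8, omega = NA, kappa = 2, n_codons = n,
                            seed = 77, site_omega = so)
  m1a <- fit_codon_model(sim$alignment, tr8, "M1a", n_starts = 1)
  m2a <- fit_codon_model(sim$alignment, tr8, "M2a", start = m1a, n_starts = 1)
  res <- lrt(m1a, m2a)
  expect_lt(res$p, 0.05)
  post <- neb_positive_posterior(sim$alignment, m2a)
  expect_length(post, n)
  planted <- which(so == 3)
  expect_gt(mean(post[planted] > 0.5), 0.5)
  ## class posteriors are probabilities
  expect_true(all(post >= 0 & post <= 1))
})
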