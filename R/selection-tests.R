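## Likelihood-ratio testing layer: chi-square tail probabilities, nested
## model comparison, the branch-model ladder (one-ratio / neutral /
## two-ratio / two-ratio-fg1 / free-ratio), clade and site model tests.

#' Upper-tail chi-square probability
#'
#' The survival function of the chi-square distribution, i.e. the
#' regularized upper incomplete gamma function Q(df/2, x/2), used for
#' every likelihood ratio test in the package. A validated wrapper over
#' R's `pchisq`, accurate in the far tail (p down to ~1e-300).
#'
#' @param x Test statistic, >= 0 (vectorized).
#' @param df Degrees of freedom, positive integer.
#' @return P(X >= x) for X ~ chi-square(df).
#' @examples
#' chi2_sf(0.93, 1)   # ~0.33
#' chi2_sf(48.81, 1)  # ~2.8e-12
#' @export
chi2_sf <- function(x, df) {
  if (any(!is.finite(x)) || any(x < 0)) stop("'x' must be finite and >= 0")
  if (any(df < 1) || any(df != round(df))) stop("'df' must be a positive integer")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood ratio test between two nested codon model fits
#'
#' Computes `2 * (lnL_alt - lnL_null)` (clipped at zero), degrees of
#' freedom from the free-parameter counts, and the chi-square upper-tail
#' p-value. Refuses non-nested model pairs. An unconverged fit is
#' reported in the result, never silently accepted. For the positive-class
#' boundary test (M8a vs M8) a 50:50 chi-square(0):chi-square(1) mixture
#' p-value is available via `boundary_mixture = TRUE`; the default is the
#' plain chi-square(1).
#'
#' @param null_fit,alt_fit `codon_fit` objects (null nested in
#'   alternative).
#' @param boundary_mixture Use the 50:50 boundary mixture null
#'   distribution (df must be 1).
#' @return Object of class `lrt_result`: list with `stat`, `df`, `p`,
#'   `null_model`, `alt_model`, `null_loglik`, `alt_loglik`, `warnings`.
#' @export
lrt <- function(null_fit, alt_fit, boundary_mixture = FALSE) {
  stopifnot(inherits(null_fit, "codon_fit"), inherits(alt_fit, "codon_fit"))
  nested <- list(
    neutral = c("one_ratio", "two_ratio", "two_ratio_fg1", "free_ratio"),
    one_ratio = c("two_ratio", "free_ratio"),
    two_ratio = c("free_ratio"),
    two_ratio_fg1 = c("two_ratio", "free_ratio"),
    M1a = "M2a", M8a = "M8", M2a_rel = "cladeC")
  ok <- alt_fit$model %in% nested[[null_fit$model]]
  if (!isTRUE(ok))
    stop("models '", null_fit$model, "' and '", alt_fit$model,
         "' are not a nested null/alternative pair")
  df <- alt_fit$np - null_fit$np
  if (df < 1L) stop("alternative must have more free parameters than the null")
  warn <- character(0)
  if (!null_fit$converged) warn <- c(warn, "null fit did not converge")
  if (!alt_fit$converged) warn <- c(warn, "alternative fit did not converge")
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  p <- if (boundary_mixture) {
    if (df != 1L) stop("boundary mixture defined for df = 1")
    if (stat == 0) 1 else 0.5 * chi2_sf(stat, 1L)
  } else chi2_sf(stat, df)
  structure(list(stat = stat, df = df, p = p,
                 null_model = null_fit$model, alt_model = alt_fit$model,
                 null_loglik = null_fit$loglik, alt_loglik = alt_fit$loglik,
                 warnings = warn), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2*dlnL = %.4f, df = %d, p = %.3g\n",
              x$null_model, x$alt_model, x$stat, x$df, x$p))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Likelihood ratio statistic from reported log-likelihoods
#'
#' Convenience for auditing published model tables: computes
#' `2 * (lnL_alt - lnL_null)` and its chi-square p-value directly from
#' log-likelihood values (accepts either log-likelihoods or the
#' conventional positive `-lnL` values, as long as both arguments use the
#' same sign convention).
#'
#' @param lnl_null,lnl_alt Log-likelihoods (or both as -lnL).
#' @param df Degrees of freedom.
#' @return A list with `stat` and `p`.
#' @export
lrt_from_loglik <- function(lnl_null, lnl_alt, df = 1L) {
  stat <- abs(2 * (lnl_alt - lnl_null))
  list(stat = stat, p = chi2_sf(stat, df))
}

## fit 'model', and if its lnL falls below the nested null's, refit from
## the null's solution so the nesting bound holds.
fit_at_least <- function(aln, tree, model, floor_fit, start, ...) {
  f <- fit_codon_model(aln, tree, model, start = start, ...)
  if (!is.null(floor_fit) && f$loglik < floor_fit$loglik - 1e-9) {
    f2 <- fit_codon_model(aln, tree, model, start = floor_fit,
                          n_starts = 1L, ...)
    if (f2$loglik > f$loglik) f <- f2
  }
  f
}

#' Branch-model relaxation ladder
#'
#' Fits the five branch models — A: one omega for all branches; B: omega
#' fixed at 1; C: two-ratio (background omega1, foreground omega2); D:
#' two-ratio with foreground omega2 fixed at 1; E: free omega per branch —
#' and runs the four standard comparisons B-vs-A (purifying selection
#' overall), A-vs-C (foreground differs: relaxation when omega2 > omega1),
#' D-vs-C (constraint not fully removed when rejected), C-vs-E
#' (heterogeneity beyond two ratios). Fits are warm-started along the
#' nesting chain so the likelihood ordering
#' lnL(B) <= lnL(A) <= lnL(C) <= lnL(E), lnL(D) <= lnL(C) holds.
#'
#' The verdict rule: if A-vs-C is significant (at `alpha`) and
#' omega2 > omega1, the foreground is `partially_relaxed` when D-vs-C is
#' also significant and `fully_relaxed` otherwise; if A-vs-C is not
#' significant but C-vs-E is, `heterogeneous`; otherwise `purifying`.
#'
#' @param aln Repaired `codon_aln`.
#' @param tree A `phylo` tree; foreground branches either already tagged
#'   (partition 1) or given via `foreground`.
#' @param foreground Optional tip set defining the foreground clade
#'   (tagged stem + descendants).
#' @param alpha Significance level for the verdict (default 0.05).
#' @param ... Passed to [fit_codon_model()] (e.g. `n_starts`, `seed`).
#' @return Object of class `ladder_report`: list with `fits` (A..E),
#'   `tests` (named `lrt_result`s), `omega` (ladder omega estimates),
#'   `verdict`.
#' @export
run_ladder <- function(aln, tree, foreground = NULL, alpha = 0.05, ...) {
  if (!is.null(foreground)) tree <- tag_branches(tree, foreground, tag = 1L)
  has_fg <- any(branch_tags(tree) > 0L)
  A <- fit_codon_model(aln, tree, "one_ratio", ...)
  B <- fit_at_least(aln, tree, "neutral", NULL, start = A, ...)
  if (has_fg) {
    C <- fit_at_least(aln, tree, "two_ratio", A, start = A, ...)
    D <- fit_at_least(aln, tree, "two_ratio_fg1", NULL, start = C, ...)
    if (D$loglik > C$loglik) C <- fit_at_least(aln, tree, "two_ratio", D,
                                               start = D, ...)
  } else {
    warning("no foreground branches tagged; models C and D collapse to A and B")
    C <- A; D <- B
  }
  estart <- C$params
  om_edge <- rep(estart$omega0 %||% estart$omega %||% 0.4,
                 length(postorder_edges(tree)$tags))
  tags_po <- postorder_edges(tree)$tags
  if (!is.null(estart$omega1)) om_edge[tags_po > 0L] <- estart$omega1
  estart_list <- c(estart, stats::setNames(as.list(om_edge),
                                           paste0("omega_e", seq_along(om_edge))))
  Efit <- fit_at_least(aln, tree, "free_ratio", C, start = estart_list, ...)

  tests <- list(
    B_vs_A = lrt(B, A),
    A_vs_C = if (has_fg) lrt(A, C) else NULL,
    D_vs_C = if (has_fg) lrt(D, C) else NULL,
    C_vs_E = lrt(C, Efit))
  om1 <- if (has_fg) C$params$omega0 else A$params$omega
  om2 <- if (has_fg) C$params$omega1 else A$params$omega
  relaxed <- has_fg && tests$A_vs_C$p < alpha && om2 > om1
  verdict <- if (relaxed && tests$D_vs_C$p < alpha) "partially_relaxed"
  else if (relaxed) "fully_relaxed"
  else if (tests$C_vs_E$p < alpha) "heterogeneous"
  else "purifying"
  structure(list(
    fits = list(A = A, B = B, C = C, D = D, E = Efit),
    tests = tests,
    omega = c(omega_A = unname(A$params$omega),
              omega1_C = unname(om1), omega2_C = unname(om2)),
    alpha = alpha, verdict = verdict), class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  cat("Branch-model ladder\n")
  tab <- ladder_table(x)
  print(tab, row.names = FALSE)
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Table-style view of a ladder report
#'
#' One row per model with omega estimates, -lnL, np, and the comparison
#' statistics, mirroring the conventional published layout of codon-model
#' LRT tables.
#'
#' @param x A `ladder_report`.
#' @return A data.frame.
#' @export
ladder_table <- function(x) {
  f <- x$fits
  fmt_om <- function(fit) {
    if (is.null(fit$omega)) return("site classes")
    if (length(fit$omega) > 3L) return("variable by branch")
    paste(sprintf("%s=%.5f", names(fit$omega), fit$omega), collapse = " ")
  }
  cmp <- c(NA, "B vs. A", "A vs. C", "D vs. C", "C vs. E")
  tst <- list(NULL, x$tests$B_vs_A, x$tests$A_vs_C, x$tests$D_vs_C,
              x$tests$C_vs_E)
  data.frame(
    model = c("A", "B", "C", "D", "E"),
    omega = vapply(f, fmt_om, ""),
    neg_lnL = vapply(f, function(z) -z$loglik, 0),
    np = vapply(f, `[[`, 0L, "np"),
    comparison = cmp,
    stat = vapply(tst, function(z) if (is.null(z)) NA_real_ else z$stat, 0),
    p = vapply(tst, function(z) if (is.null(z)) NA_real_ else z$p, 0),
    stringsAsFactors = FALSE)
}

#' Clade model C test for divergent selection
#'
#' Fits the null M2a_rel (three site classes, the third with one omega
#' shared by all branches) and clade model C (the third class's omega
#' differs between the background partition and the designated clade),
#' compares them with a 1-df LRT, and reports the divergent-class omegas.
#'
#' @param aln Repaired `codon_aln`.
#' @param tree A `phylo` tree; clade branches either tagged (partition 1)
#'   or given via `clade`.
#' @param clade Optional tip set marking the clade (stem + descendants
#'   tagged).
#' @param ... Passed to [fit_codon_model()].
#' @return List with `null_fit`, `alt_fit`, `test` (`lrt_result`),
#'   `omega2` (background divergent-class omega), `omega3` (clade
#'   divergent-class omega).
#' @export
run_clade_test <- function(aln, tree, clade = NULL, ...) {
  if (!is.null(clade)) tree <- tag_branches(tree, clade, tag = 1L)
  null_fit <- fit_codon_model(aln, tree, "M2a_rel", ...)
  alt_fit <- fit_at_least(aln, tree, "cladeC", null_fit, start = null_fit, ...)
  list(null_fit = null_fit, alt_fit = alt_fit,
       test = lrt(null_fit, alt_fit),
       omega2 = unname(alt_fit$params$omega2),
       omega3 = unname(alt_fit$params$omega3))
}

#' Site-model tests for positively selected sites
#'
#' Runs the two standard site-model comparisons, M1a vs M2a and M8a vs
#' M8, and computes naive empirical Bayes (NEB) posterior probabilities
#' of the positive site class under each alternative model.
#'
#' @param aln Repaired `codon_aln`.
#' @param tree A `phylo` tree.
#' @param ... Passed to [fit_codon_model()].
#' @return List with `fits` (M1a, M2a, M8a, M8), `tests`
#'   (`M1a_vs_M2a`, `M8a_vs_M8` as `lrt_result`s), and
#'   `positive_site_posterior` (matrix: sites x 2 models, NEB posterior
#'   of the omega > 1 class).
#' @export
run_site_tests <- function(aln, tree, ...) {
  m1a <- fit_codon_model(aln, tree, "M1a", ...)
  m2a <- fit_at_least(aln, tree, "M2a", m1a, start = m1a, ...)
  m8a <- fit_codon_model(aln, tree, "M8a", ...)
  m8 <- fit_at_least(aln, tree, "M8", m8a, start = m8a, ...)
  post <- cbind(M2a = neb_positive_posterior(aln, m2a),
                M8 = neb_positive_posterior(aln, m8))
  list(fits = list(M1a = m1a, M2a = m2a, M8a = m8a, M8 = m8),
       tests = list(M1a_vs_M2a = lrt(m1a, m2a),
                    M8a_vs_M8 = lrt(m8a, m8)),
       positive_site_posterior = post)
}

#' Naive empirical Bayes posterior of the positive site class
#'
#' Posterior probability, per codon site, that the site belongs to the
#' fitted model's omega > 1 class (the last class of M2a/M8;
#' all-zero for models without such a class).
#'
#' @param aln The alignment used for the fit.
#' @param fit A site-model `codon_fit`.
#' @return Numeric vector over sites.
#' @export
neb_positive_posterior <- function(aln, fit) {
  states <- if (inherits(aln, "codon_aln")) codon_states(aln) else aln
  states <- states[fit$tree$tip.label, , drop = FALSE]
  ed <- postorder_edges(fit$tree)
  ed$lengths <- unname(fit$params$t[as.character(ed$edge[, 2L])])
  pat <- site_patterns(states)
  res <- loglik_core(pat, ed, fit$classes, fit$kappa, fit$pi, per_site = TRUE)
  ll <- res$class_loglik
  w <- fit$classes$weights
  M <- apply(ll, 1L, max)
  num <- exp(ll - M) * rep(w, each = nrow(ll))
  post <- num / rowSums(num)
  pos_class <- which(fit$classes$omega[, 1L] > 1)
  p <- if (length(pos_class)) rowSums(post[, pos_class, drop = FALSE]) else
    rep(0, nrow(post))
  p[res$site_index]
}
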