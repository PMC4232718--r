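## Maximum-likelihood fitting of codon models: the package's central
## modelling function. Parameters are optimized on transformed scales
## (log branch lengths and rates, logit proportions) by bounded
## quasi-Newton (L-BFGS-B) with seeded multi-start.

.fit_bounds <- list(t = c(1e-6, 50), kappa = c(1e-3, 100),
                    omega = c(1e-4, 20), shape = c(0.05, 99))

## run expr with a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## model-specific free-parameter layout ---------------------------------------
## Each entry: names of natural-scale parameters (beyond t, kappa), their
## transform to the optimizer scale and back, counts depending on the tree.
model_layout <- function(model, npart, E) {
  lg <- log
  ex <- exp
  bO <- log(.fit_bounds$omega)
  bS <- log(.fit_bounds$shape)
  par1 <- function(nm, init, lower, upper, fwd = lg, bwd = ex)
    list(names = nm, init = fwd(init), lower = lower, upper = upper,
         fwd = fwd, bwd = bwd)
  blocks <- switch(model,
    one_ratio = list(par1("omega", 0.4, bO[1], bO[2])),
    neutral = list(),
    two_ratio = list(par1(paste0("omega", seq_len(npart) - 1L),
                          rep(0.4, npart), rep(bO[1], npart), rep(bO[2], npart))),
    two_ratio_fg1 = list(par1("omega0", 0.4, bO[1], bO[2])),
    free_ratio = list(par1(paste0("omega_e", seq_len(E)),
                           rep(0.4, E), rep(bO[1], E), rep(bO[2], E))),
    M1a = list(
      par1("p0", 0.8, -15, 15, stats::qlogis, stats::plogis),
      par1("omega0", 0.1, -15, 15, stats::qlogis, stats::plogis)),
    M2a = list(
      par1("p0", 0.7, -15, 15, stats::qlogis, stats::plogis),
      par1("p1r", 0.7, -15, 15, stats::qlogis, stats::plogis),
      par1("omega0", 0.1, -15, 15, stats::qlogis, stats::plogis),
      par1("omega2m1", 1, -15, log(19), lg, ex)),
    M8 = list(
      par1("p0", 0.9, -15, 15, stats::qlogis, stats::plogis),
      par1("p", 0.5, bS[1], bS[2]),
      par1("q", 1.5, bS[1], bS[2]),
      par1("omega_sm1", 0.5, -15, log(19), lg, ex)),
    M8a = list(
      par1("p0", 0.9, -15, 15, stats::qlogis, stats::plogis),
      par1("p", 0.5, bS[1], bS[2]),
      par1("q", 1.5, bS[1], bS[2])),
    cladeC = list(
      par1("p0", 0.7, -15, 15, stats::qlogis, stats::plogis),
      par1("p1r", 0.7, -15, 15, stats::qlogis, stats::plogis),
      par1("omega0", 0.1, -15, 15, stats::qlogis, stats::plogis),
      par1("omega2", 0.8, bO[1], bO[2]),
      par1("omega3", 0.8, bO[1], bO[2])),
    M2a_rel = list(
      par1("p0", 0.7, -15, 15, stats::qlogis, stats::plogis),
      par1("p1r", 0.7, -15, 15, stats::qlogis, stats::plogis),
      par1("omega0", 0.1, -15, 15, stats::qlogis, stats::plogis),
      par1("omega2", 0.8, bO[1], bO[2])),
    stop("unknown model '", model, "'")
  )
  list(names = unlist(lapply(blocks, `[[`, "names")),
       init = unlist(lapply(blocks, `[[`, "init")),
       lower = unlist(lapply(blocks, `[[`, "lower")),
       upper = unlist(lapply(blocks, `[[`, "upper")),
       blocks = blocks)
}

## natural-scale params from the model block of theta
decode_model_pars <- function(layout, theta_model) {
  out <- list()
  i <- 0L
  for (b in layout$blocks) {
    k <- length(b$names)
    v <- b$bwd(theta_model[i + seq_len(k)])
    names(v) <- b$names
    out <- c(out, as.list(v))
    i <- i + k
  }
  out
}

## classes/omega_edge for loglik_core from natural model parameters
model_classes <- function(model, pars, tags, n_beta = 10L) {
  E <- length(tags)
  npart <- max(tags) + 1L
  one <- function(om_part) {
    list(classes = list(weights = 1,
                        omega = matrix(om_part, 1L, length(om_part))),
         omega_edge = NULL)
  }
  switch(model,
    one_ratio = one(rep(pars$omega, max(npart, 1L))),
    neutral = one(rep(1, max(npart, 1L))),
    two_ratio = one(unlist(pars[paste0("omega", seq_len(npart) - 1L)])),
    two_ratio_fg1 = one(c(pars$omega0, rep(1, npart - 1L))),
    free_ratio = list(
      classes = list(weights = 1, omega = matrix(1, 1L, 1L)),
      omega_edge = matrix(unlist(pars[paste0("omega_e", seq_len(E))]), 1L, E)),
    M1a = list(classes = site_classes("M1a", pars), omega_edge = NULL),
    M2a = {
      p <- pars; p$p1 <- (1 - p$p0) * p$p1r; p$omega2 <- 1 + p$omega2m1
      list(classes = site_classes("M2a", p), omega_edge = NULL)
    },
    M8 = {
      p <- pars; p$omega_s <- 1 + p$omega_sm1; p$n_beta_categories <- n_beta
      list(classes = site_classes("M8", p), omega_edge = NULL)
    },
    M8a = {
      p <- pars; p$n_beta_categories <- n_beta
      list(classes = site_classes("M8a", p), omega_edge = NULL)
    },
    cladeC = ,
    M2a_rel = {
      p <- pars; p$p1 <- (1 - p$p0) * p$p1r
      list(classes = site_classes(model, p), omega_edge = NULL)
    })
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Fits branch, site, or clade dN/dS models to a codon alignment on a
#' phylogeny. Branch lengths, kappa and all model parameters are estimated
#' jointly by bounded quasi-Newton optimization (multi-start, seeded).
#' Foreground/background structure comes from the tree's branch partition
#' tags (see [tag_branches()], [read_newick()]).
#'
#' Models:
#' \describe{
#'   \item{`one_ratio`}{a single omega for all branches (branch model A).}
#'   \item{`neutral`}{omega fixed at 1 (model B).}
#'   \item{`two_ratio`}{one omega per branch partition (model C when the
#'     tree has a foreground partition).}
#'   \item{`two_ratio_fg1`}{background omega free, foreground omega fixed
#'     at 1 (model D).}
#'   \item{`free_ratio`}{every branch its own omega (model E).}
#'   \item{`M1a`, `M2a`, `M8`, `M8a`}{site-class models; `M8` uses a
#'     discretized beta (default 10 equal-probability categories
#'     represented by their means) plus a positive class, `M8a` pins that
#'     class at omega = 1.}
#'   \item{`cladeC`, `M2a_rel`}{clade models: three site classes, the third
#'     with partition-specific omega (`cladeC`) or a shared omega
#'     (`M2a_rel`, the null).}
#' }
#'
#' The free-parameter count `np` follows the convention of mainstream
#' codon-model software: number of branches + 1 (kappa) + model-specific
#' free parameters; codon frequencies counted from data are not included.
#'
#' @param aln A `codon_aln` without in-frame stops (see
#'   [repair_alignment()]).
#' @param tree Tagged `phylo` tree; tip labels must be present in `aln`.
#' @param model Model name (see Details).
#' @param frequencies Codon frequency scheme passed to
#'   [estimate_frequencies()], or a 61-vector `pi` via the `pi` argument.
#' @param pi Optional explicit codon frequencies (overrides
#'   `frequencies`).
#' @param start Optional warm start: a named list with any of `t` (branch
#'   lengths named by child node id), `kappa`, and natural-scale model
#'   parameters (`omega`, `omega0`, `p0`, ...), or a `codon_fit` whose
#'   overlapping parameters are reused.
#' @param n_starts Number of optimization starts (first from `start`/
#'   defaults, the rest jittered; default 3).
#' @param seed Seed for start jitter (default 1234).
#' @param n_beta_categories Categories for the M8/M8a beta (default 10).
#' @param control Passed to [stats::optim()] (`maxit`, `factr`).
#' @return An object of class `codon_fit`.
#' @seealso [lrt()], [run_ladder()], [run_site_tests()],
#'   [run_clade_test()]
#' @export
fit_codon_model <- function(aln, tree,
                            model = c("one_ratio", "neutral", "two_ratio",
                                      "two_ratio_fg1", "free_ratio",
                                      "M1a", "M2a", "M8", "M8a",
                                      "cladeC", "M2a_rel"),
                            frequencies = "F3x4", pi = NULL,
                            start = NULL, n_starts = 3L, seed = 1234L,
                            n_beta_categories = 10L, control = list()) {
  model <- match.arg(model)
  states <- if (inherits(aln, "codon_aln")) codon_states(aln) else aln
  if (!all(tree$tip.label %in% rownames(states)))
    stop("alignment is missing taxa present in the tree")
  states <- states[tree$tip.label, , drop = FALSE]
  ed <- postorder_edges(tree)
  E <- nrow(ed$edge)
  npart <- max(ed$tags) + 1L
  if (model %in% c("two_ratio", "two_ratio_fg1", "cladeC", "M2a_rel") &&
      npart < 2L)
    warning("model '", model, "' requested but the tree has a single ",
            "branch partition; it collapses to its background-only form")
  if (is.null(pi))
    pi <- estimate_frequencies(if (inherits(aln, "codon_aln")) aln else NULL,
                               scheme = frequencies)
  pat <- site_patterns(states)

  layout <- model_layout(model, npart, E)
  bT <- log(.fit_bounds$t); bK <- log(.fit_bounds$kappa)
  t0 <- ed$lengths
  if (is.null(t0) || any(!is.finite(t0))) t0 <- rep(0.1, E)
  t0 <- pmin(pmax(t0, .fit_bounds$t[1] * 2), .fit_bounds$t[2] / 2)
  theta0 <- c(log(t0), log(2), layout$init)
  lower <- c(rep(bT[1], E), bK[1], layout$lower)
  upper <- c(rep(bT[2], E), bK[2], layout$upper)

  ## warm start mapping
  if (inherits(start, "codon_fit")) start <- start$params
  if (!is.null(start)) {
    if (!is.null(start$t)) {
      tw <- start$t[as.character(ed$edge[, 2L])]
      ok <- !is.na(tw)
      theta0[which(ok)] <- log(pmin(pmax(tw[ok], .fit_bounds$t[1]),
                                    .fit_bounds$t[2]))
    }
    if (!is.null(start$kappa)) theta0[E + 1L] <- log(start$kappa)
    i <- E + 1L
    for (b in layout$blocks) {
      for (j in seq_along(b$names)) {
        nm <- b$names[j]
        v <- start[[nm]]
        ## allow seeding every partition/branch omega from a single 'omega'
        if (is.null(v) && grepl("^omega", nm) &&
            nm %in% c(paste0("omega", 0:9), paste0("omega_e", seq_len(E))) &&
            !is.null(start$omega))
          v <- start$omega
        if (!is.null(v)) theta0[i + j] <- b$fwd(min(max(v, 1e-6), 19.9))
      }
      i <- i + length(b$names)
    }
  }
  theta0 <- pmin(pmax(theta0, lower), upper)

  dec_cache <- new.env(parent = emptyenv())
  negll <- function(theta) {
    tv <- exp(theta[seq_len(E)])
    kappa <- exp(theta[E + 1L])
    pars <- decode_model_pars(layout, theta[-seq_len(E + 1L)])
    mc <- model_classes(model, pars, ed$tags, n_beta_categories)
    edl <- ed; edl$lengths <- tv
    -loglik_core(pat, edl, mc$classes, kappa, pi,
                 omega_edge = mc$omega_edge, cache = dec_cache)$loglik
  }

  ctrl <- utils::modifyList(list(maxit = 500L, factr = 1e7), control)
  starts <- list(theta0)
  if (n_starts > 1L) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 1L), function(i)
      pmin(pmax(theta0 + stats::rnorm(length(theta0), 0, 0.4), lower), upper)))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (th in starts) {
    opt <- tryCatch(
      stats::optim(th, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed for all starts")

  theta <- best$par
  tv <- exp(theta[seq_len(E)])
  kappa <- exp(theta[E + 1L])
  pars <- decode_model_pars(layout, theta[-seq_len(E + 1L)])
  mc <- model_classes(model, pars, ed$tags, n_beta_categories)

  ## fitted branch lengths back onto the tree (original edge order)
  fitted_tree <- tree
  m <- match(paste(tree$edge[, 1L], tree$edge[, 2L]),
             paste(ed$edge[, 1L], ed$edge[, 2L]))
  fitted_tree$edge.length <- tv[m]

  params <- c(list(t = stats::setNames(tv, ed$edge[, 2L]), kappa = kappa),
              pars)
  ## user-facing omega summary on the natural scale
  omega <- switch(model,
    one_ratio = c(omega = unname(pars$omega)),
    neutral = c(omega = 1),
    two_ratio = unlist(pars[paste0("omega", seq_len(npart) - 1L)]),
    two_ratio_fg1 = c(omega0 = unname(pars$omega0), omega1 = 1),
    free_ratio = stats::setNames(unlist(pars), paste0("branch_", ed$edge[, 2L])),
    NULL)

  structure(list(
    model = model, loglik = -best$value, np = E + 1L + length(layout$names),
    kappa = kappa, omega = omega, params = params,
    classes = mc$classes, pi = pi,
    frequencies = attr(pi, "scheme") %||% "supplied",
    tree = fitted_tree, n_codons = ncol(states),
    n_patterns = ncol(pat$patterns),
    converged = best$convergence == 0L, optim = best[c("counts", "message")],
    seed = seed, call = match.call()),
    class = "codon_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codon_fit <- function(x, ...) {
  cat("Codon model fit (", x$model, ")\n", sep = "")
  cat("  taxa: ", length(x$tree$tip.label),
      "   codons: ", x$n_codons,
      "   site patterns: ", x$n_patterns, "\n", sep = "")
  cat(sprintf("  lnL = %.4f   np = %d   kappa = %.4f%s\n",
              x$loglik, x$np, x$kappa,
              if (!x$converged) "   [NOT CONVERGED]" else ""))
  if (!is.null(x$omega) && length(x$omega) <= 8L) {
    cat("  omega: ", paste(sprintf("%s = %.5f", names(x$omega), x$omega),
                           collapse = ", "), "\n", sep = "")
  } else if (!is.null(x$omega)) {
    cat("  omega: free per branch (", length(x$omega), " values)\n", sep = "")
  } else {
    cls <- x$classes
    cat("  site classes (proportion, omega[background/foreground]):\n")
    for (k in seq_along(cls$weights))
      cat(sprintf("    %6.4f  %.5f / %.5f\n", cls$weights[k],
                  cls$omega[k, 1L], cls$omega[k, ncol(cls$omega)]))
  }
  invisible(x)
}

#' @export
summary.codon_fit <- function(object, ...) {
  print(object)
  cat("  tree length: ",
      sprintf("%.4f", sum(object$tree$edge.length)),
      " expected substitutions/codon\n", sep = "")
  invisible(object)
}

#' @export
coef.codon_fit <- function(object, ...) {
  p <- object$params
  p$t <- NULL
  unlist(p)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$loglik, df = object$np, nobs = object$n_codons,
            class = "logLik")
}

#' Simulate alignments from a fitted codon model
#'
#' Draws new codon alignments from the fitted tree, kappa, frequencies and
#' omega structure (branch models use their per-partition or per-branch
#' omega; site-mixture models draw a class per site).
#'
#' @param object A `codon_fit`.
#' @param nsim Number of alignments.
#' @param seed Seed (required for reproducibility; default 1).
#' @param n_codons Number of codons (default: as fitted).
#' @param ... Unused.
#' @return A list of `codon_aln` objects (length `nsim`).
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = 1L,
                               n_codons = object$n_codons, ...) {
  cls <- object$classes
  ed <- postorder_edges(object$tree)
  lapply(seq_len(nsim), function(i) {
    s <- seed + i - 1L
    k <- with_seed(s * 11L,
                   sample.int(length(cls$weights), n_codons, TRUE,
                              prob = cls$weights))
    site_om <- cls$omega[k, 1L]
    fg_om <- cls$omega[k, ncol(cls$omega), drop = TRUE]
    if (!all(fg_om == site_om)) {
      sim <- simulate_alignment(object$tree, omega = NA, kappa = object$kappa,
                                pi = object$pi, n_codons = n_codons, seed = s,
                                site_omega = site_om, site_omega_fg = fg_om)
    } else {
      sim <- simulate_alignment(object$tree, omega = NA, kappa = object$kappa,
                                pi = object$pi, n_codons = n_codons, seed = s,
                                site_omega = site_om)
    }
    sim$alignment
  })
}
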