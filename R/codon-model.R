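## Goldman-Yang style codon substitution machinery: rate matrix over the 61
## sense codons, spectral transition probabilities, site-class mixtures and
## the pruning log-likelihood (C++ kernel in src/pruning.cpp).

## ---- single-nucleotide change structure ------------------------------------

## 61x61 integer matrix classifying each codon pair:
## 0 = same codon or >1 nucleotide difference,
## 1 = synonymous transversion, 2 = synonymous transition,
## 3 = nonsynonymous transversion, 4 = nonsynonymous transition.
## Computed once and cached.
.pkg_cache <- new.env(parent = emptyenv())

codon_change_types <- function(code = genetic_code()) {
  if (!is.null(.pkg_cache$types)) return(.pkg_cache$types)
  sense <- code$sense_codons
  aa <- code$codon_to_aa[sense]
  n <- length(sense)
  bases <- do.call(rbind, strsplit(sense, "", fixed = TRUE))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  ty <- matrix(0L, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- which(bases[i, ] != bases[j, ])
    if (length(diff) != 1L) next
    is_ts <- transitions[[bases[i, diff]]] == bases[j, diff]
    is_syn <- aa[i] == aa[j]
    ty[i, j] <- if (is_syn) (if (is_ts) 2L else 1L) else (if (is_ts) 4L else 3L)
  }
  .pkg_cache$types <- ty
  ty
}

#' Codon substitution rate matrix
#'
#' Builds the 61x61 reversible codon generator Q of the Goldman-Yang
#' parameterization with target-codon frequencies: for codons i != j
#' differing at exactly one nucleotide,
#' `q_ij = pi_j`, `kappa * pi_j`, `omega * pi_j`, or `omega * kappa * pi_j`
#' for synonymous transversions, synonymous transitions, nonsynonymous
#' transversions and nonsynonymous transitions respectively; zero for
#' multi-nucleotide changes. The diagonal makes rows sum to zero and the
#' matrix is scaled so the expected substitution rate at stationarity,
#' `-sum(pi_i q_ii)`, equals 1 (branch lengths are then expected
#' substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param pi Sense-codon frequencies from [estimate_frequencies()].
#' @return 61x61 matrix with attributes `pi`, `kappa`, `omega`.
#' @export
build_generator <- function(kappa, omega, pi) {
  if (!is.finite(kappa) || kappa <= 0) stop("'kappa' must be finite and > 0")
  if (!is.finite(omega) || omega < 0) stop("'omega' must be finite and >= 0")
  if (length(pi) != 61L || any(!is.finite(pi)) || any(pi <= 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("'pi' must be 61 positive frequencies summing to 1")
  ty <- codon_change_types()
  mult <- c(0, 1, kappa, omega, omega * kappa)[ty + 1L]
  Q <- matrix(mult, 61L, 61L) * rep(pi, each = 61L)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  dimnames(Q) <- dimnames(ty)
  attr(Q, "pi") <- pi
  attr(Q, "kappa") <- kappa
  attr(Q, "omega") <- omega
  Q
}

## pi-symmetrized spectral decomposition of Q: returns L, R, lambda with
## P(t) = L diag(exp(lambda t)) R.
decompose_generator <- function(Q, pi = attr(Q, "pi")) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))          # D^1/2 Q D^-1/2, symmetric
  S <- (S + t(S)) / 2               # symmetrize rounding noise
  eig <- eigen(S, symmetric = TRUE)
  list(L = eig$vectors / d,          # D^-1/2 V
       R = t(eig$vectors) * rep(d, each = 61L),  # V' D^1/2
       lambda = eig$values)
}

#' Transition probability matrix of a codon generator
#'
#' `P(t) = exp(Qt)` computed through the pi-weighted symmetric
#' eigendecomposition of `Q`; entries that round below zero are clipped at
#' zero.
#'
#' @param Q Generator from [build_generator()].
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @return 61x61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("'t' must be finite and >= 0")
  dec <- decompose_generator(Q)
  P <- .cpp_transition_cubes(dec$L, dec$R, dec$lambda, t)[, , 1L]
  dimnames(P) <- dimnames(Q)
  P
}

## ---- site classes ----------------------------------------------------------

## Discretize beta(p, q) into k equal-probability categories represented by
## their conditional means.
beta_category_means <- function(p, q, k = 10L) {
  brk <- stats::qbeta(seq(0, 1, length.out = k + 1L), p, q)
  upper <- stats::pbeta(brk[-1L], p + 1, q)
  lower <- stats::pbeta(brk[-(k + 1L)], p + 1, q)
  (upper - lower) * (p / (p + q)) * k
}

#' Site classes of a codon model
#'
#' Expands a site/clade model specification into its mixture of
#' (proportion, omega) classes. For clade models the omega of the divergent
#' class differs between branch partitions, so omegas are returned as a
#' matrix with one column per partition (column 1 = background partition 0,
#' column 2 = foreground partition 1).
#'
#' @param model One of `"M1a"`, `"M2a"`, `"M8"`, `"M8a"`, `"cladeC"`,
#'   `"M2a_rel"`.
#' @param params Named list of hyperparameters: proportions `p0`, `p1`;
#'   omegas `omega0` (in (0,1)), `omega2`, `omega3`; beta shapes `p`, `q`;
#'   positive-class `omega_s`; `n_beta_categories` (default 10).
#' @return A list with `weights` (proportions summing to 1) and `omega`
#'   (classes x partitions matrix).
#' @export
site_classes <- function(model, params) {
  gp <- function(nm, default = NULL) {
    if (!is.null(params[[nm]])) params[[nm]]
    else if (!is.null(default)) default
    else stop("missing site-class parameter '", nm, "'")
  }
  two <- function(x) matrix(x, length(x), 2L)  # same omega in both partitions
  out <- switch(model,
    M1a = {
      p0 <- gp("p0")
      list(weights = c(p0, 1 - p0), omega = two(c(gp("omega0"), 1)))
    },
    M2a = {
      p0 <- gp("p0"); p1 <- gp("p1")
      list(weights = c(p0, p1, 1 - p0 - p1),
           omega = two(c(gp("omega0"), 1, gp("omega2"))))
    },
    M8 = ,
    M8a = {
      p0 <- gp("p0"); k <- gp("n_beta_categories", 10L)
      ws <- if (model == "M8a") 1 else gp("omega_s")
      bm <- beta_category_means(gp("p"), gp("q"), k)
      list(weights = c(rep(p0 / k, k), 1 - p0), omega = two(c(bm, ws)))
    },
    cladeC = ,
    M2a_rel = {
      p0 <- gp("p0"); p1 <- gp("p1")
      o2 <- gp("omega2")
      o3 <- if (model == "M2a_rel") o2 else gp("omega3")
      list(weights = c(p0, p1, 1 - p0 - p1),
           omega = cbind(c(gp("omega0"), 1, o2), c(gp("omega0"), 1, o3)))
    },
    stop("unknown site-class model '", model, "'")
  )
  if (any(out$weights < -1e-12) || abs(sum(out$weights) - 1) > 1e-8)
    stop("class proportions must lie in the simplex")
  out$weights <- pmax(out$weights, 0)
  out
}

## Raw mean substitution rate of the unnormalized GY94 generator with the
## given parameters (used to put site classes on a common scale: within a
## mixture, classes are scaled by r_k / rho with rho = sum_k w_k r_k, the
## convention of mainstream codon-model software, so omega > 1 classes
## evolve faster, not just differently).
raw_mean_rate <- function(kappa, omega, pi) {
  ty <- codon_change_types()
  pp <- pi %o% pi
  s_tv <- sum(pp[ty == 1L]); s_ts <- sum(pp[ty == 2L])
  n_tv <- sum(pp[ty == 3L]); n_ts <- sum(pp[ty == 4L])
  s_tv + kappa * s_ts + omega * (n_tv + kappa * n_ts)
}

## ---- pruning likelihood ----------------------------------------------------

## Postorder view of a tagged tree: edge matrix, lengths and tags in
## postorder row order.
postorder_edges <- function(tree) {
  tags <- branch_tags(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  ord <- match(paste(po$edge[, 1L], po$edge[, 2L]), key)
  list(edge = po$edge, lengths = tree$edge.length[ord], tags = tags[ord],
       ntip = length(tree$tip.label))
}

## Compress codon-state columns into unique site patterns.
## states: taxa x sites integer matrix (NA = missing).
site_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  ux <- !duplicated(key)
  pats <- states[, ux, drop = FALSE]
  pats[is.na(pats)] <- 0L
  list(patterns = pats - 1L,                  # 0-based, -1 missing
       weights = as.numeric(table(key)[key[ux]]),
       index = match(key, key[ux]))
}

## Core mixture log-likelihood.
## pat: list from site_patterns (rows must be ordered as tree tip indices);
## ed: list from postorder_edges; classes: list(weights, omega) where omega
## is classes x npartition matrix; returns total lnL plus per-class
## per-pattern log-likelihood matrix (for empirical Bayes).
loglik_core <- function(pat, ed, classes, kappa, pi,
                        omega_edge = NULL, per_site = FALSE, cache = NULL) {
  E <- nrow(ed$edge)
  nclass <- length(classes$weights)
  if (is.null(omega_edge)) {
    omega_edge <- classes$omega[, ed$tags + 1L, drop = FALSE]  # nclass x E
  }
  stopifnot(ncol(omega_edge) == E)
  omu <- unique(as.vector(omega_edge))
  ## generator decompositions, memoized per (kappa, omega) across calls
  ## (numeric-gradient evaluations change one parameter at a time, so most
  ## decompositions can be reused)
  decs <- lapply(omu, function(w) {
    key <- sprintf("k%.17g_w%.17g", kappa, w)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    d <- decompose_generator(build_generator(kappa, w, pi))
    if (!is.null(cache)) {
      if (length(ls(cache)) > 500L) rm(list = ls(cache), envir = cache)
      cache[[key]] <- d
    }
    d
  })
  names(decs) <- sprintf("%.17g", omu)
  ## common-scale class rate multipliers: r_k / rho per edge
  scale_ek <- matrix(1, nclass, E)
  if (nclass > 1L) {
    rate_map <- vapply(omu, function(w) raw_mean_rate(kappa, w, pi), 0)
    names(rate_map) <- sprintf("%.17g", omu)
    r_ek <- matrix(rate_map[sprintf("%.17g", omega_edge)], nclass, E)
    rho_e <- as.vector(classes$weights %*% r_ek)
    scale_ek <- r_ek / rep(rho_e, each = nclass)
  }
  npat <- ncol(pat$patterns)
  ll <- matrix(0, npat, nclass)
  for (k in seq_len(nclass)) {
    P <- array(0, c(61L, 61L, E))
    tk <- ed$lengths * scale_ek[k, ]
    for (w in omu) {
      idx <- which(omega_edge[k, ] == w)
      if (!length(idx)) next
      d <- decs[[sprintf("%.17g", w)]]
      P[, , idx] <- .cpp_transition_cubes(d$L, d$R, d$lambda, tk[idx])
    }
    ll[, k] <- .cpp_prune_loglik(ed$edge, ed$ntip, pat$patterns, P, pi)
  }
  ## log-sum-exp mixture over classes
  M <- apply(ll, 1L, max)
  site_ll <- M + log(as.vector(exp(ll - M) %*% classes$weights))
  out <- list(loglik = sum(pat$weights * site_ll), class_loglik = ll,
              site_loglik = site_ll, pattern_weights = pat$weights)
  if (per_site) out$site_index <- pat$index
  out
}

#' Codon-model log-likelihood of an alignment on a tree
#'
#' Felsenstein-pruning log-likelihood of a (repaired) codon alignment under
#' a Goldman-Yang model with fixed parameters. Missing codon states (gaps,
#' `N`, recoded stops) contribute all-ones partials. With a single taxon
#' (or `tree = NULL`) the likelihood degenerates to
#' `sum(log(pi[state]))`.
#'
#' @param aln A `codon_aln` (stop-free; see [repair_alignment()]) or an
#'   integer state matrix from [codon_states()].
#' @param tree Tagged `phylo` tree with branch lengths; tip labels must
#'   match alignment taxa.
#' @param kappa,pi Model parameters ([build_generator()]).
#' @param omega Either a single dN/dS for all branches or a vector with one
#'   value per branch partition (index = tag + 1).
#' @param classes Optional site-class mixture from [site_classes()]
#'   (overrides `omega`).
#' @return The log-likelihood (a single number).
#' @export
codon_loglik <- function(aln, tree, kappa, omega = NULL, pi,
                         classes = NULL) {
  states <- if (inherits(aln, "codon_aln")) codon_states(aln) else aln
  if (is.null(tree) || nrow(states) == 1L) {
    s <- states[!is.na(states)]
    return(sum(log(pi[s])))
  }
  if (!all(tree$tip.label %in% rownames(states)))
    stop("alignment is missing taxa present in the tree")
  states <- states[tree$tip.label, , drop = FALSE]
  ed <- postorder_edges(tree)
  if (is.null(classes)) {
    npart <- max(ed$tags) + 1L
    om <- if (length(omega) == 1L) rep(omega, max(npart, 2L)) else omega
    if (length(om) < npart)
      stop("'omega' must supply a value for every branch partition")
    classes <- list(weights = 1, omega = matrix(om, 1L, length(om)))
  }
  pat <- site_patterns(states)
  loglik_core(pat, ed, classes, kappa, pi)$loglik
}
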