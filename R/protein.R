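## Protein-level analyses: conservation profiling with reference
## numbering, variant scanning in conserved columns, motif checks, and
## physicochemical-property z-scores of nonsynonymous changes along the
## tree (8 magnitude categories, sliding window).

.aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

## display name -> AAindex accession for the packaged 31-property table
.aa_property_accessions <- c(
  "tendency to form alpha-helix"                = "CHOP780201",
  "beta-structure tendency"                     = "CHOP780202",
  "turn tendency"                               = "CHOP780101",
  "coil tendency"                               = "NAGK730103",
  "power to be at the N-terminal of alpha-helix" = "CHOP780204",
  "power to be at the middle of alpha-helix"    = "CRAJ730101",
  "power to be at the C-terminal"               = "CHOP780205",
  "helix-coil equilibrium constant"             = "FINA770101",
  "bulkiness"                                   = "ZIMJ680102",
  "buriedness"                                  = "CHOC760103",
  "average number of surrounding residues"      = "PONP800108",
  "chromatographic index"                       = "MEEJ800101",
  "composition"                                 = "GRAR740101",
  "equilibrium constant (ionization of COOH)"   = "JOND750102",
  "accessible surface area"                     = "JANJ780101",
  "hydropathy"                                  = "KYTJ820101",
  "isoelectric point"                           = "ZIMJ680104",
  "long-range non-bonded energy"                = "OOBM770103",
  "flexibility"                                 = "VINM940101",
  "molecular volume"                            = "GRAR740103",
  "molecular weight"                            = "FASG760101",
  "normalized consensus hydrophobicity"         = "EISD840101",
  "partial specific volume"                     = "COHE430101",
  "polar requirement"                           = "WOEC730101",
  "polarity"                                    = "GRAR740102",
  "refractive index"                            = "MCMT640101",
  "short and medium range non-bonded energy"    = "OOBM770102",
  "solvent accessible reduction ratio"          = "PONP800107",
  "surrounding hydrophobicity"                  = "PONP800101",
  "thermodynamic transfer hydrophobicity"       = "NOZY710101",
  "total non-bonded energy"                     = "OOBM770104")

#' Amino-acid physicochemical property table
#'
#' The packaged table of 31 structural and biochemical amino-acid property
#' scales used by [property_zscores()], assembled from the AAindex
#' compilation shipped with the seqinr package; each column keeps its
#' AAindex accession as provenance (attribute `accession`). Scales include
#' the classics of this style of analysis: equilibrium constant
#' (ionization of COOH), isoelectric point, power to be at the C-terminal,
#' tendency to form alpha-helix, hydropathy, polarity, molecular volume,
#' and so on.
#'
#' @return A 20 x 31 numeric matrix (rows = one-letter amino acids,
#'   columns = property names), attribute `accession`.
#' @export
aa_property_table <- function() {
  if (!is.null(.pkg_cache$aaprops)) return(.pkg_cache$aaprops)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  acc <- .aa_property_accessions
  missing_acc <- setdiff(acc, names(aaindex))
  if (length(missing_acc))
    stop("AAindex accessions not found: ", paste(missing_acc, collapse = ", "))
  cols <- lapply(acc, function(a) {
    v <- aaindex[[a]]$I
    one <- toupper(seqinr::a(names(v)))  # three-letter -> one-letter
    v[match(.aa1, one)]
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(.aa1, names(acc))
  if (any(is.na(m))) stop("NA values in property table")
  attr(m, "accession") <- acc
  .pkg_cache$aaprops <- m
  m
}

#' Column conservation profile of a protein alignment
#'
#' Computes, for every alignment column that is not a gap in the
#' numbering reference, the consensus residue and its conservation level
#' over a chosen set of reference taxa, classifying columns as completely
#' conserved (level 1), partially conserved (level >= 0.8), or below.
#' Positions are reported in the coordinates of the numbering reference
#' (its gap columns are skipped).
#'
#' @param msa Named character vector of aligned protein sequences.
#' @param reference_taxa Taxa over which conservation is computed.
#' @param numbering_ref Taxon whose residue numbering labels positions.
#' @param partial_threshold Partial-conservation threshold (default 0.8).
#' @return Data.frame: `ref_position`, `column` (alignment column),
#'   `consensus`, `level`, `class` in `{complete, partial80, below}`.
#' @export
conservation_profile <- function(msa, reference_taxa,
                                 numbering_ref, partial_threshold = 0.8) {
  stopifnot(numbering_ref %in% names(msa), length(reference_taxa) >= 1L,
            all(reference_taxa %in% names(msa)))
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  ref_row <- mat[numbering_ref, ]
  cols <- which(ref_row != "-")
  rows <- mat[reference_taxa, , drop = FALSE]
  out <- lapply(seq_along(cols), function(i) {
    j <- cols[i]
    col <- rows[, j]
    obs <- col[col != "-"]
    if (!length(obs)) return(NULL)  # all-gap over reference taxa: skipped
    tab <- sort(table(obs), decreasing = TRUE)
    level <- as.numeric(tab[1L]) / nrow(rows)
    data.frame(ref_position = i, column = j,
               consensus = names(tab)[1L], level = level,
               class = if (level == 1) "complete"
               else if (level >= partial_threshold) "partial80"
               else "below",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan conserved columns for variants in target taxa
#'
#' For every completely or partially conserved column of a
#' [conservation_profile()], reports target taxa whose residue differs
#' from the consensus, with a rendered label in the conventional
#' `<gene><consensus><position><observed>` form (e.g. `aM12V`).
#'
#' @param msa Named character vector of aligned protein sequences.
#' @param target_taxa Taxa to scan.
#' @param profile Output of [conservation_profile()].
#' @param gene Gene/subunit label used in rendered variant labels.
#' @return Data.frame: gene, ref_position, consensus, observed, label,
#'   carriers (comma-joined), n_carriers.
#' @export
variant_scan <- function(msa, target_taxa, profile, gene = "") {
  stopifnot(all(target_taxa %in% names(msa)))
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  cons <- profile[profile$class %in% c("complete", "partial80"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cons)), function(i) {
    j <- cons$column[i]
    obs <- mat[target_taxa, j]
    diff <- obs != cons$consensus[i] & obs != "-"
    if (!any(diff)) return(NULL)
    vars <- split(names(obs)[diff], obs[diff])
    do.call(rbind, lapply(names(vars), function(v) data.frame(
      gene = gene, ref_position = cons$ref_position[i],
      consensus = cons$consensus[i], observed = v,
      label = paste0(gene, cons$consensus[i], cons$ref_position[i], v),
      carriers = paste(sort(vars[[v]]), collapse = ","),
      n_carriers = length(vars[[v]]), stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), ref_position = integer(0),
                      consensus = character(0), observed = character(0),
                      label = character(0), carriers = character(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Check a protein sequence for functional motifs
#'
#' Scans for motif patterns written in the one-letter alphabet with `X`
#' as a wildcard; default patterns are the channel-function motifs
#' PPPXYXXL (C-terminal proline-rich), HG (N-terminal gating pair) and
#' FPXXTXC (post-M1).
#'
#' @param seq A protein sequence (gaps are removed before matching).
#' @param patterns Character vector of motifs over the 20 amino acids
#'   plus `X`.
#' @return Data.frame: pattern, start (1-based), match.
#' @export
motif_check <- function(seq, patterns = c("PPPXYXXL", "HG", "FPXXTXC")) {
  s <- gsub("-", "", toupper(seq), fixed = TRUE)
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", patterns)))
    stop("patterns must use the 20 amino-acid letters plus X")
  rows <- lapply(patterns, function(p) {
    rx <- gsub("X", ".", p, fixed = TRUE)
    m <- gregexpr(paste0("(?=(", rx, "))"), s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    data.frame(pattern = p, start = starts,
               match = substring(s, starts, starts + nchar(p) - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pattern = character(0), start = integer(0),
                      match = character(0), stringsAsFactors = FALSE)
  out
}

## Fitch parsimony ancestral amino acids on a rooted tree.
## aas: taxa x sites character matrix ("X"/"-" treated as unknown).
## Returns (ntips+nnodes) x sites character matrix of single states;
## ties broken deterministically (root: alphabetically first member of the
## state set; descent: keep the parent's state when admissible).
fitch_ancestral <- function(tree, aas) {
  ed <- postorder_edges(tree)
  ntip <- ed$ntip
  nnode <- ntip + tree$Nnode
  nsite <- ncol(aas)
  sets <- vector("list", nnode)
  all20 <- .aa1
  for (i in seq_len(ntip)) {
    tx <- tree$tip.label[i]
    sets[[i]] <- lapply(seq_len(nsite), function(s) {
      a <- aas[tx, s]
      if (a %in% all20) a else all20
    })
  }
  kids <- split(ed$edge[, 2L], ed$edge[, 1L])
  ## bottom-up in postorder node order
  for (e in seq_len(nrow(ed$edge))) {
    p <- ed$edge[e, 1L]
    if (!is.null(sets[[p]])) next
    ch <- kids[[as.character(p)]]
    sets[[p]] <- lapply(seq_len(nsite), function(s) {
      ss <- lapply(ch, function(c) sets[[c]][[s]])
      inter <- Reduce(intersect, ss)
      if (length(inter)) inter else Reduce(union, ss)
    })
  }
  states <- matrix(NA_character_, nnode, nsite)
  root <- ed$edge[nrow(ed$edge), 1L]
  states[root, ] <- vapply(sets[[root]], function(s) sort(s)[1L], "")
  for (e in rev(seq_len(nrow(ed$edge)))) {  # preorder
    p <- ed$edge[e, 1L]; c <- ed$edge[e, 2L]
    states[c, ] <- vapply(seq_len(nsite), function(s) {
      if (states[p, s] %in% sets[[c]][[s]]) states[p, s]
      else sort(sets[[c]][[s]])[1L]
    }, "")
  }
  states
}

#' Physicochemical property z-scores of nonsynonymous changes
#'
#' TreeSAAP-style analysis: amino-acid replacements along all branches of
#' the tree (ancestral states by Fitch parsimony) are scored, for each
#' property scale, by the magnitude of the property change and binned into
#' 8 equal-width categories spanning the range attainable by
#' single-nucleotide nonsynonymous codon exchanges (1-3 conservative, 6-8
#' radical). The expected category distribution comes from all possible
#' single-nucleotide nonsynonymous exchanges weighted by the observed
#' codon frequencies; each category is z-scored as
#' `z = (obs - N p) / sqrt(N p (1 - p))`. A property/category is flagged
#' in categories 6-8 when the excess is positive and significant at
#' two-sided level `alpha`; significance uses the exact binomial upper
#' tail rather than the normal approximation to z, which overstates
#' significance when a radical category expects counts near zero (z is
#' still reported). Replacements between amino acids not connected by any
#' single-nucleotide codon exchange (multi-hit reconstruction artifacts)
#' are excluded from the tally. A sliding window (width 15 codons, step
#' 1; edge windows shorter than 15 are skipped) repeats the test
#' regionally.
#'
#' @param tree A `phylo` tree.
#' @param aln A `codon_aln` over the tree's tips.
#' @param properties Property matrix from [aa_property_table()] (a subset
#'   of its columns is allowed).
#' @param window Sliding-window width in codons (default 15; `NULL`
#'   disables windows).
#' @param alpha Two-sided significance level on z (default 0.001).
#' @param kappa Transition/transversion rate ratio used to weight the
#'   expected exchange distribution (default 1 = unweighted; supply an
#'   estimate, e.g. from [fit_codon_model()], to sharpen the null).
#' @return A list with `global` (data.frame: property, category,
#'   observed, expected, z, significant_positive) and `windows`
#'   (data.frame with window start/end columns added; only flagged
#'   windows are returned), plus `n_changes`.
#' @export
property_zscores <- function(tree, aln, properties = aa_property_table(),
                             window = 15L, alpha = 0.001, kappa = 1) {
  stopifnot(inherits(aln, "codon_aln"))
  code <- genetic_code()
  states <- codon_states(aln, stops = "missing")
  states <- states[tree$tip.label, , drop = FALSE]
  nsite <- ncol(states)
  aas_chr <- matrix("X", nrow(states), nsite, dimnames = dimnames(states))
  sense_aa <- code$codon_to_aa[code$sense_codons]
  ok <- !is.na(states)
  aas_chr[ok] <- sense_aa[states[ok]]
  anc <- fitch_ancestral(tree, aas_chr)

  ## expected-change weights: all single-nt nonsynonymous codon exchanges,
  ## weighted by observed codon usage of the source codon
  ty <- codon_change_types(code)
  nonsyn <- which(ty == 3L | ty == 4L, arr.ind = TRUE)

  ## observed replacements: per edge x site where parent != child.
  ## Replacements whose amino-acid pair is not attainable by any
  ## single-nucleotide codon exchange (multi-hit artifacts of ancestral
  ## reconstruction) are outside the expected model's domain and are
  ## excluded from the tally.
  sense_aa_v <- code$codon_to_aa[code$sense_codons]
  attainable <- matrix(FALSE, 20L, 20L, dimnames = list(.aa1, .aa1))
  attainable[cbind(sense_aa_v[nonsyn[, 1L]], sense_aa_v[nonsyn[, 2L]])] <- TRUE
  ed <- postorder_edges(tree)
  froms <- character(0); tos <- character(0); sites <- integer(0)
  for (e in seq_len(nrow(ed$edge))) {
    p <- anc[ed$edge[e, 1L], ]; c <- anc[ed$edge[e, 2L], ]
    d <- which(p != c & attainable[cbind(p, c)])
    froms <- c(froms, p[d]); tos <- c(tos, c[d]); sites <- c(sites, d)
  }
  N <- length(froms)
  usage <- tabulate(states[ok], nbins = 61L)
  usage <- if (sum(usage) > 0) usage / sum(usage) else rep(1 / 61, 61)
  wts <- usage[nonsyn[, 1L]]
  ## transition exchanges (type 4) proceed kappa times faster
  wts <- wts * ifelse(ty[nonsyn] == 4L, kappa, 1)
  ex_from <- sense_aa[nonsyn[, 1L]]
  ex_to <- sense_aa[nonsyn[, 2L]]

  res_g <- list(); res_w <- list()
  for (pn in colnames(properties)) {
    prop <- properties[, pn]
    ex_mag <- abs(prop[ex_to] - prop[ex_from])
    rng <- range(ex_mag)
    brk <- seq(rng[1L], rng[2L], length.out = 9L)
    bin <- function(m) pmin(pmax(findInterval(m, brk, rightmost.closed = TRUE),
                                 1L), 8L)
    p_k <- vapply(1:8, function(k) sum(wts[bin(ex_mag) == k]), 0)
    p_k <- p_k / sum(p_k)
    obs_mag <- abs(prop[tos] - prop[froms])
    obs_bin <- if (N > 0) bin(obs_mag) else integer(0)
    O_k <- tabulate(obs_bin, nbins = 8L)
    z <- rep(NA_real_, 8L)
    valid <- N > 0 & p_k > 0 & p_k < 1
    z[valid] <- (O_k[valid] - N * p_k[valid]) /
      sqrt(N * p_k[valid] * (1 - p_k[valid]))
    ## significance by the exact binomial upper tail (the normal
    ## approximation to z badly overstates significance when the expected
    ## count in a radical category is near zero)
    ptail <- rep(NA_real_, 8L)
    ptail[valid] <- stats::pbinom(O_k[valid] - 1L, N, p_k[valid],
                                  lower.tail = FALSE)
    sig <- valid & O_k > N * p_k & ptail < alpha / 2 & seq_len(8L) >= 6L
    res_g[[pn]] <- data.frame(
      property = pn, category = 1:8, observed = O_k, expected = N * p_k,
      z = z, significant_positive = sig, stringsAsFactors = FALSE)
    if (!is.null(window) && nsite >= window && N > 0) {
      for (w0 in seq_len(nsite - window + 1L)) {
        inw <- sites >= w0 & sites <= w0 + window - 1L
        Nw <- sum(inw)
        if (Nw == 0L) next
        Ow <- tabulate(obs_bin[inw], nbins = 8L)
        zw <- rep(NA_real_, 8L)
        zw[valid] <- (Ow[valid] - Nw * p_k[valid]) /
          sqrt(Nw * p_k[valid] * (1 - p_k[valid]))
        pw <- rep(NA_real_, 8L)
        pw[valid] <- stats::pbinom(Ow[valid] - 1L, Nw, p_k[valid],
                                   lower.tail = FALSE)
        sigw <- which(valid & Ow > Nw * p_k & pw < alpha / 2 &
                      seq_len(8L) >= 6L)
        for (k in sigw)
          res_w[[length(res_w) + 1L]] <- data.frame(
            property = pn, category = k, window_start = w0,
            window_end = w0 + window - 1L, observed = Ow[k],
            expected = Nw * p_k[k], z = zw[k], stringsAsFactors = FALSE)
      }
    }
  }
  list(global = {g <- do.call(rbind, res_g); rownames(g) <- NULL; g},
       windows = if (length(res_w)) do.call(rbind, res_w) else NULL,
       n_changes = N)
}
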