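## Seed-deterministic codon sequence simulation on a phylogeny, and
## injection of pseudogenizing mutations (frameshifting indels, premature
## stop codons) with a truth manifest, so that the scanning, mapping and
## model-fitting layers can be validated against known answers.

#' Simulate a codon alignment on a tree
#'
#' Evolves codon sequences along a rooted tree under the Goldman-Yang
#' model: the root sequence is drawn from `pi` and each branch applies the
#' transition matrix of its own omega (branch lengths are expected
#' substitutions per codon). Deterministic given `seed`. Only sense codons
#' are produced; disruptions are injected afterwards with
#' [inject_pseudogenization()] so that the recorded truth stays exact.
#'
#' @param tree A `phylo` tree with branch lengths (tags define partitions
#'   when `omega` is per-partition).
#' @param omega dN/dS: a scalar for all branches, or a vector with one
#'   entry per branch partition (index = tag + 1). Ignored when
#'   `site_omega` is given.
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (61-vector; default equal).
#' @param n_codons Alignment length in codons.
#' @param seed Integer seed (mandatory: the truth manifest must fully
#'   determine the data).
#' @param site_omega Optional per-site omega vector (length `n_codons`)
#'   applied on background branches, for site-model scenarios.
#' @param site_omega_fg Optional per-site omega on foreground (tag > 0)
#'   branches; defaults to `site_omega`.
#' @param ref_taxon Reference taxon for the returned alignment (default:
#'   first tip label).
#' @return A list with `alignment` (a `codon_aln`) and `truth` (a
#'   `sim_truth` manifest: tree, per-branch omega, kappa, pi, n_codons,
#'   seed, empty `injected_events`).
#' @export
simulate_alignment <- function(tree, omega, kappa, pi = NULL, n_codons,
                               seed, site_omega = NULL, site_omega_fg = NULL,
                               ref_taxon = tree$tip.label[1L]) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (is.null(pi)) pi <- estimate_frequencies(scheme = "equal")
  stopifnot(length(pi) == 61L, abs(sum(pi) - 1) < 1e-8)
  if (!is.finite(kappa) || kappa <= 0) stop("'kappa' must be > 0")
  ed <- postorder_edges(tree)
  E <- nrow(ed$edge)
  if (any(!is.finite(ed$lengths)) || any(ed$lengths < 0))
    stop("tree must have finite non-negative branch lengths")

  ## per-edge, per-site omega
  if (is.null(site_omega)) {
    om_part <- if (length(omega) == 1L) rep(omega, max(ed$tags) + 1L) else omega
    if (length(om_part) < max(ed$tags) + 1L)
      stop("'omega' must supply a value for every branch partition")
    edge_site_omega <- function(e) rep(om_part[ed$tags[e] + 1L], n_codons)
  } else {
    stopifnot(length(site_omega) == n_codons)
    if (is.null(site_omega_fg)) site_omega_fg <- site_omega
    stopifnot(length(site_omega_fg) == n_codons)
    edge_site_omega <- function(e)
      if (ed$tags[e] > 0L) site_omega_fg else site_omega
  }
  ## common-scale multiplier per edge/site: classes within a mixture share
  ## one normalization (rho = average raw rate over the realized site
  ## classes), mirroring the likelihood's convention
  edge_site_scale <- function(e) {
    om <- edge_site_omega(e)
    uo <- unique(om)
    if (length(uo) == 1L) return(rep(1, n_codons))
    r <- vapply(uo, function(w) raw_mean_rate(kappa, w, pi), 0)
    names(r) <- sprintf("%.17g", uo)
    r_site <- r[sprintf("%.17g", om)]
    unname(r_site / mean(r_site))
  }

  ## decompositions per distinct omega value
  all_om <- unique(unlist(lapply(seq_len(E), edge_site_omega)))
  decs <- lapply(all_om, function(w)
    decompose_generator(build_generator(kappa, w, pi)))
  names(decs) <- sprintf("%.17g", all_om)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_codons)
  root <- ed$edge[E, 1L]
  with_seed(seed, {
    states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    for (e in rev(seq_len(E))) {  # reverse postorder = parents before children
      pa <- ed$edge[e, 1L]; ch <- ed$edge[e, 2L]
      om_site <- edge_site_omega(e)
      sc_site <- edge_site_scale(e)
      child <- integer(n_codons)
      grp <- paste(sprintf("%.17g", om_site), sprintf("%.17g", sc_site))
      for (g in unique(grp)) {
        sel <- which(grp == g)
        w <- om_site[sel[1L]]
        d <- decs[[sprintf("%.17g", w)]]
        P <- .cpp_transition_cubes(d$L, d$R, d$lambda,
                                   ed$lengths[e] * sc_site[sel[1L]])[, , 1L]
        ps <- states[pa, sel]
        for (s in unique(ps)) {
          idx <- sel[ps == s]
          child[idx] <- sample.int(61L, length(idx), replace = TRUE,
                                   prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
  })

  sense <- genetic_code()$sense_codons
  seqs <- vapply(seq_len(ntip), function(i)
    paste(sense[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  aln <- codon_alignment(seqs, ref_taxon)
  truth <- structure(list(
    tree = tree, omega = if (is.null(site_omega)) omega else NULL,
    site_omega = site_omega, kappa = kappa, pi = pi,
    n_codons = n_codons, seed = seed, injected_events = list()),
    class = "sim_truth")
  list(alignment = aln, truth = truth)
}

#' Inject pseudogenizing mutations into a simulated alignment
#'
#' Applies ORF-disrupting mutations to every taxon descending from a
#' chosen branch, identically placed, editing the final alignment (not the
#' evolutionary process), so the recorded truth is exactly recoverable by
#' the scanning and mapping layers. Event kinds:
#' \describe{
#'   \item{deletion}{`length` reference nucleotides starting at `at`
#'     replaced by gaps in all carriers.}
#'   \item{insertion}{`length` random nucleotides inserted immediately
#'     before reference position `at` in carriers; all other rows get a
#'     gap block.}
#'   \item{premature_stop}{the codon at codon index `at` replaced by
#'     `stop_codon` (default `"TGA"`).}
#' }
#' Multiple events are applied right-to-left so recorded reference
#' coordinates stay valid; overlapping events are refused. The reference
#' taxon must not be a carrier.
#'
#' @param sim A list with `alignment` and `truth` from
#'   [simulate_alignment()] (events accumulate across calls).
#' @param branch A tip label, internal node label, or node id; carriers
#'   are all tips descending from the branch subtending it.
#' @param events A list of event specs, each a list with `kind`, `at`
#'   (1-based reference nucleotide position; codon index for stops),
#'   and `length` (nt, for indels) or `stop_codon`.
#' @param seed Seed for random inserted nucleotides.
#' @return The updated `sim` list.
#' @export
inject_pseudogenization <- function(sim, branch, events, seed = 1L) {
  aln <- sim$alignment
  tree <- sim$truth$tree
  node <- resolve_node(tree, branch)
  tips <- descendant_tips(tree)[[node]]
  carriers <- tree$tip.label[tips]
  if (aln$ref_taxon %in% carriers)
    stop("reference taxon '", aln$ref_taxon, "' cannot carry a disruption")
  ## normalize: nt position for ordering (stops given per codon)
  norm <- lapply(events, function(ev) {
    kind <- match.arg(ev$kind, c("deletion", "insertion", "premature_stop"))
    at <- as.integer(ev$at)
    if (kind == "premature_stop") {
      list(kind = kind, nt = 3L * (at - 1L) + 1L, at = at,
           length = 0L, stop_codon = ev$stop_codon %||% "TGA")
    } else {
      list(kind = kind, nt = at, at = at, length = as.integer(ev$length),
           stop_codon = NA_character_)
    }
  })
  ord <- order(vapply(norm, `[[`, 0L, "nt"), decreasing = TRUE)
  norm <- norm[ord]
  ## overlap guard (reference coordinates)
  iv <- t(vapply(norm, function(e)
    c(e$nt, e$nt + max(e$length - 1L, if (e$kind == "premature_stop") 2L else 0L)),
    numeric(2)))
  if (nrow(iv) > 1L) {
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] <= iv[-nrow(iv), 2L]))
      stop("injected events overlap in reference coordinates")
  }
  mat <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(mat) <- names(aln$seqs)
  is_carrier <- rownames(mat) %in% carriers
  rng_i <- 0L
  for (ev in norm) {
    ## map reference coordinates to alignment columns (earlier insertions
    ## may have put gaps into the reference row)
    refpos <- which(mat[aln$ref_taxon, ] != "-")
    if (ev$kind == "deletion") {
      if (ev$nt + ev$length - 1L > length(refpos))
        stop("deletion extends past the reference")
      cols <- refpos[ev$nt:(ev$nt + ev$length - 1L)]
      mat[is_carrier, cols] <- "-"
    } else if (ev$kind == "insertion") {
      rng_i <- rng_i + 1L
      ins <- with_seed(seed + rng_i,
                       sample(c("A", "C", "G", "T"), ev$length * sum(is_carrier),
                              replace = TRUE))
      block <- matrix("-", nrow(mat), ev$length)
      block[is_carrier, ] <- matrix(ins, ncol = ev$length)
      at_col <- refpos[ev$nt]  # insert immediately before this column
      left <- if (at_col > 1L) mat[, seq_len(at_col - 1L), drop = FALSE] else NULL
      right <- mat[, at_col:ncol(mat), drop = FALSE]
      mat <- cbind(left, block, right)
    } else {  # premature_stop
      cols <- refpos[ev$nt:(ev$nt + 2L)]
      stopifnot(ev$stop_codon %in% c("TGA", "TAA", "TAG"))
      mat[is_carrier, cols] <- matrix(rep(strsplit(ev$stop_codon, "")[[1L]],
                                          each = sum(is_carrier)),
                                      sum(is_carrier), 3L)
    }
  }
  seqs <- apply(mat, 1L, paste, collapse = "")
  sim$alignment <- codon_alignment(seqs, aln$ref_taxon)
  recorded <- lapply(norm, function(ev)
    list(branch = branch_label(tree, node), node = node, kind = ev$kind,
         ref_nt_start = ev$nt, ref_codon_start = (ev$nt - 1L) %/% 3L + 1L,
         length_nt = ev$length, stop_codon = ev$stop_codon,
         carriers = carriers))
  sim$truth$injected_events <- c(sim$truth$injected_events, recorded)
  sim
}

## node id from a tip label, node label, or id
resolve_node <- function(tree, branch) {
  if (is.numeric(branch)) return(as.integer(branch))
  i <- match(branch, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(branch, tree$node.label)
    if (!is.na(j)) return(length(tree$tip.label) + j)
  }
  stop("branch '", branch, "' not found in tree")
}

#' A 13-taxon artiodactyl/cetacean-style fixture tree
#'
#' A rooted, fully labelled tree mirroring the breadth of taxon sampling
#' typical of cetacean gene-loss studies: a toothed-whale clade (three
#' delphinids, a porpoise, a river dolphin, a beaked whale, two sperm
#' whales), a baleen-whale clade, the hippopotamus as the cetacean sister
#' lineage, and two terrestrial outgroups. Internal nodes carry clade
#' labels (Delphinidae, Odontoceti, Mysticeti, Cetacea, ...); branch
#' lengths are plausible round values in expected substitutions per codon,
#' not estimates for any particular gene.
#'
#' @return A `phylo` tree with node labels and zero branch tags.
#' @export
fixture_tree <- function() {
  txt <- paste0(
    "((((baiji:0.06,((((bottlenose_dolphin:0.02,striped_dolphin:0.02)",
    "Delphininae:0.015,killer_whale:0.03)Delphinidae:0.02,",
    "finless_porpoise:0.05)Delphinoidea:0.03,(beaked_whale:0.07,",
    "(sperm_whale:0.04,dwarf_sperm_whale:0.05)Physeteroidea:0.02)",
    "Ziphioidea:0.01)OdontocetiCore:0.02)Odontoceti:0.02,",
    "(minke_whale:0.03,fin_whale:0.03)Mysticeti:0.04)Cetacea:0.04,",
    "hippopotamus:0.10)Whippomorpha:0.03,(cow:0.09,pig:0.10)Outgroup:0.03)Root;")
  tr <- read_newick(txt, text = TRUE)
  ## (inner topology places the river dolphin as the earliest-diverging
  ## toothed whale, so "all cetaceans but one odontocete" carrier sets
  ## exercise the two-origin / reversal-note mapping path)
  tr
}

#' Canonical validation datasets with known truth
#'
#' Generates the bundled synthetic scenarios used throughout the tests and
#' the vignette, deterministically from one seed:
#' \describe{
#'   \item{oracle}{tiny 3- and 4-taxon, <= 10-codon alignments for
#'     exhaustive-enumeration likelihood checks.}
#'   \item{taste_gene}{a 13-taxon gene-loss scenario on [fixture_tree()]
#'     with a stem-cetacean premature stop, a stem-odontocete 5 nt
#'     deletion, a baleen-whale 17 nt deletion, a delphinid 1 nt deletion
#'     and an independent hippopotamus 2 nt deletion.}
#'   \item{relaxation}{a foreground/background two-ratio dataset at
#'     omega = (0.26, 0.68) with the cetacean clade as foreground, plus a
#'     matched one-ratio null at omega = 0.26.}
#'   \item{protein}{a small protein MSA with conserved motifs
#'     (PPPXYXXL, HG, FPXXTXC) and a planted V -> I variant in an
#'     otherwise conserved column.}
#' }
#'
#' @param seed Integer seed.
#' @param dir Optional directory: when given, FASTA/Newick/truth files are
#'   written there.
#' @param n_codons_scenario Codons for the taste_gene scenario (default
#'   300).
#' @param n_codons_relax Codons for the relaxation datasets (default 500).
#' @return A named list of scenarios (each with alignments, trees, truth).
#' @export
fixture_suite <- function(seed = 1L, dir = NULL,
                          n_codons_scenario = 300L, n_codons_relax = 500L) {
  tr3 <- read_newick("((A:0.2,B:0.3)AB:0.1,C:0.4)R;", text = TRUE)
  tr4 <- read_newick("(((A:0.2,B:0.3)AB:0.1,C:0.4)ABC:0.1,D:0.5)R;", text = TRUE)
  oracle <- list(
    t3 = simulate_alignment(tr3, omega = 0.5, kappa = 2, n_codons = 5L,
                            seed = seed + 101L),
    t4 = simulate_alignment(tr4, omega = 0.5, kappa = 2, n_codons = 10L,
                            seed = seed + 102L))

  ft <- fixture_tree()
  tg <- simulate_alignment(ft, omega = 0.25, kappa = 3, n_codons = n_codons_scenario,
                           seed = seed + 201L, ref_taxon = "cow")
  tg <- inject_pseudogenization(tg, "Cetacea",
          list(list(kind = "premature_stop", at = 20L, stop_codon = "TGA")),
          seed = seed + 202L)
  tg <- inject_pseudogenization(tg, "Odontoceti",
          list(list(kind = "deletion", at = 200L, length = 5L)),
          seed = seed + 203L)
  tg <- inject_pseudogenization(tg, "Mysticeti",
          list(list(kind = "deletion", at = 400L, length = 17L)),
          seed = seed + 204L)
  tg <- inject_pseudogenization(tg, "Delphinidae",
          list(list(kind = "deletion", at = 550L, length = 1L)),
          seed = seed + 205L)
  tg <- inject_pseudogenization(tg, "hippopotamus",
          list(list(kind = "deletion", at = 700L, length = 2L)),
          seed = seed + 206L)

  ft_fg <- tag_branches(ft, cetacean_taxa(), tag = 1L)
  relax <- list(
    alt = simulate_alignment(ft_fg, omega = c(0.26, 0.68), kappa = 3,
                             n_codons = n_codons_relax, seed = seed + 301L,
                             ref_taxon = "cow"),
    null = simulate_alignment(ft_fg, omega = 0.26, kappa = 3,
                              n_codons = n_codons_relax, seed = seed + 302L,
                              ref_taxon = "cow"))

  protein <- protein_fixture_msa()

  out <- list(oracle = oracle, taste_gene = tg, relax = relax,
              protein = protein, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(tg$alignment$seqs, file.path(dir, "taste_gene.fasta"))
    write_newick(ft, file.path(dir, "fixture_tree.nwk"))
    write_fasta(relax$alt$alignment$seqs, file.path(dir, "relax_alt.fasta"))
    write_fasta(relax$null$alignment$seqs, file.path(dir, "relax_null.fasta"))
    write_newick(ft_fg, file.path(dir, "fixture_tree_tagged.nwk"))
    write_fasta(protein, file.path(dir, "protein_msa.fasta"))
    writeLines(yaml::as.yaml(truth_manifest(tg$truth)),
               file.path(dir, "taste_gene.truth.yaml"))
  }
  out
}

#' Cetacean tip labels of the fixture tree
#' @return Character vector of the ten cetacean tips of [fixture_tree()].
#' @export
cetacean_taxa <- function() {
  c("bottlenose_dolphin", "striped_dolphin", "killer_whale",
    "finless_porpoise", "baiji", "beaked_whale", "sperm_whale",
    "dwarf_sperm_whale", "minke_whale", "fin_whale")
}

## serializable view of a truth manifest
truth_manifest <- function(truth) {
  list(kappa = truth$kappa, n_codons = truth$n_codons, seed = truth$seed,
       omega = truth$omega,
       tree = ape::write.tree(truth$tree),
       injected_events = lapply(truth$injected_events, function(e)
         e[c("branch", "kind", "ref_nt_start", "ref_codon_start",
             "length_nt", "stop_codon", "carriers")]))
}

## small protein MSA with conserved motifs and a planted variant
protein_fixture_msa <- function() {
  core <- "MHGALKTWFPAKTLCDEKRNSVVVLPIGSTRQE"
  tail0 <- "KDEPPPAYKKLSG"
  base <- paste0(core, "VIS", tail0)
  taxa <- c("rat", "cow", "hippopotamus", "minke_whale", "baiji",
            "bottlenose_dolphin", "killer_whale", "sperm_whale")
  seqs <- rep(base, length(taxa))
  names(seqs) <- taxa
  ## planted V -> I in the conserved column 34 (within "VIS") for the
  ## toothed-whale taxa
  toothed <- c("baiji", "bottlenose_dolphin", "killer_whale", "sperm_whale")
  for (tx in toothed) {
    s <- strsplit(seqs[[tx]], "")[[1L]]
    s[34L] <- "I"
    seqs[[tx]] <- paste(s, collapse = "")
  }
  ## one neutral polymorphism outside conserved interest
  s <- strsplit(seqs[["cow"]], "")[[1L]]; s[25L] <- "T"
  seqs[["cow"]] <- paste(s, collapse = "")
  seqs
}
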