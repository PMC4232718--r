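## Independent oracles used across the test suite. Each re-derives the
## quantity it checks from first principles, without touching the package's
## own computational path.

## -- flat-file genetic code table (hand-typed standard code) ------------------
oracle_code_table <- local({
  txt <- "
TTT F  TTC F  TTA L  TTG L  CTT L  CTC L  CTA L  CTG L
ATT I  ATC I  ATA I  ATG M  GTT V  GTC V  GTA V  GTG V
TCT S  TCC S  TCA S  TCG S  CCT P  CCC P  CCA P  CCG P
ACT T  ACC T  ACA T  ACG T  GCT A  GCC A  GCA A  GCG A
TAT Y  TAC Y  TAA *  TAG *  CAT H  CAC H  CAA Q  CAG Q
AAT N  AAC N  AAA K  AAG K  GAT D  GAC D  GAA E  GAG E
TGT C  TGC C  TGA *  TGG W  CGT R  CGC R  CGA R  CGG R
AGT S  AGC S  AGA R  AGG R  GGT G  GGC G  GGA G  GGG G"
  toks <- strsplit(trimws(gsub("\\s+", " ", txt)), " ")[[1]]
  stats::setNames(toks[seq(2, length(toks), 2)], toks[seq(1, length(toks), 2)])
})

## -- minimal FASTA parser (line-by-line, no Biostrings) -----------------------
oracle_read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  nm <- sub("^>", "", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i)
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), character(1))
  stats::setNames(seqs, nm)
}

## -- quadratic-time affine-gap global alignment score -------------------------
oracle_align_score <- function(a, b, match = 2, mismatch = -2,
                               gap_open = 8, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  ## Biostrings charges gapOpening + gapExtension for the first gap position
  open1 <- -(gap_open + gap_extend)
  ext <- -gap_extend
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- open1 + (j - 2) * ext
  for (i in 2:(n + 1)) X[i, 1] <- open1 + (i - 2) * ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] + open1, X[i - 1, j] + ext)
    Y[i, j] <- max(M[i, j - 1] + open1, Y[i, j - 1] + ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## -- exhaustive-enumeration codon likelihood ---------------------------------
## Sums the joint probability over all internal-node state assignments for a
## rooted tree with at most two internal nodes beyond the root handled by
## explicit loops (root + one or two inner nodes). Trees are given as nested
## lists: leaf = list(name), internal = list(children = list(...)), with
## branch length on each non-root node ($t).
oracle_enum_loglik <- function(tree, states, kappa, omega, pi) {
  Q <- genedecay::build_generator(kappa, omega, pi)
  Pm <- function(t) genedecay::transition_matrix(Q, t)
  nsite <- ncol(states)
  ## precompute P per node
  attachP <- function(node) {
    if (!is.null(node$t)) node$P <- Pm(node$t)
    if (!is.null(node$children))
      node$children <- lapply(node$children, attachP)
    node
  }
  tree <- attachP(tree)
  ## recursive conditional probability of everything below `node` given its
  ## state, enumerating internal children states explicitly
  below <- function(node, s, site) {
    if (is.null(node$children)) stop("leaf has no below()")
    prob <- 1
    for (ch in node$children) {
      if (is.null(ch$children)) {
        cs <- states[ch$name, site]
        prob <- prob * (if (is.na(cs)) 1 else ch$P[s, cs])
      } else {
        tot <- 0
        for (cs in 1:61) tot <- tot + ch$P[s, cs] * below(ch, cs, site)
        prob <- prob * tot
      }
    }
    prob
  }
  ll <- 0
  for (site in seq_len(nsite)) {
    tot <- 0
    for (r in 1:61) tot <- tot + unname(pi[r]) * below(tree, r, site)
    ll <- ll + log(tot)
  }
  ll
}

## -- chi-square upper tail by series / continued fraction ---------------------
## Regularized upper incomplete gamma Q(a, x) with a = df/2, x = stat/2.
oracle_chi2_sf <- function(x, df, nterm = 10000L) {
  a <- df / 2; x2 <- x / 2
  if (x2 <= 0) return(1)
  if (x2 < a + 1) {
    ## lower series P(a,x), then Q = 1 - P
    term <- 1 / a; total <- term; n <- 0
    while (n < nterm) {
      n <- n + 1
      term <- term * x2 / (a + n)
      total <- total + term
      if (abs(term) < abs(total) * 1e-18) break
    }
    p_low <- total * exp(-x2 + a * log(x2) - lgamma(a))
    return(1 - p_low)
  }
  ## continued fraction for Q(a,x) (Lentz)
  tiny <- 1e-300
  b <- x2 + 1 - a; c <- 1 / tiny; d <- 1 / b; h <- d
  for (i in seq_len(nterm)) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b; if (abs(d) < tiny) d <- tiny
    c <- b + an / c; if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < 1e-16) break
  }
  h * exp(-x2 + a * log(x2) - lgamma(a))
}

## -- Nei-Gojobori style counting dN/dS for two sequences ----------------------
oracle_counting_dnds <- function(seq1, seq2) {
  code <- genedecay::genetic_code()
  aa <- code$codon_to_aa
  syn_sites <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    s <- 0
    for (p in 1:3) {
      alt <- setdiff(c("A", "C", "G", "T"), b[p])
      for (x in alt) {
        nb <- b; nb[p] <- x
        ncod <- paste(nb, collapse = "")
        if (aa[ncod] != "*" && aa[ncod] == aa[codon]) s <- s + 1 / 3
      }
    }
    s
  }
  c1 <- genedecay:::split_codons(seq1); c2 <- genedecay:::split_codons(seq2)
  keep <- !grepl("[-N]", c1) & !grepl("[-N]", c2) &
    !(c1 %in% code$stop_codons) & !(c2 %in% code$stop_codons)
  c1 <- c1[keep]; c2 <- c2[keep]
  S <- sum(vapply(c1, syn_sites, 0))
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    if (c1[i] == c2[i]) next
    b1 <- strsplit(c1[i], "")[[1]]; b2 <- strsplit(c2[i], "")[[1]]
    diff <- which(b1 != b2)
    ## average over substitution paths (single-step approximation for
    ## multi-hit codons: count each differing position against the codon
    ## context of sequence 1)
    for (p in diff) {
      nb <- b1; nb[p] <- b2[p]
      ncod <- paste(nb, collapse = "")
      if (aa[ncod] == "*") next
      if (aa[ncod] == aa[c1[i]]) sd <- sd + 1 else nd <- nd + 1
    }
  }
  pS <- sd / S; pN <- nd / N
  dS <- -3 / 4 * log(1 - 4 / 3 * pS)
  dN <- -3 / 4 * log(1 - 4 / 3 * pN)
  dN / dS
}

## -- shared tiny fixtures -----------------------------------------------------
small_tagged_tree <- function() {
  tr <- read_newick("(((A:0.15,B:0.15)n1:0.08,C:0.2)n2:0.08,(D:0.15,E:0.15)n3:0.08,F:0.25)R;",
                    text = TRUE)
  tag_branches(tr, c("A", "B"), 1L)
}
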