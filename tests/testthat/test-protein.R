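protein_msa <- genedecay:::protein_fixture_msa()

test_that("conservation profile classifies complete and partial columns", {
  msa <- c(rat = "MKV", cow = "MKV", dog = "MRV", pig = "MKV", cat = "MKV")
  prof <- conservation_profile(msa, names(msa), "rat")
  expect_identical(prof$class, c("complete", "partial80", "complete"))
  expect_equal(prof$level, c(1, 0.8, 1))
  expect_identical(prof$consensus, c("M", "K", "V"))
})

test_that("conservation levels equal a direct counting oracle and are order-invariant", {
  set.seed(81)
  for (i in 1:10) {
    n <- 6; L <- 20
    msa <- vapply(1:n, function(j)
      paste(sample(c("A", "R", "N", "D", "-"), L, TRUE,
                   prob = c(0.5, 0.2, 0.15, 0.1, 0.05)), collapse = ""),
      character(1))
    names(msa) <- paste0("t", 1:n)
    prof <- conservation_profile(msa, names(msa), "t1")
    mat <- do.call(rbind, strsplit(msa, ""))
    ref_cols <- which(mat[1, ] != "-")
    for (r in seq_len(nrow(prof))) {
      col <- mat[, prof$column[r]]
      obs <- col[col != "-"]
      expect_equal(prof$level[r], max(table(obs)) / n)
    }
    prof2 <- conservation_profile(msa[sample(n)], names(msa), "t1")
    expect_equal(prof2$level, prof$level)
  }
})

test_that("numbering skips gap columns of the numbering reference", {
  msa <- c(rat = "M-KV", cow = "MAKV")
  prof <- conservation_profile(msa, names(msa), "rat")
  expect_identical(prof$ref_position, c(1L, 2L, 3L))
  expect_identical(prof$column, c(1L, 3L, 4L))
})

test_that("variant scan finds the planted substitution with correct label and carriers", {
  ref_taxa <- c("rat", "cow", "hippopotamus", "minke_whale")
  prof <- conservation_profile(protein_msa, ref_taxa, "rat")
  toothed <- c("baiji", "bottlenose_dolphin", "killer_whale", "sperm_whale")
  vars <- variant_scan(protein_msa, toothed, prof, gene = "g")
  expect_identical(nrow(vars), 1L)
  expect_identical(vars$label, "gV34I")
  expect_setequal(strsplit(vars$carriers, ",")[[1]], toothed)
  ## a target identical to consensus gives no calls
  none <- variant_scan(protein_msa, c("cow"), prof, gene = "g")
  none <- none[none$ref_position == 34, ]
  expect_identical(nrow(none), 0L)
})

test_that("variant label renders gene, consensus, position, observed", {
  msa <- c(a = "AVC", b = "AVC", c = "AIC")
  prof <- conservation_profile(msa, c("a", "b"), "a")
  v <- variant_scan(msa, "c", prof, gene = "y")
  expect_identical(v$label, "yV2I")
})

test_that("motif check matches wildcards and agrees with a naive scan", {
  m <- motif_check("PPPAYKKL")
  expect_identical(m$pattern[1], "PPPXYXXL")
  expect_identical(m$start[1], 1L)
  ## fixture protein contains all three default motifs
  hits <- motif_check(protein_msa[["rat"]])
  expect_setequal(unique(hits$pattern), c("PPPXYXXL", "HG", "FPXXTXC"))
  ## naive sliding-window oracle on random sequences
  set.seed(82)
  aas <- c("A", "R", "N", "D", "C", "P", "Y", "L", "H", "G", "F", "T")
  for (i in 1:20) {
    s <- paste(sample(aas, 60, TRUE), collapse = "")
    for (p in c("HG", "PPPXYXXL", "FPXXTXC", "AXA")) {
      got <- motif_check(s, p)$start
      pc <- strsplit(p, "")[[1]]
      want <- integer(0)
      for (st in seq_len(60 - length(pc) + 1)) {
        seg <- strsplit(substr(s, st, st + length(pc) - 1), "")[[1]]
        if (all(pc == "X" | pc == seg)) want <- c(want, st)
      }
      expect_identical(got, want, info = paste(p, s))
    }
  }
  expect_error(motif_check("AAA", "P1X"), "amino-acid")
})

test_that("the packaged property table has 31 complete scales with provenance", {
  tab <- aa_property_table()
  expect_identical(dim(tab), c(20L, 31L))
  expect_false(anyNA(tab))
  expect_true(all(c("equilibrium constant (ionization of COOH)",
                    "isoelectric point",
                    "power to be at the C-terminal",
                    "tendency to form alpha-helix") %in% colnames(tab)))
  expect_length(attr(tab, "accession"), 31L)
})

test_that("an alignment with no replacements flags nothing", {
  tr <- read_newick("((A:0.1,B:0.1)AB:0.1,C:0.1)R;", text = TRUE)
  s <- "ATGAAACCCGGGTTTCTG"
  aln <- codon_alignment(c(A = s, B = s, C = s), "A")
  pz <- property_zscores(tr, aln, window = NULL)
  expect_identical(pz$n_changes, 0L)
  expect_true(all(pz$global$observed == 0))
  expect_false(any(pz$global$significant_positive))
})

test_that("expected category proportions sum to one for every property", {
  tr <- fixture_tree()
  sim <- simulate_alignment(tr, omega = 0.5, kappa = 2, n_codons = 60,
                            seed = 83, ref_taxon = "cow")
  pz <- property_zscores(tr, sim$alignment, window = NULL)
  agg <- tapply(pz$global$expected, pz$global$property, sum)
  expect_true(all(abs(agg - pz$n_changes) < 1e-9))
})

test_that("sliding windows cover exactly 15 codon sites", {
  tr <- fixture_tree()
  sim <- simulate_alignment(tr, omega = 1, kappa = 2, n_codons = 40,
                            seed = 84, ref_taxon = "cow")
  pz <- property_zscores(tr, sim$alignment, window = 15L, alpha = 0.5)
  if (!is.null(pz$windows)) {
    expect_true(all(pz$windows$window_end - pz$windows$window_start + 1L == 15L))
    expect_true(all(pz$windows$window_start >= 1L))
    expect_true(all(pz$windows$window_end <= 40L))
  }
})

test_that("neutral simulation rarely flags radical property categories", {
  tr <- read_newick("(((A:0.2,B:0.2)n1:0.1,C:0.3)n2:0.1,(D:0.2,E:0.2)n3:0.1,F:0.3)R;",
                    text = TRUE)
  n_flag <- 0L; n_tests <- 0L
  for (i in 1:50) {
    sim <- simulate_alignment(tr, omega = 1, kappa = 2, n_codons = 100,
                              seed = 9000 + i)
    pz <- property_zscores(tr, sim$alignment, window = NULL, alpha = 0.001)
    n_flag <- n_flag + sum(pz$global$significant_positive)
    n_tests <- n_tests + sum(pz$global$category >= 6)
  }
  expect_lte(n_flag / n_tests, 0.01)
})
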