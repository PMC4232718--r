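test_that("mrca handles single taxa, full sets, and errors", {
  tr <- fixture_tree()
  expect_identical(mrca_node(tr, "baiji"), match("baiji", tr$tip.label))
  expect_identical(mrca_node(tr, tr$tip.label),
                   length(tr$tip.label) + 1L)  # root
  expect_error(mrca_node(tr, character(0)), "empty")
  expect_error(mrca_node(tr, "orca"), "unknown")
})

test_that("mrca agrees with brute-force ancestor-set intersection on random trees", {
  set.seed(41)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:12, 1))
    taxa <- sample(tr$tip.label, sample(2:length(tr$tip.label), 1))
    got <- mrca_node(tr, taxa)
    ## oracle: intersect each taxon's root path, take the deepest node
    parent <- integer(max(tr$edge))
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    path <- function(tip) {
      n <- match(tip, tr$tip.label); out <- n
      while (parent[n] != 0) { n <- parent[n]; out <- c(out, n) }
      out
    }
    common <- Reduce(intersect, lapply(taxa, path))
    depth <- genedecay:::node_depths(tr)
    expect_identical(got, common[which.max(depth[common])])
  }
})

test_that("clade carriers map to a single stem origin", {
  tr <- fixture_tree()
  me <- map_event(tr, cetacean_taxa())
  expect_true(me$monophyletic)
  expect_identical(me$n_independent_origins, 1L)
  expect_identical(me$origin_branches, "Cetacea")

  toothed <- setdiff(cetacean_taxa(), c("minke_whale", "fin_whale"))
  me2 <- map_event(tr, toothed)
  expect_identical(me2$origin_branches, "Odontoceti")

  me3 <- map_event(tr, "baiji")
  expect_identical(me3$origin_branches, "baiji")
  expect_true(me3$monophyletic)
})

test_that("all cetaceans minus baiji yields two Dollo origins and a reversal note", {
  tr <- fixture_tree()
  me <- map_event(tr, setdiff(cetacean_taxa(), "baiji"))
  expect_false(me$monophyletic)
  expect_identical(me$n_independent_origins, 2L)
  expect_setequal(me$origin_branches, c("OdontocetiCore", "Mysticeti"))
  expect_match(me$note, "reversal in baiji")
})

test_that("mapping is invariant to leaf order and newick rotation", {
  tr <- fixture_tree()
  carriers <- setdiff(cetacean_taxa(), "baiji")
  a <- map_event(tr, carriers)
  b <- map_event(tr, rev(carriers))
  expect_identical(a$origin_branches, b$origin_branches)
  rot <- ape::rotate(tr, mrca_node(tr, c("minke_whale", "fin_whale")))
  rot <- ape::read.tree(text = ape::write.tree(rot))
  c <- map_event(rot, carriers)
  expect_setequal(c$origin_branches, a$origin_branches)
  expect_identical(c$n_independent_origins, a$n_independent_origins)
})

test_that("origin count never exceeds carrier count and is 1 iff monophyletic", {
  set.seed(42)
  tr <- fixture_tree()
  for (i in 1:50) {
    carriers <- sample(tr$tip.label, sample(1:12, 1))
    me <- map_event(tr, carriers)
    expect_lte(me$n_independent_origins, length(carriers))
    expect_identical(me$monophyletic, me$n_independent_origins == 1L)
  }
})

test_that("gene loss summary reports earliest origin and independence", {
  tr <- fixture_tree()
  events <- data.frame(
    gene = c("g1", "g1", "g2", "g2"),
    kind = c("deletion", "deletion", "deletion", "deletion"),
    ref_nt_start = c(10L, 50L, 30L, 90L),
    length_nt = c(5L, 1L, 2L, 2L),
    stop_codon = NA_character_,
    carriers = c(
      paste(setdiff(cetacean_taxa(), c("minke_whale", "fin_whale")), collapse = ","),
      "bottlenose_dolphin,striped_dolphin,killer_whale",
      paste(cetacean_taxa(), collapse = ","),
      "hippopotamus"),
    stringsAsFactors = FALSE)
  mapped <- map_events(tr, events)
  lineages <- list(cetacea = cetacean_taxa(), hippo = "hippopotamus")
  summ <- gene_loss_summary(tr, mapped, lineages)
  g1 <- summ$per_lineage[summ$per_lineage$gene == "g1", ]
  expect_identical(g1$earliest_origin[g1$lineage == "cetacea"], "Odontoceti")
  g2 <- summ$per_lineage[summ$per_lineage$gene == "g2", ]
  expect_identical(g2$earliest_origin[g2$lineage == "cetacea"], "Cetacea")
  ind <- summ$independence
  expect_true(ind$independent[ind$gene == "g2"])
  ## single event summarizes to itself
  one <- map_events(tr, events[4, , drop = FALSE])
  s1 <- gene_loss_summary(tr, one, lineages["hippo"])
  expect_identical(s1$per_lineage$earliest_origin, "hippopotamus")
  expect_identical(s1$per_lineage$n_events, 1L)
})

test_that("synthetic taste-gene scenario recovers every injected origin branch", {
  fx <- fixture_suite(seed = 3)
  tg <- fx$taste_gene
  reports <- scan_alignment(tg$alignment, gene = "tg")
  events <- find_shared_events(reports)
  mapped <- map_events(fixture_tree(), events)
  for (truth in tg$truth$injected_events) {
    hit <- mapped[mapped$kind == truth$kind &
                  mapped$ref_nt_start == truth$ref_nt_start &
                  mapped$length_nt == truth$length_nt, , drop = FALSE]
    expect_equal(nrow(hit), 1L, info = truth$branch)
    expect_identical(hit$origin_branch, truth$branch)
    expect_true(hit$monophyletic)
  }
})
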