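## End-to-end orchestration from one config file: ORF scan -> event
## mapping -> alignment repair -> branch-model ladder (and optional clade,
## site and protein-level analyses), with deterministic seeded outputs.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with:
#' \describe{
#'   \item{tree}{path to the Newick species tree.}
#'   \item{genes}{list of entries, each with `name`, `alignment` (aligned
#'     FASTA path) and `ref_taxon`; optional `exons` (data.frame-style
#'     list of start/end/name).}
#'   \item{foreground}{`"derive"` (default: mapped origin branch of the
#'     earliest event plus its descendants) or an explicit list of tip
#'     labels.}
#'   \item{seed}{integer, mandatory.}
#'   \item{lineages}{optional named list of tip sets for the loss
#'     summary.}
#'   \item{run}{optional character vector among `"ladder"`,
#'     `"clade_test"`, `"site_tests"`, `"properties"` (default
#'     `"ladder"`).}
#'   \item{n_starts}{optimization starts per fit (default 2).}
#' }
#'
#' @param config A named list or a YAML file path.
#' @return The validated config list (paths checked, defaults filled).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$tree)) stop("config must name a tree path")
  if (!file.exists(config$tree)) stop("tree file not found: ", config$tree)
  if (!length(config$genes)) stop("config lists no genes")
  for (g in config$genes) {
    if (is.null(g$name) || is.null(g$alignment) || is.null(g$ref_taxon))
      stop("each gene needs name, alignment, ref_taxon")
    if (!file.exists(g$alignment))
      stop("alignment not found: ", g$alignment)
  }
  config$foreground <- config$foreground %||% "derive"
  config$run <- config$run %||% "ladder"
  config$n_starts <- config$n_starts %||% 2L
  config
}

#' Run the full gene-loss analysis pipeline
#'
#' For each configured gene: scans the alignment for ORF disruptions,
#' groups shared events, maps them onto the species tree, repairs the
#' alignment, derives (or applies) the foreground branch set, and runs
#' the requested selection analyses. All reports are written as TSV under
#' `out_dir`, along with a `MANIFEST.yaml` recording seeds, the repair
#' recipe, the foreground set, and any stage failure.
#'
#' @param config Config list or YAML path (see [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of per-gene results (reports, events,
#'   mapped, ladder, ...). Stage failures are recorded in the manifest
#'   and re-raised after partial outputs are written.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- read_newick(config$tree)
  manifest <- list(seed = config$seed, tree = config$tree,
                   genes = vapply(config$genes, `[[`, "", "name"),
                   run = config$run, status = "running")
  results <- list()
  failed <- NULL
  for (g in config$genes) {
    res <- tryCatch({
      seqs <- read_fasta(g$alignment)
      aln <- codon_alignment(seqs, g$ref_taxon)
      exons <- if (!is.null(g$exons)) as.data.frame(do.call(rbind, lapply(
        g$exons, as.data.frame)), stringsAsFactors = FALSE) else NULL
      reports <- scan_alignment(aln, gene = g$name, exons = exons)
      write_disruption_tsv(reports,
                           file.path(out_dir, paste0(g$name, "_disruptions.tsv")))
      ## primary inactivating mutations only: stops created downstream of a
      ## frameshift are consequences of the indel, not independent events
      events <- find_shared_events(
        reports,
        include_post_frameshift = isTRUE(config$include_post_frameshift))
      mapped <- map_events(tree, events)
      utils::write.table(mapped,
                         file.path(out_dir, paste0(g$name, "_mapped_events.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep_aln <- repair_alignment(aln)
      manifest$repair[[g$name]] <- attr(rep_aln, "repair")

      ## foreground: explicit, or earliest origin branch + descendants
      fg_taxa <- if (identical(config$foreground, "derive")) {
        if (nrow(mapped)) {
          dep <- node_depths(tree)
          nodes <- unlist(lapply(seq_len(nrow(mapped)), function(i)
            map_event(tree, mapped[i, "carriers"] |>
                        strsplit(",", fixed = TRUE) |> unlist())$origin_nodes))
          best <- nodes[which.min(dep[nodes])]
          tree$tip.label[descendant_tips(tree)[[best]]]
        } else character(0)
      } else unlist(config$foreground)
      manifest$foreground[[g$name]] <- fg_taxa

      out <- list(reports = reports, events = events, mapped = mapped,
                  foreground = fg_taxa)
      tr_tag <- if (length(fg_taxa)) tag_branches(tree, fg_taxa, 1L) else tree
      ctl <- list(maxit = config$maxit %||% 500L)
      if ("ladder" %in% config$run) {
        lad <- run_ladder(rep_aln, tr_tag, seed = config$seed,
                          n_starts = config$n_starts, control = ctl)
        utils::write.table(ladder_table(lad),
                           file.path(out_dir, paste0(g$name, "_ladder.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$ladder <- lad
      }
      if ("clade_test" %in% config$run) {
        out$clade_test <- run_clade_test(rep_aln, tr_tag, seed = config$seed,
                                         n_starts = config$n_starts,
                                         control = ctl)
      }
      if ("site_tests" %in% config$run) {
        out$site_tests <- run_site_tests(rep_aln, tr_tag, seed = config$seed,
                                         n_starts = config$n_starts,
                                         control = ctl)
      }
      if ("properties" %in% config$run) {
        pz <- property_zscores(tree, rep_aln)
        utils::write.table(pz$global,
                           file.path(out_dir, paste0(g$name, "_properties.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$properties <- pz
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- list(gene = g$name, error = conditionMessage(res)); break }
    results[[g$name]] <- res
  }
  ## loss summary across genes
  if (is.null(failed) && !is.null(config$lineages)) {
    mapped_all <- do.call(rbind, lapply(results, `[[`, "mapped"))
    if (!is.null(mapped_all) && nrow(mapped_all)) {
      summ <- gene_loss_summary(tree, mapped_all,
                                lapply(config$lineages, unlist))
      if (!is.null(summ$per_lineage))
        utils::write.table(summ$per_lineage,
                           file.path(out_dir, "loss_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(summ$independence))
        utils::write.table(summ$independence,
                           file.path(out_dir, "loss_independence.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest$status <- if (is.null(failed)) "ok" else "failed"
  manifest$failure <- failed
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "MANIFEST.yaml"))
  if (!is.null(failed))
    stop("pipeline failed at gene '", failed$gene, "': ", failed$error)
  invisible(results)
}
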