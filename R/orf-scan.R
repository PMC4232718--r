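## Detection of ORF-disrupting mutations (frameshifting indels, premature
## stop codons) in query coding sequences relative to a functional
## reference, and grouping of identical disruptions into shared
## inactivation events.

#' Codon-aware pairwise alignment of a query against a reference CDS
#'
#' Global (Needleman-Wunsch) alignment with affine gap costs via
#' [Biostrings::pairwiseAlignment()], followed by a canonicalization pass
#' that shifts every gap run to its leftmost score-equivalent placement,
#' so indel coordinates are deterministic and reported in a single
#' documented dialect.
#'
#' @param ref_cds In-frame reference coding sequence (no gaps).
#' @param query Query sequence (no gaps).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (defaults
#'   2, -2, 8, 1; gap penalties positive).
#' @return A list with aligned strings `ref` and `qry` (equal length) and
#'   the alignment `score`.
#' @export
align_codon_aware <- function(ref_cds, query, match = 2, mismatch = -2,
                              gap_open = 8, gap_extend = 1) {
  if (!nzchar(ref_cds) || !nzchar(query)) stop("sequences must be non-empty")
  if (nchar(ref_cds) < 3L || nchar(query) < 3L)
    stop("sequences must contain at least one codon")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(query)), Biostrings::DNAString(toupper(ref_cds)),
    type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  out <- list(ref = as.character(Biostrings::alignedSubject(pa)),
              qry = as.character(Biostrings::alignedPattern(pa)),
              score = Biostrings::score(pa))
  canonicalize_gaps(out)
}

## shift every gap run leftwards while the flanking characters permit an
## equal-scoring placement (standard left-normalization of indels)
canonicalize_gaps <- function(alig) {
  shift_left <- function(gapped, other) {
    g <- strsplit(gapped, "", fixed = TRUE)[[1L]]
    repeat {
      moved <- FALSE
      runs <- rle(g == "-")
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        s <- starts[r]; e <- ends[r]
        while (s > 1L && g[s - 1L] != "-" && g[s - 1L] == g[e]) {
          ## moving the run one left keeps the same multiset of aligned pairs
          g[e] <- g[s - 1L]; g[s - 1L] <- "-"
          s <- s - 1L; e <- e - 1L
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    paste(g, collapse = "")
  }
  ## a gap run in one row can shift only if the other row is gapless there;
  ## shifting within a homopolymer-like context preserves the pair scores
  alig$qry <- shift_left(alig$qry, alig$ref)
  alig$ref <- shift_left(alig$ref, alig$qry)
  alig
}

#' Detect ORF disruptions in one aligned query
#'
#' Walks an aligned reference/query pair left to right in the reference
#' reading frame, classifying every gap run as an insertion (gap in the
#' reference) or deletion (gap in the query) with 1-based reference
#' coordinates, tracking the cumulative frame offset, and translating the
#' query in its *current local frame* so that premature stop codons are
#' found whether they predate or are created by a frameshift (the latter
#' are marked `cause = "post-frameshift"`). Columns gapped in both rows
#' are ignored, so equal terminal padding does not change the report.
#'
#' @param ref Aligned reference row (in frame; must translate without
#'   internal stops).
#' @param qry Aligned query row (same length).
#' @param taxon,gene Labels carried into the report.
#' @param code Genetic code.
#' @return An object of class `disruption_report`: list with `taxon`,
#'   `gene`, `disruptions` (data.frame: kind, ref_codon_start,
#'   ref_nt_start, length_nt, frameshifting, stop_codon, cause),
#'   `first_stop_codon`, `truncation_fraction`, `intact`,
#'   `ref_protein_length`.
#' @export
detect_disruptions <- function(ref, qry, taxon = "query", gene = "gene",
                               code = genetic_code()) {
  if (nchar(ref) != nchar(qry)) stop("aligned rows must have equal length")
  r <- strsplit(toupper(ref), "", fixed = TRUE)[[1L]]
  q <- strsplit(toupper(qry), "", fixed = TRUE)[[1L]]
  keep <- !(r == "-" & q == "-")
  r <- r[keep]; q <- q[keep]

  ## validate reference
  ref_seq <- paste(r[r != "-"], collapse = "")
  ref_prot <- translate_cds(ref_seq, 1L, code)
  ref_aa <- strsplit(ref_prot, "", fixed = TRUE)[[1L]]
  n_ref_cod <- length(ref_aa)
  has_term <- n_ref_cod > 0L && ref_aa[n_ref_cod] == "*"
  ref_protein_length <- if (has_term) n_ref_cod - 1L else n_ref_cod
  if (any(ref_aa[seq_len(ref_protein_length)] == "*"))
    stop("invalid reference: internal stop codon")

  disruptions <- list()
  ## --- indels: runs of gap in exactly one row ---
  refpos <- cumsum(r != "-")      # reference nt index at/just before column
  gap_ref <- r == "-"
  gap_qry <- q == "-"
  add_runs <- function(mask, kind) {
    runs <- rle(mask)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      s <- starts[i]; len <- runs$lengths[i]
      nt0 <- if (kind == "deletion") refpos[s] else refpos[s] + 1L
      disruptions[[length(disruptions) + 1L]] <<- data.frame(
        kind = kind, ref_codon_start = (nt0 - 1L) %/% 3L + 1L,
        ref_nt_start = nt0, length_nt = len,
        frameshifting = (len %% 3L) != 0L,
        stop_codon = NA_character_, cause = "indel",
        stringsAsFactors = FALSE)
    }
  }
  add_runs(gap_qry, "deletion")
  add_runs(gap_ref, "insertion")

  ## --- premature stops: translate query in its local frame ---
  buf <- character(0)
  buf_col <- integer(0)
  first_stop <- NA_integer_
  stop_rows <- list()
  offset <- 0L          # cumulative query-vs-reference frame offset
  offset_start <- 0L    # offset when the current query codon began
  for (j in seq_along(r)) {
    if (q[j] != "-") {
      if (!length(buf)) offset_start <- offset
      buf <- c(buf, q[j]); buf_col <- c(buf_col, j)
      if (length(buf) == 3L) {
        cod <- paste(buf, collapse = "")
        ref_nt_here <- max(refpos[buf_col[1L]], 1L)
        cod_idx <- (ref_nt_here - 1L) %/% 3L + 1L
        shifted <- offset_start %% 3L != 0L || offset %% 3L != 0L
        if (!grepl("[N-]", cod) && cod %in% code$stop_codons &&
            cod_idx <= ref_protein_length) {
          stop_rows[[length(stop_rows) + 1L]] <- data.frame(
            kind = "premature_stop", ref_codon_start = cod_idx,
            ref_nt_start = ref_nt_here, length_nt = 0L,
            frameshifting = FALSE, stop_codon = cod,
            cause = if (shifted) "post-frameshift" else "point",
            stringsAsFactors = FALSE)
          if (is.na(first_stop)) first_stop <- cod_idx
        }
        buf <- character(0); buf_col <- integer(0)
      }
    }
    ## update frame offset after processing the column
    if (q[j] == "-" && r[j] != "-") offset <- offset - 1L
    if (r[j] == "-" && q[j] != "-") offset <- offset + 1L
  }
  disruptions <- c(disruptions, stop_rows)
  dd <- if (length(disruptions)) do.call(rbind, disruptions) else
    data.frame(kind = character(0), ref_codon_start = integer(0),
               ref_nt_start = integer(0), length_nt = integer(0),
               frameshifting = logical(0), stop_codon = character(0),
               cause = character(0), stringsAsFactors = FALSE)
  dd <- dd[order(dd$ref_nt_start, dd$kind), , drop = FALSE]
  rownames(dd) <- NULL
  trunc_frac <- if (!is.na(first_stop))
    1 - (first_stop - 1) / ref_protein_length else NA_real_
  structure(list(
    taxon = taxon, gene = gene, disruptions = dd,
    first_stop_codon = first_stop, truncation_fraction = trunc_frac,
    intact = nrow(dd) == 0L, ref_protein_length = ref_protein_length),
    class = "disruption_report")
}

#' @export
print.disruption_report <- function(x, ...) {
  cat("ORF scan of '", x$taxon, "' (", x$gene, "): ",
      if (x$intact) "intact" else paste0(nrow(x$disruptions), " disruption(s)"),
      "\n", sep = "")
  if (!x$intact) {
    print(x$disruptions)
    if (!is.na(x$first_stop_codon))
      cat(sprintf("first premature stop at codon %d; truncation fraction %.3f\n",
                  x$first_stop_codon, x$truncation_fraction))
  }
  invisible(x)
}

#' Scan every taxon of a codon alignment against its reference
#'
#' Runs [detect_disruptions()] for each non-reference row of an aligned
#' `codon_aln`. Optionally, gap runs covering at least `exon_loss_frac`
#' of an annotated exon interval are additionally summarized as
#' whole-exon losses.
#'
#' @param aln A `codon_aln` (aligned; rows equal length).
#' @param gene Gene label for the reports.
#' @param exons Optional data.frame of 1-based closed reference nt
#'   intervals (`start`, `end`, `name`) marking exons.
#' @param exon_loss_frac Gap coverage needed to call an exon lost
#'   (default 0.95).
#' @return A named list of `disruption_report`s (one per non-reference
#'   taxon); attribute `exon_loss` holds any whole-exon-loss calls.
#' @export
scan_alignment <- function(aln, gene = "gene", exons = NULL,
                           exon_loss_frac = 0.95) {
  stopifnot(inherits(aln, "codon_aln"))
  ref <- aln$seqs[[aln$ref_taxon]]
  taxa <- setdiff(names(aln$seqs), aln$ref_taxon)
  reports <- lapply(taxa, function(tx)
    detect_disruptions(ref, aln$seqs[[tx]], taxon = tx, gene = gene))
  names(reports) <- taxa
  if (!is.null(exons)) {
    losses <- list()
    refpos_col <- which(strsplit(ref, "")[[1L]] != "-")
    for (tx in taxa) {
      qc <- strsplit(aln$seqs[[tx]], "")[[1L]]
      for (i in seq_len(nrow(exons))) {
        cols <- refpos_col[exons$start[i]:exons$end[i]]
        frac <- mean(qc[cols] == "-")
        if (frac >= exon_loss_frac)
          losses[[length(losses) + 1L]] <- data.frame(
            taxon = tx, exon = exons$name[i], gap_fraction = frac,
            stringsAsFactors = FALSE)
      }
    }
    attr(reports, "exon_loss") <-
      if (length(losses)) do.call(rbind, losses) else NULL
  }
  reports
}

#' Group identical disruptions across taxa into shared inactivation events
#'
#' Disruptions with the same kind, the same length (and stop codon), and
#' reference coordinates within `tolerance` are grouped into one
#' inactivation event carried by all taxa exhibiting it; disruptions seen
#' in a single taxon become single-carrier events.
#'
#' @param reports A list of `disruption_report`s for one gene (from
#'   [scan_alignment()]).
#' @param tolerance Coordinate tolerance in nucleotides (default 0 =
#'   exact identity).
#' @param include_post_frameshift Keep stops created by an upstream
#'   frameshift (default `TRUE`).
#' @return A data.frame of events: gene, kind, ref_codon_start,
#'   ref_nt_start, length_nt, frameshifting, stop_codon, n_carriers,
#'   carriers (comma-joined).
#' @export
find_shared_events <- function(reports, tolerance = 0L,
                               include_post_frameshift = TRUE) {
  if (length(reports) < 1L) stop("need at least one report")
  genes <- unique(vapply(reports, `[[`, "", "gene"))
  if (length(genes) != 1L)
    stop("reports mix genes: ", paste(genes, collapse = ", "))
  rows <- do.call(rbind, lapply(reports, function(rp) {
    d <- rp$disruptions
    if (!nrow(d)) return(NULL)
    d$taxon <- rp$taxon
    d
  }))
  if (is.null(rows) || !nrow(rows))
    return(data.frame(gene = character(0), kind = character(0),
                      ref_codon_start = integer(0), ref_nt_start = integer(0),
                      length_nt = integer(0), frameshifting = logical(0),
                      stop_codon = character(0), n_carriers = integer(0),
                      carriers = character(0), stringsAsFactors = FALSE))
  if (!include_post_frameshift) rows <- rows[rows$cause != "post-frameshift", ]
  ## cluster: same kind+length(+stop codon), positions within tolerance
  key0 <- paste(rows$kind, rows$length_nt, ifelse(is.na(rows$stop_codon), "", rows$stop_codon))
  rows$cluster <- NA_integer_
  cl <- 0L
  for (k in unique(key0)) {
    idx <- which(key0 == k)
    idx <- idx[order(rows$ref_nt_start[idx])]
    pos <- rows$ref_nt_start[idx]
    brk <- c(TRUE, diff(pos) > tolerance)
    rows$cluster[idx] <- cl + cumsum(brk)
    cl <- max(rows$cluster[idx])
  }
  ev <- lapply(split(rows, rows$cluster), function(g) {
    data.frame(gene = genes, kind = g$kind[1L],
               ref_codon_start = g$ref_codon_start[1L],
               ref_nt_start = g$ref_nt_start[1L],
               length_nt = g$length_nt[1L],
               frameshifting = g$frameshifting[1L],
               stop_codon = g$stop_codon[1L],
               n_carriers = length(unique(g$taxon)),
               carriers = paste(sort(unique(g$taxon)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ev)
  out <- out[order(out$ref_nt_start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write disruption reports as TSV
#'
#' @param reports List of `disruption_report`s.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_disruption_tsv <- function(reports, path) {
  rows <- do.call(rbind, lapply(reports, function(rp) {
    d <- rp$disruptions
    if (!nrow(d)) {
      return(data.frame(taxon = rp$taxon, gene = rp$gene, kind = "none",
                        ref_codon_start = NA, ref_nt_start = NA,
                        length_nt = NA, frameshifting = NA, stop_codon = NA,
                        first_stop_codon = NA, truncation_fraction = NA,
                        stringsAsFactors = FALSE))
    }
    data.frame(taxon = rp$taxon, gene = rp$gene, d[, 1:6],
               first_stop_codon = rp$first_stop_codon,
               truncation_fraction = rp$truncation_fraction,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
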