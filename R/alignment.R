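#' Construct a codon alignment
#'
#' A codon alignment is the package's central sequence container: a set of
#' equal-length aligned coding sequences in the reading frame of a
#' designated functional reference taxon. Columns are nucleotide columns;
#' codon columns are consecutive triples in the reference frame (the
#' reference row must be in frame, i.e. its first non-gap nucleotide is
#' codon 1 position 1). Coordinates are 1-based and intervals closed.
#'
#' @param seqs Named character vector of aligned sequences (equal length,
#'   alphabet `A,C,G,T,N,-`).
#' @param ref_taxon Name of the functional reference sequence; must
#'   translate without internal stop codons.
#' @return An object of class `codon_aln`: list with `seqs`, `ref_taxon`,
#'   `n_col` (alignment width in nucleotides).
#' @export
codon_alignment <- function(seqs, ref_taxon) {
  if (is.null(names(seqs))) stop("'seqs' must be named")
  if (!ref_taxon %in% names(seqs))
    stop("reference taxon '", ref_taxon, "' not in alignment")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned sequences must have equal length")
  seqs <- toupper(seqs)
  structure(list(seqs = seqs, ref_taxon = ref_taxon, n_col = w),
            class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("Codon alignment: ", length(x$seqs), " taxa, ", x$n_col,
      " nt columns (", x$n_col %/% 3L, " codons), reference '",
      x$ref_taxon, "'\n", sep = "")
  invisible(x)
}

#' Codon state matrix of an alignment
#'
#' Converts a [codon_alignment()] to the integer state representation used
#' by the likelihood machinery: one row per taxon, one column per codon
#' column of the alignment, values 1..61 indexing
#' `genetic_code()$sense_codons`, and `NA` for missing states (codons
#' containing gaps or `N`). Stop codons are *not* representable as states;
#' by default they raise an error so that unrepaired pseudogene sequences
#' cannot silently enter a likelihood (see [repair_alignment()]);
#' `stops = "missing"` recodes them as `NA` instead.
#'
#' @param aln A `codon_aln`.
#' @param stops `"error"` (default) or `"missing"`.
#' @param code Genetic code.
#' @return Integer matrix, taxa x codons, with `NA` for missing.
#' @export
codon_states <- function(aln, stops = c("error", "missing"),
                         code = genetic_code()) {
  stops <- match.arg(stops)
  stopifnot(inherits(aln, "codon_aln"))
  if (aln$n_col %% 3L != 0L)
    stop("alignment width not a multiple of 3; not in codon frame")
  n_cod <- aln$n_col %/% 3L
  m <- matrix(NA_integer_, length(aln$seqs), n_cod,
              dimnames = list(names(aln$seqs), NULL))
  for (i in seq_along(aln$seqs)) {
    codons <- split_codons(aln$seqs[[i]])
    st <- codon_state(codons, code)
    is_stop <- codons %in% code$stop_codons
    if (any(is_stop) && stops == "error")
      stop("in-frame stop codon in '", names(aln$seqs)[i], "' at codon ",
           which(is_stop)[1L],
           "; repair the alignment first (see repair_alignment)")
    m[i, ] <- st
  }
  m
}

#' Repair a codon alignment for likelihood analysis
#'
#' Codon substitution models are defined over the 61 sense codons only, so
#' pseudogenized sequences must be repaired before entering a likelihood:
#' codon columns containing any alignment gap (which include all frameshift
#' columns) are removed, and remaining codons that are stop codons or
#' contain `N` are recoded as missing. The repair recipe applied is
#' recorded in the returned object's `"repair"` attribute and can be
#' logged by callers.
#'
#' @param aln A `codon_aln`.
#' @param code Genetic code.
#' @return A repaired `codon_aln` (attribute `repair` lists removed codon
#'   columns and recoded stop positions), flagged `repaired = TRUE`.
#' @export
repair_alignment <- function(aln, code = genetic_code()) {
  stopifnot(inherits(aln, "codon_aln"))
  if (aln$n_col %% 3L != 0L) {
    ## trim incomplete trailing codon
    aln$seqs <- substr(aln$seqs, 1L, 3L * (aln$n_col %/% 3L))
    aln$n_col <- 3L * (aln$n_col %/% 3L)
  }
  n_cod <- aln$n_col %/% 3L
  cods <- do.call(rbind, lapply(aln$seqs, split_codons))
  has_gap <- apply(cods, 2L, function(col) any(grepl("-", col, fixed = TRUE)))
  ## drop terminal stop column of the reference too (model is over the ORF)
  ref_cod <- cods[aln$ref_taxon, ]
  last_ref <- max(which(!grepl("[-N]", ref_cod)), 0L)
  if (last_ref > 0L && ref_cod[last_ref] %in% code$stop_codons)
    has_gap[last_ref] <- TRUE
  keep <- which(!has_gap)
  cods <- cods[, keep, drop = FALSE]
  n_stop <- 0L
  for (i in seq_len(nrow(cods))) {
    is_stop <- cods[i, ] %in% code$stop_codons
    if (any(is_stop)) {
      cods[i, is_stop] <- "NNN"
      n_stop <- n_stop + sum(is_stop)
    }
  }
  seqs <- apply(cods, 1L, paste, collapse = "")
  names(seqs) <- names(aln$seqs)
  out <- codon_alignment(seqs, aln$ref_taxon)
  attr(out, "repair") <- list(
    removed_codon_columns = setdiff(seq_len(n_cod), keep),
    n_stops_recoded = n_stop)
  attr(out, "repaired") <- TRUE
  out
}

#' Estimate codon equilibrium frequencies
#'
#' Computes the 61 sense-codon frequencies pi used by the substitution
#' model. `"F3x4"` (the default, the convention of mainstream codon-model
#' software) multiplies the position-specific nucleotide frequencies of
#' the alignment's three codon positions, zeroes the stop codons, and
#' renormalizes; `"equal"` gives 1/61 each; `"empirical"` counts observed
#' codons directly. All schemes floor frequencies at `1e-8` before the
#' final renormalization so that every sense codon has positive mass (a
#' requirement of the reversible-generator parameterization).
#'
#' @param aln A `codon_aln` (ignored for `"equal"`).
#' @param scheme One of `"F3x4"`, `"equal"`, `"empirical"`.
#' @param code Genetic code.
#' @return Numeric vector of length 61 summing to 1, named by codon, with
#'   attribute `scheme`.
#' @export
estimate_frequencies <- function(aln = NULL, scheme = c("F3x4", "equal", "empirical"),
                                 code = genetic_code()) {
  scheme <- match.arg(scheme)
  sense <- code$sense_codons
  if (scheme == "equal") {
    pi <- rep(1 / 61, 61)
  } else {
    stopifnot(inherits(aln, "codon_aln"))
    cods <- unlist(lapply(aln$seqs, split_codons), use.names = FALSE)
    cods <- cods[!grepl("[-N]", cods)]
    if (!length(cods)) stop("no complete codons in alignment")
    if (scheme == "empirical") {
      cnt <- table(factor(cods, levels = sense))
      pi <- as.numeric(cnt)
    } else {  # F3x4
      pos <- matrix(unlist(strsplit(cods, "", fixed = TRUE)), nrow = 3L)
      nf <- apply(pos, 1L, function(p)
        table(factor(p, levels = c("A", "C", "G", "T"))) / length(p))
      ## nf: 4 x 3 matrix of nucleotide freq by codon position
      pi <- vapply(sense, function(cod) {
        b <- strsplit(cod, "", fixed = TRUE)[[1L]]
        nf[b[1L], 1L] * nf[b[2L], 2L] * nf[b[3L], 3L]
      }, numeric(1))
    }
  }
  pi <- pmax(pi, 1e-8)
  pi <- pi / sum(pi)
  names(pi) <- sense
  attr(pi, "scheme") <- scheme
  pi
}
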