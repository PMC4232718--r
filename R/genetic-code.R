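#' The standard nuclear genetic code
#'
#' Returns the standard genetic code as used throughout the package: a
#' translation table over the 64 trinucleotides plus the fixed ordering of
#' the 61 sense codons that defines row/column indices of every codon rate
#' and probability matrix.
#'
#' The code table is taken from [Biostrings::GENETIC_CODE] (the standard
#' code, id 1), not re-typed here. Sense codons are ordered
#' lexicographically over the nucleotide alphabet (A, C, G, T); this
#' ordering is part of the package's numeric contract, since codon state
#' `i` always refers to `genetic_code()$sense_codons[i]`.
#'
#' @return A list with components:
#'   \describe{
#'     \item{codon_to_aa}{named character vector of length 64 mapping each
#'       codon to its one-letter amino acid, with `"*"` for the three stop
#'       codons (TAA, TAG, TGA).}
#'     \item{sense_codons}{character vector of the 61 non-stop codons in
#'       lexicographic (A < C < G < T) order.}
#'     \item{stop_codons}{character vector of the 3 stop codons.}
#'   }
#' @examples
#' code <- genetic_code()
#' code$codon_to_aa[["ATG"]]   # "M"
#' length(code$sense_codons)   # 61
#' @export
genetic_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  tab <- tab[order(names(tab))]  # A < C < G < T lexicographic
  sense <- names(tab)[tab != "*"]
  stops <- names(tab)[tab == "*"]
  list(codon_to_aa = tab, sense_codons = sense, stop_codons = stops)
}

#' Translate a coding nucleotide sequence
#'
#' Translates `seq` codon-by-codon in the given reading frame. Codons
#' containing `N` or an alignment gap `-` translate to `"X"` (unknown);
#' stop codons translate to `"*"`. Trailing nucleotides that do not form a
#' complete codon are ignored.
#'
#' @param seq A single nucleotide string over `A,C,G,T,N,-` (case
#'   insensitive).
#' @param frame 1-based frame offset, one of 1, 2, 3.
#' @param code Genetic code as returned by [genetic_code()].
#' @return A single protein string, one symbol per complete codon.
#' @examples
#' translate_cds("ATGTGA")  # "M*"
#' @export
translate_cds <- function(seq, frame = 1L, code = genetic_code()) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq))
    stop("'seq' must be a single character string")
  if (nchar(seq) == 0L) stop("empty sequence")
  if (!frame %in% 1:3) stop("'frame' must be 1, 2 or 3")
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1L]], bad[1L]))
  chars <- chars[frame:length(chars)]
  n_cod <- length(chars) %/% 3L
  if (n_cod == 0L) return("")
  m <- matrix(chars[seq_len(3L * n_cod)], nrow = 3L)
  codons <- paste0(m[1L, ], m[2L, ], m[3L, ])
  aa <- ifelse(grepl("[N-]", codons), "X", unname(code$codon_to_aa[codons]))
  paste(aa, collapse = "")
}

## Internal: codon string -> sense-codon state index (1..61), NA for
## anything else (gap, N, stop). Vectorized.
codon_state <- function(codons, code = genetic_code()) {
  match(codons, code$sense_codons)
}

## Internal: split an (aligned or plain) sequence string into codon triplets
## in frame 1. Length must be a multiple of 3 for alignment use.
split_codons <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars) %/% 3L
  m <- matrix(chars[seq_len(3L * n)], nrow = 3L)
  paste0(m[1L, ], m[2L, ], m[3L, ])
}
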