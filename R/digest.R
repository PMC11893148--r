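AA_ALLOWED <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y","X","B","Z","U")

# split a sequence into tryptic fragments: cleave C-terminal of K/R unless
# the next residue is P
tryptic_fragments <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(character(0))
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  substring(sequence, starts, ends)
}

#' Count observable tryptic peptides of a protein sequence
#'
#' In-silico trypsin digestion (cleave after K or R, suppressed before P).
#' With `missed_cleavages = m`, every concatenation of up to `m + 1`
#' consecutive fragments is a candidate peptide; distinct candidate sequences
#' with length in `[min_len, max_len]` are counted. This count is the iBAQ
#' divisor.
#'
#' @param sequence uppercase amino-acid string (standard 20 letters plus
#'   X/B/Z/U ambiguity codes).
#' @param min_len,max_len peptide length window (defaults 7-30).
#' @param missed_cleavages maximum missed cleavages (default 0).
#' @return Integer count of distinct observable peptides.
#' @export
#' @examples
#' count_observable_peptides("MKWVTFISLLLLFSSAYSRGVFRR")
count_observable_peptides <- function(sequence, min_len = 7L, max_len = 30L,
                                      missed_cleavages = 0L) {
  if (nchar(sequence) == 0L) abort("empty protein sequence")
  stopifnot(min_len >= 1L, min_len <= max_len, missed_cleavages >= 0L)
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, AA_ALLOWED)
  if (length(bad) > 0L)
    abort("sequence contains non-amino-acid character(s): %s",
          paste(bad, collapse = ", "))
  frags <- tryptic_fragments(sequence)
  k <- length(frags)
  peptides <- character(0)
  for (i in seq_len(k)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > k) break
      pep <- paste(frags[i:j], collapse = "")
      len <- nchar(pep)
      if (len >= min_len && len <= max_len) peptides <- c(peptides, pep)
    }
  }
  length(unique(peptides))
}

#' Build a digestion index over a protein FASTA
#'
#' @param sequences named character vector from [read_fasta()].
#' @param min_len,max_len,missed_cleavages see [count_observable_peptides()].
#' @return A `digest_index`: named integer vector (accession -> observable
#'   peptide count) with the digestion parameters attached as attributes.
#' @export
digest_index <- function(sequences, min_len = 7L, max_len = 30L,
                         missed_cleavages = 0L) {
  counts <- vapply(sequences, count_observable_peptides, integer(1),
                   min_len = min_len, max_len = max_len,
                   missed_cleavages = missed_cleavages)
  structure(counts, min_len = min_len, max_len = max_len,
            missed_cleavages = missed_cleavages, class = "digest_index")
}
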