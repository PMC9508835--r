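#' Transcript records
#'
#' A transcript record holds an RNA sequence (internally always over
#' `A`, `C`, `G`, `U`; `T` is converted on input) together with optional
#' annotations used downstream: `utr5_end` (1-based position of the last
#' 5'-UTR nucleotide), `start_codon` (1-based position of the A of the
#' main AUG) and `numbering_offset` (integer mapping internal position 1
#' to the transcript-level "+1" coordinate; e.g. a reporter carrying 45
#' promoter-derived nucleotides 5' of the transcript start uses -45).
#'
#' @param id Character identifier.
#' @param sequence Character string over `A`, `C`, `G`, `U`/`T`
#'   (case-insensitive).
#' @param utr5_end,start_codon,numbering_offset Optional integer
#'   annotations (see Details).
#'
#' @return An object of class `transcript_record`: a list with elements
#'   `id`, `sequence` and `annotations`.
#' @examples
#' tr <- transcript_record("x", "ggcacgaAUGgcu", start_codon = 8, utr5_end = 7)
#' nchar(tr$sequence)
#' @export
transcript_record <- function(id, sequence, utr5_end = NULL,
                              start_codon = NULL, numbering_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  seq <- normalize_rna(sequence)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence for record '", id, "'")
  if (!is.null(start_codon)) {
    start_codon <- as.integer(start_codon)
    if (start_codon < 1L || start_codon + 2L > n)
      stop("start_codon out of range")
    if (substr(seq, start_codon, start_codon + 2L) != "AUG")
      stop("residues at start_codon do not spell AUG")
  }
  if (!is.null(utr5_end)) {
    utr5_end <- as.integer(utr5_end)
    if (!is.null(start_codon) && utr5_end >= start_codon)
      stop("utr5_end must precede start_codon")
  }
  structure(list(id = id, sequence = seq,
                 annotations = list(utr5_end = utr5_end,
                                    start_codon = start_codon,
                                    numbering_offset = as.integer(numbering_offset))),
            class = "transcript_record")
}

# uppercase, T -> U, reject anything outside the RNA alphabet
normalize_rna <- function(sequence) {
  seq <- chartr("t", "u", toupper(sequence))
  seq <- chartr("T", "U", seq)
  bad <- regmatches(seq, regexpr("[^ACGU]", seq))
  if (length(bad) > 0 && nzchar(bad))
    stop("non-nucleotide character '", bad, "' in sequence")
  seq
}

#' @export
print.transcript_record <- function(x, ...) {
  cat("<transcript_record> ", x$id, ": ", nchar(x$sequence), " nt",
      if (!is.null(x$annotations$start_codon))
        paste0(", AUG at ", x$annotations$start_codon), "\n", sep = "")
  invisible(x)
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]
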