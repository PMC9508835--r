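#' Read RNA sequences from a FASTA file
#'
#' Parses a FASTA file into a list of [transcript_record()] objects.
#' Sequences are upper-cased and `T` residues are converted to `U`;
#' any character outside `A/C/G/U/T` is an error.
#'
#' @param path Path to a FASTA file.
#' @return A list of `transcript_record` objects, one per entry.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), fa)
#' read_rna_fasta(fa)[[1]]$sequence
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  lapply(seq_along(set), function(i) {
    transcript_record(names(set)[i], as.character(set[[i]]))
  })
}

#' Write transcript records to FASTA
#'
#' @param records A list of [transcript_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id), r$sequence)))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SHAPE reactivity profiles

#' SHAPE reactivity profiles
#'
#' A reactivity profile is a data frame with one row per nucleotide and
#' columns `position` (1-based, contiguous from 1), `raw` (reactivity on
#' the mutation-rate scale), `norm` (normalized reactivity), `stderr`
#' (standard error) and `mask` (one of `none`, `low_depth`,
#' `high_replicate_variability`, `primer_region`). Missing values are
#' `NA` internally and serialize as the `-999` sentinel.
#'
#' @param position Integer vector, strictly increasing and contiguous
#'   from 1.
#' @param raw,norm,stderr Numeric vectors (NA allowed).
#' @param mask Character vector of mask reasons.
#' @return A data frame of class `shape_profile`.
#' @export
shape_profile <- function(position, raw = NA_real_, norm = NA_real_,
                          stderr = NA_real_, mask = "none") {
  position <- as.integer(position)
  if (length(position) == 0L || !identical(position, seq_len(length(position))))
    stop("profile positions must be contiguous from 1")
  ok <- c("none", "low_depth", "high_replicate_variability", "primer_region")
  mask <- rep_len(as.character(mask), length(position))
  if (!all(mask %in% ok)) stop("unknown mask reason")
  out <- data.frame(position = position,
                    raw = rep_len(as.numeric(raw), length(position)),
                    norm = rep_len(as.numeric(norm), length(position)),
                    stderr = rep_len(as.numeric(stderr), length(position)),
                    mask = mask)
  class(out) <- c("shape_profile", "data.frame")
  out
}

#' Working reactivity values of a profile
#'
#' Returns the per-position reactivity used by downstream stages:
#' normalized values where available, raw values otherwise, and `NA`
#' at masked positions.
#'
#' @param profile A [shape_profile()].
#' @return Numeric vector, one value per position.
#' @export
reactivities <- function(profile) {
  v <- if (any(!is.na(profile$norm))) profile$norm else profile$raw
  v[profile$mask != "none"] <- NA_real_
  v
}

#' Read and write `.shape` files
#'
#' Three whitespace-delimited columns: 1-based position, reactivity and
#' standard error, with `-999` marking missing data in both value
#' columns. Values are written with enough digits to round-trip within
#' 1e-6.
#'
#' @param profile A [shape_profile()]. Values written are the working
#'   reactivities (normalized if present, else raw).
#' @param path File path.
#' @return `read_shape` returns a `shape_profile` (values land in the
#'   `norm` column); `write_shape` returns `path` invisibly.
#' @export
write_shape <- function(profile, path) {
  v <- reactivities(profile)
  e <- profile$stderr
  e[is.na(v)] <- NA_real_
  vv <- ifelse(is.na(v), NO_DATA, v)
  ee <- ifelse(is.na(e), ifelse(is.na(v), NO_DATA, 0), e)
  writeLines(sprintf("%d\t%.8g\t%.8g", profile$position, vv, ee), path)
  invisible(path)
}

#' @rdname write_shape
#' @export
read_shape <- function(path) {
  tab <- read.table(path, header = FALSE,
                    col.names = c("position", "reactivity", "stderr"))
  if (!identical(as.integer(tab$position), seq_len(nrow(tab))))
    stop("positions in ", path, " are not contiguous from 1")
  v <- tab$reactivity
  e <- tab$stderr
  miss <- v <= NO_DATA
  v[miss] <- NA_real_
  e[miss] <- NA_real_
  shape_profile(tab$position, norm = v, stderr = e,
                mask = ifelse(miss, "low_depth", "none"))
}

# ---------------------------------------------------------------------------
# Secondary structures: pair sets, CT, dot-bracket

#' Secondary structure objects
#'
#' A secondary structure is a set of base pairs over a sequence. Pairs
#' are stored as a two-column integer matrix `(i, j)` with `i < j`,
#' sorted by `i`. Structures produced by the folding engine are nested
#' (pseudoknot-free) and obey the minimum hairpin-loop length of 3.
#'
#' @param sequence RNA sequence string the pairs refer to.
#' @param pairs Two-column matrix (or empty) of paired positions.
#' @param energy Optional free energy in kcal/mol.
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(sequence, pairs, energy = NULL) {
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs) > 0) {
    if (any(pairs < 1L | pairs > n)) stop("pair index out of range")
    if (any(pairs[, 2] - pairs[, 1] < 4L))
      stop("hairpin loop shorter than 3 nucleotides")
    if (anyDuplicated(c(pairs[, 1], pairs[, 2])))
      stop("a position participates in more than one pair")
  }
  structure(list(sequence = sequence, pairs = pairs, energy = energy),
            class = "rna_structure")
}

as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  ij <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  ij <- ij[order(ij[, 1]), , drop = FALSE]
  dimnames(ij) <- list(NULL, c("i", "j"))
  ij
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", nchar(x$sequence), " nt, ", nrow(x$pairs), " pairs",
      if (!is.null(x$energy)) sprintf(", %.2f kcal/mol", x$energy),
      "\n", sep = "")
  invisible(x)
}

# partner vector: 0 = unpaired
pair_partner <- function(structure) {
  n <- nchar(structure$sequence)
  p <- integer(n)
  if (nrow(structure$pairs) > 0) {
    p[structure$pairs[, 1]] <- structure$pairs[, 2]
    p[structure$pairs[, 2]] <- structure$pairs[, 1]
  }
  p
}

#' Convert between structures, dot-bracket strings and pair sets
#'
#' `structure_to_dotbracket()` renders a nested structure as a balanced
#' `()` string; `dotbracket_to_pairs()` parses such a string into a pair
#' matrix. Pseudoknots are not representable.
#'
#' @param structure An [rna_structure()].
#' @param text Dot-bracket string using `.`, `(` and `)`.
#' @return A character string, or a two-column pair matrix.
#' @examples
#' dotbracket_to_pairs("((...))")
#' @export
structure_to_dotbracket <- function(structure) {
  n <- nchar(structure$sequence)
  db <- rep(".", n)
  if (nrow(structure$pairs) > 0) {
    assert_nested(structure$pairs)
    db[structure$pairs[, 1]] <- "("
    db[structure$pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' @rdname structure_to_dotbracket
#' @export
dotbracket_to_pairs <- function(text) {
  chars <- seq_chars(text)
  if (!all(chars %in% c(".", "(", ")")))
    stop("dot-bracket string may contain only '.', '(' and ')'")
  open <- integer(0)
  pairs <- NULL
  for (k in seq_along(chars)) {
    if (chars[k] == "(") open <- c(open, k)
    else if (chars[k] == ")") {
      if (length(open) == 0L)
        stop("unbalanced bracket at position ", k)
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L)
    stop("unbalanced bracket at position ", open[length(open)])
  as_pair_matrix(pairs)
}

assert_nested <- function(pairs) {
  if (nrow(pairs) < 2) return(invisible(TRUE))
  for (a in seq_len(nrow(pairs) - 1)) {
    i <- pairs[a, 1]; j <- pairs[a, 2]
    b <- (a + 1):nrow(pairs)
    k <- pairs[b, 1]; l <- pairs[b, 2]
    if (any(k < j & j < l & i < k))
      stop("pseudoknotted pairs cannot be written in dot-bracket notation")
  }
  invisible(TRUE)
}

#' Read and write connect (CT) files
#'
#' The standard CT layout: a header line with the length and title, then
#' one row per nucleotide with index, residue, 5' and 3' neighbors, pair
#' partner (0 if unpaired) and natural numbering. The pairing column must
#' be involutive.
#'
#' @param structure An [rna_structure()].
#' @param path File path.
#' @param title Title written to the CT header.
#' @return `read_ct` returns an `rna_structure`; `write_ct` returns
#'   `path` invisibly.
#' @export
write_ct <- function(structure, path, title = "structure") {
  n <- nchar(structure$sequence)
  p <- pair_partner(structure)
  res <- seq_chars(structure$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, title), con)
  writeLines(sprintf("%d %s %d %d %d %d",
                     1:n, res, 0:(n - 1), c(2:n, 0), p, 1:n), con)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty CT file: ", path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed CT header in ", path)
  fields <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  res <- vapply(fields, `[[`, "", 2)
  partner <- as.integer(vapply(fields, `[[`, "", 5))
  if (!all(partner[partner > 0] <= n) ||
      !all(partner[partner[partner > 0]] == which(partner > 0)))
    stop("CT pairing column is not involutive in ", path)
  keep <- which(partner > seq_len(n))
  rna_structure(paste(res, collapse = ""), cbind(keep, partner[keep]))
}

#' Write a pairing-probability table
#'
#' Serializes a pair-probability matrix as a TSV of `(i, j, probability)`
#' for entries at or above `min_prob`, upper triangle only.
#'
#' @param pp A square pairing-probability matrix.
#' @param path Output path.
#' @param min_prob Smallest probability written (default 0.001).
#' @return `path`, invisibly.
#' @export
write_pairprob <- function(pp, path, min_prob = 0.001) {
  idx <- which(upper.tri(pp) & pp >= min_prob, arr.ind = TRUE)
  tab <- data.frame(i = idx[, 1], j = idx[, 2],
                    probability = signif(pp[idx], 6))
  tab <- tab[order(tab$i, tab$j), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
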