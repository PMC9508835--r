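RNA_CODE <- c(A = 0L, C = 1L, G = 2L, U = 3L)

# assemble the parameter list handed to the C++ engine
engine_params <- function(model) {
  dense <- function(table) {
    sizes <- as.integer(names(table))
    out <- numeric(max(sizes) + 1)
    out[sizes + 1] <- table
    out
  }
  stack <- model$stack
  stack[is.na(stack)] <- 0
  list(stack = unname(stack), hairpin = dense(model$hairpin),
       bulge = dense(model$bulge), internal = dense(model$internal),
       ml_a = model$ml_a, ml_b = model$ml_b, ml_c = model$ml_c,
       RT = model$RT, max_dist = model$max_pairing_dist,
       max_interior = model$max_interior)
}

prepare_fold_input <- function(record, profile, model) {
  seq <- if (inherits(record, "transcript_record")) record$sequence
         else normalize_rna(record)
  n <- nchar(seq)
  if (n > 1200L)
    stop("sequence longer than 1200 nt; the folding engine runs in a single ",
         "partition window and refuses longer inputs")
  codes <- unname(RNA_CODE[seq_chars(seq)])
  pseudo <- numeric(n)
  if (!is.null(profile)) {
    v <- reactivities(profile)
    if (length(v) != n)
      stop("reactivity profile length (", length(v),
           ") does not match sequence length (", n, ")")
    pseudo <- shape_pseudo_energy(v, model)
  }
  list(seq = seq, codes = codes, pseudo = pseudo)
}

#' SHAPE-directed minimum free energy structure
#'
#' Computes the nested secondary structure minimizing the total free
#' energy (nearest-neighbor terms plus optional per-nucleotide
#' pseudo-free energies) by dynamic programming. Ties are broken toward
#' structures with fewer pairs, then by a fixed traceback order, so the
#' result is deterministic.
#'
#' @param record A [transcript_record()] or plain sequence string.
#' @param profile Optional [shape_profile()] whose working reactivities
#'   steer folding through [shape_pseudo_energy()]. `NULL` folds with
#'   thermodynamic terms only.
#' @param model An [energy_model()].
#' @return An [rna_structure()] with the `energy` field populated
#'   (kcal/mol).
#' @examples
#' s <- mfe_fold("GGGGGAAAACCCCC")
#' s$energy
#' @export
mfe_fold <- function(record, profile = NULL, model = energy_model()) {
  inp <- prepare_fold_input(record, profile, model)
  res <- .fold_engine(inp$codes, inp$pseudo, engine_params(model), FALSE)
  partner <- res$partner
  keep <- which(partner > seq_along(partner))
  rna_structure(inp$seq, cbind(keep, partner[keep]), energy = res$energy)
}

#' Partition-function pairing probabilities
#'
#' Computes the Boltzmann pairing-probability matrix `P(i, j)` at 37 C
#' under the same energy function as [mfe_fold()], via inside-outside
#' dynamic programming with internal rescaling for long sequences.
#'
#' @inheritParams mfe_fold
#' @return A symmetric `n x n` matrix with `P[i, j]` the probability
#'   that `i` pairs `j` in the thermodynamic ensemble. The per-position
#'   paired probability is `rowSums()` of the result.
#' @export
partition_pair_probs <- function(record, profile = NULL,
                                 model = energy_model()) {
  inp <- prepare_fold_input(record, profile, model)
  res <- .fold_engine(inp$codes, inp$pseudo, engine_params(model), TRUE)
  res$pairprob
}

#' Free energy of a fixed secondary structure
#'
#' Decomposes a structure into its loops (hairpin, stack, bulge,
#' internal, multibranch, exterior) and sums the energy-model terms, in
#' the manner of the classic \code{efn2} structure-evaluation tool. With
#' `profile = NULL` this is a purely thermodynamic evaluation; with a
#' profile, SHAPE pseudo-free energies are added per helix stack, and
#' the value of the minimum free energy structure equals the energy
#' reported by [mfe_fold()].
#'
#' @param structure An [rna_structure()].
#' @param profile Optional [shape_profile()] (adds pseudo-energies).
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol (0 for the open chain).
#' @export
evaluate_energy <- function(structure, profile = NULL,
                            model = energy_model()) {
  seq <- structure$sequence
  n <- nchar(seq)
  chars <- seq_chars(seq)
  pairs <- structure$pairs
  if (nrow(pairs) == 0L) return(0)

  violations <- character(0)
  ptype <- paste0(chars[pairs[, 1]], chars[pairs[, 2]])
  bad <- !(ptype %in% PAIR_TYPES)
  if (any(bad))
    violations <- c(violations, paste0("non-canonical pair ", pairs[bad, 1],
                                       "-", pairs[bad, 2], " (", ptype[bad], ")"))
  if (any(pairs[, 2] - pairs[, 1] > model$max_pairing_dist))
    violations <- c(violations, "pair span exceeds max_pairing_dist")
  if (length(violations) > 0)
    stop("invalid structure: ", paste(violations, collapse = "; "))
  assert_nested(pairs)

  pseudo <- numeric(n)
  if (!is.null(profile)) {
    v <- reactivities(profile)
    if (length(v) != n) stop("profile length does not match sequence")
    pseudo <- shape_pseudo_energy(v, model)
  }

  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]

  # children of the loop closed by (i, j); i = 0, j = n + 1 for exterior
  loop_children <- function(i, j) {
    kids <- NULL
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        kids <- rbind(kids, c(k, partner[k]))
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    kids
  }

  total <- 0
  stack_pairs <- rbind(loop_children(0L, n + 1L))
  todo <- stack_pairs
  while (!is.null(todo) && nrow(todo) > 0) {
    i <- todo[1, 1]; j <- todo[1, 2]
    todo <- todo[-1, , drop = FALSE]
    kids <- loop_children(i, j)
    nk <- if (is.null(kids)) 0L else nrow(kids)
    if (nk == 0L) {
      size <- j - i - 1L
      if (size < 3L) stop("invalid structure: hairpin loop of size ", size)
      total <- total + loop_penalty(model$hairpin, size, model$RT)
    } else if (nk == 1L) {
      k <- kids[1, 1]; l <- kids[1, 2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        total <- total + model$stack[paste0(chars[i], chars[j]),
                                     paste0(chars[k], chars[l])] +
          pseudo[i] + pseudo[j] + pseudo[k] + pseudo[l]
      } else if (l1 == 0L || l2 == 0L) {
        total <- total + loop_penalty(model$bulge, l1 + l2, model$RT)
      } else {
        total <- total + loop_penalty(model$internal, l1 + l2, model$RT)
      }
    } else {
      unpaired <- (j - i - 1L) - sum(kids[, 2] - kids[, 1] + 1L)
      total <- total + model$ml_a + model$ml_b * (nk + 1L) +
        model$ml_c * unpaired
    }
    todo <- rbind(todo, kids)
  }
  total
}
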