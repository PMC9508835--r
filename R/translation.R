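#' Strip base pairs around the translation initiation site
#'
#' Returns the reference structure minus every pair with either endpoint
#' inside the window `[A - w, A + w]` around the start-codon adenosine.
#' All other pairs are untouched: this is the non-equilibrium constraint
#' (the RNA is not allowed to refold) used for unfolding-cost scoring.
#'
#' @param reference An [rna_structure()].
#' @param start_a 1-based position of the A of the start codon.
#' @param w Window half-width in nucleotides, conventionally 13-16
#'   (default 15).
#' @return An [rna_structure()] with the window single-stranded; the
#'   number of removed pairs is attached as attribute `pairs_removed`.
#' @export
constrain_structure <- function(reference, start_a, w = 15L) {
  n <- nchar(reference$sequence)
  if (start_a < 1L || start_a > n) stop("start position outside sequence")
  lo <- start_a - w
  hi <- start_a + w
  if (lo < 1L || hi > n) {
    warning("unfolding window clipped to sequence bounds")
    lo <- max(1L, lo)
    hi <- min(n, hi)
  }
  pairs <- reference$pairs
  touches <- (pairs[, 1] >= lo & pairs[, 1] <= hi) |
             (pairs[, 2] >= lo & pairs[, 2] <= hi)
  out <- rna_structure(reference$sequence, pairs[!touches, , drop = FALSE])
  attr(out, "pairs_removed") <- sum(touches)
  out
}

#' Unfolding cost of the translation initiation site
#'
#' The non-equilibrium free-energy cost of making the start-codon region
#' single-stranded: `dG_unfold = dG_constrained - dG_reference`, where
#' the constrained structure is the reference with every pair touching
#' the `[A - w, A + w]` window removed ([constrain_structure()]), and
#' both structures are evaluated with [evaluate_energy()]. Following the
#' efn2 convention for SHAPE-directed structures, the evaluation is
#' thermodynamic-only by default (no pseudo-energies), even when the
#' reference was folded with SHAPE data.
#'
#' @param reference An [rna_structure()], typically the SHAPE-directed
#'   minimum free energy structure of the construct.
#' @param start_a 1-based position of the start-codon adenosine.
#' @param w Window half-width (default 15; the conventional sweep is
#'   13-16).
#' @param model An [energy_model()].
#' @param profile Optional [shape_profile()]; supply to include
#'   pseudo-energies in the evaluation (off by default).
#' @param label Construct label carried into the result.
#' @return A data frame of class `unfold_result` with one row:
#'   `label`, `start_a`, `w`, `dg_reference`, `dg_constrained`,
#'   `dg_unfold`, `pairs_removed`.
#' @export
delta_g_unfold <- function(reference, start_a, w = 15L,
                           model = energy_model(), profile = NULL,
                           label = "construct") {
  constrained <- constrain_structure(reference, start_a, w)
  g_ref <- evaluate_energy(reference, profile, model)
  g_con <- evaluate_energy(constrained, profile, model)
  out <- data.frame(label = label, start_a = as.integer(start_a),
                    w = as.integer(w), dg_reference = g_ref,
                    dg_constrained = g_con, dg_unfold = g_con - g_ref,
                    pairs_removed = attr(constrained, "pairs_removed"))
  class(out) <- c("unfold_result", "data.frame")
  out
}

#' Window sweep of the unfolding cost
#'
#' @inheritParams delta_g_unfold
#' @param w_range Window half-widths to evaluate (default `13:16`).
#' @return An `unfold_result` data frame, one row per half-width.
#' @export
delta_g_unfold_sweep <- function(reference, start_a, w_range = 13:16,
                                 model = energy_model(), profile = NULL,
                                 label = "construct") {
  out <- do.call(rbind, lapply(w_range, function(w)
    delta_g_unfold(reference, start_a, w, model, profile, label)))
  class(out) <- c("unfold_result", "data.frame")
  out
}

#' Relative translation from dual-luciferase readouts
#'
#' Per replicate, nanoluciferase luminescence is normalized to the
#' co-transfected firefly signal (NL/FF); per construct, replicate
#' ratios are divided by the native construct's mean ratio to give
#' relative translation, summarized as mean, SD and n. The native
#' construct's relative translation is 1 by construction. Replicates
#' with non-positive firefly signal are dropped with a warning.
#'
#' @param luminescence Data frame with columns `construct`, `replicate`,
#'   `nl`, `ff`.
#' @param native Label of the native-sequence construct.
#' @param threshold Effect-classification threshold as a fractional
#'   change (default 0.15).
#' @return A data frame of class `translation_record` with columns
#'   `construct`, `mean_relative`, `sd_relative`, `n`, `effect`.
#' @export
relative_translation <- function(luminescence, native, threshold = 0.15) {
  need <- c("construct", "replicate", "nl", "ff")
  if (!all(need %in% names(luminescence)))
    stop("luminescence table needs columns: ", paste(need, collapse = ", "))
  if (!native %in% luminescence$construct)
    stop("native label '", native, "' not present")
  bad <- luminescence$ff <= 0
  if (any(bad)) {
    warning(sum(bad), " replicate(s) with non-positive firefly signal dropped")
    luminescence <- luminescence[!bad, ]
  }
  if (nrow(luminescence) == 0L) stop("no usable replicates remain")
  ratio <- luminescence$nl / luminescence$ff
  native_mean <- mean(ratio[luminescence$construct == native])
  rel <- ratio / native_mean
  split_rel <- split(rel, luminescence$construct)
  out <- data.frame(
    construct = names(split_rel),
    mean_relative = vapply(split_rel, mean, 0.0),
    sd_relative = vapply(split_rel, function(x)
      if (length(x) < 2L) NA_real_ else sd(x), 0.0),
    n = vapply(split_rel, length, 0L),
    row.names = NULL)
  out$effect <- classify_effect(out$mean_relative, threshold)
  ord <- order(match(out$construct, unique(luminescence$construct)))
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("translation_record", "data.frame")
  out
}

#' Classify a translation effect
#'
#' A relative translation at or below `1 - threshold` is a `decrease`,
#' at or above `1 + threshold` an `increase`, anything between is
#' `no_effect`. The boundary itself (exactly a 15% change by default)
#' counts as an effect.
#'
#' @param relative Positive relative-translation values.
#' @param threshold Fractional change defining an effect (default 0.15).
#' @return Character vector over `increase`, `no_effect`, `decrease`.
#' @export
classify_effect <- function(relative, threshold = 0.15) {
  if (any(relative <= 0, na.rm = TRUE)) stop("relative translation must be > 0")
  ifelse(relative <= 1 - threshold, "decrease",
         ifelse(relative >= 1 + threshold, "increase", "no_effect"))
}

#' Two-tailed t-test between two groups
#'
#' Welch's unequal-variance two-sample t-test by default (group sizes
#' and variances in mutant panels differ); set `var_equal = TRUE` for
#' Student's variant.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances (default `FALSE`).
#' @return A list with `t` and `p` (two-tailed).
#' @export
group_ttest <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least two values")
  res <- t.test(values_a, values_b, var.equal = var_equal,
                alternative = "two.sided")
  list(t = unname(res$statistic), p = res$p.value)
}

#' Scan a 5'-UTR for upstream open reading frames
#'
#' Finds every occurrence of the given start codons 5' of the annotated
#' main start codon that opens an in-frame stretch of at least `min_len`
#' nucleotides (start through the last codon before the first in-frame
#' stop; ORFs that run past the analyzed region without a stop are
#' flagged stop-less). Each call records whether the start codon is
#' followed by a G (the favorable `CUG/G`-type context).
#'
#' @param record A [transcript_record()] with `start_codon` annotated.
#' @param start_codons Codons treated as initiators (default AUG and
#'   CUG; near-cognate GUG/UUG/ACG may be added).
#' @param min_len Minimum ORF length in nucleotides (default 30).
#' @return A data frame with columns `start`, `codon`, `stop`
#'   (position of the first stop-codon nucleotide, `NA` if stop-less),
#'   `length_nt`, `followed_by_g`.
#' @export
scan_uorfs <- function(record, start_codons = c("AUG", "CUG"),
                       min_len = 30L) {
  main <- record$annotations$start_codon
  if (is.null(main)) stop("record has no annotated main start codon")
  seq <- record$sequence
  n <- nchar(seq)
  stops <- c("UAA", "UAG", "UGA")
  calls <- NULL
  for (p in seq_len(main - 1L)) {
    if (p + 2L > n) break
    codon <- substr(seq, p, p + 2L)
    if (!codon %in% start_codons) next
    stop_at <- NA_integer_
    q <- p + 3L
    while (q + 2L <= n) {
      if (substr(seq, q, q + 2L) %in% stops) { stop_at <- q; break }
      q <- q + 3L
    }
    len <- if (is.na(stop_at)) {
      3L * ((n - p + 1L) %/% 3L)
    } else stop_at - p
    if (len < min_len) next
    calls <- rbind(calls, data.frame(
      start = p, codon = codon, stop = stop_at, length_nt = len,
      followed_by_g = p + 3L <= n && substr(seq, p + 3L, p + 3L) == "G"))
  }
  if (is.null(calls))
    calls <- data.frame(start = integer(0), codon = character(0),
                        stop = integer(0), length_nt = integer(0),
                        followed_by_g = logical(0))
  calls
}

#' Structure-translation summary over a mutant panel
#'
#' Joins per-construct unfolding costs, relative translation and
#' structure-group assignments into the panel-level report: per-group
#' translation and unfolding-cost distributions (median, IQR), pairwise
#' Welch t-tests between groups on both quantities, and the overall
#' Spearman and Pearson correlations between unfolding cost and
#' relative translation.
#'
#' @param unfold An `unfold_result` data frame (one row per construct).
#' @param translation A `translation_record` data frame.
#' @param grouping Optional [kmeans_groups()] result; when `NULL`, all
#'   constructs form one group and between-group tests are skipped.
#' @param luminescence Optional raw replicate table (as for
#'   [relative_translation()]) used for per-replicate group tests.
#' @return A list of class `structure_translation_report` with elements
#'   `per_construct`, `per_group`, `group_tests` and `correlation`.
#' @export
structure_translation_report <- function(unfold, translation,
                                         grouping = NULL,
                                         luminescence = NULL) {
  miss_t <- setdiff(unfold$label, translation$construct)
  miss_u <- setdiff(translation$construct, unfold$label)
  if (length(miss_t) || length(miss_u))
    stop("labels missing from ",
         if (length(miss_t)) paste0("translation: ",
                                    paste(miss_t, collapse = ", ")),
         if (length(miss_u)) paste0(" unfold: ",
                                    paste(miss_u, collapse = ", ")))
  tab <- merge(unfold[, c("label", "dg_unfold")],
               translation[, c("construct", "mean_relative", "effect")],
               by.x = "label", by.y = "construct")
  tab$group <- 1L
  if (!is.null(grouping))
    tab$group <- grouping$assignments$group[
      match(tab$label, grouping$assignments$label)]

  per_group <- do.call(rbind, lapply(split(tab, tab$group), function(g)
    data.frame(group = g$group[1], n = nrow(g),
               translation_median = median(g$mean_relative),
               translation_iqr = IQR(g$mean_relative),
               dg_unfold_median = median(g$dg_unfold),
               dg_unfold_iqr = IQR(g$dg_unfold))))

  groups <- sort(unique(tab$group))
  tests <- NULL
  if (length(groups) > 1L) {
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      ga <- tab[tab$group == groups[a], ]
      gb <- tab[tab$group == groups[b], ]
      if (nrow(ga) < 2L || nrow(gb) < 2L) next
      tt <- group_ttest(ga$mean_relative, gb$mean_relative)
      td <- if (sd(ga$dg_unfold) > 0 || sd(gb$dg_unfold) > 0)
        group_ttest(ga$dg_unfold, gb$dg_unfold) else list(t = NA, p = NA)
      tests <- rbind(tests, data.frame(
        group_a = groups[a], group_b = groups[b],
        translation_t = tt$t, translation_p = tt$p,
        dg_unfold_t = td$t, dg_unfold_p = td$p))
    }
  }

  correlation <- if (sd(tab$dg_unfold) > 0 && sd(tab$mean_relative) > 0) {
    list(spearman = cor(tab$dg_unfold, tab$mean_relative, method = "spearman"),
         pearson = cor(tab$dg_unfold, tab$mean_relative))
  } else list(spearman = NA_real_, pearson = NA_real_)

  structure(list(per_construct = tab, per_group = per_group,
                 group_tests = tests, correlation = correlation),
            class = "structure_translation_report")
}

#' @export
print.structure_translation_report <- function(x, ...) {
  cat("<structure_translation_report>\n")
  print(x$per_group, row.names = FALSE)
  cat(sprintf("Spearman(dG_unfold, translation) = %.3f\n",
              x$correlation$spearman))
  invisible(x)
}
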