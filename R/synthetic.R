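#' Tile structure-destabilizing UUAUUA mutants across a 5'-UTR
#'
#' Generates the panel of six-nucleotide `5'-UUAUUA-3'` substitution
#' variants tiled in consecutive non-overlapping windows from position 1
#' to `region_end` (normally the last position before the Kozak
#' sequence). Mutants are named by the 1-based position of their 3'-most
#' substituted nucleotide, so a 252-nt region yields 42 mutants named
#' 6, 12, ..., 252. A trailing window shorter than 6 nt is dropped with
#' a warning. A variant whose window already reads UUAUUA in the native
#' sequence is flagged degenerate.
#'
#' @param native A [transcript_record()].
#' @param region_end Last 1-based position eligible for substitution.
#' @return A data frame of class `mutant_panel` with columns `name`,
#'   `start`, `end`, `is_degenerate`, `sequence`.
#' @examples
#' native <- transcript_record("wt", strrep("GC", 30))
#' tile_mutants(native, 24)$name
#' @export
tile_mutants <- function(native, region_end) {
  seq <- native$sequence
  n <- nchar(seq)
  region_end <- as.integer(region_end)
  if (region_end > n) stop("region_end beyond sequence length")
  if (region_end < 6L) {
    warning("region_end < 6: empty mutant panel")
    out <- data.frame(name = integer(0), start = integer(0), end = integer(0),
                      is_degenerate = logical(0), sequence = character(0))
    class(out) <- c("mutant_panel", "data.frame")
    return(out)
  }
  if (region_end %% 6L != 0L) {
    warning("region_end not divisible by 6; trailing partial window dropped")
    region_end <- 6L * (region_end %/% 6L)
  }
  ends <- seq(6L, region_end, by = 6L)
  rows <- lapply(ends, function(e) {
    s <- e - 5L
    mut <- paste0(substr(seq, 1L, s - 1L), "UUAUUA",
                  substr(seq, e + 1L, n))
    data.frame(name = e, start = s, end = e,
               is_degenerate = substr(seq, s, e) == "UUAUUA",
               sequence = mut)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mutant_panel", "data.frame")
  out
}

#' Random sequence with a target G+C content
#'
#' Each position is independently G or C with probability `gc_fraction`
#' (split evenly between the two), A or U otherwise. Deterministic given
#' the seed.
#'
#' @param length Sequence length (>= 1).
#' @param gc_fraction Expected G+C fraction in `[0, 1]` (a G/C-rich
#'   5'-UTR such as the one motivating this package has about 0.58).
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A [transcript_record()].
#' @export
random_structured_sequence <- function(length, gc_fraction = 0.58, seed = 1L,
                                       id = "random") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  set.seed(seed)
  gc <- runif(length) < gc_fraction
  res <- ifelse(gc, ifelse(runif(length) < 0.5, "G", "C"),
                ifelse(runif(length) < 0.5, "A", "U"))
  transcript_record(id, paste(res, collapse = ""))
}

#' Simulation parameters for synthetic probing and translation data
#'
#' Per-read mutation probabilities place the simulated rate separation
#' in the regime where the standard depth filter and differential-
#' reactivity significance thresholds are meaningful; they are tunable
#' conventions, not measured constants.
#'
#' @param seed Integer seed.
#' @param depth Reads per position (default 20000, a typical
#'   mutational-profiling median depth).
#' @param p_mod_unpaired,p_mod_paired Added per-read modification-driven
#'   mutation probability at unpaired / paired nucleotides (defaults
#'   0.03 and 0.004).
#' @param p_background Per-read background mutation probability in both
#'   channels (default 0.002).
#' @param sigma Lognormal noise sd on simulated translation ratios.
#' @param beta Coupling between unfolding cost (kcal/mol) and log
#'   relative translation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, depth = 20000L,
                              p_mod_unpaired = 0.03, p_mod_paired = 0.004,
                              p_background = 0.002, sigma = 0.1, beta = 0.1) {
  probs <- c(p_mod_unpaired, p_mod_paired, p_background)
  stopifnot(all(probs >= 0 & probs <= 1),
            p_mod_unpaired > p_mod_paired, p_mod_paired >= p_background,
            depth >= 0, sigma >= 0, beta >= 0)
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 p_mod_unpaired = p_mod_unpaired,
                 p_mod_paired = p_mod_paired, p_background = p_background,
                 sigma = sigma, beta = beta),
            class = "simulation_config")
}

#' Simulate a mutational-profiling rate table from a planted structure
#'
#' Emulates the measurement model behind mutational profiling: per
#' position, the untreated mutation count is Binomial(depth,
#' p_background) and the modified count is Binomial(depth, p_background
#' + p_mod_unpaired) at unpaired positions or Binomial(depth,
#' p_background + p_mod_paired) at paired positions; rates are
#' count/depth. Bit-reproducible under the config seed.
#'
#' @param structure An [rna_structure()]; its pairs define which
#'   positions are paired.
#' @param config A [simulation_config()].
#' @return A [map_rate_table()].
#' @export
simulate_map_rates <- function(structure, config = simulation_config()) {
  n <- nchar(structure$sequence)
  paired <- pair_partner(structure) > 0L
  p_mod <- config$p_background +
    ifelse(paired, config$p_mod_paired, config$p_mod_unpaired)
  set.seed(config$seed)
  d <- config$depth
  if (d == 0L) {
    return(map_rate_table(seq_len(n), rep(NA_real_, n), rep(NA_real_, n),
                          rep(0L, n), rep(0L, n)))
  }
  rate_mod <- rbinom(n, d, pmin(p_mod, 1)) / d
  rate_unt <- rbinom(n, d, config$p_background) / d
  map_rate_table(seq_len(n), rate_mod, rate_unt, rep(d, n), rep(d, n))
}

#' Design a transcript with a planted secondary structure
#'
#' Builds a sequence whose intended fold is known exactly: a helix
#' layout (a single hairpin, or a three-helix junction of two hairpins
#' closed by an outer stem) is drawn with randomized stem lengths and
#' loop sizes, stems are filled with G/C-biased Watson-Crick pairs and
#' loops with A/C-biased unpaired residues. The planted structure is
#' returned alongside the sequence and serves as ground truth for
#' probing-and-folding recovery experiments.
#'
#' @param length Total length in nucleotides (>= 60).
#' @param seed Integer seed (layout and residues are deterministic given
#'   the seed).
#' @param kind `"junction"` (default) or `"hairpin"`.
#' @param id Record identifier.
#' @return A list with `record` ([transcript_record()]) and `structure`
#'   ([rna_structure()]).
#' @export
synthetic_structured_rna <- function(length, seed = 1L,
                                     kind = c("junction", "hairpin"),
                                     id = "planted") {
  kind <- match.arg(kind)
  stopifnot(length >= 60)
  set.seed(seed)
  helix <- function(i, j, s) cbind(i + 0:(s - 1L), j - 0:(s - 1L))

  pairs <- NULL
  if (kind == "hairpin") {
    t5 <- sample(3:6, 1)
    t3 <- sample(3:6, 1)
    span <- length - t5 - t3
    s <- min(sample(8:12, 1), (span - 4L) %/% 2L)
    pairs <- helix(t5 + 1L, length - t3, s)
  } else {
    t5 <- sample(3:5, 1)
    t3 <- sample(3:5, 1)
    s0 <- sample(5:7, 1)
    l1 <- sample(2:4, 1)
    l2 <- sample(3:5, 1)
    l3 <- sample(2:4, 1)
    i0 <- t5 + s0 + 1L
    i1 <- length - t3 - s0
    inner <- i1 - i0 + 1L
    h1 <- (inner - l1 - l2 - l3) %/% 2L
    h2 <- inner - l1 - l2 - l3 - h1
    a <- i0 + l1
    b <- a + h1 + l2
    s1 <- min(sample(8:10, 1), (h1 - 3L) %/% 2L)
    s2 <- min(sample(8:10, 1), (h2 - 3L) %/% 2L)
    pairs <- rbind(helix(t5 + 1L, length - t3, s0),
                   helix(a, a + h1 - 1L, s1),
                   helix(b, b + h2 - 1L, s2))
  }

  res <- character(length)
  unp <- setdiff(seq_len(length), c(pairs[, 1], pairs[, 2]))
  res[unp] <- sample(c("A", "C", "U"), length(unp), replace = TRUE,
                     prob = c(0.55, 0.3, 0.15))
  kinds <- sample(c("GC", "CG", "AU", "UA"), nrow(pairs), replace = TRUE,
                  prob = c(0.4, 0.4, 0.1, 0.1))
  res[pairs[, 1]] <- substr(kinds, 1, 1)
  res[pairs[, 2]] <- substr(kinds, 2, 2)
  seq <- paste(res, collapse = "")
  list(record = transcript_record(id, seq),
       structure = rna_structure(seq, pairs))
}

#' Simulate a dual-luciferase panel coupled to unfolding cost
#'
#' Draws replicate nanoluciferase/firefly readouts whose expected
#' construct-level ratio decays exponentially with the construct's
#' unfolding cost, `exp(-beta * dG_unfold)`, times multiplicative
#' lognormal noise -- embedding an anti-correlation between start-codon
#' structure and translation as the generative truth. Six replicates per
#' construct (two plasmid preparations, three biological replicates
#' each) mirror a standard dual-luciferase design.
#'
#' @param dg_unfold Named numeric vector of unfolding costs (kcal/mol),
#'   one per construct; names are construct labels.
#' @param config A [simulation_config()] (uses `beta`, `sigma`, `seed`).
#' @param base_nl,base_ff Baseline luminescence scales.
#' @return A data frame with columns `construct`, `replicate`, `nl`,
#'   `ff` suitable for [relative_translation()].
#' @export
simulate_translation_panel <- function(dg_unfold,
                                       config = simulation_config(),
                                       base_nl = 2e5, base_ff = 1e5) {
  stopifnot(!is.null(names(dg_unfold)), config$beta >= 0)
  set.seed(config$seed)
  n_rep <- 6L
  rows <- lapply(names(dg_unfold), function(lbl) {
    mu <- exp(-config$beta * dg_unfold[[lbl]])
    noise <- if (config$sigma == 0) rep(1, n_rep)
             else rlnorm(n_rep, 0, config$sigma)
    data.frame(construct = lbl,
               replicate = sprintf("p%d_b%d", rep(1:2, each = 3), rep(1:3, 2)),
               nl = base_nl * mu * noise, ff = base_ff)
  })
  do.call(rbind, rows)
}

#' Simulate pairing-probability matrices for a structural archetype panel
#'
#' Generates a labeled panel of constructs whose pairing-probability
#' matrices derive from a small number of planted structural archetypes
#' plus noise. The first archetype is a random layout of disjoint
#' helices (the native-like fold); each further archetype retains a
#' progressively smaller subset of the native helices and replaces the
#' rest with fresh helices in the freed regions. Alternative folds thus
#' share structure with the native fold (and with each other) to
#' different, graded degrees -- the geometry that makes real mutant
#' structure groups separable in a low-dimensional projection. Each
#' construct then keeps each archetype pair with high probability (at a
#' strong pairing probability), loses it otherwise, and gains a few
#' spurious low-probability pairs.
#'
#' @param n_per_group Integer vector: construct count per archetype
#'   (first group the native-like one).
#' @param n_positions Coordinate-system length (default 270).
#' @param seed Integer seed.
#' @param keep_prob Probability a construct retains an archetype pair
#'   (default 0.9).
#' @param n_noise Spurious low-probability pairs added per construct.
#' @return A list with `pp_list` (named pairing-probability matrices)
#'   and `labels` (integer archetype of each construct).
#' @export
simulate_archetype_panel <- function(n_per_group = c(25, 6, 6, 6),
                                     n_positions = 270L, seed = 1L,
                                     keep_prob = 0.9, n_noise = 5L) {
  set.seed(seed)
  n_arch <- length(n_per_group)

  # place disjoint hairpin helices into unoccupied stretches
  place_helices <- function(occupied, max_helices) {
    helices <- list()
    attempts <- 0L
    while (length(helices) < max_helices && attempts < 300L) {
      attempts <- attempts + 1L
      stem <- sample(5:10, 1L)
      loop <- sample(3:8, 1L)
      span <- 2L * stem + loop
      if (span >= n_positions) next
      a <- sample.int(n_positions - span, 1L)
      idx <- a:(a + span - 1L)
      if (any(occupied[idx])) next
      occupied[idx] <- TRUE
      helices[[length(helices) + 1L]] <-
        cbind(a + 0:(stem - 1L), a + span - 1L - 0:(stem - 1L))
    }
    list(helices = helices, occupied = occupied)
  }

  native <- place_helices(logical(n_positions), 6L)
  archetypes <- vector("list", n_arch)
  archetypes[[1]] <- native$helices
  if (n_arch > 1L) {
    # each alternative fold keeps a decreasing share of native helices
    keep_frac <- seq(0.6, 0.2, length.out = n_arch - 1L)
    for (a in 2:n_arch) {
      n_keep <- max(1L, round(keep_frac[a - 1L] * length(native$helices)))
      kept <- native$helices[sample.int(length(native$helices), n_keep)]
      occ <- logical(n_positions)
      for (h in kept) occ[min(h):max(h)] <- TRUE
      fresh <- place_helices(occ, 6L - n_keep)
      archetypes[[a]] <- c(kept, fresh$helices)
    }
  }
  archetypes <- lapply(archetypes, function(h) do.call(rbind, h))
  pp_list <- list()
  labels <- integer(0)
  idx <- 0L
  for (a in seq_len(n_arch)) {
    for (m in seq_len(n_per_group[a])) {
      idx <- idx + 1L
      P <- matrix(0, n_positions, n_positions)
      pr <- archetypes[[a]]
      keep <- runif(nrow(pr)) < keep_prob
      if (any(keep)) {
        v <- runif(sum(keep), 0.5, 0.95)
        P[pr[keep, , drop = FALSE]] <- v
      }
      for (k in seq_len(n_noise)) {
        i <- sample.int(n_positions - 10L, 1L)
        j <- i + sample(5:10, 1L)
        P[i, j] <- max(P[i, j], runif(1, 0.001, 0.08))
      }
      P[lower.tri(P)] <- t(P)[lower.tri(P)]
      nm <- if (idx == 1L) "native" else paste0("construct_", idx)
      pp_list[[nm]] <- P
      labels <- c(labels, a)
    }
  }
  list(pp_list = pp_list, labels = labels)
}
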