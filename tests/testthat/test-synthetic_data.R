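test_that("UUAUUA tiling produces the expected panel over positions 1-252", {
  native <- random_structured_sequence(300, 0.58, seed = 4, id = "native")
  panel <- tile_mutants(native, 252)
  expect_equal(nrow(panel), 42L)
  expect_equal(panel$name, seq(6L, 252L, by = 6L))
  # windows partition [1, 252] with no gaps or overlaps
  expect_equal(panel$start, panel$end - 5L)
  covered <- unlist(Map(seq, panel$start, panel$end))
  expect_equal(sort(covered), 1:252)
  # substitutions confined to the window
  for (r in c(1L, 20L, 42L)) {
    mut <- panel$sequence[r]
    expect_equal(substr(mut, panel$start[r], panel$end[r]), "UUAUUA")
    out_idx <- setdiff(seq_len(nchar(mut)), panel$start[r]:panel$end[r])
    expect_equal(strsplit(mut, "")[[1]][out_idx],
                 strsplit(native$sequence, "")[[1]][out_idx])
  }
})

test_that("tiling edge cases: single window, degenerate variant, short regions", {
  native <- transcript_record("wt", "GCGCGCGCGCGC")
  one <- tile_mutants(native, 6)
  expect_equal(one$name, 6L)

  already <- transcript_record("wt", "UUAUUAGCGCGC")
  panel <- tile_mutants(already, 12)
  expect_equal(panel$is_degenerate, c(TRUE, FALSE))
  expect_equal(panel$sequence[1], already$sequence)

  expect_warning(empty <- tile_mutants(native, 4), "empty")
  expect_equal(nrow(empty), 0L)
  expect_warning(trimmed <- tile_mutants(native, 11), "partial")
  expect_equal(trimmed$name, 6L)
})

test_that("random sequences hit the requested G+C content and are reproducible", {
  r <- random_structured_sequence(1000, 0.58, seed = 33)
  gc <- mean(strsplit(r$sequence, "")[[1]] %in% c("G", "C"))
  expect_true(abs(gc - 0.58) < 0.05)

  au_only <- random_structured_sequence(200, 0, seed = 1)
  expect_true(all(strsplit(au_only$sequence, "")[[1]] %in% c("A", "U")))

  expect_identical(random_structured_sequence(100, 0.5, seed = 9)$sequence,
                   random_structured_sequence(100, 0.5, seed = 9)$sequence)
})

test_that("simulated MaP rates separate loops from stems (and not under the null)", {
  pl <- synthetic_structured_rna(100, seed = 2, kind = "hairpin")
  paired <- pair_partner(pl$structure) > 0

  rates <- simulate_map_rates(pl$structure, simulation_config(seed = 5))
  expect_true(mean(rates$rate_mod[!paired]) > mean(rates$rate_mod[paired]))
  # untreated channel carries no structural signal
  expect_lt(abs(mean(rates$rate_unt[!paired]) - mean(rates$rate_unt[paired])),
            0.002)

  # null model: paired and unpaired modification probabilities equal
  null_cfg <- simulation_config(seed = 5, p_mod_unpaired = 0.004,
                                p_mod_paired = 0.0039999)
  null_cfg$p_mod_paired <- 0.004
  null_rates <- simulate_map_rates(pl$structure, null_cfg)
  expect_lt(abs(mean(null_rates$rate_mod[!paired]) -
                mean(null_rates$rate_mod[paired])), 0.002)

  # reproducibility
  again <- simulate_map_rates(pl$structure, simulation_config(seed = 5))
  expect_identical(rates, again)

  zero <- simulate_map_rates(pl$structure,
                             simulation_config(seed = 1, depth = 0))
  expect_true(all(is.na(zero$rate_mod)))
  expect_true(all(raw_reactivity(zero)$mask == "low_depth"))
})

test_that("simulated translation panels embed the unfolding-cost coupling", {
  dg <- setNames(seq(0, 20, length.out = 10), paste0("c", 1:10))

  flat <- simulate_translation_panel(dg, simulation_config(seed = 1, beta = 0,
                                                           sigma = 0))
  rel <- relative_translation(flat, "c1")
  expect_equal(rel$mean_relative, rep(1, 10))
  expect_equal(rel$n, rep(6L, 10))

  det <- simulate_translation_panel(dg, simulation_config(seed = 1, beta = 0.2,
                                                          sigma = 0))
  rel <- relative_translation(det, "c1")
  ord <- match(names(dg), rel$construct)
  expect_true(all(diff(rel$mean_relative[ord]) < 0))

  a <- simulate_translation_panel(dg, simulation_config(seed = 3))
  b <- simulate_translation_panel(dg, simulation_config(seed = 3))
  expect_identical(a, b)
})

test_that("planted transcripts carry realizable structures of the stated kinds", {
  for (seed in 1:6) {
    kind <- if (seed %% 2) "junction" else "hairpin"
    pl <- synthetic_structured_rna(sample(80:150, 1), seed = seed, kind = kind)
    chars <- strsplit(pl$record$sequence, "")[[1]]
    pr <- pl$structure$pairs
    expect_true(all(paste0(chars[pr[, 1]], chars[pr[, 2]]) %in%
                      c("AU", "UA", "GC", "CG")))
    expect_true(all(pr[, 2] - pr[, 1] >= 4))
    # nested (dot-bracket conversion would fail otherwise)
    expect_silent(structure_to_dotbracket(pl$structure))
  }
})

test_that("probing plus SHAPE-directed folding recovers planted structures", {
  # end-to-end generator property at default noise, several layouts
  for (seed in c(3, 8)) {
    kind <- if (seed %% 2) "junction" else "hairpin"
    pl <- synthetic_structured_rna(120, seed = seed, kind = kind)
    rates <- simulate_map_rates(pl$structure, simulation_config(seed = seed))
    prof <- normalize_profile(raw_reactivity(rates))
    mfe <- mfe_fold(pl$record, prof)
    sc <- sens_ppv(mfe$pairs, pl$structure$pairs)
    expect_gte(sc$sens, 0.8)
    expect_gte(sc$ppv, 0.8)
  }
})
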