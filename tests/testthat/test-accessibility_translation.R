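model <- energy_model()

# shared small mutant panel for window / coupling properties
panel_cache <- local({
  utr <- random_structured_sequence(180, 0.58, seed = 41)$sequence
  native <- transcript_record("native", paste0(utr, "AUG",
                                               "GCUGCAAUGGCUUCAGCU"),
                              utr5_end = 180, start_codon = 181)
  panel <- tile_mutants(native, 120)
  seqs <- c(native = native$sequence,
            setNames(panel$sequence, paste0("mut", panel$name)))
  structures <- lapply(seqs, function(s) mfe_fold(s, model = model))
  list(native = native, seqs = seqs, structures = structures, start_a = 181L)
})

test_that("constraining strips exactly the pairs touching the window", {
  pl <- synthetic_structured_rna(120, seed = 21, kind = "junction")
  s <- pl$structure
  far <- max(s$pairs) + 1L

  # no pair touches a window placed in the 3' tail
  suppressWarnings(un <- constrain_structure(s, nchar(s$sequence) - 1L, 1L))
  expect_equal(unname(un$pairs), unname(s$pairs))

  # window covering everything removes all pairs
  suppressWarnings(all_gone <- constrain_structure(s, 60L, 60L))
  expect_equal(nrow(all_gone$pairs), 0L)
  expect_equal(attr(all_gone, "pairs_removed"), nrow(s$pairs))

  # one endpoint inside suffices
  hp <- rna_structure(strrep("A", 40), NULL)
  st <- rna_structure(paste0("GGGG", strrep("A", 20), "CCCC",
                             strrep("A", 12)),
                      cbind(1:4, 28:25))
  con <- constrain_structure(st, 26L, 2L)   # window [24, 28] hits j side only
  expect_equal(nrow(con$pairs), 0L)
  expect_error(constrain_structure(st, 100L, 2L), "outside")
})

test_that("unfolding cost obeys its defining contracts", {
  # unpaired window -> zero cost (hairpin well 5' of the window)
  seq0 <- paste0("GGGGG", strrep("A", 8), "CCCCC", strrep("A", 42))
  st0 <- rna_structure(seq0, cbind(1:5, 18:14))
  res0 <- delta_g_unfold(st0, 40L, 15L, model)
  expect_equal(res0$dg_unfold, 0)
  expect_equal(res0$pairs_removed, 0L)

  # cost >= 0 whenever the reference is the thermodynamic MFE structure,
  # and zero exactly when no pair is removed
  set.seed(23)
  for (case in 1:25) {
    r <- random_structured_sequence(sample(60:140, 1), 0.55,
                                    seed = 2300 + case)
    mfe <- mfe_fold(r, model = model)
    a_pos <- sample(16:(nchar(r$sequence) - 16), 1)
    res <- delta_g_unfold(mfe, a_pos, 15L, model)
    expect_gte(res$dg_unfold, 0)
    expect_equal(res$dg_unfold == 0, res$pairs_removed == 0L)
  }
})

test_that("widening the window removes monotonically more pairs at non-negative cost", {
  # The removed-pair set grows monotonically with w and the cost stays
  # non-negative. The cost itself need not be monotone in w: widening
  # can delete a destabilizing remnant (e.g. a lone pair left from a
  # partially cleared helix), lowering the constrained energy.
  for (nm in names(panel_cache$structures)[c(1, 5, 12, 21)]) {
    sweep <- delta_g_unfold_sweep(panel_cache$structures[[nm]],
                                  panel_cache$start_a, 13:16, model,
                                  label = nm)
    expect_true(all(diff(sweep$pairs_removed) >= 0L))
    expect_true(all(sweep$dg_unfold >= 0))
  }
})

test_that("a hairpin inside the window costs exactly its negated energy", {
  # single hairpin centered on the start codon, all pairs within +/-15
  seq <- paste0(strrep("A", 90), "GGGGCC", "AUG", "AAU", "GGCCCC",
                strrep("A", 40))
  # pairs: (91..96) with (108..103): spans positions 91-108, A at 99
  st <- rna_structure(seq, cbind(91:96, 108:103))
  e <- evaluate_energy(st, NULL, model)
  expect_lt(e, 0)
  res <- delta_g_unfold(st, 99L, 15L, model)
  expect_equal(res$dg_unfold, -e)
  expect_equal(res$dg_constrained, 0)
})

test_that("relative translation normalizes, propagates and classifies", {
  reps <- expand.grid(construct = c("native", "m1", "m2"), rep = 1:6)
  lum <- data.frame(construct = as.character(reps$construct),
                    replicate = reps$rep,
                    nl = 1, ff = 1)
  lum$nl <- ifelse(lum$construct == "m1", 0.68, 1) * 2e5
  lum$nl <- ifelse(lum$construct == "m2", 1.10 * 2e5, lum$nl)
  lum$ff <- 1e5
  tr <- relative_translation(lum, "native")
  expect_equal(tr$mean_relative[tr$construct == "native"], 1)
  expect_equal(tr$sd_relative[tr$construct == "native"], 0)
  expect_equal(tr$mean_relative[tr$construct == "m1"], 0.68)
  expect_equal(tr$effect[tr$construct == "m1"], "decrease")
  expect_equal(tr$effect[tr$construct == "m2"], "no_effect")

  # scale invariance
  lum2 <- lum
  lum2$nl <- lum2$nl * 2
  lum2$ff <- lum2$ff * 2
  expect_equal(relative_translation(lum2, "native")$mean_relative,
               tr$mean_relative)

  # bad firefly wells are dropped with a warning
  lum3 <- lum
  lum3$ff[1] <- 0
  expect_warning(tr3 <- relative_translation(lum3, "native"), "dropped")
  expect_equal(tr3$n[tr3$construct == lum3$construct[1]], 5L)
  expect_error(relative_translation(lum, "missing"), "not present")
})

test_that("effect classification uses inclusive 15% boundaries", {
  expect_equal(classify_effect(c(0.68, 1.10, 0.85, 1.15, 0.851, 1.149)),
               c("decrease", "no_effect", "decrease", "increase",
                 "no_effect", "no_effect"))
  expect_error(classify_effect(-1), "> 0")
})

test_that("group t-tests are two-tailed, symmetric, and powered as expected", {
  a <- c(0.95, 1.02, 0.98, 1.05)
  expect_equal(group_ttest(a, a)$p, 1)
  set.seed(31)
  x <- rnorm(4, 0, 0.001)
  y <- 1 + rnorm(4, 0, 0.001)
  expect_lt(group_ttest(x, y)$p, 0.001)
  fwd <- group_ttest(x, y)
  rev <- group_ttest(y, x)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$t, -rev$t)
  expect_error(group_ttest(1, a), "two values")
})

test_that("uORF scanning finds constructed CUG frames and flags CUG/G context", {
  none <- transcript_record("x", paste0(strrep("A", 60), "AUG", "GCUGCU"),
                            start_codon = 61)
  expect_equal(nrow(scan_uorfs(none)), 0L)

  # CUG + 10 codons (30 nt incl start) + in-frame UAA
  body30 <- strrep("GCA", 9)                      # 27 nt after the CUG
  utr <- paste0("AAAA", "CUG", body30, "UAA", strrep("C", 10))
  rec <- transcript_record("y", paste0(utr, "AUG", "GCU"),
                           start_codon = nchar(utr) + 1L)
  calls <- scan_uorfs(rec)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 5L)
  expect_equal(calls$codon, "CUG")
  expect_equal(calls$stop, 5L + 30L)
  expect_equal(calls$length_nt, 30L)
  expect_true(calls$followed_by_g)

  # one codon shorter falls under the 30-nt threshold
  short_utr <- paste0("AAAA", "CUG", strrep("GCA", 8), "UAA", strrep("C", 10))
  rec2 <- transcript_record("z", paste0(short_utr, "AUG", "GCU"),
                            start_codon = nchar(short_utr) + 1L)
  expect_equal(nrow(scan_uorfs(rec2)), 0L)

  # stop-less frames are reported with NA stop
  open_utr <- paste0("AAAA", "CUG", strrep("GCA", 12))
  rec3 <- transcript_record("w", paste0(open_utr, "AUG", "GCU"),
                            start_codon = nchar(open_utr) + 1L)
  calls3 <- scan_uorfs(rec3)
  expect_true(any(is.na(calls3$stop)))
})

test_that("panel report recovers the planted structure-translation coupling", {
  dg <- vapply(names(panel_cache$structures), function(nm)
    delta_g_unfold(panel_cache$structures[[nm]], panel_cache$start_a, 15L,
                   model, label = nm)$dg_unfold, 0.0)
  unfold <- do.call(rbind, lapply(names(panel_cache$structures), function(nm)
    delta_g_unfold(panel_cache$structures[[nm]], panel_cache$start_a, 15L,
                   model, label = nm)))
  lum <- simulate_translation_panel(dg, simulation_config(seed = 8,
                                                          beta = 0.1,
                                                          sigma = 0.1))
  tr <- relative_translation(lum, "native")
  rep <- structure_translation_report(unfold, tr)
  expect_s3_class(rep, "structure_translation_report")
  if (sd(dg) > 0) expect_lt(rep$correlation$spearman, 0)

  # missing labels are reported, not dropped
  expect_error(structure_translation_report(unfold[-1, ], tr), "missing")
})

test_that("two groups with a planted translation offset separate at p <= 0.05", {
  set.seed(90)
  dg <- setNames(runif(20, 0, 10), paste0("c", 1:20))
  unfold <- do.call(rbind, lapply(names(dg), function(nm) {
    data.frame(label = nm, start_a = 1L, w = 15L, dg_reference = 0,
               dg_constrained = dg[[nm]], dg_unfold = dg[[nm]],
               pairs_removed = 1L)
  }))
  rel <- c(rnorm(10, 1.0, 0.05), rnorm(10, 0.7, 0.05))
  lum <- data.frame(construct = rep(names(dg), each = 6), replicate = 1:6,
                    nl = rep(rel, each = 6) * 2e5, ff = 2e5)
  tr <- relative_translation(lum, "c1")
  grouping <- list(assignments = data.frame(
    label = names(dg), group = rep(1:2, each = 10), PC1 = 0, PC2 = 0))
  rep <- structure_translation_report(unfold, tr, grouping)
  expect_lte(rep$group_tests$translation_p[1], 0.05)
})

test_that("translation coupling is specific to the start-codon window", {
  dg_at <- vapply(names(panel_cache$structures), function(nm)
    delta_g_unfold(panel_cache$structures[[nm]], panel_cache$start_a, 15L,
                   model)$dg_unfold, 0.0)
  dg_off <- vapply(names(panel_cache$structures), function(nm)
    delta_g_unfold(panel_cache$structures[[nm]], panel_cache$start_a - 90L,
                   15L, model)$dg_unfold, 0.0)
  lum <- simulate_translation_panel(dg_at, simulation_config(seed = 12,
                                                             beta = 0.1,
                                                             sigma = 0.1))
  tr <- relative_translation(lum, "native")
  ord <- match(tr$construct, names(dg_at))
  r_at <- cor(dg_at[ord], tr$mean_relative, method = "spearman")
  r_off <- cor(dg_off[ord], tr$mean_relative, method = "spearman")
  expect_lt(r_at, 0)
  expect_lt(abs(r_off), abs(r_at))
})
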