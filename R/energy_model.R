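PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Nearest-neighbor energy model
#'
#' Loads the package's reduced nearest-neighbor parameter set: stacking
#' free energies for Watson-Crick and GU wobble pairs, hairpin/bulge/
#' internal-loop length penalties (Jacobson-Stockmayer extrapolated
#' beyond tabulated sizes), and an affine multibranch-loop model. SHAPE
#' pseudo-free-energy parameters follow the standard linear-log form
#' `m * ln(S + 1) + b` with slope 1.8 and intercept -0.6 kcal/mol.
#'
#' The parameter set is deliberately compact (no dangling ends, coaxial
#' stacking or special hairpin sequences): correctness of the folding
#' engine is defined against exhaustive enumeration under these same
#' tables, and the downstream analyses are threshold- and ranking-based.
#'
#' @param max_pairing_dist Maximum allowed pair span `j - i` (default 600).
#' @param shape_slope,shape_intercept Pseudo-free-energy parameters in
#'   kcal/mol.
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C).
#' @return An object of class `energy_model`.
#' @examples
#' mod <- energy_model()
#' shape_pseudo_energy(0, mod)     # -0.6
#' @export
energy_model <- function(max_pairing_dist = 600L, shape_slope = 1.8,
                         shape_intercept = -0.6, temperature = 310.15) {
  stopifnot(shape_slope >= 0)
  ext <- function(f) system.file("extdata", f, package = "utrfold",
                                 mustWork = TRUE)
  stk <- read.table(ext("stack_energies.tsv"), header = TRUE, sep = "\t",
                    comment.char = "#")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(stk$outer, stk$inner)] <- stk$dg
  lp <- read.table(ext("loop_penalties.tsv"), header = TRUE, sep = "\t",
                   comment.char = "#")
  tab <- function(type) {
    rows <- lp[lp$type == type, ]
    setNames(rows$dg, rows$size)
  }
  RT <- 0.0019872 * temperature
  structure(list(stack = stack, hairpin = tab("hairpin"), bulge = tab("bulge"),
                 internal = tab("internal"), ml_a = 3.4, ml_b = 0.4,
                 ml_c = 0.0, temperature = temperature, RT = RT,
                 max_pairing_dist = as.integer(max_pairing_dist),
                 max_interior = 30L, shape_slope = shape_slope,
                 shape_intercept = shape_intercept),
            class = "energy_model")
}

#' SHAPE pseudo-free-energy term
#'
#' Converts a SHAPE reactivity into the per-nucleotide pseudo-free-energy
#' change `m * ln(S + 1) + b` (kcal/mol) added to the folding energy once
#' per helix stack a paired nucleotide participates in. Missing
#' reactivities (`NA`) contribute 0; reactivities at or below -1, for
#' which the logarithm is undefined, are treated as missing with a
#' warning. Negative reactivities above -1 are evaluated as written, so
#' the term can fall below the intercept.
#'
#' @param reactivity Numeric vector of reactivities (`NA` = no data).
#' @param model An [energy_model()].
#' @return Numeric vector of pseudo-free energies, kcal/mol.
#' @export
shape_pseudo_energy <- function(reactivity, model) {
  out <- numeric(length(reactivity))
  bad <- !is.na(reactivity) & reactivity <= -1
  if (any(bad)) {
    warning(sum(bad), " reactivity value(s) <= -1 treated as missing")
    reactivity[bad] <- NA_real_
  }
  ok <- !is.na(reactivity)
  out[ok] <- model$shape_slope * log(reactivity[ok] + 1) + model$shape_intercept
  out
}

# loop penalty lookup with Jacobson-Stockmayer extrapolation
loop_penalty <- function(table, size, RT) {
  sizes <- as.integer(names(table))
  last <- max(sizes)
  ifelse(size <= last,
         unname(table[as.character(pmax(size, min(sizes)))]),
         unname(table[as.character(last)]) + 1.75 * RT * log(size / last))
}
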