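#' Differential reactivity between two profiles
#'
#' Windowed, significance-tested comparison of two reactivity profiles
#' in the style of the deltaSHAPE framework. Per position, the centered
#' mean difference over a sliding window (masked positions dropped) is
#' tested two ways: a Z-factor, `1 - 1.96 * (SEM_a + SEM_b) /
#' |mu_a - mu_b|`, must exceed 0, and the standard score of the
#' difference against the profile-wide difference distribution must
#' reach `|Z| >= 1`. A position is called significant when it passes
#' both tests and at least `min_hits` positions in its window
#' (including itself) pass both. Positions inside excluded intervals
#' (e.g. primer-binding sites) are never significant.
#'
#' @param profile_a,profile_b Equal-length [shape_profile()]s; windows
#'   are compared at the same coordinates.
#' @param window Odd window width (default 5).
#' @param exclusions Optional two-column matrix of 1-based inclusive
#'   intervals to exclude.
#' @param min_hits Number of passing positions required within a window
#'   (default 3).
#' @return A data frame of class `delta_shape_result` with per-position
#'   columns `position`, `diff` (windowed mean difference, a minus b),
#'   `z_factor`, `std_score`, `significant` and `direction`
#'   (`increase` when a exceeds b).
#' @export
delta_shape <- function(profile_a, profile_b, window = 5L,
                        exclusions = NULL, min_hits = 3L) {
  if (nrow(profile_a) != nrow(profile_b))
    stop("profiles have different lengths")
  if (window %% 2L != 1L) stop("window must be odd")
  n <- nrow(profile_a)
  va <- reactivities(profile_a)
  vb <- reactivities(profile_b)
  ea <- profile_a$stderr
  eb <- profile_b$stderr
  ea[is.na(ea)] <- 0
  eb[is.na(eb)] <- 0

  excluded <- rep(FALSE, n)
  if (!is.null(exclusions) && length(exclusions) > 0) {
    exclusions <- matrix(as.integer(exclusions), ncol = 2)
    for (r in seq_len(nrow(exclusions)))
      excluded[exclusions[r, 1]:exclusions[r, 2]] <- TRUE
  }
  va[excluded] <- NA_real_
  vb[excluded] <- NA_real_

  half <- (window - 1L) %/% 2L
  win_mean <- function(v) {
    vapply(seq_len(n), function(i) {
      idx <- max(1L, i - half):min(n, i + half)
      x <- v[idx]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0.0)
  }
  mu_a <- win_mean(va)
  mu_b <- win_mean(vb)
  sa <- win_mean(ea)
  sb <- win_mean(eb)
  d <- mu_a - mu_b

  z_factor <- 1 - 1.96 * (sa + sb) / abs(d)
  z_factor[!is.finite(z_factor)] <- -Inf

  mu_d <- mean(d, na.rm = TRUE)
  sd_d <- sd(d, na.rm = TRUE)
  std_score <- if (is.na(sd_d) || sd_d == 0) rep(0, n) else (d - mu_d) / sd_d

  pass <- !is.na(d) & z_factor > 0 & abs(std_score) >= 1 & !excluded
  hits <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    sum(pass[idx])
  }, 0L)
  significant <- pass & hits >= min_hits

  out <- data.frame(position = profile_a$position, diff = d,
                    z_factor = z_factor, std_score = std_score,
                    significant = significant,
                    direction = ifelse(is.na(d) | d == 0, NA_character_,
                                       ifelse(d > 0, "increase", "decrease")))
  class(out) <- c("delta_shape_result", "data.frame")
  out
}

#' Base-pair sensitivity and positive predictive value
#'
#' Compares a model pair set against a reference pair set:
#' `sens = |model intersect reference| / |reference|` and
#' `ppv = |model intersect reference| / |model|`; their arithmetic mean
#' is the overall similarity. An empty reference yields `sens = 1` only
#' when the model is also empty (two agreeing null models), otherwise 0;
#' empty model sets are handled symmetrically for ppv.
#'
#' @param model,reference Two-column pair matrices over the same
#'   coordinate system.
#' @return A list with `sens`, `ppv`, `overall`, and the shared pair
#'   count `n_shared`.
#' @export
sens_ppv <- function(model, reference) {
  model <- as_pair_matrix(model)
  reference <- as_pair_matrix(reference)
  key <- function(p) paste(p[, 1], p[, 2])
  shared <- length(intersect(key(model), key(reference)))
  sens <- if (nrow(reference) == 0) as.numeric(nrow(model) == 0)
          else shared / nrow(reference)
  ppv <- if (nrow(model) == 0) as.numeric(nrow(reference) == 0)
         else shared / nrow(model)
  list(sens = sens, ppv = ppv, overall = (sens + ppv) / 2, n_shared = shared)
}

#' Pair set of a probability matrix at a cutoff
#'
#' All pairs `(i, j)`, `i < j`, whose pairing probability reaches the
#' cutoff (inclusive; the conventional threshold is 0.1).
#'
#' @param pp Square pairing-probability matrix.
#' @param cutoff Inclusive probability threshold.
#' @return A two-column pair matrix.
#' @export
probability_pair_set <- function(pp, cutoff = 0.1) {
  idx <- which(upper.tri(pp) & pp >= cutoff, arr.ind = TRUE)
  as_pair_matrix(idx)
}

restrict_pairs <- function(pairs, region) {
  if (is.null(region)) return(pairs)
  keep <- pairs[, 1] >= region[1] & pairs[, 1] <= region[2] &
          pairs[, 2] >= region[1] & pairs[, 2] <= region[2]
  pairs[keep, , drop = FALSE]
}

#' Overall similarity between two pairing-probability matrices
#'
#' Thresholds both matrices into pair sets (probability >= `cutoff`),
#' restricts them to pairs with both ends inside `region`, and returns
#' the mean of sens and ppv of A against B as reference. With
#' `symmetric = TRUE` the value is additionally averaged over both
#' reference orientations.
#'
#' @param pp_a,pp_b Equal-dimension pairing-probability matrices.
#' @param region Length-2 vector of 1-based inclusive bounds (e.g.
#'   `c(1, 270)` for a 5'-UTR), or `NULL` for no restriction.
#' @param cutoff Probability threshold (default 0.1).
#' @param symmetric Average over both reference orientations.
#' @return Overall similarity in `[0, 1]`.
#' @export
overall_similarity <- function(pp_a, pp_b, region = NULL, cutoff = 0.1,
                               symmetric = FALSE) {
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[2] < region[1])
      stop("region must be a non-empty interval c(start, end)")
  }
  pa <- restrict_pairs(probability_pair_set(pp_a, cutoff), region)
  pb <- restrict_pairs(probability_pair_set(pp_b, cutoff), region)
  ab <- sens_ppv(pa, pb)$overall
  if (!symmetric) return(ab)
  (ab + sens_ppv(pb, pa)$overall) / 2
}
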