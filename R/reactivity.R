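#' Mutational-profiling rate tables
#'
#' A MaP rate table holds, per nucleotide, the apparent mutation rate and
#' read depth of the chemically modified sample and of the untreated
#' control. It is the input currency of reactivity calling.
#'
#' @param position 1-based positions, contiguous from 1.
#' @param rate_mod,rate_unt Mutation rates in `[0, 1]`.
#' @param depth_mod,depth_unt Non-negative read depths.
#' @return A data frame of class `map_rate_table`.
#' @export
map_rate_table <- function(position, rate_mod, rate_unt, depth_mod, depth_unt) {
  position <- as.integer(position)
  if (!identical(position, seq_len(length(position))))
    stop("positions must be contiguous from 1")
  rates <- c(rate_mod, rate_unt)
  if (any(rates < 0 | rates > 1, na.rm = TRUE)) stop("rates must be in [0, 1]")
  if (any(c(depth_mod, depth_unt) < 0)) stop("depths must be non-negative")
  out <- data.frame(position = position, rate_mod = rate_mod,
                    rate_unt = rate_unt, depth_mod = as.integer(depth_mod),
                    depth_unt = as.integer(depth_unt))
  class(out) <- c("map_rate_table", "data.frame")
  out
}

#' Raw SHAPE reactivity from mutation rates
#'
#' Per-nucleotide raw reactivity in the two-sample scheme: the modified
#' mutation rate minus the untreated control rate. Nucleotides where
#' either channel has read depth below `min_depth` (default 4000) are
#' masked `low_depth` rather than reported.
#'
#' @param rates A [map_rate_table()].
#' @param min_depth Minimum acceptable read depth in both channels.
#' @return A [shape_profile()] with the `raw` column filled.
#' @export
raw_reactivity <- function(rates, min_depth = 4000L) {
  low <- rates$depth_mod < min_depth | rates$depth_unt < min_depth |
    is.na(rates$rate_mod) | is.na(rates$rate_unt)
  raw <- rates$rate_mod - rates$rate_unt
  raw[low] <- NA_real_
  shape_profile(rates$position, raw = raw,
                mask = ifelse(low, "low_depth", "none"))
}

#' Normalize a reactivity profile (2%/8% rule)
#'
#' Scales raw reactivities so that a value of 1 corresponds to the mean
#' of the upper reference band: the unmasked values are ranked in
#' descending order, the top 2% are excluded as outliers, and all values
#' are divided by the mean of the next 8%. Masked positions pass through
#' unchanged; negative raw values are retained (not clipped).
#'
#' @param profile A [shape_profile()] with raw values.
#' @param exclude_frac,scale_frac Outlier and reference-band fractions
#'   (defaults 0.02 and 0.08).
#' @return The profile with the `norm` column filled.
#' @export
normalize_profile <- function(profile, exclude_frac = 0.02, scale_frac = 0.08) {
  v <- profile$raw
  ok <- !is.na(v) & profile$mask == "none"
  n <- sum(ok)
  if (n < 20L) stop("too few unmasked positions (", n, ") to normalize")
  sorted <- sort(v[ok], decreasing = TRUE)
  n_excl <- ceiling(exclude_frac * n)
  n_band <- ceiling(scale_frac * n)
  band <- sorted[(n_excl + 1):min(n_excl + n_band, n)]
  scale <- mean(band)
  if (!is.finite(scale) || scale <= 0)
    stop("normalization scale is not positive; profile may be all zero")
  profile$norm <- ifelse(ok, v / scale, NA_real_)
  if (!all(is.na(profile$stderr)))
    profile$stderr <- ifelse(ok, profile$stderr / scale, profile$stderr)
  profile
}

#' Direct reactivity, ln(rateMod / rateUnt)
#'
#' The log-ratio of modified to untreated mutation rates. Nucleotides
#' with read depth below `min_depth` in either channel, or with a zero
#' rate in either channel, carry no data.
#'
#' @inheritParams raw_reactivity
#' @return A data frame with columns `position` and `direct` (`NA`
#'   where masked).
#' @export
direct_reactivity <- function(rates, min_depth = 4000L) {
  bad <- rates$depth_mod < min_depth | rates$depth_unt < min_depth |
    is.na(rates$rate_mod) | is.na(rates$rate_unt) |
    rates$rate_mod == 0 | rates$rate_unt == 0
  val <- log(rates$rate_mod / rates$rate_unt)
  val[bad] <- NA_real_
  data.frame(position = rates$position, direct = val)
}

#' Average reactivity profiles across biological replicates
#'
#' Per nucleotide, the arithmetic mean and standard error of the mean of
#' the working reactivities over the replicates carrying data. Positions
#' whose SEM is at least 50% of the absolute mean are masked
#' `high_replicate_variability`; with a single contributing replicate the
#' SEM is undefined and the position is left unmasked. Masks only grow:
#' a position masked in every replicate stays masked.
#'
#' @param profiles A list of [shape_profile()]s over identical position
#'   ranges.
#' @param sem_frac Masking threshold as a fraction of the absolute mean.
#' @return A [shape_profile()] with `norm`, `stderr` and `mask` filled.
#' @export
average_replicates <- function(profiles, sem_frac = 0.5) {
  stopifnot(length(profiles) >= 1L)
  lens <- vapply(profiles, nrow, 0L)
  if (length(unique(lens)) != 1L)
    stop("replicate profiles have mismatched lengths")
  vals <- sapply(profiles, reactivities)
  vals <- matrix(vals, nrow = lens[1])
  m <- rowMeans(vals, na.rm = TRUE)
  k <- rowSums(!is.na(vals))
  sem <- apply(vals, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  })
  m[k == 0L] <- NA_real_
  variable <- !is.na(sem) & k >= 2L & sem >= sem_frac * abs(m)
  mask <- ifelse(k == 0L, "low_depth",
                 ifelse(variable, "high_replicate_variability", "none"))
  shape_profile(profiles[[1]]$position, norm = m, stderr = sem, mask = mask)
}
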