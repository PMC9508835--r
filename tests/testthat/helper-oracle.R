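# Exhaustive enumeration of nested secondary structures, used as the
# independent oracle for the dynamic-programming folding engine.

enumerate_structures <- function(seq, model) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  ok_pair <- function(i, j)
    paste0(chars[i], chars[j]) %in% c("AU", "UA", "GC", "CG", "GU", "UG") &&
      j - i >= 4 && j - i <= model$max_pairing_dist
  memo <- new.env()
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)                      # i unpaired
    for (l in (i + 4):j) {
      if (l > j) break
      if (!ok_pair(i, l)) next
      ins <- rec(i + 1, l - 1)
      outs <- rec(l + 1, j)
      for (a in ins) for (b in outs)
        out <- c(out, list(c(list(c(i, l)), a, b)))
    }
    memo[[key]] <- out
    out
  }
  lapply(rec(1, n), function(s)
    if (length(s) == 0) matrix(integer(0), ncol = 2) else do.call(rbind, s))
}

# minimum energy and Boltzmann pair probabilities by brute force
oracle_fold <- function(seq, model, profile = NULL) {
  structs <- enumerate_structures(seq, model)
  E <- vapply(structs, function(p)
    evaluate_energy(rna_structure(seq, p), profile, model), 0.0)
  w <- exp(-E / model$RT)
  Z <- sum(w)
  n <- nchar(seq)
  P <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    p <- structs[[k]]
    if (nrow(p) > 0) P[p] <- P[p] + w[k]
  }
  P <- (P + t(P)) / Z
  list(mfe = min(E), P = P, n_structures = length(structs))
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")
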