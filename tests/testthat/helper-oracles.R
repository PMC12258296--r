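# Brute-force oracles for the normalization factor formulas; deliberately
# written as direct transcriptions of the definitions, independent of the
# package's code paths.

brute_rle <- function(mat) {
  usable <- apply(mat, 1, function(r) all(r > 0))
  ref <- apply(mat[usable, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(mat[usable, , drop = FALSE], 2, function(col) median(col / ref))
}

brute_tmm <- function(mat, ref_i, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(mat)
  fac <- numeric(ncol(mat))
  for (s in seq_len(ncol(mat))) {
    if (s == ref_i) {
      fac[s] <- 1
      next
    }
    keep <- mat[, s] > 0 & mat[, ref_i] > 0
    o <- mat[keep, s] / lib[s]
    r <- mat[keep, ref_i] / lib[ref_i]
    m <- log2(o / r)
    a <- 0.5 * log2(o * r)
    w <- 1 / ((lib[s] - mat[keep, s]) / (lib[s] * mat[keep, s]) +
      (lib[ref_i] - mat[keep, ref_i]) / (lib[ref_i] * mat[keep, ref_i]))
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    sel <- rank(m) >= lo_m & rank(m) <= hi_m & rank(a) >= lo_a & rank(a) <= hi_a
    fac[s] <- 2^(sum(w[sel] * m[sel]) / sum(w[sel]))
  }
  fac / prod(fac)^(1 / length(fac))
}

brute_cpm <- function(mat) sweep(mat, 2, colSums(mat), "/") * 1e6
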