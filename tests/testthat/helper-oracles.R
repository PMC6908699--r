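# Independent oracles used by the property suites. These are deliberately
# brute-force / closed-form and share no code with the implementation paths
# they check.

# all tryptic peptides by exhaustive enumeration of cut-point subsets:
# for every subset of legal cut sites, fully cleave, keep fragments whose
# internal uncleaved-site count is within max_missed
oracle_digest <- function(sequence, max_missed) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (!n) return(data.frame(start = integer(0), end = integer(0)))
  sites <- which(res[-n] %in% c("K", "R"))
  sites <- sites[res[sites + 1L] != "P"]
  stopifnot(length(sites) <= 12)  # keep 2^m enumerable
  found <- new.env()
  for (mask in 0:(2^length(sites) - 1)) {
    cuts <- sites[bitwAnd(mask, 2^(seq_along(sites) - 1)) > 0]
    bounds <- c(0L, cuts, n)
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L]
      internal <- sum(sites >= s & sites < e)
      if (internal <= max_missed)
        assign(sprintf("%d_%d", s, e), c(s, e), envir = found)
    }
  }
  spans <- do.call(rbind, mget(ls(found), envir = found))
  out <- data.frame(start = spans[, 1], end = spans[, 2])
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# position-bitmap coverage oracle
oracle_coverage <- function(starts, ends, len) {
  hit <- rep(FALSE, len)
  for (i in seq_along(starts)) hit[starts[i]:ends[i]] <- TRUE
  mean(hit) * 100
}

# random peptide string over the canonical alphabet
random_peptide <- function(len, alphabet = strsplit("GASPVTCLINDQKEMHFRYW",
                                                    "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# pooled-variance t statistic (closed form, scalar path)
oracle_pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# vectorised permutation p-value for the pooled t (random label swaps)
oracle_permutation_p <- function(a, b, n_perm = 1e5) {
  x <- c(a, b)
  na <- length(a); n <- length(x)
  t_obs <- abs(oracle_pooled_t(a, b))
  keys <- matrix(runif(n * n_perm), nrow = n)
  idx <- apply(keys, 2, order)
  xa <- matrix(x[idx[seq_len(na), ]], nrow = na)
  xb <- matrix(x[idx[(na + 1):n, ]], nrow = n - na)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - (n - na) * mb^2) / (n - na - 1)
  sp2 <- ((na - 1) * va + (n - na - 1) * vb) / (n - 2)
  t_perm <- abs((ma - mb) / sqrt(sp2 * (1 / na + 1 / (n - na))))
  mean(t_perm >= t_obs)
}
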