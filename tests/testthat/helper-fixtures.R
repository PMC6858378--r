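# build an incidence from a list of target sets, one read per set,
# entries "gene:allele"
inc_from_sets <- function(sets, cell = "c1") {
  hits <- unlist(sets)
  rid <- rep(paste0("r", seq_along(sets)), lengths(sets))
  key <- hits
  targets <- unique(key)
  ga <- do.call(rbind, strsplit(targets, ":", fixed = TRUE))
  m <- Matrix::sparseMatrix(i = match(rid, unique(rid)),
                            j = match(key, targets), x = 1,
                            dims = c(length(sets), length(targets)))
  alignment_incidence(m, genes = ga[, 1], alleles = ga[, 2],
                      reads = unique(rid), cell = cell)
}

# independent fixed-point oracle for weighted allocation: dense
# iteration run to machine-level tolerance
em_oracle <- function(inc, iters = 50000L, tol = 1e-12) {
  A <- as.matrix(inc$membership)
  rs0 <- rowSums(A)
  cnt <- colSums(A / rs0)
  for (i in seq_len(iters)) {
    W <- sweep(A, 2, cnt, "*")
    rs <- rowSums(W)
    dead <- rs <= 0
    W[!dead, ] <- W[!dead, , drop = FALSE] / rs[!dead]
    if (any(dead))
      W[dead, ] <- A[dead, , drop = FALSE] / rs0[dead]
    newc <- colSums(W)
    done <- max(abs(newc - cnt)) < tol
    cnt <- newc
    if (done) break
  }
  cnt
}

# direct (non-log) evaluation of the three weighted beta-binomial masses
classify_oracle <- function(x, n, pi, av, bv) {
  f <- vapply(1:3, function(s) {
    if (n == 0) return(pi[s])
    pi[s] * choose(n, x) * beta(x + av[s], n - x + bv[s]) / beta(av[s], bv[s])
  }, 0)
  f / sum(f)
}

# two-sided Fisher p-value by exhaustive hypergeometric enumeration
fisher_oracle <- function(tb) {
  m <- matrix(tb, 2)
  rtot <- rowSums(m); ctot <- colSums(m); n <- sum(m)
  ks <- max(0, ctot[1] - rtot[2]):min(rtot[1], ctot[1])
  dens <- dhyper(ks, rtot[1], rtot[2], ctot[1])
  obs <- dhyper(m[1, 1], rtot[1], rtot[2], ctot[1])
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# counts object whose per-cell (x, y) reproduce a given state table
counts_from_state_table <- function(silent, mat, pat, bi, hi = 3, lo = 0) {
  x <- c(rep(lo, silent), rep(hi, mat), rep(lo, pat), rep(hi, bi))
  y <- c(rep(lo, silent), rep(lo, mat), rep(hi, pat), rep(hi, bi))
  allele_counts(matrix(x, nrow = 1), matrix(y, nrow = 1),
                genes = "g1")
}

count_monoallelic_calls <- function(counts, threshold = 1) {
  sum((counts$x > threshold) != (counts$y > threshold))
}
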