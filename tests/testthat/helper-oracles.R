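## Independent brute-force oracles used across the suite. These are
## deliberately written as plain, loop-heavy re-derivations from the
## definitions, separate from the package's implementations.

## TMM factor for one sample against a reference: materialize all
## M/A values, sort, trim by count, average with precision weights.
oracle_tmm_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  m <- a <- w <- numeric(0)
  for (g in seq_along(obs)) {
    if (obs[g] > 0 && ref[g] > 0) {
      po <- obs[g] / n_obs; pr <- ref[g] / n_ref
      m <- c(m, signif(log2(po / pr), 10))
      a <- c(a, signif(0.5 * log2(po * pr), 10))
      w <- c(w, (1 - po) / po + (1 - pr) / pr)
    }
  }
  n <- length(m)
  drop_m <- floor(n * trim_m); drop_a <- floor(n * trim_a)
  keep_m_idx <- order(m)[(drop_m + 1):(n - drop_m)]
  keep_a_idx <- order(a)[(drop_a + 1):(n - drop_a)]
  sel <- intersect(keep_m_idx, keep_a_idx)
  if (length(sel) == 0) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

oracle_tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(x)
  f75 <- sapply(seq_len(ncol(x)), function(j)
    quantile(x[, j] / lib[j], 0.75, names = FALSE))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- sapply(seq_len(ncol(x)), function(j)
    if (j == ref) 1 else oracle_tmm_factor(x[, j], x[, ref],
                                           trim_m, trim_a))
  f / exp(mean(log(f)))
}

## Benjamini-Hochberg step-up from first principles
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

## Bray-Curtis from the definition
oracle_bray_curtis <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

## transitive-closure RT binning: O(n^2) union-find
oracle_rt_bins <- function(rt, tol) {
  n <- length(rt)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(rt[i] - rt[j]) <= tol) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  sapply(seq_len(n), find)
}

## available-electron count of a species (degree of reduction),
## recomputed from the formula and charge
oracle_electrons <- function(sp) {
  val <- c(C = 4, H = 1, O = -2, N = -3, S = 6, P = 5)
  tot <- 0
  for (el in names(sp$formula)) tot <- tot + val[[el]] * sp$formula[[el]]
  tot - sp$charge
}

## random count matrix for normalization tests
random_counts <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = runif(n_genes, 5, 200)),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

random_catalog <- function(counts, seed = 1, n_mags = 4) {
  set.seed(seed + 1000)
  data.frame(gene_id = rownames(counts),
             mag_id = sample(sprintf("MAG_%02d", seq_len(n_mags)),
                             nrow(counts), replace = TRUE),
             length_bp = sample(300:3000, nrow(counts), replace = TRUE),
             ko_id = sprintf("K%05d", sample(1:500, nrow(counts),
                                             replace = TRUE)),
             cazy_best_hit = NA_character_,
             camper_id = NA_character_,
             stringsAsFactors = FALSE)
}
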