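## Multi-level beta-diversity and hypothesis testing: abundance
## summaries at gene / MAG / annotation level, Bray-Curtis distances,
## between-treatment contrasts, Kruskal-Wallis + Dunn + BH, and a
## permutation MANOVA on distance matrices.

#' Abundance matrices at gene, MAG, and annotation level
#'
#' The gene level is the expression matrix itself; the MAG level sums
#' gene expression per MAG per sample (column sums are conserved); the
#' annotation level sums gene expression per annotation identifier
#' over the ko_id, cazy_best_hit, and camper_id columns (a gene with
#' several annotations contributes to each; unannotated genes are
#' excluded and counted in the coverage report).
#'
#' @param expr geTMM matrix.
#' @param catalog Gene catalog.
#' @return List: `gene`, `mag`, `annotation` (matrices with a `level`
#'   attribute), `coverage` (list: n_genes, n_annotated,
#'   n_unannotated).
#' @export
level_summaries <- function(expr, catalog) {
  idx <- match(rownames(expr), catalog$gene_id)
  if (anyNA(idx)) stop("catalog does not cover all genes")
  mag <- rowsum(expr, catalog$mag_id[idx])
  cols <- intersect(c("ko_id", "cazy_best_hit", "camper_id"),
                    names(catalog))
  pieces <- list()
  for (cc in cols) {
    ann <- catalog[[cc]][idx]
    keep <- !is.na(ann) & nzchar(ann)
    if (any(keep))
      pieces[[cc]] <- rowsum(expr[keep, , drop = FALSE], ann[keep])
  }
  annotation <- if (length(pieces)) {
    all_ids <- sort(unique(unlist(lapply(pieces, rownames))))
    acc <- matrix(0, length(all_ids), ncol(expr),
                  dimnames = list(all_ids, colnames(expr)))
    for (p in pieces) acc[rownames(p), ] <- acc[rownames(p), ] + p
    acc
  } else matrix(0, 0, ncol(expr), dimnames = list(NULL, colnames(expr)))
  annotated <- rep(FALSE, nrow(expr))
  for (cc in cols) {
    a <- catalog[[cc]][idx]
    annotated <- annotated | (!is.na(a) & nzchar(a))
  }
  out <- list(gene = expr, mag = mag, annotation = annotation,
              coverage = list(n_genes = nrow(expr),
                              n_annotated = sum(annotated),
                              n_unannotated = sum(!annotated)))
  attr(out$gene, "level") <- "gene"
  attr(out$mag, "level") <- "MAG"
  attr(out$annotation, "level") <- "annotation"
  out
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' BC(x, y) = 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y) on
#' nonnegative abundance columns, computed with vegan.
#'
#' @param abund Units x samples abundance matrix (nonnegative).
#' @return Symmetric sample x sample distance matrix (zero diagonal)
#'   with a `metric` attribute.
#' @export
bray_curtis <- function(abund) {
  if (ncol(abund) < 2) stop("need at least two samples")
  if (any(abund < 0)) stop("abundances must be nonnegative")
  zero <- colSums(abund) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for all-zero sample pairs: ",
         paste(colnames(abund)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(abund), method = "bray"))
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Cross-treatment distances at one timepoint
#'
#' The multiset of pairwise distances between every catechin-amended
#' and every unamended sample of a day (within-treatment pairs
#' excluded). With `matched = TRUE` only same-replicate pairs are
#' kept.
#'
#' @param d Sample distance matrix.
#' @param samples Sample table.
#' @param day Timepoint.
#' @param matched Restrict to matched replicates (default FALSE).
#' @return Data frame: day, sample_unamended, sample_catechin,
#'   distance; `NULL` (with a message) when a treatment is missing.
#' @export
between_treatment_distances <- function(d, samples, day, matched = FALSE) {
  check_sample_table(samples)
  su <- samples[samples$day == day & samples$treatment == "unamended", ]
  sc <- samples[samples$day == day & samples$treatment == "catechin", ]
  su <- su[su$sample_id %in% rownames(d), ]
  sc <- sc[sc$sample_id %in% rownames(d), ]
  if (nrow(su) == 0 || nrow(sc) == 0) {
    message("day ", day, ": one treatment missing, skipped")
    return(NULL)
  }
  grid <- expand.grid(u = su$sample_id, c = sc$sample_id,
                      stringsAsFactors = FALSE)
  if (matched) {
    ru <- su$replicate[match(grid$u, su$sample_id)]
    rc <- sc$replicate[match(grid$c, sc$sample_id)]
    grid <- grid[ru == rc, , drop = FALSE]
  }
  data.frame(day = day, sample_unamended = grid$u,
             sample_catechin = grid$c,
             distance = d[cbind(grid$u, grid$c)],
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis with Dunn's post-hoc and Benjamini-Hochberg
#'
#' Runs the (tie-corrected) Kruskal-Wallis test across groups, then
#' Dunn's pairwise z tests on the pooled ranks with the tie
#' correction, two-sided p-values, and BH adjustment across the
#' pairwise family.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned with `values`.
#' @return List: `kruskal` (htest), `dunn` (data frame: group1,
#'   group2, z, p, p_adj).
#' @export
kruskal_dunn_bh <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) == 0)) stop("empty group")
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- table(groups)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
               (1 / ng[[a]] + 1 / ng[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                     p = p, p_adj = stats::p.adjust(p, method = "BH"),
                     stringsAsFactors = FALSE)
  list(kruskal = kw, dunn = dunn)
}

#' Permutational multivariate analysis of variance on a distance matrix
#'
#' Sequential (terms-in-order) partitioning of the squared-distance
#' sums via the Gower-centered inner-product matrix, with pseudo-F per
#' term and p-values from free permutation of sample labels:
#' p = (1 + number of permuted F >= observed) / (1 + n_perm).
#'
#' @param d Sample distance matrix.
#' @param samples Sample table (rows matched to `d` by sample_id).
#' @param factors Character vector of sample-table columns, fitted
#'   sequentially as factors (default treatment then day).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Data frame: term, df, ss, r2, f, p (plus Residual and Total
#'   rows).
#' @export
permanova <- function(d, samples, factors = c("treatment", "day"),
                      n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 1)
  d <- as.matrix(d)
  ## canonical sample order: results are invariant to any consistent
  ## row/column permutation of the input distance matrix
  ord <- order(rownames(d))
  d <- d[ord, ord]
  ids <- rownames(d)
  idx <- match(ids, samples$sample_id)
  if (anyNA(idx)) stop("distance matrix samples missing from sample table")
  meta <- samples[idx, , drop = FALSE]
  n <- nrow(d)
  for (f in factors) {
    if (!f %in% names(meta)) stop("unknown factor: ", f)
    if (any(table(factor(meta[[f]])) < 2))
      stop("factor ", f, " has a level with a single sample")
  }
  ## Gower-centered inner-product matrix
  a <- -0.5 * d^2
  G <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  hats <- list(); dfs <- integer(length(factors))
  X <- matrix(1, n, 1)
  H_prev <- X %*% solve(crossprod(X)) %*% t(X)
  rank_prev <- 1
  for (k in seq_along(factors)) {
    X <- cbind(X, stats::model.matrix(~ factor(meta[[factors[k]]]))[, -1,
                                                                    drop = FALSE])
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    H <- tcrossprod(Q)
    dfs[k] <- qrX$rank - rank_prev
    hats[[k]] <- H - H_prev
    H_prev <- H; rank_prev <- qrX$rank
  }
  df_res <- n - rank_prev
  if (df_res <= 0) stop("no residual degrees of freedom")
  H_res <- diag(n) - H_prev
  stat <- function(Gm) {
    ss <- vapply(hats, function(Hk) sum(Hk * Gm), numeric(1))
    ss_res <- sum(H_res * Gm)
    (ss / dfs) / (ss_res / df_res)
  }
  ss_obs <- vapply(hats, function(Hk) sum(Hk * G), numeric(1))
  ss_res <- sum(H_res * G)
  ss_tot <- sum(diag(G))
  f_obs <- (ss_obs / dfs) / (ss_res / df_res)
  ## seed the permutation stream without disturbing the caller's RNG
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  exceed <- numeric(length(factors))
  for (b in seq_len(n_perm)) {
    pp <- sample.int(n)
    exceed <- exceed + (stat(G[pp, pp]) >= f_obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    term = c(factors, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    ss = c(ss_obs, ss_res, ss_tot),
    r2 = c(ss_obs, ss_res, ss_tot) / ss_tot,
    f = c(f_obs, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
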