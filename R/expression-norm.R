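#' Normalization configuration for the geTMM pipeline
#'
#' Bundles the thresholds used by the count-to-expression pipeline:
#' low-count removal, the TMM trim fractions, and the per-sample
#' genome-activity ("MAG on") threshold.
#'
#' @param min_count Integer; cells with `0 < count < min_count` are set
#'   to zero before normalization. Default 5.
#' @param mag_on_threshold Integer number of genes with non-zero geTMM a
#'   MAG must have in a sample for its genes to be retained in that
#'   sample, or `"auto"` to take the median over all (MAG, sample)
#'   pairs with at least one active gene. Default 22.
#' @param tmm_trim_m Fraction of genes trimmed from each tail of the
#'   log-ratio (M) distribution. Default 0.30.
#' @param tmm_trim_a Fraction trimmed from each tail of the average
#'   log-expression (A) distribution. Default 0.05.
#' @param mag_on_population Either `"mag_sample"` (default; the "auto"
#'   median is taken over (MAG, sample) pairs) or `"mag"` (genes "on"
#'   pooled per MAG across samples before the median).
#' @return A list of class `norm_config`.
#' @export
norm_config <- function(min_count = 5L, mag_on_threshold = 22L,
                        tmm_trim_m = 0.30, tmm_trim_a = 0.05,
                        mag_on_population = c("mag_sample", "mag")) {
  mag_on_population <- match.arg(mag_on_population)
  stopifnot(min_count >= 0, tmm_trim_m >= 0, tmm_trim_m < 0.5,
            tmm_trim_a >= 0, tmm_trim_a < 0.5)
  if (!identical(mag_on_threshold, "auto")) {
    stopifnot(is.numeric(mag_on_threshold), length(mag_on_threshold) == 1)
    if (mag_on_threshold <= 0) stop("mag_on_threshold must be positive")
  }
  structure(list(min_count = as.integer(min_count),
                 mag_on_threshold = mag_on_threshold,
                 tmm_trim_m = tmm_trim_m, tmm_trim_a = tmm_trim_a,
                 mag_on_population = mag_on_population),
            class = "norm_config")
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene_id rownames and sample_id colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  invisible(counts)
}

#' Remove low counts from a count matrix
#'
#' Sets every cell with `0 < value < min_count` to zero; cells at or
#' above the threshold are untouched, so the operation is idempotent.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns.
#' @param min_count Minimum retained count (default 5).
#' @return Matrix of the same dimensions.
#' @export
filter_low_counts <- function(counts, min_count = 5L) {
  check_count_matrix(counts)
  stopifnot(min_count >= 0)
  counts[counts < min_count] <- 0
  counts
}

#' Reads per kilobase
#'
#' Divides each gene's counts by its length in kilobases. Gene lengths
#' come from the catalog's `length_bp` column keyed by `gene_id`.
#'
#' @param counts Count matrix (genes x samples).
#' @param catalog Gene catalog data frame with columns `gene_id` and
#'   `length_bp`.
#' @return Numeric matrix of RPK values.
#' @export
rpk <- function(counts, catalog) {
  check_count_matrix(counts)
  len <- catalog$length_bp[match(rownames(counts), catalog$gene_id)]
  missing <- rownames(counts)[is.na(len) | len <= 0]
  if (length(missing) > 0)
    stop("missing or non-positive gene length for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  counts / (len / 1000)
}

## Reference column for TMM: the sample whose upper quartile of
## relative expression is closest to the mean upper quartile.
tmm_pick_reference <- function(x) {
  lib <- colSums(x)
  f75 <- vapply(seq_len(ncol(x)), function(j) {
    stats::quantile(x[, j] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  which.min(abs(f75 - mean(f75)))
}

tmm_one_factor <- function(obs, ref, trim_m, trim_a) {
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("no co-expressed genes between sample and reference")
  o <- obs[keep]; r <- ref[keep]
  ## M and A are rounded to 10 significant digits before trimming so
  ## that mathematically tied log-ratios (equal count ratios) trim
  ## identically regardless of floating-point evaluation order
  m <- signif(log2((o / n_obs) / (r / n_ref)), 10)
  a <- signif(0.5 * log2((o / n_obs) * (r / n_ref)), 10)
  ## precision weights: delta-method variance of M computed on the
  ## relative proportions (1-p)/p per sample, which keeps the factors
  ## exactly invariant under per-sample depth rescaling
  w <- (n_obs - o) / o + (n_ref - r) / r
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n - floor(n * trim_m)
  lo_a <- floor(n * trim_a) + 1; hi_a <- n - floor(n * trim_a)
  ## ties at the trim boundary are broken by original index so the
  ## selection is well defined
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(sel)) return(1)
  2^(sum(m[sel] / w[sel]) / sum(1 / w[sel]))
}

#' Trimmed mean of M-values scaling factors
#'
#' Computes per-sample TMM scaling factors on a (nonnegative) expression
#' matrix, doubly trimming the per-gene log-ratios (M, by `trim_m`) and
#' average log-expression (A, by `trim_a`) against a reference sample,
#' averaging the retained M-values with inverse delta-method precision
#' weights, and rescaling so the factors have geometric mean one. Genes
#' with a zero in either member of a pair are excluded pairwise.
#'
#' @param x Numeric matrix (typically RPK values), >= 2 columns.
#' @param trim_m,trim_a Tail trim fractions for M and A.
#' @param reference Column index/name of the reference sample, or
#'   `"auto"` (upper-quartile rule).
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05, reference = "auto") {
  if (ncol(x) < 2) stop("tmm_factors needs at least two samples")
  stopifnot(trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  ref <- if (identical(reference, "auto")) tmm_pick_reference(x)
         else if (is.character(reference)) match(reference, colnames(x))
         else reference
  if (is.na(ref) || ref < 1 || ref > ncol(x)) stop("invalid reference sample")
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    tmm_one_factor(x[, j], x[, ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  f
}

#' Gene-length-corrected TMM (geTMM) expression values
#'
#' Converts raw gene-level counts to geTMM: low counts are removed,
#' counts are length-corrected to RPK, per-sample TMM factors are
#' estimated on the RPK matrix, and each column is scaled to
#' per-million by its effective library size (RPK column sum times TMM
#' factor). A single-sample matrix gets a TMM factor of 1.
#'
#' @param counts Count matrix (genes x samples).
#' @param catalog Gene catalog with `gene_id` and `length_bp`.
#' @param config A [norm_config()].
#' @param apply_low_count_filter Apply `config$min_count` first
#'   (default TRUE; set FALSE if counts are already filtered).
#' @return Matrix of geTMM values (zeros preserved).
#' @export
getmm <- function(counts, catalog, config = norm_config(),
                  apply_low_count_filter = TRUE) {
  if (apply_low_count_filter)
    counts <- filter_low_counts(counts, config$min_count)
  if (all(counts == 0)) stop("no counts remain after low-count filtering")
  r <- rpk(counts, catalog)
  f <- if (ncol(r) >= 2)
    tmm_factors(r, config$tmm_trim_m, config$tmm_trim_a)
  else stats::setNames(1, colnames(r))
  eff <- colSums(r) * f
  sweep(r, 2, eff, "/") * 1e6
}

#' Genome-activity ("MAG on") filter
#'
#' For each sample, zeroes all genes of a MAG that has fewer than
#' `threshold` genes with non-zero expression in that sample. With
#' `threshold = "auto"` the threshold is the median number of "on"
#' genes over all (MAG, sample) pairs having at least one active gene
#' (or pooled per MAG when `population = "mag"`).
#'
#' @param expr geTMM matrix (genes x samples).
#' @param catalog Gene catalog with `gene_id` and `mag_id`.
#' @param threshold Positive integer or `"auto"`.
#' @param population Median population for `"auto"`; see [norm_config()].
#' @return List with `expr` (filtered matrix), `activity` (data frame:
#'   mag_id, sample_id, genes_on, pass) and `threshold` used.
#' @export
mag_on_filter <- function(expr, catalog, threshold = 22L,
                          population = c("mag_sample", "mag")) {
  population <- match.arg(population)
  if (nrow(expr) == 0) stop("empty expression matrix")
  mags <- catalog$mag_id[match(rownames(expr), catalog$gene_id)]
  if (anyNA(mags)) stop("genes missing from catalog: ",
                        paste(utils::head(rownames(expr)[is.na(mags)], 5),
                              collapse = ", "))
  on_counts <- rowsum((expr > 0) + 0, mags)  # MAG x sample genes-on
  if (identical(threshold, "auto")) {
    pool <- if (population == "mag_sample") on_counts[on_counts > 0]
            else rowSums(on_counts)[rowSums(on_counts) > 0]
    threshold <- stats::median(pool)
  }
  if (!is.numeric(threshold) || threshold <= 0)
    stop("mag-on threshold must be positive")
  pass <- on_counts >= threshold
  keep <- pass[cbind(match(mags, rownames(on_counts)),
                     rep(seq_len(ncol(expr)), each = nrow(expr)))]
  out <- expr
  out[!keep] <- 0
  activity <- data.frame(
    mag_id = rep(rownames(on_counts), times = ncol(on_counts)),
    sample_id = rep(colnames(expr), each = nrow(on_counts)),
    genes_on = as.vector(on_counts),
    pass = as.vector(pass),
    stringsAsFactors = FALSE)
  list(expr = out, activity = activity, threshold = threshold)
}

#' Full count-to-expression pipeline
#'
#' Convenience wrapper running, in order: low-count filtering, geTMM
#' conversion, and the MAG activity filter.
#'
#' @inheritParams getmm
#' @return As [mag_on_filter()], plus `unfiltered_expr` (geTMM before
#'   the activity filter).
#' @export
normalize_expression <- function(counts, catalog, config = norm_config()) {
  e <- getmm(counts, catalog, config)
  res <- mag_on_filter(e, catalog, config$mag_on_threshold,
                       config$mag_on_population)
  res$unfiltered_expr <- e
  res
}
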