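## In-source-fragment and halogen filtering for untargeted LC-MS
## feature tables.

#' LC-MS artifact-filter configuration
#'
#' @param rt_tolerance Co-elution window between consecutive features,
#'   in the retention-time units of the table (default 0.005; the
#'   default assumes seconds-scaled retention times - check your
#'   export's units, minutes-scaled tables need a converted
#'   tolerance).
#' @param min_correlation Minimum cross-sample Pearson correlation for
#'   a candidate parent/fragment pair (default 0.98; pairs must
#'   exceed it).
#' @param ppm_tolerance MS2 mass-match tolerance in parts per million
#'   (default 5; matches must be strictly below it).
#' @param halogens Elements whose presence in a predicted composition
#'   rejects the feature.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(rt_tolerance = 0.005, min_correlation = 0.98,
                          ppm_tolerance = 5,
                          halogens = c("F", "Cl", "Br", "I")) {
  stopifnot(rt_tolerance > 0, min_correlation > 0, min_correlation <= 1,
            ppm_tolerance > 0)
  structure(list(rt_tolerance = rt_tolerance,
                 min_correlation = min_correlation,
                 ppm_tolerance = ppm_tolerance, halogens = halogens),
            class = "filter_config")
}

check_feature_table <- function(features) {
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(features)))
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(features$feature_id)) stop("duplicate feature_id")
  if (nrow(features) > 0 && (any(features$mz <= 0) || any(features$rt < 0)))
    stop("mz must be positive and rt nonnegative")
  invisible(features)
}

intensity_columns <- function(features) {
  setdiff(names(features), c("feature_id", "mz", "rt", "formula",
                             "annotation_level"))
}

#' Bin features by retention-time co-elution
#'
#' Single-linkage chaining on the retention-time axis: features are
#' sorted by rt and consecutive features closer than the tolerance
#' share a bin, so bins are transitive co-elution groups and the
#' result is independent of input order.
#'
#' @param features Feature table.
#' @param rt_tolerance Maximum gap (same units as `rt`).
#' @return Integer vector of bin ids aligned with `features` rows.
#' @export
bin_by_rt <- function(features, rt_tolerance = 0.005) {
  check_feature_table(features)
  n <- nrow(features)
  if (n == 0) return(integer(0))
  o <- order(features$rt)
  gaps <- diff(features$rt[o])
  bin_sorted <- cumsum(c(1L, as.integer(gaps > rt_tolerance)))
  bins <- integer(n)
  bins[o] <- bin_sorted
  bins
}

#' Correlated candidate pairs within a co-elution bin
#'
#' Computes cross-sample Pearson correlations (pairwise-complete) for
#' every pair of co-eluting features and keeps pairs exceeding the
#' threshold; the heavier ion of each pair is designated the parent.
#' Pairs with a zero-variance intensity vector are skipped (their
#' correlation is undefined) and listed in the `skipped` attribute.
#'
#' @param features Feature table (one bin).
#' @param min_correlation Threshold (exceed to retain).
#' @return Data frame: parent_id, fragment_id, r.
#' @export
correlated_pairs <- function(features, min_correlation = 0.98) {
  check_feature_table(features)
  icols <- intensity_columns(features)
  n <- nrow(features)
  out <- list(); skipped <- list()
  if (n >= 2) {
    im <- as.matrix(features[, icols, drop = FALSE])
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        xi <- im[i, ]; xj <- im[j, ]
        ok <- stats::complete.cases(cbind(xi, xj))
        if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
          skipped[[length(skipped) + 1]] <- data.frame(
            a = features$feature_id[i], b = features$feature_id[j],
            reason = "zero-variance intensity vector",
            stringsAsFactors = FALSE)
          next
        }
        r <- stats::cor(xi[ok], xj[ok])
        if (!is.na(r) && r > min_correlation) {
          heavier <- if (features$mz[i] >= features$mz[j]) i else j
          lighter <- if (heavier == i) j else i
          out[[length(out) + 1]] <- data.frame(
            parent_id = features$feature_id[heavier],
            fragment_id = features$feature_id[lighter],
            r = r, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(parent_id = character(), fragment_id = character(),
               r = numeric())
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}

#' Confirm a candidate fragment in the parent's MS2 spectrum
#'
#' @param candidate_mz Candidate fragment m/z.
#' @param parent_spectrum Two-column matrix (`mz`, `intensity`) or
#'   `NULL` (no MS2 recorded: unconfirmed).
#' @param ppm_tolerance Strict upper bound on the relative mass error.
#' @return List: `confirmed` (logical), `ppm` (best match, NA when no
#'   spectrum).
#' @export
confirm_in_ms2 <- function(candidate_mz, parent_spectrum,
                           ppm_tolerance = 5) {
  if (is.null(parent_spectrum) || nrow(parent_spectrum) == 0)
    return(list(confirmed = FALSE, ppm = NA_real_))
  ppm <- abs(parent_spectrum[, "mz"] - candidate_mz) / candidate_mz * 1e6
  list(confirmed = min(ppm) < ppm_tolerance, ppm = min(ppm))
}

#' Remove confirmed in-source fragments from a feature table
#'
#' The three-stage filter: retention-time binning, cross-sample
#' intensity correlation within bins, and MS2 confirmation of the
#' candidate fragment m/z in the parent's spectrum. Fragments passing
#' all three stages are removed; parents are always retained. The
#' removal log records every removal (and every unconfirmed candidate)
#' for manual review, in place of the original workflow's by-hand
#' inspection of the candidate list.
#'
#' @param features Feature table.
#' @param spectra Named list of MS2 peak matrices keyed by precursor
#'   feature_id.
#' @param config A [filter_config()].
#' @return List: `features` (filtered), `log` (data frame: bin,
#'   parent_id, fragment_id, r, ppm, removed, reason).
#' @export
remove_artifacts <- function(features, spectra = list(),
                             config = filter_config()) {
  check_feature_table(features)
  if (nrow(features) == 0)
    return(list(features = features,
                log = data.frame(bin = integer(), parent_id = character(),
                                 fragment_id = character(), r = numeric(),
                                 ppm = numeric(), removed = logical(),
                                 reason = character())))
  bins <- bin_by_rt(features, config$rt_tolerance)
  logs <- list()
  removed <- character(0)
  for (b in unique(bins)) {
    sub <- features[bins == b, , drop = FALSE]
    if (nrow(sub) < 2) next
    pairs <- correlated_pairs(sub, config$min_correlation)
    if (nrow(pairs) == 0) next
    for (k in seq_len(nrow(pairs))) {
      cand_mz <- sub$mz[sub$feature_id == pairs$fragment_id[k]]
      conf <- confirm_in_ms2(cand_mz, spectra[[pairs$parent_id[k]]],
                             config$ppm_tolerance)
      if (conf$confirmed) removed <- c(removed, pairs$fragment_id[k])
      logs[[length(logs) + 1]] <- data.frame(
        bin = b, parent_id = pairs$parent_id[k],
        fragment_id = pairs$fragment_id[k], r = pairs$r[k],
        ppm = conf$ppm, removed = conf$confirmed,
        reason = if (conf$confirmed) "fragment confirmed in parent MS2"
                 else "candidate not confirmed in MS2",
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(bin = integer(), parent_id = character(),
               fragment_id = character(), r = numeric(), ppm = numeric(),
               removed = logical(), reason = character())
  list(features = features[!(features$feature_id %in% removed), ,
                           drop = FALSE],
       log = log)
}

#' Drop features with halogenated predicted compositions
#'
#' Features whose predicted elemental composition contains any element
#' of the halogen set are removed; features without a formula are
#' kept, and unparseable formulas are kept with a warning.
#'
#' @param features Feature table with a `formula` column.
#' @param halogens Halogen element set.
#' @return Filtered feature table.
#' @export
drop_halogens <- function(features, halogens = c("F", "Cl", "Br", "I")) {
  check_feature_table(features)
  if (!"formula" %in% names(features) || nrow(features) == 0)
    return(features)
  keep <- vapply(seq_len(nrow(features)), function(i) {
    f <- features$formula[i]
    if (is.na(f) || !nzchar(trimws(f))) return(TRUE)
    counts <- parse_formula(f)
    if (is.null(counts)) {
      warning("unparseable formula kept: ", features$feature_id[i],
              " (", f, ")")
      return(TRUE)
    }
    !any(names(counts) %in% halogens & counts > 0)
  }, logical(1))
  features[keep, , drop = FALSE]
}

#' Full LC-MS artifact filter
#'
#' Applies [remove_artifacts()] then [drop_halogens()]. The operation
#' is idempotent: a second pass removes nothing further.
#'
#' @inheritParams remove_artifacts
#' @return List: `features`, `log` (fragment removal log),
#'   `n_halogen_removed`.
#' @export
filter_features <- function(features, spectra = list(),
                            config = filter_config()) {
  step1 <- remove_artifacts(features, spectra, config)
  step2 <- drop_halogens(step1$features, config$halogens)
  list(features = step2,
       log = step1$log,
       n_halogen_removed = nrow(step1$features) - nrow(step2))
}
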