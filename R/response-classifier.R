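#' Classifier configuration
#'
#' Thresholds for the six-way catechin-response classification. The
#' defaults (26 for the shared-expression percentage, 25 for the
#' absolute unique-expression difference) were derived from the
#' distribution of the two metrics across transcriptionally active
#' MAGs in the study system; both are tunable.
#'
#' @param both_threshold Percentage threshold on `%both` (default 26).
#' @param unique_threshold Percentage threshold on `|delta unique|`
#'   (default 25).
#' @param presence_rule `"union"` (a gene counts as expressed in a
#'   treatment if non-zero in at least one replicate; default) or
#'   `"all"` (non-zero in every replicate).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(both_threshold = 26, unique_threshold = 25,
                              presence_rule = c("union", "all")) {
  presence_rule <- match.arg(presence_rule)
  stopifnot(both_threshold > 0, both_threshold < 100,
            unique_threshold > 0, unique_threshold < 100)
  structure(list(both_threshold = both_threshold,
                 unique_threshold = unique_threshold,
                 presence_rule = presence_rule),
            class = "classifier_config")
}

#' Response categories
#' @return Character vector of the six category labels.
#' @export
response_categories <- function() {
  c("resistant", "responsive", "sensitive", "stimulated",
    "lost_function", "gained_function")
}

check_sample_table <- function(samples) {
  need <- c("sample_id", "treatment", "day", "replicate")
  if (!all(need %in% names(samples)))
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  bad <- setdiff(unique(samples$treatment), c("unamended", "catechin"))
  if (length(bad) > 0)
    stop("unknown treatment labels: ", paste(bad, collapse = ", "))
  invisible(samples)
}

## Gene presence per treatment at a day: union (default) or
## intersection over replicates of non-zero expression.
treatment_presence <- function(expr, samples, day, treatment,
                               presence_rule = "union") {
  ids <- samples$sample_id[samples$day == day &
                           samples$treatment == treatment]
  ids <- intersect(ids, colnames(expr))
  if (length(ids) == 0) return(NULL)
  sub <- expr[, ids, drop = FALSE]
  if (presence_rule == "union") rowSums(sub > 0) > 0
  else rowSums(sub > 0) == length(ids)
}

#' Cross-treatment gene-presence pattern for one MAG at one day
#'
#' Partitions the MAG's expressed genes at a timepoint into genes
#' expressed in both treatments, only in unamended, and only in
#' catechin microcosms.
#'
#' @param expr Filtered geTMM matrix.
#' @param catalog Gene catalog (`gene_id`, `mag_id`).
#' @param samples Sample table (`sample_id`, `treatment`, `day`,
#'   `replicate`).
#' @param mag_id MAG to examine.
#' @param day Timepoint (day).
#' @param presence_rule See [classifier_config()].
#' @return A list (class `presence_pattern`) with counts `n_both`,
#'   `n_unamended_only`, `n_catechin_only`, `n_total`, or `NULL` when
#'   the MAG is inactive at that day.
#' @export
presence_pattern <- function(expr, catalog, samples, mag_id, day,
                             presence_rule = "union") {
  check_sample_table(samples)
  genes <- catalog$gene_id[catalog$mag_id == mag_id]
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) return(NULL)
  sub <- expr[genes, , drop = FALSE]
  pu <- treatment_presence(sub, samples, day, "unamended", presence_rule)
  pc <- treatment_presence(sub, samples, day, "catechin", presence_rule)
  if (is.null(pu) || is.null(pc))
    stop("both treatments are required at day ", day)
  n_both <- sum(pu & pc)
  n_u <- sum(pu & !pc)
  n_c <- sum(!pu & pc)
  n_total <- n_both + n_u + n_c
  if (n_total == 0) return(NULL)  # inactive at this day
  structure(list(mag_id = mag_id, day = day, n_both = n_both,
                 n_unamended_only = n_u, n_catechin_only = n_c,
                 n_total = n_total),
            class = "presence_pattern")
}

#' Response metrics from a presence pattern
#'
#' `%both` is the percentage of the MAG's expressed genes shared by
#' both treatments; `delta unique` is the signed difference between the
#' percentages expressed only in unamended and only in catechin
#' microcosms.
#'
#' @param p A `presence_pattern` (or list with the same count fields).
#' @return Named numeric vector `c(pct_both, delta_unique)`.
#' @export
response_metrics <- function(p) {
  n_total <- p$n_both + p$n_unamended_only + p$n_catechin_only
  if (n_total == 0) stop("no expressed genes: metrics undefined")
  c(pct_both = 100 * p$n_both / n_total,
    delta_unique = 100 * (p$n_unamended_only - p$n_catechin_only) / n_total)
}

#' Classify a (%both, delta-unique) pair
#'
#' Assigns one of six response categories. The four extreme categories
#' (|delta unique| at or above the unique threshold) are evaluated
#' before resistant/responsive, so a MAG sitting exactly on the unique
#' threshold resolves to the extreme category: a 25-point asymmetry in
#' treatment-exclusive expression is read as a response.
#'
#' @param pct_both Percentage in \[0, 100\].
#' @param delta_unique Signed percentage in \[-100, 100\].
#' @param config A [classifier_config()].
#' @return Single category label.
#' @export
classify_response <- function(pct_both, delta_unique,
                              config = classifier_config()) {
  stopifnot(pct_both >= 0, pct_both <= 100,
            delta_unique >= -100, delta_unique <= 100)
  bt <- config$both_threshold; ut <- config$unique_threshold
  if (delta_unique >= ut) {
    if (pct_both >= bt) "lost_function" else "sensitive"
  } else if (delta_unique <= -ut) {
    if (pct_both >= bt) "gained_function" else "stimulated"
  } else {
    if (pct_both >= bt) "resistant" else "responsive"
  }
}

#' Classify every active MAG at every timepoint
#'
#' Runs [presence_pattern()], [response_metrics()] and
#' [classify_response()] over all MAGs and days, and tabulates per-day
#' category proportions over the classified MAGs. MAGs with no
#' expressed genes at a day are reported as inactive and excluded from
#' the proportions.
#'
#' @inheritParams presence_pattern
#' @param config A [classifier_config()].
#' @return List with `records` (data frame: mag_id, day, n_both,
#'   n_unamended_only, n_catechin_only, pct_both, delta_unique,
#'   category), `proportions` (data frame: day, category, proportion),
#'   and `inactive` (data frame: mag_id, day).
#' @export
classify_all <- function(expr, catalog, samples,
                         config = classifier_config()) {
  check_sample_table(samples)
  if (length(unique(samples$treatment)) < 2)
    stop("both treatments are required for response classification")
  days <- sort(unique(samples$day))
  mags <- unique(catalog$mag_id[catalog$gene_id %in% rownames(expr)])
  rec <- list(); inact <- list()
  for (d in days) {
    for (m in mags) {
      p <- presence_pattern(expr, catalog, samples, m, d,
                            config$presence_rule)
      if (is.null(p)) {
        inact[[length(inact) + 1]] <- data.frame(mag_id = m, day = d)
        next
      }
      met <- response_metrics(p)
      rec[[length(rec) + 1]] <- data.frame(
        mag_id = m, day = d, n_both = p$n_both,
        n_unamended_only = p$n_unamended_only,
        n_catechin_only = p$n_catechin_only,
        pct_both = met[["pct_both"]],
        delta_unique = met[["delta_unique"]],
        category = classify_response(met[["pct_both"]],
                                     met[["delta_unique"]], config),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  props <- NULL
  if (!is.null(records)) {
    props <- do.call(rbind, lapply(split(records, records$day), function(g) {
      tab <- table(factor(g$category, levels = response_categories()))
      data.frame(day = g$day[1], category = names(tab),
                 proportion = as.numeric(tab) / nrow(g),
                 stringsAsFactors = FALSE)
    }))
    rownames(props) <- NULL
  }
  list(records = records, proportions = props,
       inactive = if (length(inact)) do.call(rbind, inact) else
         data.frame(mag_id = character(), day = numeric()))
}
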