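## Hydrogenase directionality atlas: map (family, group) labels to
## hydrogen-use classes, aggregate class-level expression, and test
## treatment differences per timepoint.

#' Default hydrogenase directionality map
#'
#' Maps hydrogenase (family, group) pairs to a hydrogen-use class:
#' `h2_uptake`, `h2_evolving`, `bidirectional`, or `bifurcating`.
#' Entries encode the activity semantics of the HydDB group
#' classification; every row carries a provenance note and the table
#' is plain data, so curators can amend or replace it. `[FeFe]` group
#' `"A"` (unrefined into subgroups) defaults to `bifurcating` and is
#' flagged with a warning by [assign_directionality()]; subgroups
#' A1-A4 are mapped individually when provided.
#'
#' @return Data frame: family, group, activity_class, provenance.
#' @export
default_directionality_map <- function() {
  e <- function(family, group, class, note)
    data.frame(family = family, group = group, activity_class = class,
               provenance = note, stringsAsFactors = FALSE)
  rbind(
    do.call(rbind, lapply(c("1a","1b","1c","1d","1e","1f","1g","1h",
                            "1i","1j","1k","1l"), function(g)
      e("[NiFe]", g, "h2_uptake",
        "HydDB activity: H2-uptake (respiratory group 1)"))),
    e("[NiFe]", "2a", "h2_uptake", "HydDB activity: H2-uptake"),
    e("[NiFe]", "2b", "h2_uptake",
      "HydDB activity: H2-sensing; consumes H2, grouped with uptake"),
    e("[NiFe]", "3a", "bidirectional",
      "HydDB activity: bidirectional (F420-coupled)"),
    e("[NiFe]", "3b", "bidirectional",
      "HydDB activity: bidirectional (NADP-coupled)"),
    e("[NiFe]", "3c", "bifurcating",
      "HydDB activity: electron-bifurcating Mvh-Hdr complex"),
    e("[NiFe]", "3d", "bidirectional",
      "HydDB activity: bidirectional (NAD-coupled)"),
    do.call(rbind, lapply(c("4a","4b","4c","4d","4e","4f","4g","4h","4i"),
                          function(g)
      e("[NiFe]", g, "h2_evolving",
        "HydDB activity: H2-evolving (energy-converting group 4)"))),
    e("[FeFe]", "A", "bifurcating",
      "unrefined group A default; subgroups differ - supply A1-A4 to refine"),
    e("[FeFe]", "A1", "h2_evolving",
      "HydDB activity: fermentative H2 evolution"),
    e("[FeFe]", "A2", "h2_evolving", "HydDB activity: H2 evolution"),
    e("[FeFe]", "A3", "bifurcating",
      "HydDB activity: electron-bifurcating (NADH + ferredoxin)"),
    e("[FeFe]", "A4", "h2_evolving",
      "HydDB activity: H2 evolution (formate-associated)"),
    e("[FeFe]", "B", "h2_evolving", "HydDB activity: H2-evolving"),
    e("[Fe]", "Fe", "bidirectional",
      "Hmd: reversible methylene-H4MPT hydride chemistry"))
}

#' Assign a hydrogen-use class to every hydrogenase gene
#'
#' Joins a hydrogenase gene table against a directionality map on
#' (family, group). Genes whose (family, group) has no map entry get
#' `activity_class = "unmapped"` and `unmapped = TRUE`; they are never
#' dropped. Bare `[FeFe]` group `"A"` assignments trigger a warning
#' because the subgroup-level classes differ.
#'
#' @param genes Data frame: gene_id, mag_id, family, group.
#' @param map Directionality map (default
#'   [default_directionality_map()]).
#' @return The input with `activity_class` and `unmapped` columns.
#' @export
assign_directionality <- function(genes, map = default_directionality_map()) {
  need <- c("gene_id", "mag_id", "family", "group")
  if (!all(need %in% names(genes)))
    stop("hydrogenase table needs columns: ", paste(need, collapse = ", "))
  key <- paste(genes$family, genes$group, sep = "|")
  mkey <- paste(map$family, map$group, sep = "|")
  idx <- match(key, mkey)
  genes$activity_class <- ifelse(is.na(idx), "unmapped",
                                 map$activity_class[idx])
  genes$unmapped <- is.na(idx)
  if (any(genes$family == "[FeFe]" & genes$group == "A" & !genes$unmapped))
    warning("[FeFe] group 'A' assigned without subgroup refinement; ",
            "default class 'bifurcating' used")
  genes
}

#' Summed hydrogenase expression per hydrogen-use class
#'
#' Sums geTMM over hydrogenase genes per activity class per sample.
#' Classes (including `"unmapped"`) partition the genes, so the class
#' totals sum to the total hydrogenase expression. MAGs in
#' `exclude_mags` (typically methanogens) are removed first.
#'
#' @param expr geTMM matrix.
#' @param genes Output of [assign_directionality()].
#' @param exclude_mags MAG ids to exclude (default none).
#' @return Matrix: activity classes x samples.
#' @export
class_expression <- function(expr, genes, exclude_mags = character(0)) {
  g <- genes[!(genes$mag_id %in% exclude_mags), , drop = FALSE]
  classes <- c("h2_uptake", "h2_evolving", "bidirectional", "bifurcating",
               "unmapped")
  out <- matrix(0, nrow = length(classes), ncol = ncol(expr),
                dimnames = list(classes, colnames(expr)))
  g <- g[g$gene_id %in% rownames(expr), , drop = FALSE]
  for (cl in classes) {
    ids <- g$gene_id[g$activity_class == cl]
    if (length(ids) > 0)
      out[cl, ] <- colSums(expr[ids, , drop = FALSE])
  }
  out
}

#' Per-day treatment comparison of class-level expression
#'
#' For each activity class and day, runs a one-way ANOVA of
#' log-transformed class totals (log10 of value + 1) between
#' treatments, then adjusts all p-values with Benjamini-Hochberg
#' across the whole family of tests. Significance tiers at adjusted
#' p < 0.10 and < 0.05 are reported. Cells with fewer than two
#' replicates in either treatment are skipped with a notice.
#'
#' @param totals Class x sample matrix (see [class_expression()]).
#' @param samples Sample table.
#' @return Data frame: activity_class, day, n, F, p, p_adj, signif
#'   (`""`, `"*"` for < 0.10, `"**"` for < 0.05), note.
#' @export
compare_classes <- function(totals, samples) {
  check_sample_table(samples)
  out <- list()
  for (cl in rownames(totals)) {
    for (d in sort(unique(samples$day))) {
      sel <- samples$day == d & samples$sample_id %in% colnames(totals)
      sub <- samples[sel, , drop = FALSE]
      y <- log10(totals[cl, sub$sample_id] + 1)
      n_per <- table(sub$treatment)
      if (length(n_per) < 2 || any(n_per < 2)) {
        out[[length(out) + 1]] <- data.frame(
          activity_class = cl, day = d, n = nrow(sub), F = NA_real_,
          p = NA_real_, note = "skipped: <2 replicates per treatment",
          stringsAsFactors = FALSE)
        next
      }
      if (stats::var(y) == 0) {
        out[[length(out) + 1]] <- data.frame(
          activity_class = cl, day = d, n = nrow(sub), F = 0, p = 1,
          note = "", stringsAsFactors = FALSE)
        next
      }
      fit <- stats::aov(y ~ treatment, data = cbind(sub, y = y))
      an <- summary(fit)[[1]]
      out[[length(out) + 1]] <- data.frame(
        activity_class = cl, day = d, n = nrow(sub),
        F = an[["F value"]][1], p = an[["Pr(>F)"]][1], note = "",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  tested <- !is.na(res$p)
  res$p_adj[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$signif <- ifelse(is.na(res$p_adj), "",
                ifelse(res$p_adj < 0.05, "**",
                ifelse(res$p_adj < 0.10, "*", "")))
  rownames(res) <- NULL
  res
}
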