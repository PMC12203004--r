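## Synthetic-data generators: every input the pipeline consumes, with
## planted ground truth, so downstream modules are testable without any
## external download.

#' Simulation design for the expression generator
#'
#' Describes a two-treatment, multi-timepoint microcosm
#' metatranscriptome: MAG inventory, per-cell replication, planted
#' response categories, and the count-noise model (negative binomial
#' with per-gene means and a common overdispersion).
#'
#' @param n_mags Number of MAGs.
#' @param genes_per_mag Length-2 range of genes per MAG.
#' @param days Timepoint day labels.
#' @param replicates_per_cell Replicates per treatment x day cell.
#' @param treatments Two treatment labels.
#' @param planted_categories Optional data frame (mag_id, day,
#'   category) fixing the planted category per MAG x timepoint;
#'   by default categories are drawn uniformly from the six labels.
#' @param dispersion Negative-binomial overdispersion (size = 1 /
#'   dispersion).
#' @param gene_mean_range Range of per-gene expected counts when a
#'   gene is expressed.
#' @param library_size_range Range of relative per-sample depth
#'   factors.
#' @param length_range Range of gene lengths (bp).
#' @param expressed_fraction Fraction of a MAG's genes expressed at a
#'   timepoint (before the both/unique split).
#' @param dropout_rate Per-replicate probability that an expressed
#'   gene records zero counts in one replicate (default 0).
#' @param margin Minimum distance (percentage points) of every planted
#'   (%both, delta-unique) value from every classification threshold.
#' @param seed Integer seed; identical seeds give identical outputs.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n_mags = 60L, genes_per_mag = c(80L, 150L),
                              days = c(0, 7, 14, 21, 35),
                              replicates_per_cell = 3L,
                              treatments = c("unamended", "catechin"),
                              planted_categories = NULL,
                              dispersion = 0.5,
                              gene_mean_range = c(30, 150),
                              library_size_range = c(0.7, 1.3),
                              length_range = c(300L, 3000L),
                              expressed_fraction = 0.8,
                              dropout_rate = 0,
                              margin = 5,
                              seed = 1L) {
  stopifnot(replicates_per_cell >= 1, length(treatments) == 2,
            dispersion > 0, margin >= 0, dropout_rate >= 0,
            dropout_rate < 1)
  if (!is.null(planted_categories)) {
    bad <- setdiff(planted_categories$category, response_categories())
    if (length(bad) > 0)
      stop("invalid planted categories: ", paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "simulation_design")
}

## distance of a (%both, delta-unique) point from the nearest
## classification threshold
threshold_margin <- function(pb, du, bt = 26, ut = 25) {
  min(abs(pb - bt), abs(du - ut), abs(du + ut))
}

## sample a target (%both, delta-unique) strictly inside a category's
## region, `m` points clear of every threshold
sample_region_point <- function(category, bt = 26, ut = 25, m = 6.5) {
  pb_hi <- function(lo, hi) stats::runif(1, lo, hi)
  switch(category,
    resistant = c(pb_hi(bt + m, 70), stats::runif(1, -(ut - m), ut - m)),
    responsive = c(pb_hi(5, bt - m), stats::runif(1, -(ut - m), ut - m)),
    sensitive = c(pb_hi(5, bt - m), stats::runif(1, ut + m, 60)),
    stimulated = c(pb_hi(5, bt - m), -stats::runif(1, ut + m, 60)),
    lost_function = c(pb_hi(bt + m, 55), stats::runif(1, ut + m, 40)),
    gained_function = c(pb_hi(bt + m, 55), -stats::runif(1, ut + m, 40)),
    stop("unknown category: ", category))
}

## integer (n_both, n_u, n_c) realizing a target point on T expressed
## genes, re-sampled until the realized point keeps the margin
plant_counts <- function(category, n_total, margin, bt = 26, ut = 25) {
  for (attempt in 1:50) {
    tgt <- sample_region_point(category, bt, ut, m = margin + 1.5)
    n_both <- round(tgt[1] / 100 * n_total)
    d <- round(tgt[2] / 100 * n_total)
    rest <- n_total - n_both
    if (abs(d) > rest) next
    n_u <- (rest + d) / 2
    ## force integer split
    n_u <- if ((rest + d) %% 2 == 0) n_u else n_u + 0.5
    n_c <- rest - n_u
    if (n_u < 0 || n_c < 0 || n_u != round(n_u)) next
    pb <- 100 * n_both / n_total
    du <- 100 * (n_u - n_c) / n_total
    if (threshold_margin(pb, du, bt, ut) < margin) next
    if (classify_response(pb, du) != category) next
    return(c(n_both = n_both, n_u = n_u, n_c = n_c))
  }
  NULL
}

#' Generate a synthetic metatranscriptome with planted response truth
#'
#' For every MAG x timepoint a response category is planted by
#' partitioning the MAG's expressed genes into shared,
#' unamended-exclusive, and catechin-exclusive sets whose noiseless
#' (%both, delta-unique) point lies strictly inside the category's
#' region with the design margin. Counts for expressed genes are drawn
#' from a negative binomial with per-gene means and per-sample depth
#' factors; absent genes get zero counts.
#'
#' @param design A [simulation_design()].
#' @return List: `counts` (integer matrix), `catalog` (gene_id,
#'   mag_id, length_bp, ko_id, cazy_best_hit, camper_id), `samples`
#'   (sample table), `truth` (mag_id, day, category, counts, planted
#'   metrics, margin), `presence` (per mag/day/treatment planted gene
#'   sets, as a data frame).
#' @export
gen_expression_dataset <- function(design = simulation_design()) {
  set.seed(design$seed)
  d <- design
  mags <- sprintf("MAG_%03d", seq_len(d$n_mags))
  n_genes <- sample(d$genes_per_mag[1]:d$genes_per_mag[2], d$n_mags,
                    replace = TRUE)
  gene_mag <- rep(mags, n_genes)
  gene_ids <- sprintf("%s_g%03d", gene_mag,
                      unlist(lapply(n_genes, seq_len)))
  catalog <- data.frame(
    gene_id = gene_ids, mag_id = gene_mag,
    length_bp = round(stats::runif(length(gene_ids), d$length_range[1],
                                   d$length_range[2])),
    ko_id = sprintf("K%05d", sample(1:20000, length(gene_ids),
                                    replace = TRUE)),
    cazy_best_hit = NA_character_, camper_id = NA_character_,
    stringsAsFactors = FALSE)
  samples <- expand.grid(replicate = paste0("r", seq_len(d$replicates_per_cell)),
                         treatment = d$treatments, day = d$days,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_d%02d_%s", substr(samples$treatment, 1, 3),
                               samples$day, samples$replicate)
  samples <- samples[, c("sample_id", "treatment", "day", "replicate")]
  depth <- stats::runif(nrow(samples), d$library_size_range[1],
                        d$library_size_range[2])
  gene_mu <- stats::runif(length(gene_ids), d$gene_mean_range[1],
                          d$gene_mean_range[2])
  counts <- matrix(0L, nrow = length(gene_ids), ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  truth <- list(); presence_rows <- list()
  size <- 1 / d$dispersion
  for (mi in seq_along(mags)) {
    m <- mags[mi]
    g <- gene_ids[gene_mag == m]
    for (day in d$days) {
      cat_planted <- if (!is.null(d$planted_categories)) {
        pc <- d$planted_categories
        hit <- pc$category[pc$mag_id == m & pc$day == day]
        if (length(hit) == 1) hit else sample(response_categories(), 1)
      } else sample(response_categories(), 1)
      n_total <- round(d$expressed_fraction * length(g))
      parts <- plant_counts(cat_planted, n_total, d$margin)
      if (is.null(parts))
        stop("infeasible design for ", m, " at day ", day,
             ": cannot realize '", cat_planted, "' with margin ",
             d$margin, " on ", n_total, " expressed genes")
      expressed <- sample(g, n_total)
      set_both <- expressed[seq_len(parts["n_both"])]
      set_u <- expressed[parts["n_both"] + seq_len(parts["n_u"])]
      set_c <- setdiff(expressed, c(set_both, set_u))
      for (trt in d$treatments) {
        present <- c(set_both, if (trt == "unamended") set_u else set_c)
        cols <- which(samples$treatment == trt & samples$day == day)
        for (j in cols) {
          mu <- gene_mu[match(present, gene_ids)] * depth[j]
          v <- stats::rnbinom(length(present), size = size, mu = mu)
          if (d$dropout_rate > 0)
            v[stats::runif(length(v)) < d$dropout_rate] <- 0L
          counts[present, j] <- as.integer(v)
        }
        presence_rows[[length(presence_rows) + 1]] <- data.frame(
          mag_id = m, day = day, treatment = trt,
          gene_id = present, stringsAsFactors = FALSE)
      }
      pb <- 100 * parts[["n_both"]] / n_total
      du <- 100 * (parts[["n_u"]] - parts[["n_c"]]) / n_total
      truth[[length(truth) + 1]] <- data.frame(
        mag_id = m, day = day, category = cat_planted,
        n_both = parts[["n_both"]], n_unamended_only = parts[["n_u"]],
        n_catechin_only = parts[["n_c"]], n_total = n_total,
        pct_both = pb, delta_unique = du,
        margin = threshold_margin(pb, du), stringsAsFactors = FALSE)
    }
  }
  list(counts = counts, catalog = catalog, samples = samples,
       truth = do.call(rbind, truth),
       presence = do.call(rbind, presence_rows))
}

#' Methanogen rule fixture with expected calls
#'
#' Builds a small annotated MAG set and expression matrix that
#' instantiates each substrate rule exactly once: a hydrogenotroph, a
#' methylotroph, an acetoclast, an obligate-acetoclast
#' Methanotrichales genome (also expressing a methyltransferase, to
#' exercise the override), a multifunctional genome, a confirmed
#' methanogen expressing only `mcrA` (active but unclassifiable), and
#' a non-methanogen.
#'
#' @param seed Integer seed (controls expression magnitudes only; the
#'   layout is fixed).
#' @return List: `catalog`, `taxonomy` (mag_id, domain, class, order),
#'   `expr` (geTMM-scale matrix, 2 samples), `expected` (data frame of
#'   expected potential and active calls).
#' @export
gen_methanogen_fixture <- function(seed = 1L) {
  set.seed(seed)
  gs <- default_gene_sets()
  spec <- list(
    MAG_hydro = list(class = "Methanobacteria", order = "Methanobacteriales",
      present = c("K00399", "K03388", "K00200", "K00672", "K00577", "K14126"),
      expressed = c("K00399", "K00200", "K14126")),
    MAG_methylo = list(class = "Thermoplasmata", order = "Methanomassiliicoccales",
      present = c("K00399", "K03389", "K04480", "K14080", "K14081"),
      expressed = c("K00399", "K04480")),
    MAG_aceto = list(class = "Methanosarcinia", order = "Methanosarcinales",
      present = c("K00399", "K03388", "K00192", "K00193", "K00925", "K00625"),
      expressed = c("K00399", "K00925")),
    MAG_methanothrix = list(class = "Methanosarcinia", order = "Methanotrichales",
      present = c("K00399", "K03388", "K00192", "K01895", "K04480", "K14080"),
      expressed = c("K00399", "K01895", "K04480")),
    MAG_multi = list(class = "Methanobacteria", order = "Methanobacteriales",
      present = c("K00399", "K03388", "K00200", "K00319", "K00578", "K00440",
                  "K04480", "K14080"),
      expressed = c("K00200", "K00440", "K04480")),
    MAG_mcr_only = list(class = "Methanomicrobia", order = "Methanomicrobiales",
      present = c("K00399", "K03388"),
      expressed = c("K00399")),
    MAG_not_methanogen = list(class = "Clostridia", order = "Eubacteriales",
      present = c("K00925", "K00625", "K01895"),
      expressed = c("K00925")))
  rows <- list(); taxonomy <- list(); expr_rows <- list()
  for (m in names(spec)) {
    s <- spec[[m]]
    ids <- sprintf("%s_g%02d", m, seq_along(s$present))
    rows[[m]] <- data.frame(gene_id = ids, mag_id = m,
                            length_bp = 900L, ko_id = s$present,
                            cazy_best_hit = NA_character_,
                            camper_id = NA_character_,
                            stringsAsFactors = FALSE)
    taxonomy[[m]] <- data.frame(mag_id = m, domain = "Archaea",
                                class = s$class, order = s$order,
                                stringsAsFactors = FALSE)
    on <- s$present %in% s$expressed
    expr_rows[[m]] <- stats::setNames(
      ifelse(on, round(stats::runif(length(ids), 2, 50), 3), 0), ids)
  }
  catalog <- do.call(rbind, rows); rownames(catalog) <- NULL
  taxonomy <- do.call(rbind, taxonomy); rownames(taxonomy) <- NULL
  v <- unlist(expr_rows)
  names(v) <- catalog$gene_id
  expr <- cbind(una_d14_r1 = v, cat_d14_r1 = v)
  expected <- data.frame(
    mag_id = names(spec),
    is_methanogen = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    potential = c("hydrogenotrophic", "methylotrophic", "acetoclastic",
                  "acetoclastic+methylotrophic",
                  "hydrogenotrophic+methylotrophic", "", ""),
    active = c("hydrogenotrophic", "methylotrophic", "acetoclastic",
               "acetoclastic", "hydrogenotrophic+methylotrophic",
               "ignored", ""),
    stringsAsFactors = FALSE)
  list(catalog = catalog, taxonomy = taxonomy, expr = expr,
       expected = expected)
}

#' Generate an LC-MS feature table with planted in-source artifacts
#'
#' Plants parent ions with co-eluting in-source fragments (intensity
#' profiles proportional to the parent, m/z present in the parent's
#' MS2), independent features (isolated, co-eluting but decorrelated,
#' or correlated without MS2 confirmation), and halogen-containing
#' compositions.
#'
#' @param n_parents Number of parent ions.
#' @param n_fragments_per_parent Fragments planted per parent.
#' @param n_independents Independent features. Of these, roughly 20%
#'   are planted co-eluting with a parent but decorrelated (r < 0.8)
#'   and 20% co-eluting and correlated but absent from the parent MS2.
#' @param n_halogen Features with halogenated predicted compositions.
#' @param n_samples Number of intensity columns.
#' @param seed Integer seed.
#' @return List: `features` (feature_id, mz, rt (seconds), formula,
#'   intensity columns `I1..In`), `spectra` (named list of MS2 peak
#'   matrices for parents), `truth` (feature_id, label, parent_id).
#' @export
gen_lcms_dataset <- function(n_parents = 50L, n_fragments_per_parent = 2L,
                             n_independents = 100L, n_halogen = 10L,
                             n_samples = 12L, seed = 1L) {
  stopifnot(n_parents >= 0, n_fragments_per_parent >= 0,
            n_independents >= 0, n_halogen >= 0, n_samples >= 3)
  set.seed(seed)
  n_co_decor <- if (n_parents > 0) floor(n_independents * 0.2) else 0
  n_co_corr <- if (n_parents > 0) floor(n_independents * 0.2) else 0
  n_iso <- n_independents - n_co_decor - n_co_corr
  n_slots <- n_parents + n_iso + n_halogen
  slot_rt <- sort(stats::runif(n_slots, 60, 900))
  ## keep unrelated features at least 1 s apart so co-elution is only
  ## ever planted, never accidental
  slot_rt <- slot_rt + seq_len(n_slots)  # enforce >= 1 s spacing
  slot_rt <- sample(slot_rt)
  base_int <- function() exp(stats::rnorm(n_samples, stats::runif(1, 8, 12), 1))
  feats <- list(); truth <- list(); spectra <- list(); ints <- list()
  fid <- 0
  new_id <- function() { fid <<- fid + 1; sprintf("F%04d", fid) }
  parents <- character(n_parents)
  parent_rt <- numeric(n_parents); parent_mz <- numeric(n_parents)
  for (i in seq_len(n_parents)) {
    id <- new_id(); parents[i] <- id
    mz <- stats::runif(1, 250, 850)
    parent_rt[i] <- slot_rt[i]; parent_mz[i] <- mz
    ints[[id]] <- base_int()
    feats[[id]] <- data.frame(feature_id = id, mz = mz, rt = slot_rt[i],
                              formula = sprintf("C%dH%dO%d",
                                                sample(8:30, 1),
                                                sample(8:40, 1),
                                                sample(2:10, 1)),
                              stringsAsFactors = FALSE)
    truth[[id]] <- data.frame(feature_id = id, label = "parent",
                              parent_id = NA_character_,
                              stringsAsFactors = FALSE)
  }
  ## fragments: scaled parent intensities, co-eluting, in parent MS2
  frag_mz_of <- vector("list", n_parents)
  for (i in seq_len(n_parents)) {
    for (k in seq_len(n_fragments_per_parent)) {
      id <- new_id()
      fmz <- parent_mz[i] * stats::runif(1, 0.3, 0.8)
      frag_mz_of[[i]] <- c(frag_mz_of[[i]], fmz)
      ints[[id]] <- ints[[parents[i]]] * stats::runif(1, 0.2, 0.8) *
        (1 + stats::rnorm(n_samples, 0, 0.004))
      feats[[id]] <- data.frame(feature_id = id, mz = fmz,
                                rt = parent_rt[i] +
                                  stats::runif(1, -0.002, 0.002),
                                formula = NA_character_,
                                stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(feature_id = id, label = "fragment",
                                parent_id = parents[i],
                                stringsAsFactors = FALSE)
    }
  }
  ## independents
  add_independent <- function(rt, intensities, mz) {
    id <- new_id()
    ints[[id]] <<- intensities
    feats[[id]] <<- data.frame(feature_id = id, mz = mz, rt = rt,
                               formula = sprintf("C%dH%dO%d",
                                                 sample(5:25, 1),
                                                 sample(6:30, 1),
                                                 sample(1:8, 1)),
                               stringsAsFactors = FALSE)
    truth[[id]] <<- data.frame(feature_id = id, label = "independent",
                               parent_id = NA_character_,
                               stringsAsFactors = FALSE)
    id
  }
  for (k in seq_len(n_iso))
    add_independent(slot_rt[n_parents + k], base_int(),
                    stats::runif(1, 100, 900))
  for (k in seq_len(n_co_decor)) {
    host <- ((k - 1) %% n_parents) + 1
    repeat {
      v <- base_int()
      if (abs(stats::cor(v, ints[[parents[host]]])) < 0.8) break
    }
    add_independent(parent_rt[host] + stats::runif(1, -0.002, 0.002), v,
                    stats::runif(1, 100, 900))
  }
  for (k in seq_len(n_co_corr)) {
    host <- ((k - 1) %% n_parents) + 1
    ## correlated with the parent but its m/z is kept far from every
    ## MS2 peak, so MS2 confirmation must fail
    v <- ints[[parents[host]]] * stats::runif(1, 0.1, 0.9) *
      (1 + stats::rnorm(n_samples, 0, 0.004))
    repeat {
      mz <- stats::runif(1, 100, parent_mz[host] * 0.95)
      ok <- all(abs(mz - frag_mz_of[[host]]) / mz * 1e6 > 100)
      if (ok) break
    }
    add_independent(parent_rt[host] + stats::runif(1, -0.002, 0.002), v, mz)
  }
  ## halogenated compositions (isolated)
  for (k in seq_len(n_halogen)) {
    id <- new_id()
    hal <- sample(c("Cl", "Br", "F", "I"), 1)
    ints[[id]] <- base_int()
    feats[[id]] <- data.frame(
      feature_id = id, mz = stats::runif(1, 150, 700),
      rt = slot_rt[n_parents + n_iso + k],
      formula = sprintf("C%dH%d%s%d", sample(5:20, 1), sample(5:25, 1),
                        hal, sample(1:3, 1)),
      stringsAsFactors = FALSE)
    truth[[id]] <- data.frame(feature_id = id, label = "halogen",
                              parent_id = NA_character_,
                              stringsAsFactors = FALSE)
  }
  ## MS2 spectra for parents: fragment m/z within 1 ppm + noise peaks
  for (i in seq_len(n_parents)) {
    fmz <- frag_mz_of[[i]]
    peaks_mz <- if (length(fmz) > 0)
      fmz * (1 + stats::runif(length(fmz), -0.8e-6, 0.8e-6)) else numeric(0)
    n_noise <- 5
    noise <- numeric(0)
    while (length(noise) < n_noise) {
      cand <- stats::runif(1, 50, parent_mz[i])
      if (all(abs(cand - c(fmz, 0)) / cand * 1e6 > 100)) noise <- c(noise, cand)
    }
    mzv <- c(peaks_mz, noise)
    spectra[[parents[i]]] <- cbind(mz = mzv,
                                   intensity = stats::runif(length(mzv), 1e3, 1e6))
  }
  features <- do.call(rbind, feats)
  imat <- do.call(rbind, ints)
  colnames(imat) <- paste0("I", seq_len(n_samples))
  features <- cbind(features, as.data.frame(imat))
  rownames(features) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(features = features, spectra = spectra, truth = truth)
}
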