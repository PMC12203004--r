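## Rule-based calling of methanogen substrate potential and active
## methanogenesis pathways, plus a generic boolean rule engine over
## annotation identifiers usable for arbitrary carbon-cycle roles.

#' Curated default gene sets for methanogenesis calling
#'
#' Named lists of annotation identifiers (KEGG orthology ids plus
#' gene-symbol style identifiers for systems without stable KO ids).
#' These are curated defaults for the marker systems used by the
#' rules: the methanogen-confirming Mcr and Hdr complexes, the
#' Wood-Ljungdahl (reductive acetyl-CoA) pathway, the Mtr complex,
#' methanogenesis-relevant hydrogenases, the ACS/CODH complex and
#' acetate-activation genes, substrate:corrinoid methyltransferases
#' (mtxB-type) and their partner components, and formate
#' dehydrogenase (kept as an evidence flag, not a category). All sets
#' are plain data and can be replaced by the caller.
#'
#' @return Named list of character vectors.
#' @export
default_gene_sets <- function() {
  list(
    mcr = c("K00399", "K00401", "K00402"),
    hdr = c("K03388", "K03389", "K03390", "K08264", "K08265"),
    wood_ljungdahl = c("K00200", "K00201", "K00202", "K00203", "K00205",
                       "K00672", "K01499", "K00319", "K00320"),
    mtr_complex = c("K00577", "K00578", "K00579", "K00580", "K00581",
                    "K00582", "K00583", "K00584"),
    hydrogenase = c("K14126", "K14127", "K14128",   # MvhADG
                    "K00440", "K00441", "K00443",   # FrhABG
                    "K14086", "K14087", "K14088", "K14089"),  # Ech
    acs_codh = c("K00192", "K00193", "K00194", "K00197"),
    acs = "K01895",
    ack = "K00925",
    pta = "K00625",
    mtxB = c("K04480",                       # mtaB (methanol)
             "K16176", "K16178", "K14083",   # methylamine mtxB types
             "mtsD", "mtsF", "mtsH"),        # methyl-sulfur systems
    mtx_partner = c("K14080", "K14081", "K14082", "K16177", "K16179"),
    fdh = c("K00123", "K00124", "K00127", "K22515"))
}

## ---- generic boolean rule engine ------------------------------------------

#' Rule-expression constructors
#'
#' Build boolean expressions over gene-set predicates and taxonomy
#' guards for [evaluate_rule()] / [evaluate_ruleset()].
#'
#' `gene_pred(set, min_genes, mode)` is satisfied when at least
#' `min_genes` genes carrying an identifier from gene set `set` are
#' present (`mode = "present"`) or expressed (`mode = "expressed"`).
#' `taxon_pred(field, value)` guards on a taxonomy column.
#'
#' @param set Gene-set name (resolved in the rule set's `gene_sets`).
#' @param min_genes Minimum number of matching genes.
#' @param mode `"expressed"` or `"present"`.
#' @param field Taxonomy column name.
#' @param value Required value.
#' @param ... Sub-expressions.
#' @param x Sub-expression.
#' @return An expression node (list).
#' @export
gene_pred <- function(set, min_genes = 1L, mode = c("expressed", "present")) {
  mode <- match.arg(mode)
  list(type = "geneset", set = set, min = as.integer(min_genes), mode = mode)
}

#' @rdname gene_pred
#' @export
taxon_pred <- function(field, value) {
  list(type = "taxon", field = field, value = value)
}

#' @rdname gene_pred
#' @export
rule_and <- function(...) list(type = "and", args = list(...))

#' @rdname gene_pred
#' @export
rule_or <- function(...) list(type = "or", args = list(...))

#' @rdname gene_pred
#' @export
rule_not <- function(x) list(type = "not", args = list(x))

#' Assemble a rule set
#'
#' @param rules List of `list(rule_id =, label =, expr =)` entries.
#' @param gene_sets Named list of identifier vectors the predicates
#'   refer to (default [default_gene_sets()]).
#' @return List of class `rule_set`.
#' @export
rule_set <- function(rules, gene_sets = default_gene_sets()) {
  for (r in rules)
    if (is.null(r$rule_id) || is.null(r$label) || is.null(r$expr))
      stop("each rule needs rule_id, label, and expr")
  if (any(lengths(gene_sets) == 0)) stop("gene sets must be non-empty")
  structure(list(rules = rules, gene_sets = gene_sets), class = "rule_set")
}

## annotation identifiers of one gene (any of the three DRAM-style
## annotation columns)
gene_annotations <- function(catalog) {
  cols <- intersect(c("ko_id", "cazy_best_hit", "camper_id"),
                    names(catalog))
  ann <- catalog[, cols, drop = FALSE]
  lapply(seq_len(nrow(ann)), function(i) {
    v <- unlist(ann[i, ], use.names = FALSE)
    v[!is.na(v) & nzchar(v)]
  })
}

## context for one MAG: vectors of annotation ids for present and
## expressed genes (one entry per gene, multi-annotation genes carry
## all their ids)
mag_context <- function(catalog, mag_id, expressed_genes = NULL,
                        taxonomy = NULL) {
  rows <- which(catalog$mag_id == mag_id)
  ann <- gene_annotations(catalog[rows, , drop = FALSE])
  genes <- catalog$gene_id[rows]
  expr_ann <- if (is.null(expressed_genes)) ann[0] else
    ann[genes %in% expressed_genes]
  tax <- if (is.null(taxonomy)) NULL else
    taxonomy[taxonomy$mag_id == mag_id, , drop = FALSE]
  list(present = ann, expressed = expr_ann, taxonomy = tax)
}

count_geneset_hits <- function(ann_list, set_ids) {
  sum(vapply(ann_list, function(v) any(v %in% set_ids), logical(1)))
}

#' Evaluate one rule expression against a MAG context
#'
#' @param expr Expression built with the [gene_pred()] constructors.
#' @param context As built internally from a catalog/expression pair:
#'   list with `present` / `expressed` per-gene annotation lists and a
#'   one-row `taxonomy`.
#' @param gene_sets Named list resolving predicate set names.
#' @return Logical scalar.
#' @export
evaluate_rule <- function(expr, context, gene_sets = default_gene_sets()) {
  if (is.null(expr$type)) stop("malformed rule expression (no type)")
  switch(expr$type,
    geneset = {
      ids <- gene_sets[[expr$set]]
      if (is.null(ids)) stop("unknown gene set: ", expr$set)
      pool <- if (expr$mode == "expressed") context$expressed
              else context$present
      count_geneset_hits(pool, ids) >= expr$min
    },
    taxon = {
      tx <- context$taxonomy
      if (is.null(tx) || nrow(tx) == 0) return(FALSE)
      fld <- tx[[expr$field]]
      !is.null(fld) && !is.na(fld[1]) && fld[1] == expr$value
    },
    and = all(vapply(expr$args, evaluate_rule, logical(1),
                     context = context, gene_sets = gene_sets)),
    or = any(vapply(expr$args, evaluate_rule, logical(1),
                    context = context, gene_sets = gene_sets)),
    not = !evaluate_rule(expr$args[[1]], context, gene_sets),
    stop("malformed rule expression: unknown node type '", expr$type, "'"))
}

#' Evaluate a rule set over every MAG
#'
#' Generic boolean evaluation: each MAG receives every rule label
#' whose expression is satisfied. "Expressed" predicates use non-zero
#' expression in at least one column of `expr` (the same presence rule
#' as the response classifier).
#'
#' @param catalog Gene catalog (gene_id, mag_id, annotation columns).
#' @param expr Expression matrix or `NULL` (then only `"present"`
#'   predicates can fire).
#' @param rules A [rule_set()].
#' @param taxonomy Optional taxonomy data frame (mag_id + rank
#'   columns).
#' @return Data frame: mag_id, rule_id, label, satisfied.
#' @export
evaluate_ruleset <- function(catalog, expr = NULL, rules, taxonomy = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  expressed <- if (is.null(expr)) NULL else
    rownames(expr)[rowSums(expr > 0) > 0]
  mags <- unique(catalog$mag_id)
  out <- list()
  for (m in mags) {
    ctx <- mag_context(catalog, m, expressed, taxonomy)
    for (r in rules$rules) {
      ok <- tryCatch(evaluate_rule(r$expr, ctx, rules$gene_sets),
                     error = function(e)
                       stop("rule ", r$rule_id, ": ", conditionMessage(e),
                            call. = FALSE))
      out[[length(out) + 1]] <- data.frame(
        mag_id = m, rule_id = r$rule_id, label = r$label,
        satisfied = ok, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## ---- methanogen-specific calls --------------------------------------------

#' Default substrate-potential rules expressed in the generic grammar
#'
#' @param gene_sets Gene sets to resolve against.
#' @param hydrogenotrophic_require_all Require all three marker systems
#'   (Wood-Ljungdahl, Mtr, hydrogenase) for hydrogenotrophic potential
#'   (default TRUE, the conjunction reading).
#' @return A [rule_set()].
#' @export
methanogen_potential_rules <- function(gene_sets = default_gene_sets(),
                                       hydrogenotrophic_require_all = TRUE) {
  hyd <- if (hydrogenotrophic_require_all)
    rule_and(gene_pred("wood_ljungdahl", 1, "present"),
             gene_pred("mtr_complex", 1, "present"),
             gene_pred("hydrogenase", 1, "present"))
  else
    rule_or(rule_and(gene_pred("wood_ljungdahl", 1, "present"),
                     gene_pred("mtr_complex", 1, "present")),
            rule_and(gene_pred("wood_ljungdahl", 1, "present"),
                     gene_pred("hydrogenase", 1, "present")))
  rule_set(list(
    list(rule_id = "pot_h2", label = "hydrogenotrophic", expr = hyd),
    list(rule_id = "pot_ac", label = "acetoclastic",
         expr = rule_and(taxon_pred("class", "Methanosarcinia"),
                         gene_pred("acs_codh", 1, "present"),
                         rule_or(gene_pred("acs", 1, "present"),
                                 rule_and(gene_pred("ack", 1, "present"),
                                          gene_pred("pta", 1, "present"))))),
    list(rule_id = "pot_me", label = "methylotrophic",
         expr = rule_and(gene_pred("mtxB", 1, "present"),
                         gene_pred("mtx_partner", 1, "present")))),
    gene_sets)
}

methanogenesis_all_ids <- function(gene_sets) {
  unique(unlist(gene_sets[c("mcr", "hdr", "wood_ljungdahl", "mtr_complex",
                            "hydrogenase", "acs_codh", "acs", "ack", "pta",
                            "mtxB", "mtx_partner")]))
}

#' Call methanogen substrate-use potential
#'
#' A MAG is first confirmed as a methanogen by the presence of Mcr and
#' Hdr complex genes; confirmed methanogens are screened for
#' hydrogenotrophic, acetoclastic (Methanosarcinia only), and
#' methylotrophic potential. Genomes encoding more than one pathway
#' are flagged multifunctional; a confirmed methanogen matching no
#' substrate rule keeps an empty potential set.
#'
#' @param catalog Gene catalog.
#' @param taxonomy Taxonomy data frame (mag_id, class, order, ...).
#' @param gene_sets Gene sets (default [default_gene_sets()]).
#' @param hydrogenotrophic_require_all See
#'   [methanogen_potential_rules()].
#' @return Data frame: mag_id, is_methanogen, hydrogenotrophic,
#'   acetoclastic, methylotrophic, multifunctional, potential
#'   (collapsed label), evidence.
#' @export
call_potential <- function(catalog, taxonomy,
                           gene_sets = default_gene_sets(),
                           hydrogenotrophic_require_all = TRUE) {
  rules <- methanogen_potential_rules(gene_sets,
                                      hydrogenotrophic_require_all)
  mags <- unique(catalog$mag_id)
  out <- list()
  for (m in mags) {
    ctx <- mag_context(catalog, m, NULL, taxonomy)
    is_mg <- count_geneset_hits(ctx$present, gene_sets$mcr) >= 1 &&
             count_geneset_hits(ctx$present, gene_sets$hdr) >= 1
    hy <- ac <- me <- FALSE
    if (is_mg) {
      sat <- vapply(rules$rules, function(r)
        evaluate_rule(r$expr, ctx, rules$gene_sets), logical(1))
      hy <- sat[1]; ac <- sat[2]; me <- sat[3]
    }
    lab <- c("hydrogenotrophic", "acetoclastic", "methylotrophic")[c(hy, ac, me)]
    ev <- character(0)
    if (is_mg) ev <- c(ev, "mcr+hdr")
    if (hy) ev <- c(ev, "WL+Mtr+hydrogenase")
    if (ac) ev <- c(ev, "Methanosarcinia+ACS/CODH+acetate-activation")
    if (me) ev <- c(ev, "mtxB+partner")
    out[[length(out) + 1]] <- data.frame(
      mag_id = m, is_methanogen = is_mg,
      hydrogenotrophic = hy, acetoclastic = ac, methylotrophic = me,
      multifunctional = sum(hy, ac, me) > 1,
      potential = paste(lab, collapse = "+"),
      evidence = paste(ev, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Call actively used methanogenesis pathways per sample
#'
#' Applies the activity rules to the genes a MAG expresses in each
#' sample: hydrogenotrophic needs at least one expressed
#' Wood-Ljungdahl gene plus one relevant hydrogenase gene;
#' methylotrophic needs an expressed substrate:corrinoid
#' methyltransferase (mtxB); acetoclastic needs an expressed
#' acetate-utilization gene (acs, ack, or pta). Active
#' Methanotrichales MAGs are obligate acetoclasts regardless of other
#' genes. MAGs expressing no methanogenesis genes, or genes
#' insufficient for any rule, are reported as `"ignored"`. Expressed
#' formate dehydrogenase is reported as an evidence flag.
#'
#' @param expr Filtered geTMM matrix.
#' @param catalog Gene catalog.
#' @param taxonomy Taxonomy data frame.
#' @param potential Output of [call_potential()] (used to restrict to
#'   confirmed methanogens and to flag calls outside the genomic
#'   potential).
#' @param gene_sets Gene sets.
#' @return Data frame: mag_id, sample_id, active (label or
#'   "ignored"), beyond_potential (flag), formate_evidence.
#' @export
call_active <- function(expr, catalog, taxonomy, potential,
                        gene_sets = default_gene_sets()) {
  all_ids <- methanogenesis_all_ids(gene_sets)
  mg <- potential$mag_id[potential$is_methanogen]
  out <- list()
  for (m in mg) {
    pot <- potential[potential$mag_id == m, ]
    tx <- taxonomy[taxonomy$mag_id == m, , drop = FALSE]
    is_mtx <- nrow(tx) > 0 && !is.na(tx$order[1]) &&
      tx$order[1] == "Methanotrichales"
    for (s in colnames(expr)) {
      expressed <- rownames(expr)[expr[, s] > 0]
      ctx <- mag_context(catalog, m, expressed, taxonomy)
      n_any <- count_geneset_hits(ctx$expressed, all_ids)
      hy <- count_geneset_hits(ctx$expressed, gene_sets$wood_ljungdahl) >= 1 &&
            count_geneset_hits(ctx$expressed, gene_sets$hydrogenase) >= 1
      me <- count_geneset_hits(ctx$expressed, gene_sets$mtxB) >= 1
      ac <- count_geneset_hits(ctx$expressed,
                               c(gene_sets$acs, gene_sets$ack,
                                 gene_sets$pta)) >= 1
      active <- c("hydrogenotrophic", "acetoclastic",
                  "methylotrophic")[c(hy, ac, me)]
      if (is_mtx) active <- if (n_any >= 1) "acetoclastic" else character(0)
      label <- if (n_any == 0 || length(active) == 0) "ignored"
               else paste(active, collapse = "+")
      beyond <- any(c(hy && !pot$hydrogenotrophic,
                      ac && !pot$acetoclastic,
                      me && !pot$methylotrophic)) && !is_mtx
      out[[length(out) + 1]] <- data.frame(
        mag_id = m, sample_id = s, active = label,
        beyond_potential = beyond,
        formate_evidence =
          count_geneset_hits(ctx$expressed, gene_sets$fdh) >= 1,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Methanogenesis pathway groups
#'
#' @param gene_sets Gene sets.
#' @return Named list mapping the four pathway groups to identifier
#'   vectors: Wood-Ljungdahl, methyltransferase systems, acetate
#'   utilization, and methanogenic protein complexes.
#' @export
pathway_groups <- function(gene_sets = default_gene_sets()) {
  list(wood_ljungdahl = gene_sets$wood_ljungdahl,
       methyltransferase = unique(c(gene_sets$mtxB, gene_sets$mtx_partner)),
       acetate = unique(c(gene_sets$acs_codh, gene_sets$acs,
                          gene_sets$ack, gene_sets$pta)),
       complexes = unique(c(gene_sets$mcr, gene_sets$hdr,
                            gene_sets$mtr_complex, gene_sets$hydrogenase)))
}

#' Summed pathway expression per sample
#'
#' Sums geTMM values over the genes of each methanogenesis pathway
#' group, restricted to the given MAGs.
#'
#' @param expr geTMM matrix.
#' @param catalog Gene catalog.
#' @param mag_ids MAGs to include (e.g. confirmed methanogens).
#' @param groups Pathway grouping (default [pathway_groups()]).
#' @return Matrix: pathway groups x samples.
#' @export
pathway_expression_summary <- function(expr, catalog, mag_ids,
                                       groups = pathway_groups()) {
  sub_cat <- catalog[catalog$mag_id %in% mag_ids, , drop = FALSE]
  ann <- gene_annotations(sub_cat)
  out <- matrix(0, nrow = length(groups), ncol = ncol(expr),
                dimnames = list(names(groups), colnames(expr)))
  for (gname in names(groups)) {
    hit <- vapply(ann, function(v) any(v %in% groups[[gname]]), logical(1))
    genes <- intersect(sub_cat$gene_id[hit], rownames(expr))
    if (length(genes) > 0)
      out[gname, ] <- colSums(expr[genes, , drop = FALSE])
  }
  out
}
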