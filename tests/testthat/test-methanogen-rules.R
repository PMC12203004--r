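fixture <- gen_methanogen_fixture(seed = 1)

test_that("substrate potential follows the marker-system rules", {
  pot <- call_potential(fixture$catalog, fixture$taxonomy)
  p <- function(m) pot[pot$mag_id == m, ]
  ## WL + Mtr + hydrogenase -> hydrogenotrophic
  expect_true(p("MAG_hydro")$hydrogenotrophic)
  expect_false(p("MAG_hydro")$acetoclastic)
  ## Methanosarcinia + ACS/CODH + ack/pta -> acetoclastic
  expect_true(p("MAG_aceto")$acetoclastic)
  ## mtxB + partner -> methylotrophic
  expect_true(p("MAG_methylo")$methylotrophic)
  ## multiple pathways -> multifunctional
  expect_true(p("MAG_multi")$multifunctional)
  ## missing Mcr/Hdr -> not a methanogen, no exception
  expect_false(p("MAG_not_methanogen")$is_methanogen)
  expect_equal(p("MAG_not_methanogen")$potential, "")
  ## confirmed methanogen with no substrate rule: empty potential
  expect_true(p("MAG_mcr_only")$is_methanogen)
  expect_equal(p("MAG_mcr_only")$potential, "")
})

test_that("taxonomy guard blocks acetoclastic potential outside Methanosarcinia", {
  cat2 <- fixture$catalog
  tax2 <- fixture$taxonomy
  tax2$class[tax2$mag_id == "MAG_aceto"] <- "Clostridia"
  pot <- call_potential(cat2, tax2)
  expect_false(pot$acetoclastic[pot$mag_id == "MAG_aceto"])
})

test_that("active pathway calls follow the expression rules per sample", {
  pot <- call_potential(fixture$catalog, fixture$taxonomy)
  act <- call_active(fixture$expr, fixture$catalog, fixture$taxonomy, pot)
  a <- function(m) act$active[act$mag_id == m &
                              act$sample_id == "una_d14_r1"]
  ## 1 WL gene + 1 hydrogenase expressed -> hydrogenotrophic
  expect_equal(a("MAG_hydro"), "hydrogenotrophic")
  ## ack alone expressed -> acetoclastic
  expect_equal(a("MAG_aceto"), "acetoclastic")
  ## mtxB expressed -> methylotrophic
  expect_equal(a("MAG_methylo"), "methylotrophic")
  ## mcrA alone: active but not classifiable -> ignored
  expect_equal(a("MAG_mcr_only"), "ignored")
  ## no methanogenesis genes expressed at all -> ignored
  e0 <- fixture$expr
  e0[fixture$catalog$gene_id[fixture$catalog$mag_id == "MAG_hydro"], ] <- 0
  act0 <- call_active(e0, fixture$catalog, fixture$taxonomy, pot)
  expect_equal(act0$active[act0$mag_id == "MAG_hydro" &
                           act0$sample_id == "una_d14_r1"], "ignored")
})

test_that("the Methanotrichales obligate-acetoclast override is absolute", {
  pot <- call_potential(fixture$catalog, fixture$taxonomy)
  ## the fixture Methanotrichales MAG expresses both acs and mtaB, yet
  ## must be called acetoclastic only
  act <- call_active(fixture$expr, fixture$catalog, fixture$taxonomy, pot)
  expect_equal(unique(act$active[act$mag_id == "MAG_methanothrix"]),
               "acetoclastic")
  ## even with every methyltransferase gene expressed at high level
  e2 <- fixture$expr
  mtx_genes <- fixture$catalog$gene_id[
    fixture$catalog$mag_id == "MAG_methanothrix"]
  e2[mtx_genes, ] <- 99
  act2 <- call_active(e2, fixture$catalog, fixture$taxonomy, pot)
  expect_equal(unique(act2$active[act2$mag_id == "MAG_methanothrix"]),
               "acetoclastic")
})

test_that("adding expressed genes never removes a satisfied label", {
  pot <- call_potential(fixture$catalog, fixture$taxonomy)
  act1 <- call_active(fixture$expr, fixture$catalog, fixture$taxonomy, pot)
  e2 <- fixture$expr
  e2[e2 == 0] <- 7  # express everything
  act2 <- call_active(e2, fixture$catalog, fixture$taxonomy, pot)
  for (m in unique(act1$mag_id)) {
    if (m == "MAG_methanothrix") next  # obligate override, fixed label
    before <- act1$active[act1$mag_id == m & act1$sample_id == "una_d14_r1"]
    after <- act2$active[act2$mag_id == m & act2$sample_id == "una_d14_r1"]
    if (before == "ignored") next
    for (lab in strsplit(before, "+", fixed = TRUE)[[1]])
      expect_match(after, lab, fixed = TRUE)
  }
})

test_that("the generic rule engine evaluates boolean expressions", {
  sets <- list(set1 = "K00001", set2 = c("K00002", "K00003"))
  cat <- data.frame(gene_id = c("g1", "g2"), mag_id = "M1",
                    length_bp = 1000, ko_id = c("K00001", "K00009"),
                    cazy_best_hit = NA, camper_id = NA)
  expr <- matrix(c(5, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tax <- data.frame(mag_id = "M1", class = "Clostridia")
  rs <- rule_set(list(
    list(rule_id = "r1", label = "has_K00001",
         expr = gene_pred("set1", 1, "expressed")),
    list(rule_id = "r2", label = "guarded",
         expr = rule_and(taxon_pred("class", "Bacilli"),
                         gene_pred("set1", 1, "expressed"))),
    list(rule_id = "r3", label = "negation",
         expr = rule_not(gene_pred("set2", 1, "present")))), sets)
  res <- evaluate_ruleset(cat, expr, rs, tax)
  expect_true(res$satisfied[res$rule_id == "r1"])
  ## failing taxonomy guard blocks the rule regardless of genes
  expect_false(res$satisfied[res$rule_id == "r2"])
  expect_true(res$satisfied[res$rule_id == "r3"])
  ## malformed expression fails naming the rule
  rs_bad <- rule_set(list(list(rule_id = "rX", label = "bad",
                               expr = list(type = "xor"))), sets)
  expect_error(evaluate_ruleset(cat, expr, rs_bad), "rX")
})

test_that("rule evaluation is order-independent and deterministic", {
  sets <- list(a = "K1", b = "K2")
  cat <- data.frame(gene_id = c("g1", "g2"), mag_id = "M1",
                    length_bp = 1000, ko_id = c("K1", "K2"),
                    cazy_best_hit = NA, camper_id = NA)
  rules <- list(
    list(rule_id = "p", label = "A",
         expr = gene_pred("a", 1, "present")),
    list(rule_id = "q", label = "B",
         expr = gene_pred("b", 1, "present")))
  r1 <- evaluate_ruleset(cat, NULL, rule_set(rules, sets))
  r2 <- evaluate_ruleset(cat, NULL, rule_set(rev(rules), sets))
  m1 <- setNames(r1$satisfied, r1$rule_id)
  expect_equal(m1[sort(names(m1))],
               setNames(r2$satisfied, r2$rule_id)[sort(names(m1))])
})

test_that("potential rules in the generic grammar match call_potential", {
  rules <- methanogen_potential_rules()
  res <- evaluate_ruleset(fixture$catalog, NULL, rules, fixture$taxonomy)
  pot <- call_potential(fixture$catalog, fixture$taxonomy)
  for (m in pot$mag_id[pot$is_methanogen]) {
    grid <- res[res$mag_id == m, ]
    expect_equal(grid$satisfied[grid$rule_id == "pot_h2"],
                 pot$hydrogenotrophic[pot$mag_id == m], label = m)
    expect_equal(grid$satisfied[grid$rule_id == "pot_ac"],
                 pot$acetoclastic[pot$mag_id == m], label = m)
    expect_equal(grid$satisfied[grid$rule_id == "pot_me"],
                 pot$methylotrophic[pot$mag_id == m], label = m)
  }
})

test_that("pathway expression sums match a group-by oracle", {
  fx <- fixture
  pot <- call_potential(fx$catalog, fx$taxonomy)
  mags <- pot$mag_id[pot$is_methanogen]
  ps <- pathway_expression_summary(fx$expr, fx$catalog, mags)
  ## independent oracle: explicit loop over genes and groups
  groups <- pathway_groups()
  for (g in names(groups)) {
    for (s in colnames(fx$expr)) {
      tot <- 0
      for (i in seq_len(nrow(fx$catalog))) {
        row <- fx$catalog[i, ]
        if (!(row$mag_id %in% mags)) next
        if (!is.na(row$ko_id) && row$ko_id %in% groups[[g]])
          tot <- tot + fx$expr[row$gene_id, s]
      }
      expect_equal(ps[g, s], tot)
    }
  }
  ## all-zero expression gives all-zero totals
  e0 <- fx$expr * 0
  expect_true(all(pathway_expression_summary(e0, fx$catalog, mags) == 0))
})
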