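make_expr <- function(presence_u, presence_c, genes, reps = 2, day = 14) {
  ## build a tiny expression matrix + tables from per-treatment
  ## presence vectors (logical, per gene)
  samples <- expand.grid(replicate = paste0("r", seq_len(reps)),
                         treatment = c("unamended", "catechin"),
                         day = day, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s", substr(samples$treatment, 1, 3),
                               samples$replicate)
  samples <- samples[, c("sample_id", "treatment", "day", "replicate")]
  e <- matrix(0, length(genes), nrow(samples),
              dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    pres <- if (samples$treatment[j] == "unamended") presence_u else presence_c
    e[pres, j] <- 5
  }
  list(expr = e, samples = samples,
       catalog = data.frame(gene_id = genes, mag_id = "M1",
                            length_bp = 1000))
}

test_that("presence pattern partitions expressed genes across treatments", {
  g <- sprintf("g%02d", 1:10)
  fx <- make_expr(rep(TRUE, 10), rep(TRUE, 10), g)
  p <- presence_pattern(fx$expr, fx$catalog, fx$samples, "M1", 14)
  expect_equal(c(p$n_both, p$n_unamended_only, p$n_catechin_only),
               c(10, 0, 0))
  fx <- make_expr(c(rep(TRUE, 8), rep(FALSE, 2)),
                  c(rep(TRUE, 2), rep(FALSE, 6), TRUE, TRUE), g)
  p <- presence_pattern(fx$expr, fx$catalog, fx$samples, "M1", 14)
  expect_equal(c(p$n_both, p$n_unamended_only, p$n_catechin_only),
               c(2, 6, 2))
})

test_that("union presence rule counts a gene expressed in one replicate", {
  g <- sprintf("g%02d", 1:4)
  fx <- make_expr(rep(TRUE, 4), rep(FALSE, 4), g, reps = 3)
  ## g1 on in exactly one catechin replicate
  fx$expr["g01", "cat_r2"] <- 5
  p <- presence_pattern(fx$expr, fx$catalog, fx$samples, "M1", 14,
                        presence_rule = "union")
  expect_equal(p$n_both, 1)
  expect_equal(p$n_unamended_only, 3)
  p_all <- presence_pattern(fx$expr, fx$catalog, fx$samples, "M1", 14,
                            presence_rule = "all")
  expect_equal(p_all$n_both, 0)
})

test_that("response metrics follow the percentage definitions", {
  m <- response_metrics(list(n_both = 2, n_unamended_only = 6,
                             n_catechin_only = 2))
  expect_equal(unname(m), c(20, 40))
  m <- response_metrics(list(n_both = 10, n_unamended_only = 0,
                             n_catechin_only = 0))
  expect_equal(unname(m), c(100, 0))
  m <- response_metrics(list(n_both = 0, n_unamended_only = 0,
                             n_catechin_only = 8))
  expect_equal(unname(m), c(0, -100))
  expect_error(response_metrics(list(n_both = 0, n_unamended_only = 0,
                                     n_catechin_only = 0)), "undefined")
})

test_that("the six categories are assigned per the threshold rules", {
  expect_equal(classify_response(40, 0), "resistant")
  expect_equal(classify_response(10, 0), "responsive")
  expect_equal(classify_response(10, 40), "sensitive")
  expect_equal(classify_response(10, -40), "stimulated")
  expect_equal(classify_response(30, 30), "lost_function")
  expect_equal(classify_response(30, -30), "gained_function")
  ## boundary precedence: the extreme categories win ties
  expect_equal(classify_response(26, 25), "lost_function")
  expect_equal(classify_response(26, -25), "gained_function")
  expect_equal(classify_response(20, 25), "sensitive")
  expect_equal(classify_response(26, 24.9), "resistant")
})

test_that("threshold regions tile the metric space exactly once", {
  ## independent region definitions straight from the inequalities
  raw_regions <- function(pb, du, bt = 26, ut = 25) {
    c(resistant = pb >= bt && abs(du) <= ut,
      responsive = pb < bt && abs(du) <= ut,
      sensitive = pb < bt && du >= ut,
      stimulated = pb < bt && du <= -ut,
      lost_function = pb >= bt && du >= ut,
      gained_function = pb >= bt && du <= -ut)
  }
  for (pb in seq(0, 100, by = 2.5)) {
    for (du in seq(-100, 100, by = 2.5)) {
      hits <- raw_regions(pb, du)
      got <- classify_response(pb, du)
      expect_true(hits[[got]])          # label satisfies its inequalities
      expect_gte(sum(hits), 1)          # full coverage
      if (sum(hits) > 1)                # overlaps resolve to the extreme
        expect_true(got %in% c("sensitive", "stimulated",
                               "lost_function", "gained_function"))
    }
  }
})

test_that("swapping treatment labels mirrors the signed categories", {
  for (case in list(c(10, 40), c(10, -40), c(30, 30), c(30, -30),
                    c(40, 0), c(10, 0))) {
    a <- classify_response(case[1], case[2])
    b <- classify_response(case[1], -case[2])
    map <- c(sensitive = "stimulated", stimulated = "sensitive",
             lost_function = "gained_function",
             gained_function = "lost_function",
             resistant = "resistant", responsive = "responsive")
    expect_equal(b, unname(map[a]))
  }
})

test_that("classification depends only on the zero pattern", {
  g <- sprintf("g%02d", 1:10)
  fx <- make_expr(rep(TRUE, 10), c(rep(TRUE, 3), rep(FALSE, 7)), g)
  p1 <- presence_pattern(fx$expr, fx$catalog, fx$samples, "M1", 14)
  scaled <- fx$expr * 137.5
  p2 <- presence_pattern(scaled, fx$catalog, fx$samples, "M1", 14)
  expect_equal(unclass(p1), unclass(p2))
})

test_that("classify_all recovers planted categories and reports inactives", {
  ds <- gen_expression_dataset(simulation_design(n_mags = 12, seed = 5))
  res <- normalize_expression(ds$counts, ds$catalog)
  cl <- classify_all(res$expr, ds$catalog, ds$samples)
  key <- paste(cl$records$mag_id, cl$records$day)
  truth_cat <- ds$truth$category[match(key, paste(ds$truth$mag_id,
                                                  ds$truth$day))]
  expect_equal(cl$records$category, truth_cat)
  ## per-day proportions sum to one over classified MAGs
  sums <- tapply(cl$proportions$proportion, cl$proportions$day, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("classification requires both treatments", {
  g <- sprintf("g%02d", 1:5)
  fx <- make_expr(rep(TRUE, 5), rep(TRUE, 5), g)
  one_trt <- fx$samples[fx$samples$treatment == "unamended", ]
  expect_error(classify_all(fx$expr[, one_trt$sample_id], fx$catalog,
                            one_trt), "both treatments")
})

test_that("identical expression across treatments classifies all MAGs resistant", {
  g <- sprintf("g%02d", 1:20)
  fx <- make_expr(rep(TRUE, 20), rep(TRUE, 20), g)
  cl <- classify_all(fx$expr, fx$catalog, fx$samples)
  expect_true(all(cl$records$category == "resistant"))
})
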