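test_that("level summaries conserve column sums and report coverage", {
  cat <- data.frame(gene_id = c("g1", "g2", "g3"), mag_id = "M1",
                    length_bp = 1000,
                    ko_id = c("K1", "K1", NA),
                    cazy_best_hit = c(NA, "GH5", NA),
                    camper_id = NA_character_)
  e <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  lv <- level_summaries(e, cat)
  expect_equal(unname(lv$mag["M1", ]), unname(colSums(e)))
  ## annotation level: K1 = g1+g2, GH5 = g2; g3 unannotated
  expect_equal(unname(lv$annotation["K1", "s1"]), 3)
  expect_equal(unname(lv$annotation["GH5", "s1"]), 2)
  expect_false("g3" %in% rownames(lv$annotation))
  expect_equal(lv$coverage$n_unannotated, 1)
})

test_that("level summaries match a brute-force group-by oracle", {
  counts <- random_counts(60, 5, seed = 31)
  catal <- random_catalog(counts, seed = 31, n_mags = 6)
  e <- getmm(counts, catal)
  lv <- level_summaries(e, catal)
  for (m in unique(catal$mag_id)) {
    genes <- catal$gene_id[catal$mag_id == m]
    expect_equal(lv$mag[m, ], colSums(e[genes, , drop = FALSE]))
  }
  for (k in sample(rownames(lv$annotation), 5)) {
    genes <- catal$gene_id[!is.na(catal$ko_id) & catal$ko_id == k]
    expect_equal(lv$annotation[k, ], colSums(e[genes, , drop = FALSE]))
  }
})

test_that("bray-curtis matches the hand example and metric properties", {
  a <- matrix(c(2, 0, 1, 1, 1, 0), nrow = 3,
              dimnames = list(NULL, c("x", "y")))
  d <- bray_curtis(a)
  expect_equal(d["x", "y"], 0.6)
  ## identical columns -> 0; disjoint supports -> 1
  b <- matrix(c(1, 2, 3, 1, 2, 3, 0, 0, 5), nrow = 3,
              dimnames = list(NULL, c("p", "q", "r")))
  b2 <- cbind(b, z = c(4, 0, 0) * 0)
  d2 <- bray_curtis(b)
  expect_equal(d2["p", "q"], 0)
  disj <- matrix(c(1, 2, 0, 0, 0, 0, 3, 4), nrow = 4,
                 dimnames = list(NULL, c("u", "v")))
  expect_equal(bray_curtis(disj)["u", "v"], 1)
  ## symmetry, zero diagonal, range, and formula agreement
  set.seed(19)
  m <- matrix(runif(40, 0, 10), nrow = 8,
              dimnames = list(NULL, paste0("s", 1:5)))
  dm <- bray_curtis(m)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dm[i, j], oracle_bray_curtis(m[, i], m[, j]))
  ## two all-zero samples: undefined distance
  zz <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("between-treatment distances enumerate exactly the cross pairs", {
  samples <- data.frame(
    sample_id = c("u1", "u2", "c1", "c2"),
    treatment = c("unamended", "unamended", "catechin", "catechin"),
    day = 7, replicate = c("r1", "r2", "r1", "r2"))
  set.seed(2)
  m <- matrix(runif(20, 1, 5), nrow = 5,
              dimnames = list(NULL, samples$sample_id))
  d <- bray_curtis(m)
  bt <- between_treatment_distances(d, samples, 7)
  expect_equal(nrow(bt), 4)  # 2 x 2 cross pairs
  ## brute-force enumeration oracle
  expected <- c()
  for (u in c("u1", "u2")) for (cc in c("c1", "c2"))
    expected <- c(expected, d[u, cc])
  expect_equal(sort(bt$distance), sort(expected))
  ## 1 vs 1 gives a single distance; missing treatment skips
  s1 <- samples[c(1, 3), ]
  expect_equal(nrow(between_treatment_distances(d, s1, 7)), 1)
  s2 <- samples[1:2, ]
  expect_message(res <- between_treatment_distances(d, s2, 7), "missing")
  expect_null(res)
  ## matched mode keeps only same-replicate pairs
  btm <- between_treatment_distances(d, samples, 7, matched = TRUE)
  expect_equal(nrow(btm), 2)
})

test_that("kruskal-wallis and dunn agree with exact rank computations", {
  v <- c(1, 2, 3, 101, 102, 103, 201, 202, 203)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn_bh(v, g)
  ## exact H for untied ranks: 12/(N(N+1)) * sum n_i rbar_i^2 - 3(N+1)
  r <- rank(v)
  H <- 12 / (9 * 10) * sum(3 * tapply(r, g, mean)^2) - 3 * 10
  expect_equal(unname(res$kruskal$statistic), H)
  expect_lt(res$kruskal$p.value, 0.05)
  expect_equal(unname(res$kruskal$statistic), 7.2)
  ## dunn z from pooled ranks, no ties: se = sqrt(N(N+1)/12 * 2/3)
  se <- sqrt(9 * 10 / 12 * (1 / 3 + 1 / 3))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(res$dunn$z[res$dunn$group1 == "a" &
                          res$dunn$group2 == "b"], z_ab)
  expect_equal(res$dunn$p, 2 * pnorm(-abs(res$dunn$z)))
  expect_equal(res$dunn$p_adj, oracle_bh(res$dunn$p))
  ## identical groups: p in the null region
  res2 <- kruskal_dunn_bh(rep(c(5, 6, 7), 2), rep(c("a", "b"), each = 3))
  expect_gt(res2$kruskal$p.value, 0.9)
})

test_that("dunn applies the tie correction", {
  v <- c(1, 1, 2, 2, 3, 3, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn_bh(v, g)
  r <- rank(v)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (9 - 1))
  se <- sqrt((9 * 10 / 12 - tie_term) * (1 / 3 + 1 / 3))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(res$dunn$z[1], z_ab)
})

test_that("permanova detects planted separation and matches adonis2", {
  set.seed(4)
  n_feat <- 20
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:12),
    treatment = rep(c("unamended", "catechin"), each = 6),
    day = rep(c(7, 14), times = 6),
    replicate = paste0("r", 1:12))
  m <- matrix(rlnorm(n_feat * 12), nrow = n_feat,
              dimnames = list(NULL, samples$sample_id))
  m[1:10, samples$treatment == "catechin"] <-
    m[1:10, samples$treatment == "catechin"] * 8
  d <- bray_curtis(m)
  res <- permanova(d, samples, factors = "treatment", n_perm = 199,
                   seed = 1)
  ## strong planted separation: p at or near the permutation minimum
  ## (a free permutation can reproduce the observed 6/6 split)
  expect_lte(res$p[1], 2 / 200)
  ## pseudo-F agrees with vegan's adonis2 on the same distances
  ref <- vegan::adonis2(as.dist(d) ~ treatment,
                        data = samples, permutations = 99)
  expect_equal(res$f[1], ref$F[1], tolerance = 1e-10)
  expect_equal(res$ss[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
  ## two sequential factors
  res2 <- permanova(d, samples, factors = c("treatment", "day"),
                    n_perm = 99, seed = 1)
  ref2 <- vegan::adonis2(as.dist(d) ~ treatment + factor(day),
                         data = samples, permutations = 99, by = "terms")
  expect_equal(res2$f[1:2], ref2$F[1:2], tolerance = 1e-10)
  expect_equal(res2$df[1:3], ref2$Df[1:3])
})

test_that("permanova p is invariant to a consistent relabelling", {
  set.seed(9)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    treatment = rep(c("unamended", "catechin"), each = 5),
    day = 7, replicate = paste0("r", 1:10))
  m <- matrix(rlnorm(15 * 10), nrow = 15,
              dimnames = list(NULL, samples$sample_id))
  d <- bray_curtis(m)
  res1 <- permanova(d, samples, "treatment", n_perm = 199, seed = 5)
  pp <- sample(10)
  d2 <- d[pp, pp]
  res2 <- permanova(d2, samples, "treatment", n_perm = 199, seed = 5)
  expect_equal(res2$f[1], res1$f[1])
  expect_equal(res2$p[1], res1$p[1])
})

test_that("degenerate permanova inputs fail loudly", {
  samples <- data.frame(sample_id = c("a", "b", "c"),
                        treatment = c("unamended", "catechin", "catechin"),
                        day = 7, replicate = c("r1", "r2", "r3"))
  d <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
              dimnames = list(samples$sample_id, samples$sample_id))
  expect_error(permanova(d, samples, "treatment"), "single sample")
})
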