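feat <- function(id, mz, rt, intensities, formula = NA_character_) {
  cbind(data.frame(feature_id = id, mz = mz, rt = rt, formula = formula,
                   stringsAsFactors = FALSE),
        as.data.frame(matrix(intensities, nrow = length(id), byrow = TRUE,
                             dimnames = list(NULL,
                               paste0("I", seq_len(length(intensities) /
                                                     length(id)))))))
}

test_that("rt binning chains features within the tolerance", {
  f <- feat(c("a", "b", "c"), c(100, 200, 300),
            c(10.000, 10.004, 10.020), rep(1, 9))
  bins <- bin_by_rt(f, 0.005)
  expect_equal(bins[1], bins[2])
  expect_false(bins[3] == bins[1])
  ## all identical rts -> one bin
  f2 <- feat(c("a", "b", "c"), c(1, 2, 3), rep(5, 3), rep(1, 9))
  expect_equal(length(unique(bin_by_rt(f2, 0.005))), 1)
  ## order independence
  f3 <- f[c(3, 1, 2), ]
  b3 <- bin_by_rt(f3, 0.005)
  expect_equal(b3[2], b3[3])
  expect_false(b3[1] == b3[2])
})

test_that("rt bins equal the brute-force transitive-closure oracle", {
  set.seed(17)
  for (rep in 1:10) {
    rt <- sort(runif(30, 0, 1)) * 0.05
    rt <- sample(rt)
    f <- feat(sprintf("f%02d", 1:30), runif(30, 100, 500), rt,
              rep(1, 30 * 3))
    bins <- bin_by_rt(f, 0.005)
    oracle <- oracle_rt_bins(rt, 0.005)
    ## same partition: bin labels co-classify identical pairs
    for (i in 1:29) for (j in (i + 1):30)
      expect_equal(bins[i] == bins[j], oracle[i] == oracle[j])
  }
})

test_that("correlated pairs use Pearson r with the heavier ion as parent", {
  parent_i <- c(10, 200, 3000, 40, 500, 60)
  f <- feat(c("p", "f"), c(400, 200), c(10, 10),
            c(parent_i, 0.5 * parent_i))
  pairs <- correlated_pairs(f, 0.98)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$parent_id, "p")
  expect_equal(pairs$fragment_id, "f")
  expect_equal(pairs$r, 1)
  ## orthogonal patterns are not candidates
  f2 <- feat(c("p", "q"), c(400, 200), c(10, 10),
             c(1, 2, 3, 4, 5, 6, 6, 5, 4, 3, 2, 1))
  expect_equal(nrow(correlated_pairs(f2, 0.98)), 0)
  ## r matches the textbook formula on random vectors
  set.seed(3)
  for (rep in 1:5) {
    x <- runif(8); y <- 0.9 * x + runif(8, 0, 0.01)
    f3 <- feat(c("a", "b"), c(300, 100), c(5, 5), c(x, y))
    r_formula <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    got <- correlated_pairs(f3, 0)
    expect_equal(got$r, r_formula)
  }
})

test_that("zero-variance intensity vectors are skipped with a notice", {
  f <- feat(c("p", "z"), c(400, 200), c(10, 10),
            c(1, 2, 3, 4, 7, 7, 7, 7))
  pairs <- correlated_pairs(f, 0.98)
  expect_equal(nrow(pairs), 0)
  expect_equal(attr(pairs, "skipped")$reason,
               "zero-variance intensity vector")
})

test_that("MS2 confirmation applies a strict ppm bound", {
  spec <- cbind(mz = c(200.0005, 150.1), intensity = c(10, 5))
  expect_true(confirm_in_ms2(200.0000, spec, 5)$confirmed)   # 2.5 ppm
  spec2 <- cbind(mz = 200.0020, intensity = 10)
  expect_false(confirm_in_ms2(200.0000, spec2, 5)$confirmed) # 10 ppm
  expect_false(confirm_in_ms2(200, NULL, 5)$confirmed)       # no MS2
})

test_that("confirmed fragments are removed, parents and bystanders kept", {
  parent_i <- c(10, 200, 3000, 40, 500, 60)
  f <- rbind(feat("p", 400, 10.000, parent_i),
             feat("f", 200, 10.002, 0.5 * parent_i),
             feat("q", 300, 10.003, c(5, 5, 6, 80, 2, 9)))
  spectra <- list(p = cbind(mz = 200.0002, intensity = 100))
  res <- remove_artifacts(f, spectra)
  expect_equal(sort(res$features$feature_id), c("p", "q"))
  lg <- res$log[res$log$removed, ]
  expect_equal(lg$fragment_id, "f")
  expect_equal(lg$parent_id, "p")
  expect_true(lg$ppm < 5)
  ## co-eluting but uncorrelated pair: both kept
  f2 <- rbind(feat("p", 400, 10.000, parent_i),
              feat("q", 300, 10.003, c(5, 5, 6, 80, 2, 9)))
  res2 <- remove_artifacts(f2, spectra)
  expect_equal(nrow(res2$features), 2)
  ## correlated but unconfirmed candidate is kept and logged
  f3 <- rbind(feat("p", 400, 10.000, parent_i),
              feat("g", 250, 10.001, 0.3 * parent_i))
  res3 <- remove_artifacts(f3, spectra)
  expect_equal(nrow(res3$features), 2)
  expect_false(res3$log$removed)
  ## empty table passes through
  res0 <- remove_artifacts(f[0, ], spectra)
  expect_equal(nrow(res0$features), 0)
})

test_that("halogenated compositions are dropped, missing formulas kept", {
  f <- rbind(feat("a", 100, 1, rep(1, 6), "C6H5Cl"),
             feat("b", 110, 2, rep(1, 6), "C6H6O3"),
             feat("c", 120, 3, rep(1, 6), NA_character_),
             feat("d", 130, 4, rep(1, 6), "C10H8BrF"))
  out <- drop_halogens(f)
  expect_equal(out$feature_id, c("b", "c"))
  ## unparseable formula kept with a warning
  f2 <- feat("e", 140, 5, rep(1, 6), "??")
  expect_warning(out2 <- drop_halogens(f2), "unparseable")
  expect_equal(nrow(out2), 1)
})

test_that("the full filter has perfect recall and specificity on planted data", {
  lc <- gen_lcms_dataset(n_parents = 15, n_fragments_per_parent = 2,
                         n_independents = 30, n_halogen = 5, seed = 7)
  out <- filter_features(lc$features, lc$spectra)
  kept <- out$features$feature_id
  lab <- setNames(lc$truth$label, lc$truth$feature_id)
  expect_true(all(lab[kept] %in% c("parent", "independent")))
  expect_equal(sum(lab[kept] == "parent"), 15)
  expect_equal(sum(lab[kept] == "independent"), 30)
  expect_equal(sum(lab == "fragment"), 30)
  expect_false(any(lab[kept] == "fragment"))
  ## removal count is bounded by the candidate count
  expect_lte(sum(out$log$removed), nrow(out$log))
  ## idempotence
  out2 <- filter_features(out$features, lc$spectra)
  expect_equal(out2$features, out$features)
})
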