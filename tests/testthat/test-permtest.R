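test_that("normalized Z-score arithmetic", {
  expect_equal(normalized_zscore(10, 100), 1)
  expect_equal(normalized_zscore(3.7, 1), 3.7)
  expect_error(normalized_zscore(1, 0), ">= 1")
})

test_that("p-value adjustment matches an independent BH step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_error(adjust_pvalues(c(0.1, 0)), "0, 1")
  expect_error(adjust_pvalues(0.5, method = "nope"), "Unknown adjustment")
  set.seed(151)
  for (rep in 1:10) {
    p <- runif(sample(3:50, 1))
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_ref(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(rank(adj, ties.method = "min") <= rank(p, ties.method = "max"),
                 rep(TRUE, length(p)))  # BH preserves the p-value ordering
  }
  # holm and bonferroni are accepted and dominate BH
  p <- runif(20)
  expect_true(all(adjust_pvalues(p, "bonferroni") >= adjust_pvalues(p)))
  expect_true(all(adjust_pvalues(p, "holm") >= adjust_pvalues(p)))
})

test_that("pairwise permutation test: p-value floor, direction, metadata", {
  g <- toy_genome()
  set.seed(161)
  x <- random_toy_set(g, 40)
  pt <- quiet_permtest(x, x, g, n_perm = 200, seed = 3)
  expect_equal(pt$observed, 40)
  expect_equal(pt$p_value, 1 / 201)       # +1 pseudocount floor
  expect_equal(pt$alternative, "greater")
  expect_equal(pt$zscore, (pt$observed - pt$null_mean) / pt$null_sd)
  expect_equal(pt$norm_zscore, pt$zscore / sqrt(40))
  expect_equal(length(pt$null_sample), 200)
  expect_error(permutation_test(x, x, g, n_perm = 50), "at least 100")
  expect_warning(permutation_test(x, x, g, n_perm = 200),
                 class = "crosswiser_low_nperm")
  expect_s3_class(tidy(pt), "tbl_df")
  expect_equal(nrow(tidy(pt)), 1)
})

test_that("subsampling happens once, before randomization", {
  g <- toy_genome()
  set.seed(171)
  x <- random_toy_set(g, 60)
  pt <- quiet_permtest(x, x, g, n_perm = 150, seed = 4, subsample = 25)
  expect_equal(pt$n_regions, 25)
  expect_lte(pt$observed, 25)
  expect_equal(pt$norm_zscore, pt$zscore / sqrt(25))
})

test_that("a 1x1 crosswise cell is bit-identical to the pairwise test", {
  g <- toy_genome()
  set.seed(181)
  x <- random_toy_set(g, 30)
  y <- random_toy_set(g, 30)
  cw <- suppressWarnings(
    crosswise_permtest(list(a = x), list(b = y), g, n_perm = 300, seed = 17)
  )
  pt <- quiet_permtest(x, y, g, n_perm = 300, seed = child_seed(17, 1))
  cell <- tidy(cw)
  expect_identical(cell$observed, pt$observed)
  expect_identical(cell$null_mean, pt$null_mean)
  expect_identical(cell$null_sd, pt$null_sd)
  expect_identical(cell$zscore, pt$zscore)
  expect_identical(cell$p_value, pt$p_value)
  expect_identical(unname(cw$null_samples[["a"]][, "b"]), pt$null_sample)
})

test_that("crosswise results are deterministic and invariant to RS2 order", {
  g <- toy_genome()
  set.seed(191)
  sets <- setNames(lapply(1:4, function(i) random_toy_set(g, 25)),
                   paste0("s", 1:4))
  cw1 <- suppressWarnings(crosswise_permtest(sets, sets, g, n_perm = 200,
                                             seed = 5))
  cw2 <- suppressWarnings(crosswise_permtest(sets, rev(sets), g, n_perm = 200,
                                             seed = 5))
  t1 <- dplyr::arrange(tidy(cw1), rs1, rs2)
  t2 <- dplyr::arrange(tidy(cw2), rs1, rs2)
  expect_equal(t1, t2)
  cw3 <- suppressWarnings(crosswise_permtest(sets, sets, g, n_perm = 200,
                                             seed = 5))
  expect_equal(tidy(cw1), tidy(cw3))

  expect_true(all(tidy(cw1)$adj_p_value >= tidy(cw1)$p_value))
  expect_error(crosswise_permtest(setNames(sets, c("a", "a", "b", "c")),
                                  sets, g, n_perm = 200),
               "unique")
  expect_error(crosswise_permtest(unname(sets), sets, g, n_perm = 200),
               "named")
})

test_that("row-scoped adjustment adjusts within each RS1 row", {
  g <- toy_genome()
  set.seed(201)
  sets <- setNames(lapply(1:3, function(i) random_toy_set(g, 20)),
                   paste0("s", 1:3))
  cw <- suppressWarnings(crosswise_permtest(sets, sets, g, n_perm = 150,
                                            seed = 2, adjust_scope = "row"))
  tab <- tidy(cw)
  for (r in unique(tab$rs1)) {
    sub <- tab[tab$rs1 == r, ]
    expect_equal(sub$adj_p_value, adjust_pvalues(sub$p_value))
  }
})

test_that("filter_top_regions implements the upper-quartile-then-sample rule", {
  g <- toy_genome()
  set.seed(211)
  x <- random_toy_set(g, 400)
  x$score <- runif(400)
  # quartile has 100 regions; asking for 150 returns all 100 with a warning
  expect_warning(out <- filter_top_regions(x, 150), "100 regions")
  expect_equal(nrow(out), 100)
  expect_true(all(out$score >= sort(x$score, decreasing = TRUE)[100]))
  # sampled subset of the quartile
  set.seed(1)
  out2 <- filter_top_regions(x, 50)
  expect_equal(nrow(out2), 50)
  expect_true(all(region_keys(out2) %in% region_keys(out)))
  # ties broken by canonical order: uniform scores keep the first quarter
  x$score <- rep(1, 400)
  expect_equal(filter_top_regions(x, 100), x[1:100, ])
  expect_error(filter_top_regions(x[, 1:3], 10), "score")
  expect_error(filter_top_regions(x, 500), "exceeds")
})

test_that("crosswise results round-trip through TSV + JSON header", {
  g <- toy_genome()
  set.seed(221)
  sets <- setNames(lapply(1:2, function(i) random_toy_set(g, 20)),
                   c("u", "v"))
  cw <- suppressWarnings(crosswise_permtest(sets, sets, g, n_perm = 120,
                                            seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_crosswise(cw, path)
  expect_equal(length(readLines(path)), 1 + 1 + 4)  # header + colnames + cells
  back <- read_crosswise(path)
  expect_equal(back$table, cw$table)
  expect_equal(back$parameters$n_perm, cw$parameters$n_perm)
  expect_equal(back$parameters$randomization, cw$parameters$randomization)
  expect_equal(glance(back)$n_rs1, 2)

  # schema violations are named
  broken <- readLines(path)
  broken[2] <- gsub("zscore", "zzz", broken[2])
  writeLines(broken, path)
  expect_error(read_crosswise(path), "zscore")
})
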