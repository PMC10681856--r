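# build a crosswise_result by hand so matrix logic is tested in isolation
fake_crosswise <- function(vals, adj_p, zs = vals * sqrt(100)) {
  rs1 <- rownames(vals); rs2 <- colnames(vals)
  rs1_col <- rep(rs1, each = length(rs2))
  rs2_col <- rep(rs2, length(rs1))
  tab <- tibble::tibble(
    rs1 = rs1_col, rs2 = rs2_col,
    observed = as.vector(t(vals)), null_mean = 0, null_sd = 1,
    zscore = as.vector(t(zs)), norm_zscore = as.vector(t(vals)),
    p_value = pmin(as.vector(t(adj_p)), 1), alternative = "greater",
    n_regions = 100, adj_p_value = as.vector(t(adj_p)))
  structure(list(table = tab, rs1_names = rs1, rs2_names = rs2,
                 null_samples = NULL,
                 parameters = list(n_perm = 100, randomization = "x",
                                   evaluation = "y", adjust_method = "BH",
                                   adjust_scope = "global", seed = 1),
                 created = "now"),
            class = "crosswise_result")
}

test_that("make_matrix assembles values and applies the zeroing rule", {
  v <- matrix(c(5, 0.2, 0.3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  ap <- matrix(c(0.001, 0.5, 0.2, 0.01), 2, 2)
  cw <- fake_crosswise(v, ap)
  m <- make_matrix(cw)
  expect_equal(m$values, v)
  expect_equal(m$mask, ap <= 0.05, ignore_attr = TRUE)
  mz <- make_matrix(cw, zero_nonsig = TRUE, alpha = 0.05)
  expect_equal(mz$values[1, 2], 0)
  expect_equal(mz$values[2, 1], 0)
  expect_equal(mz$values[1, 1], 5)
  # every non-significant cell is exactly zero
  expect_true(all(mz$values[!mz$mask] == 0))
  # undefined Z-scores render as zero with an unset mask
  v2 <- v; v2[1, 1] <- NA
  cw2 <- fake_crosswise(v2, ap)
  m2 <- make_matrix(cw2)
  expect_equal(m2$values[1, 1], 0)
  expect_false(m2$mask[1, 1])
  expect_error(make_matrix(cw, stat = "other"), "arg")
  # 1x1 matrix
  m11 <- make_matrix(fake_crosswise(v[1, 1, drop = FALSE],
                                    ap[1, 1, drop = FALSE]))
  expect_equal(unname(m11$values), matrix(5))
})

test_that("clustering orders identical rows together and splits planted blocks", {
  set.seed(281)
  # planted 2-block structure with noise
  blk <- rbind(matrix(rnorm(5 * 6, mean = 5), 5, 6),
               matrix(rnorm(5 * 6, mean = -5), 5, 6))
  rownames(blk) <- paste0("r", 1:10); colnames(blk) <- paste0("c", 1:6)
  cw <- fake_crosswise(blk, matrix(0.01, 10, 6))
  m <- cluster_matrix(make_matrix(cw))
  ord <- m$row_order
  grp <- rep(1:2, each = 5)[ord]
  expect_equal(length(rle(grp)$lengths), 2)  # blocks not interleaved

  # identical rows end up adjacent
  dup <- blk; dup[2, ] <- dup[1, ]
  cwd <- fake_crosswise(dup, matrix(0.01, 10, 6))
  md <- cluster_matrix(make_matrix(cwd))
  pos <- match(1:2, md$row_order)
  expect_equal(abs(diff(pos)), 1)

  # deterministic: same input, same selection and order
  m2 <- cluster_matrix(make_matrix(cw))
  expect_equal(m$row_order, m2$row_order)
  expect_equal(m$linkage_method, m2$linkage_method)

  # invariant to row permutation up to relabeling: same k=2 partition
  perm <- sample(10)
  cwp <- fake_crosswise(blk[perm, ], matrix(0.01, 10, 6))
  mp <- cluster_matrix(make_matrix(cwp))
  k1 <- cutree(m$hclust_rows, 2)
  k2 <- cutree(mp$hclust_rows, 2)[rownames(blk)]
  expect_equal(length(unique(paste(k1, k2))), 2)

  # constant matrix: warning, deterministic input order
  cwc <- fake_crosswise(matrix(1, 3, 3, dimnames = list(letters[1:3],
                                                        letters[1:3])),
                        matrix(0.01, 3, 3))
  expect_warning(expect_warning(mc <- cluster_matrix(make_matrix(cwc)),
                                "Constant"), "Constant")
  expect_equal(mc$row_order, 1:3)
})

test_that("correlation_matrix matches the textbook formula", {
  set.seed(291)
  v <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:8)))
  v[2, ] <- -v[1, ]                      # perfect anticorrelation
  cw <- fake_crosswise(v, matrix(0.01, 5, 8))
  cm <- correlation_matrix(make_matrix(cw))
  # direct formula oracle
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:5) for (j in 1:5) {
    expect_equal(cm$values[i, j], pearson(v[i, ], v[j, ]), tolerance = 1e-12)
  }
  expect_equal(cm$values[1, 2], -1)
  expect_equal(unname(diag(cm$values)), rep(1, 5))
  expect_lt(max(abs(cm$values - t(cm$values))), 1e-12)

  # zero-variance row: correlations zeroed with warning
  v[3, ] <- 2
  cwz <- fake_crosswise(v, matrix(0.01, 5, 8))
  expect_warning(cz <- correlation_matrix(make_matrix(cwz)), "Zero-variance")
  expect_equal(unname(cz$values[3, 1]), 0)
  expect_false(cz$mask[3, 1])
  expect_equal(unname(cz$values[3, 3]), 1)
})

test_that("dim_red embeds rows and labels clusters from the matrix itself", {
  set.seed(301)
  blk <- rbind(matrix(rnorm(4 * 6, mean = 6), 4, 6),
               matrix(rnorm(4 * 6, mean = 0), 4, 6),
               matrix(rnorm(4 * 6, mean = -6), 4, 6))
  rownames(blk) <- paste0("r", 1:12); colnames(blk) <- paste0("c", 1:6)
  m <- cluster_matrix(make_matrix(fake_crosswise(blk, matrix(0.01, 12, 6))))

  pca <- dim_red(m, "pca", seed = 7)
  expect_equal(nrow(pca), 12)
  expect_equal(sort(unique(as.integer(pca$cluster))), 1:3)
  # labels are identical across projection methods (they come from the matrix)
  tsne <- suppressWarnings(dim_red(m, "tsne", seed = 7))
  umap <- dim_red(m, "umap", seed = 7)
  expect_equal(tsne$cluster, pca$cluster)
  expect_equal(umap$cluster, pca$cluster)
  expect_false(isTRUE(all.equal(tsne$x, pca$x)))
  # determinism under a fixed seed
  tsne2 <- suppressWarnings(dim_red(m, "tsne", seed = 7))
  umap2 <- dim_red(m, "umap", seed = 7)
  expect_equal(tsne$x, tsne2$x)
  expect_equal(umap$x, umap2$x)
  # rank-1 matrix puts all variance on the first axis
  r1 <- outer(1:5, rep(1, 4))
  rownames(r1) <- paste0("r", 1:5); colnames(r1) <- paste0("c", 1:4)
  p1 <- suppressWarnings(dim_red(cluster_matrix(make_matrix(
    fake_crosswise(r1, matrix(0.01, 5, 4)))), "pca"))
  expect_lt(max(abs(p1$y)), 1e-8)
  expect_error(dim_red(m, "lda"), "arg")
})

test_that("plot surfaces build valid ggplot objects", {
  set.seed(311)
  v <- matrix(rnorm(4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  m <- make_matrix(fake_crosswise(v, matrix(c(0.01, 0.5, 0.5, 0.01), 2, 2)),
                   zero_nonsig = TRUE)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 4)

  g <- alien_genome()
  regA <- create_random_regions(g, 50)
  mlz <- suppressWarnings(
    multi_local_zscore(regA, list(self = regA), g, n_perm = 100,
                       window = 200, step = 100, seed = 3)
  )
  expect_s3_class(autoplot(mlz), "ggplot")
  expect_s3_class(plot_local_z(local_z_matrix(mlz)), "ggplot")
  blk <- rbind(matrix(rnorm(6, 3), 3, 2))
  rownames(blk) <- paste0("r", 1:3); colnames(blk) <- c("c1", "c2")
  emb <- dim_red(cluster_matrix(make_matrix(
    fake_crosswise(blk, matrix(0.01, 3, 2)))), "pca")
  expect_s3_class(plot_dimred(emb, label = TRUE), "ggplot")
})
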