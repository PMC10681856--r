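# Hierarchical clustering with automatic linkage selection: fit every
# standard hclust linkage and keep the one whose cophenetic distances
# correlate best with the observed distances.
.linkage_methods <- c("single", "complete", "average", "ward.D2",
                      "centroid", "median", "mcquitty")

pick_linkage <- function(mat, method = NULL) {
  d <- dist(mat)
  if (all(d == 0)) {
    warn("Constant matrix: cluster order is the input order.")
    return(list(hclust = NULL, method = NA_character_,
                cophenetic_correlation = NA_real_,
                order = seq_len(nrow(mat))))
  }
  if (!is.null(method)) {
    if (!method %in% .linkage_methods) {
      abort(paste0("Unknown linkage method '", method, "'."))
    }
    hc <- hclust(d, method = method)
    cc <- suppressWarnings(cor(d, cophenetic(hc)))
    return(list(hclust = hc, method = method, cophenetic_correlation = cc,
                order = hc$order))
  }
  fits <- lapply(.linkage_methods, function(mm) hclust(d, method = mm))
  cors <- vapply(fits, function(hc) {
    suppressWarnings(cor(d, cophenetic(hc)))
  }, numeric(1))
  if (all(is.na(cors))) cors[match("average", .linkage_methods)] <- 0
  best <- which.max(cors)
  list(hclust = fits[[best]], method = .linkage_methods[best],
       cophenetic_correlation = cors[best], order = fits[[best]]$order)
}

#' Assemble the association matrix of a crosswise result
#'
#' Builds the RS1-by-RS2 matrix of normalized Z-scores (or raw Z-scores).
#' Cells with an undefined Z-score (degenerate null, sd = 0) are rendered as
#' 0 with their significance mask unset. With `zero_nonsig = TRUE` every cell
#' whose adjusted p-value exceeds `alpha` is also set to 0, so the matrix
#' displays only associations that survive multiple-testing correction.
#'
#' @param cw A `crosswise_result`.
#' @param stat `"norm_zscore"` (default) or `"zscore"`.
#' @param zero_nonsig Zero out non-significant cells.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return An `association_matrix` object with fields `values`, `mask`
#'   (TRUE where adj p <= alpha and the Z-score is defined), `zeroed`,
#'   `stat`, `alpha`.
#' @export
make_matrix <- function(cw, stat = c("norm_zscore", "zscore"),
                        zero_nonsig = FALSE, alpha = 0.05) {
  stopifnot(inherits(cw, "crosswise_result"))
  stat <- match.arg(stat)
  tab <- cw$table
  vals <- matrix(NA_real_, length(cw$rs1_names), length(cw$rs2_names),
                 dimnames = list(cw$rs1_names, cw$rs2_names))
  mask <- matrix(FALSE, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  vals[cbind(match(tab$rs1, cw$rs1_names), match(tab$rs2, cw$rs2_names))] <-
    tab[[stat]]
  mask[cbind(match(tab$rs1, cw$rs1_names), match(tab$rs2, cw$rs2_names))] <-
    !is.na(tab[[stat]]) & tab$adj_p_value <= alpha
  vals[is.na(vals)] <- 0
  if (zero_nonsig) vals[!mask] <- 0
  structure(list(values = vals, mask = mask, zeroed = zero_nonsig,
                 stat = stat, alpha = alpha,
                 row_order = NULL, col_order = NULL,
                 linkage_method = NULL, cophenetic_correlation = NULL,
                 hclust_rows = NULL),
            class = "association_matrix")
}

#' Cluster an association matrix
#'
#' Orders rows and columns by hierarchical clustering (Euclidean distance on
#' row / column vectors). When no linkage method is given, every standard
#' `hclust` linkage is fitted and the one with the highest cophenetic
#' correlation is selected — a deterministic reading of "the most efficient
#' method". Rows and columns are clustered independently since a crosswise
#' matrix need not be symmetric.
#'
#' @param m An `association_matrix`.
#' @param method Optional linkage name from
#'   single/complete/average/ward.D2/centroid/median/mcquitty.
#' @return `m` with `row_order`, `col_order`, `linkage_method`,
#'   `cophenetic_correlation` and the row dendrogram (`hclust_rows`) filled.
#' @export
cluster_matrix <- function(m, method = NULL) {
  stopifnot(inherits(m, "association_matrix"))
  if (nrow(m$values) < 2) abort("Need at least 2 rows to cluster.")
  rows <- pick_linkage(m$values, method)
  cols <- pick_linkage(t(m$values), method)
  m$row_order <- rows$order
  m$col_order <- cols$order
  m$linkage_method <- rows$method
  m$cophenetic_correlation <- rows$cophenetic_correlation
  m$hclust_rows <- rows$hclust
  m
}

#' Pearson correlation form of an association matrix
#'
#' Replaces the association values with the Pearson correlation between every
#' pair of row profiles, exposing region sets with similar association
#' patterns even when their direct association is weak. Zero-variance rows
#' get 0 with an unset mask and a warning.
#'
#' @param m An `association_matrix` with >= 2 columns.
#' @return A symmetric `association_matrix` of correlations (unit diagonal).
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "association_matrix"))
  if (ncol(m$values) < 2) abort("Need at least 2 columns for correlations.")
  C <- suppressWarnings(cor(t(m$values)))
  mask <- !is.na(C)
  if (any(!mask)) {
    warn("Zero-variance row(s): their correlations are reported as 0.")
    C[!mask] <- 0
  }
  diag(C) <- 1
  structure(list(values = C, mask = mask, zeroed = FALSE,
                 stat = "pearson_r", alpha = m$alpha,
                 row_order = NULL, col_order = NULL,
                 linkage_method = NULL, cophenetic_correlation = NULL,
                 hclust_rows = NULL),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix (", x$stat, "): ", nrow(x$values), " x ",
      ncol(x$values), if (isTRUE(x$zeroed))
        paste0(", non-significant cells (adj p > ", x$alpha, ") zeroed"),
      "\n", sep = "")
  if (!is.null(x$linkage_method)) {
    cat("Clustered with '", x$linkage_method, "' linkage (cophenetic r = ",
        round(x$cophenetic_correlation, 3), ")\n", sep = "")
  }
  print(x$values)
  invisible(x)
}

#' @method tidy association_matrix
#' @export
tidy.association_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$values, responseName = "value",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(rs1 = "Var1", rs2 = "Var2") |>
    mutate(significant = as.vector(x$mask))
}

# ---- dimensionality reduction ----------------------------------------------

silhouette_k <- function(X, hc, kmax = 10) {
  d <- dist(X)
  ks <- 2:min(kmax, nrow(X) - 1)
  if (length(ks) == 0 || ks[1] > max(ks)) return(1L)
  scores <- vapply(ks, function(k) {
    lab <- cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(-Inf)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  ks[which.max(scores)]
}

#' Project an association matrix into two dimensions
#'
#' Embeds the row profiles of the association matrix with PCA, t-SNE or UMAP.
#' Cluster labels never come from the 2-D projection: they are obtained by
#' cutting the hierarchical clustering of the matrix itself into `n_clusters`
#' groups (default: the `k` in 2..min(10, rows-1) with the highest mean
#' silhouette width), so the same labels apply across all projection methods.
#'
#' @param m An `association_matrix` (>= 3 rows for embeddings).
#' @param method `"pca"`, `"tsne"` or `"umap"`.
#' @param n_clusters Optional number of clusters to cut the row dendrogram
#'   into.
#' @param seed Integer seed controlling the stochastic embeddings.
#' @param perplexity t-SNE perplexity; reduced automatically (with a warning)
#'   when it is too large for the number of rows.
#' @return A tibble with columns `name`, `x`, `y`, `cluster`, `method`.
#' @export
dim_red <- function(m, method = c("pca", "tsne", "umap"), n_clusters = NULL,
                    seed = 1, perplexity = 30) {
  stopifnot(inherits(m, "association_matrix"))
  method <- match.arg(method)
  X <- m$values
  if (nrow(X) < 3) abort("Need at least 3 rows for a 2-D embedding.")
  cl <- if (is.null(m$hclust_rows)) pick_linkage(X) else
    list(hclust = m$hclust_rows)
  if (is.null(cl$hclust)) {
    labels <- rep(1L, nrow(X))
  } else {
    k <- if (is.null(n_clusters)) silhouette_k(X, cl$hclust) else n_clusters
    labels <- if (k >= 2) cutree(cl$hclust, k = k) else rep(1L, nrow(X))
  }
  set.seed(seed)
  coords <- switch(method,
    pca = {
      pc <- prcomp(X, center = TRUE, scale. = FALSE)
      xy <- pc$x
      if (ncol(xy) < 2) xy <- cbind(xy, 0)
      xy[, 1:2]
    },
    tsne = {
      maxp <- floor((nrow(X) - 1) / 3)
      if (perplexity > maxp) {
        warn(paste0("Perplexity reduced to ", maxp, " for ", nrow(X),
                    " rows."))
        perplexity <- maxp
      }
      Rtsne::Rtsne(X, perplexity = perplexity, check_duplicates = FALSE,
                   pca = FALSE, theta = 0, max_iter = 500)$Y
    },
    umap = {
      uwot::umap(X, n_neighbors = max(2, min(15, nrow(X) - 1)),
                 n_threads = 1)
    }
  )
  tibble(name = rownames(X), x = coords[, 1], y = coords[, 2],
         cluster = factor(labels), method = method)
}
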