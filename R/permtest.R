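# Deterministic per-element seed stream: one child seed per RS1 element, kept
# below 2^31. Evaluations consume no randomness, so a crosswise run is
# invariant to the order of RS2 and each cell is reproducible pairwise.

#' Derive the child seed used for one RS1 element
#'
#' @param master Master seed (integer).
#' @param i 1-based index of the RS1 element.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, i) {
  as.integer(((as.numeric(master) %% 2147483647) * 48271 + i * 9973) %%
               2147483646 + 1)
}

#' Normalize a Z-score by the size of the permuted set
#'
#' The raw permutation Z-score grows with the number of regions in the
#' permuted set, so Z-scores from tests of different sizes are not
#' comparable. Dividing by the square root of the region count removes most
#' of that dependence.
#'
#' @param zscore Raw Z-score(s).
#' @param n_regions Number of regions in the permuted set (>= 1).
#' @return `zscore / sqrt(n_regions)`.
#' @export
normalized_zscore <- function(zscore, n_regions) {
  if (any(n_regions < 1)) abort("`n_regions` must be >= 1.")
  zscore / sqrt(n_regions)
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method `"BH"` (Benjamini-Hochberg, default), `"bonferroni"`,
#'   `"holm"`, or any other method name known to [stats::p.adjust()].
#' @return Adjusted p-values, elementwise >= `p`, capped at 1.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  if (!method %in% stats::p.adjust.methods) {
    abort(paste0("Unknown adjustment method '", method, "'."))
  }
  p.adjust(p, method = method)
}

#' Keep the highest-scoring regions of a set
#'
#' Restricts a scored region set to its upper quartile by score, then draws
#' `n` of those uniformly (all of them, with a warning, if fewer than `n`
#' remain). Ties at the quartile boundary are broken by canonical region
#' order. Used to focus permutation tests on the strongest peaks.
#'
#' @param x Region-set tibble with a score column.
#' @param n Number of regions to keep.
#' @param score_col Name of the score column (default `"score"`).
#' @return A region-set tibble with at most `n` rows.
#' @export
filter_top_regions <- function(x, n, score_col = "score") {
  if (!score_col %in% names(x) || anyNA(x[[score_col]])) {
    abort(paste0("All regions need a score in column '", score_col, "'."))
  }
  if (n > nrow(x)) abort("`n` exceeds the number of regions.")
  k <- ceiling(nrow(x) / 4)
  idx <- order(-x[[score_col]], seq_len(nrow(x)))[seq_len(k)]
  top <- x[sort(idx), , drop = FALSE]  # canonical order among the kept rows
  if (nrow(top) < n) {
    warn(paste0("Upper quartile holds ", nrow(top), " regions; returning all ",
                "of them instead of ", n, "."))
    return(top)
  }
  top[sort(sample.int(nrow(top), n)), , drop = FALSE]
}

# ---- permutation core -------------------------------------------------------

# Compile a replicate generator for one region set. Built-in strategies get
# absolute-coordinate fast paths; registered strategies go through the tibble
# contract (validated on first use).
make_sampler <- function(randomization, x, genome, universe, params) {
  if (randomization == "resample_genome") {
    ctx <- tile_context(x, genome)
    return(function() sample_tiles(ctx))
  }
  if (randomization == "resample_regions") {
    if (is.null(universe)) abort("resample_regions needs a `universe`.")
    if (nrow(universe) < nrow(x)) {
      abort(paste0("Universe has ", nrow(universe), " regions but ",
                   nrow(x), " are required."))
    }
    U <- to_abs(universe, genome)
    n <- nrow(x)
    return(function() {
      idx <- sample.int(length(U$s), n)
      list(s = U$s[idx], e = U$e[idx])
    })
  }
  fn <- get_randomization(randomization)
  ctx <- c(list(genome = genome, universe = universe), params)
  checked <- FALSE
  function() {
    out <- fn(x, ctx)
    if (!checked) {
      out <- region_set(out, genome)
      if (nrow(out) != nrow(x)) {
        abort(paste0("Randomization strategy '", randomization, "' returned ",
                     nrow(out), " regions instead of ", nrow(x), "."))
      }
      checked <<- TRUE
    }
    to_abs(out, genome)
  }
}

# Compile one evaluator per target: function(abs_coords) -> number.
make_evaluator <- function(evaluation, target, genome) {
  if (evaluation == "num_overlaps") {
    t_abs <- to_abs(target, genome)
    m <- merge_abs(t_abs$s, t_abs$e)
    return(function(a) sum(hits_merged(a$s, a$e, m$s, m$e)))
  }
  if (evaluation == "num_overlaps_pairs") {
    t_abs <- to_abs(target, genome)
    ss <- sort(t_abs$s); se <- sort(t_abs$e)
    return(function(a) sum(findInterval(a$e - 1, ss) - findInterval(a$s, se)))
  }
  ev <- get_evaluation(evaluation)
  function(a) ev$fn(from_abs(a$s, a$e, genome), target)
}

eval_direction <- function(evaluation) {
  if (evaluation %in% c("num_overlaps", "num_overlaps_pairs")) return(TRUE)
  isTRUE(get_evaluation(evaluation)$higher_is_associated)
}

# One RS1 element against all targets: subsample once, randomize once, reuse
# every replicate's evaluation against every target.
perm_core <- function(x, targets, genome, randomization, evaluation, n_perm,
                      universe, params, subsample, seed) {
  if (nrow(x) == 0) abort("Cannot permute an empty region set.")
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  if (n_perm < 1000) {
    warn(paste0("n_perm = ", n_perm, " gives a p-value floor of 1/",
                n_perm + 1, "; 1000 or more is recommended."),
         class = "crosswiser_low_nperm")
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(subsample) && subsample < nrow(x)) {
    x <- x[sort(sample.int(nrow(x), subsample)), , drop = FALSE]
  }
  sampler <- make_sampler(randomization, x, genome, universe, params)
  replicates <- vector("list", n_perm)
  for (k in seq_len(n_perm)) replicates[[k]] <- sampler()
  x_abs <- to_abs(x, genome)
  observed <- numeric(length(targets))
  null <- matrix(NA_real_, nrow = n_perm, ncol = length(targets))
  for (j in seq_along(targets)) {
    f <- make_evaluator(evaluation, targets[[j]], genome)
    observed[j] <- f(x_abs)
    null[, j] <- vapply(replicates, f, numeric(1))
  }
  list(observed = observed, null = null, n_regions = nrow(x))
}

cell_stats <- function(observed, null, n_regions, higher_is_associated) {
  mu <- mean(null)
  sdv <- sd(null)
  n_perm <- length(null)
  if (is.na(sdv) || sdv == 0) {
    z <- NA_real_
  } else {
    z <- (observed - mu) / sdv
  }
  alt <- if (observed >= mu) "greater" else "less"
  p <- if (alt == "greater") {
    (1 + sum(null >= observed)) / (n_perm + 1)
  } else {
    (1 + sum(null <= observed)) / (n_perm + 1)
  }
  sign_flip <- if (higher_is_associated) 1 else -1
  tibble(observed = observed, null_mean = mu, null_sd = sdv, zscore = z,
         norm_zscore = sign_flip * normalized_zscore(z, n_regions),
         p_value = p, alternative = alt, n_regions = n_regions)
}

#' Pairwise permutation test between two region sets
#'
#' Compares the observed association statistic with its distribution over
#' `n_perm` randomized replicates of `x`. The one-sided direction is chosen
#' automatically (greater when the observed value exceeds the null mean), the
#' p-value carries a +1 pseudocount so its floor is `1/(n_perm + 1)`, and the
#' normalized Z-score divides the raw Z-score by `sqrt(n_regions)` (sign
#' flipped for distance-like statistics so positive always means more
#' associated than expected).
#'
#' @param x Region set that is randomized (the "query").
#' @param target Fixed region set evaluated against.
#' @param genome Genome tibble all sets live on.
#' @param randomization Strategy name: `"resample_genome"` (default),
#'   `"resample_regions"`, `"randomize_regions"` or a registered custom name.
#' @param evaluation Statistic name: `"num_overlaps"` (default),
#'   `"num_overlaps_pairs"`, `"mean_distance"` or a registered custom name.
#' @param n_perm Number of permutations (>= 100; 1000 or more recommended).
#' @param universe Universe region set (required for `resample_regions`).
#' @param subsample Optional count: uniformly subsample `x` once before
#'   randomizing.
#' @param seed Optional integer seed; with the same seed the test is
#'   reproducible bit-for-bit.
#' @param ... Extra parameters passed to the randomization strategy context
#'   (e.g. `per_chromosome`, `non_overlapping`).
#' @return An object of class `perm_test`; see [tidy.perm_test()].
#' @examples
#' g <- genome(c("chr1", "chr2"), c(1e5, 2e5))
#' set.seed(1)
#' a <- create_random_regions(g, n = 50)
#' pt <- permutation_test(a, a, g, n_perm = 200, seed = 7)
#' tidy(pt)
#' @export
permutation_test <- function(x, target, genome, randomization = "resample_genome",
                             evaluation = "num_overlaps", n_perm = 1000,
                             universe = NULL, subsample = NULL, seed = NULL,
                             ...) {
  check_genome(genome)
  core <- perm_core(x, list(target), genome, randomization, evaluation,
                    n_perm, universe, list(...), subsample, seed)
  stats <- cell_stats(core$observed[1], core$null[, 1], core$n_regions,
                      eval_direction(evaluation))
  structure(list(
    observed = stats$observed, null_sample = core$null[, 1],
    null_mean = stats$null_mean, null_sd = stats$null_sd,
    zscore = stats$zscore, norm_zscore = stats$norm_zscore,
    p_value = stats$p_value, alternative = stats$alternative,
    n_regions = stats$n_regions,
    parameters = list(randomization = randomization, evaluation = evaluation,
                      n_perm = n_perm, subsample = subsample, seed = seed)
  ), class = "perm_test")
}

#' Crosswise permutation test between two lists of region sets
#'
#' Runs the all-against-all permutation test: every element of `rs1` is
#' randomized once (`n_perm` replicates) and each replicate's evaluation is
#' reused against every element of `rs2`, so the expensive randomization step
#' is amortized over the whole row. P-values are adjusted jointly over all
#' cells (default Benjamini-Hochberg; set `adjust_scope = "row"` to adjust
#' within each RS1 row instead).
#'
#' @param rs1 Named list of region sets to randomize.
#' @param rs2 Named list of fixed target sets (defaults to `rs1`).
#' @inheritParams permutation_test
#' @param adjust_method Multiple-testing method for [adjust_pvalues()].
#' @param adjust_scope `"global"` (all cells jointly, default) or `"row"`.
#' @param seed Master seed; each RS1 element gets [child_seed()]`(seed, i)`,
#'   so any cell can be reproduced with a pairwise [permutation_test()].
#' @return An object of class `crosswise_result`: access the cell table with
#'   [tidy()], run parameters with [glance()], and build a matrix with
#'   [make_matrix()].
#' @export
crosswise_permtest <- function(rs1, rs2 = rs1, genome,
                               randomization = "resample_genome",
                               evaluation = "num_overlaps", n_perm = 1000,
                               universe = NULL, subsample = NULL,
                               adjust_method = "BH",
                               adjust_scope = c("global", "row"), seed = 1,
                               ...) {
  check_genome(genome)
  adjust_scope <- match.arg(adjust_scope)
  if (is.null(names(rs1)) || is.null(names(rs2)) ||
      any(!nzchar(names(rs1))) || any(!nzchar(names(rs2)))) {
    abort("`rs1` and `rs2` must be named lists of region sets.")
  }
  if (anyDuplicated(names(rs1)) || anyDuplicated(names(rs2))) {
    abort("Region-set names within `rs1` and within `rs2` must be unique.")
  }
  direction <- eval_direction(evaluation)
  rows <- vector("list", length(rs1))
  null_samples <- vector("list", length(rs1))
  for (i in seq_along(rs1)) {
    core <- perm_core(rs1[[i]], rs2, genome, randomization, evaluation,
                      n_perm, universe, list(...), subsample,
                      child_seed(seed, i))
    cells <- lapply(seq_along(rs2), function(j) {
      cell_stats(core$observed[j], core$null[, j], core$n_regions, direction)
    })
    rows[[i]] <- mutate(bind_rows(cells),
                        rs1 = names(rs1)[i], rs2 = names(rs2),
                        .before = 1)
    colnames(core$null) <- names(rs2)
    null_samples[[i]] <- core$null
  }
  tab <- bind_rows(rows)
  if (adjust_scope == "global") {
    tab$adj_p_value <- adjust_pvalues(tab$p_value, adjust_method)
  } else {
    tab <- tab |>
      group_by(.data$rs1) |>
      mutate(adj_p_value = adjust_pvalues(.data$p_value, adjust_method)) |>
      ungroup()
  }
  names(null_samples) <- names(rs1)
  structure(list(
    table = tab,
    rs1_names = names(rs1), rs2_names = names(rs2),
    null_samples = null_samples,
    parameters = list(randomization = randomization, evaluation = evaluation,
                      n_perm = n_perm, subsample = subsample,
                      adjust_method = adjust_method,
                      adjust_scope = adjust_scope, seed = seed,
                      genome = list(chrom = genome$chrom,
                                    length = genome$length)),
    created = format(Sys.time(), tz = "UTC")
  ), class = "crosswise_result")
}

# ---- broom-style accessors --------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a pairwise permutation test
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the observed statistic, null mean/sd,
#'   Z-score, normalized Z-score, p-value, alternative and region count.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
         zscore = x$zscore, norm_zscore = x$norm_zscore, p_value = x$p_value,
         alternative = x$alternative, n_regions = x$n_regions)
}

#' Cell table of a crosswise result
#'
#' @param x A `crosswise_result`.
#' @param ... Unused.
#' @return A tibble with one row per (rs1, rs2) cell: observed statistic,
#'   null mean/sd, `zscore`, `norm_zscore`, `p_value`, `adj_p_value`,
#'   `alternative`, `n_regions`.
#' @method tidy crosswise_result
#' @export
tidy.crosswise_result <- function(x, ...) x$table

#' One-row summary of a crosswise run
#' @inheritParams tidy.crosswise_result
#' @return A one-row tibble of run parameters and dimensions.
#' @method glance crosswise_result
#' @export
glance.crosswise_result <- function(x, ...) {
  tibble(n_rs1 = length(x$rs1_names), n_rs2 = length(x$rs2_names),
         n_perm = x$parameters$n_perm,
         randomization = x$parameters$randomization,
         evaluation = x$parameters$evaluation,
         adjust_method = x$parameters$adjust_method,
         adjust_scope = x$parameters$adjust_scope,
         seed = x$parameters$seed)
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test (", x$parameters$randomization, " / ",
      x$parameters$evaluation, ", ", x$parameters$n_perm, " permutations)\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
print.crosswise_result <- function(x, ...) {
  cat("Crosswise permutation test: ", length(x$rs1_names), " x ",
      length(x$rs2_names), " region sets, ", x$parameters$n_perm,
      " permutations (", x$parameters$randomization, " / ",
      x$parameters$evaluation, ")\n", sep = "")
  print(x$table)
  invisible(x)
}

# ---- persistence ------------------------------------------------------------

#' Save / load a crosswise result
#'
#' Writes the cell table as long-form TSV (columns rs1, rs2, observed,
#' null_mean, null_sd, zscore, norm_zscore, p_value, adj_p_value,
#' alternative, n_regions) preceded by a single `#`-prefixed JSON header
#' holding the run parameters. `read_crosswise()` restores a
#' `crosswise_result` with every saved field intact (per-cell null samples
#' are not serialized).
#'
#' @param cw A `crosswise_result`.
#' @param path Output/input path.
#' @return `write_crosswise()` the path invisibly; `read_crosswise()` a
#'   `crosswise_result`.
#' @export
write_crosswise <- function(cw, path) {
  stopifnot(inherits(cw, "crosswise_result"))
  header <- jsonlite::toJSON(cw$parameters, auto_unbox = TRUE, digits = NA)
  body <- sub("\n$", "", readr::format_tsv(cw$table))
  writeLines(c(paste0("#", header), body), path)
  invisible(path)
}

#' @rdname write_crosswise
#' @export
read_crosswise <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#")) abort("Missing JSON parameter header.")
  params <- jsonlite::fromJSON(sub("^#", "", first))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(),
                         progress = FALSE)
  need <- c("rs1", "rs2", "observed", "null_mean", "null_sd", "zscore",
            "norm_zscore", "p_value", "adj_p_value", "alternative",
            "n_regions")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Crosswise file is missing field(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  structure(list(
    table = as_tibble(tab),
    rs1_names = unique(tab$rs1), rs2_names = unique(tab$rs2),
    null_samples = NULL,
    parameters = params,
    created = NA_character_
  ), class = "crosswise_result")
}
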