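# Registries for randomization and evaluation functions. Built-ins are seeded
# at load; user functions join via register_randomization()/register_evaluation().
.cw_registry <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  reset_registries()
}

# internal: also used by tests to restore a clean state
reset_registries <- function() {
  .cw_registry$rand <- list(
    resample_regions = function(x, ctx) resample_regions(x, ctx$universe),
    resample_genome = function(x, ctx) resample_genome(x, ctx$genome),
    randomize_regions = function(x, ctx) {
      randomize_regions(x, ctx$genome,
                        per_chromosome = isTRUE(ctx$per_chromosome),
                        non_overlapping = isTRUE(ctx$non_overlapping))
    }
  )
  .cw_registry$eval <- list(
    num_overlaps = list(
      fn = function(a, b) count_overlaps(a, b, count_once = TRUE),
      higher_is_associated = TRUE
    ),
    num_overlaps_pairs = list(
      fn = function(a, b) count_overlaps(a, b, count_once = FALSE),
      higher_is_associated = TRUE
    ),
    mean_distance = list(
      fn = function(a, b) mean_distance(a, b),
      higher_is_associated = FALSE
    )
  )
  invisible(NULL)
}

#' Register a custom randomization strategy
#'
#' A strategy receives the region set to randomize and a context list with
#' elements `genome`, `universe` and any strategy parameters, and must return
#' a region set with the same number of regions, valid on the genome. The
#' contract is checked at first use inside a permutation test.
#'
#' @param name New strategy name; registering an existing name is an error.
#' @param fn `function(x, context)` returning a region-set tibble.
#' @return `name`, invisibly.
#' @seealso [resample_regions()], [resample_genome()], [randomize_regions()]
#' @export
register_randomization <- function(name, fn) {
  if (name %in% names(.cw_registry$rand)) {
    abort(paste0("Randomization strategy '", name, "' is already registered."))
  }
  stopifnot(is.function(fn))
  .cw_registry$rand[[name]] <- fn
  invisible(name)
}

#' List registered randomization and evaluation functions
#' @return Character vector of names.
#' @export
list_randomizations <- function() names(.cw_registry$rand)

get_randomization <- function(name) {
  fn <- .cw_registry$rand[[name]]
  if (is.null(fn)) {
    abort(paste0("Unknown randomization strategy '", name, "'. Available: ",
                 paste(list_randomizations(), collapse = ", "), "."))
  }
  fn
}

#' Resample a region set from a universe
#'
#' Draws `nrow(x)` distinct members of `universe` uniformly without
#' replacement; the output consists of verbatim universe intervals. This is
#' the null model of choice when a natural candidate pool exists (e.g. the
#' merged peaks of all experiments under comparison).
#'
#' @param x Region set whose size is matched.
#' @param universe Region-set tibble with at least `nrow(x)` rows.
#' @return A region-set tibble of `nrow(x)` universe rows.
#' @export
resample_regions <- function(x, universe) {
  if (is.null(universe)) abort("resample_regions needs a `universe`.")
  n <- nrow(x)
  if (nrow(universe) < n) {
    abort(paste0("Universe has ", nrow(universe), " regions but ", n,
                 " are required."))
  }
  idx <- sample.int(nrow(universe), n)
  universe[sort(idx), c("chrom", "start", "end")]
}

#' Resample fixed-width tiles from the genome
#'
#' Partitions every chromosome into consecutive non-overlapping tiles of width
#' `round(mean(region_width(x)))` (the final partial tile is discarded) and
#' samples `nrow(x)` tiles uniformly without replacement. A fast
#' genome-background null for sets of roughly constant width.
#'
#' @param x Region set providing the count and mean width.
#' @param genome Genome tibble to tile.
#' @return A region-set tibble of `nrow(x)` tiles.
#' @export
resample_genome <- function(x, genome) {
  check_genome(genome)
  ctx <- tile_context(x, genome)
  abs <- sample_tiles(ctx)
  sort_regions(from_abs(abs$s, abs$e, genome), genome)
}

tile_context <- function(x, genome) {
  w <- max(1, round(mean(region_width(x))))
  n_tiles <- floor(genome$length / w)
  total <- sum(n_tiles)
  if (total < nrow(x)) {
    abort(paste0("Only ", total, " tiles of width ", w, " available for ",
                 nrow(x), " regions."))
  }
  list(w = w, n = nrow(x), n_tiles = n_tiles, total = total,
       cum = cumsum(c(0, head(n_tiles, -1))),
       off = unname(chrom_offsets(genome)))
}

sample_tiles <- function(ctx) {
  idx <- sample.int(ctx$total, ctx$n)
  ci <- findInterval(idx - 1, ctx$cum)      # chromosome index per tile
  local <- idx - 1 - ctx$cum[ci]            # 0-based tile within chromosome
  s <- ctx$off[ci] + local * ctx$w
  list(s = s, e = s + ctx$w)
}

#' Randomly re-place regions preserving their widths
#'
#' Each region is moved to a new uniformly chosen position with its width kept.
#' By default the target chromosome is drawn with probability proportional to
#' the number of valid start positions (`length - width + 1`), which makes the
#' placement uniform over the whole genome; with `per_chromosome = TRUE` each
#' region stays on its own chromosome.
#'
#' @param x Region set to permute.
#' @param genome Genome tibble.
#' @param per_chromosome Keep each region on its original chromosome.
#' @param non_overlapping Rejection-sample until placements are mutually
#'   disjoint (at most 1000 attempts per region).
#' @return A region-set tibble with the same width multiset as `x`.
#' @export
randomize_regions <- function(x, genome, per_chromosome = FALSE,
                              non_overlapping = FALSE) {
  check_genome(genome)
  w <- region_width(x)
  n <- length(w)
  lens <- genome$length
  if (!non_overlapping) {
    abs <- place_uniform(w, x$chrom, genome, per_chromosome)
    return(sort_regions(from_abs(abs$s, abs$e, genome), genome))
  }
  # rejection sampling against already accepted placements
  acc_s <- numeric(0); acc_e <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      p <- place_uniform(w[i], x$chrom[i], genome, per_chromosome)
      m <- merge_abs(acc_s, acc_e)
      if (!any(hits_merged(p$s, p$e, m$s, m$e))) {
        acc_s <- c(acc_s, p$s); acc_e <- c(acc_e, p$e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste0("Could not place region ", i, " without overlap after ",
                   "1000 attempts; use a larger genome or fewer regions."))
    }
  }
  sort_regions(from_abs(acc_s, acc_e, genome), genome)
}

# Uniform placement of widths w over valid (chromosome, start) pairs, in
# absolute coordinates. Vectorized over regions.
place_uniform <- function(w, orig_chrom, genome, per_chromosome) {
  lens <- genome$length
  off <- unname(chrom_offsets(genome))
  n <- length(w)
  if (per_chromosome) {
    ci <- match(orig_chrom, genome$chrom)
    valid <- lens[ci] - w + 1
    if (any(valid < 1)) {
      abort("A region is wider than its chromosome.")
    }
    start <- floor(runif(n) * valid)
    s <- off[ci] + start
    return(list(s = s, e = s + w))
  }
  # valid start counts per (region, chromosome); cumulative over chromosomes
  V <- outer(w, lens, function(wi, li) pmax(li - wi + 1, 0))
  tot <- rowSums(V)
  if (any(tot < 1)) abort("A region is wider than every chromosome.")
  g <- floor(runif(n) * tot)          # uniform over all valid placements
  CV <- t(apply(V, 1, cumsum))
  ci <- max.col(CV > g, ties.method = "first")
  prev <- CV[cbind(seq_len(n), ci)] - V[cbind(seq_len(n), ci)]
  start <- g - prev
  s <- off[ci] + start
  list(s = s, e = s + w)
}
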