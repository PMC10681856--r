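#' The four-chromosome demonstration genome
#'
#' A small artificial genome used throughout the package's examples and
#' tests: four chromosomes of 0.1, 0.5, 1 and 2 Mb, large enough for
#' permutation nulls to be well behaved and small enough for tests to run in
#' seconds.
#'
#' @return A genome tibble with chromosomes `alien1`..`alien4`.
#' @export
alien_genome <- function() {
  genome(paste0("alien", 1:4), c(1e5, 5e5, 1e6, 2e6))
}

#' Create a random region set on a genome
#'
#' Widths are drawn from Normal(`width_mean`, `width_sd`), rounded and
#' floored at 1 bp; each region's chromosome is chosen with probability
#' proportional to the number of valid start positions and its start
#' uniformly among them, so placement is uniform over the genome.
#'
#' @param genome Genome tibble.
#' @param n Number of regions (default 100).
#' @param width_mean,width_sd Width distribution in bp (defaults 100 and 50).
#' @param non_overlapping Reject placements overlapping an already placed
#'   region (at most 1000 attempts each).
#' @return A canonically sorted region-set tibble of `n` rows.
#' @export
create_random_regions <- function(genome, n = 100, width_mean = 100,
                                  width_sd = 50, non_overlapping = FALSE) {
  check_genome(genome)
  if (n == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  w <- pmax(1, round(rnorm(n, width_mean, width_sd)))
  if (!non_overlapping) {
    abs <- place_uniform(w, NULL, genome, per_chromosome = FALSE)
    return(sort_regions(from_abs(abs$s, abs$e, genome), genome))
  }
  acc_s <- numeric(0); acc_e <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(1000)) {
      p <- place_uniform(w[i], NULL, genome, per_chromosome = FALSE)
      m <- merge_abs(acc_s, acc_e)
      if (!any(hits_merged(p$s, p$e, m$s, m$e))) {
        acc_s <- c(acc_s, p$s); acc_e <- c(acc_e, p$e)
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("Could not place all regions without overlap.")
  }
  sort_regions(from_abs(acc_s, acc_e, genome), genome)
}

#' Derive a region set sharing a fraction of a parent's regions
#'
#' Builds one member of a similarity ladder: `round(fraction * n)` regions
#' are copied verbatim from a uniform sample of the parent and the remainder
#' are drawn fresh with the parent's empirical width parameters. Similarity
#' is therefore the exact fraction of identical intervals, verifiable by
#' interval equality.
#'
#' @param parent Region-set tibble.
#' @param fraction Fraction in (0, 1) of regions shared verbatim.
#' @param genome Genome tibble.
#' @return A region set with `nrow(parent)` rows.
#' @export
similar_region_set <- function(parent, fraction, genome) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  n <- nrow(parent)
  k <- round(fraction * n)
  shared <- parent[sort(sample.int(n, k)), c("chrom", "start", "end")]
  w <- region_width(parent)
  fresh <- create_random_regions(genome, n - k, mean(w), max(sd(w), 0))
  sort_regions(bind_rows(shared, fresh), genome)
}

#' Compose a region set from two parents
#'
#' Takes half of its regions from each parent (a uniform sample of
#' `floor(n/2)` from each, `n` being the parent size), modelling a feature
#' genuinely associated with two independent ones. Duplicate intervals
#' sampled from both parents are kept once and topped up from the larger
#' parent with a warning.
#'
#' @param a,b Parent region sets of equal size.
#' @param genome Genome tibble.
#' @return A region set of `nrow(a)` rows (for even parent sizes).
#' @export
make_composite <- function(a, b, genome) {
  n <- nrow(a)
  h <- floor(n / 2)
  if (nrow(a) < h || nrow(b) < h) abort("Parents must have at least n/2 regions.")
  take <- function(x, k) x[sort(sample.int(nrow(x), k)), c("chrom", "start", "end")]
  out <- distinct(bind_rows(take(a, h), take(b, h)))
  if (nrow(out) < 2 * h) {
    warn(paste0(2 * h - nrow(out), " duplicate region(s) across parents; ",
                "topping up from the larger parent."))
    pool <- if (nrow(a) >= nrow(b)) a else b
    while (nrow(out) < 2 * h) {
      cand <- take(pool, 1)
      out <- distinct(bind_rows(out, cand))
    }
  }
  sort_regions(out, genome)
}

#' Build a flanking region set
#'
#' Places one region per parent region on a random side at a gap drawn
#' uniformly from 1..`max_gap` bp, with the parent's empirical width
#' distribution, re-drawing any placement that overlaps (or touches) a parent
#' region or leaves the chromosome. The result is strictly adjacent to but
#' never overlapping the parent — the geometry that makes an association
#' visible only under positional shifting.
#'
#' @param parent Region-set tibble.
#' @param genome Genome tibble.
#' @param max_gap Maximum gap to the parent region in bp (default 300).
#' @return A region set with `nrow(parent)` rows, every one within
#'   `[1, max_gap]` bp of its nearest parent region.
#' @export
make_flanking <- function(parent, genome, max_gap = 300) {
  if (max_gap < 1) abort("`max_gap` must be >= 1.")
  check_genome(genome)
  pw <- region_width(parent)
  wm <- mean(pw); ws <- max(sd(pw), 0)
  p_abs <- to_abs(parent, genome)
  pm <- merge_abs(p_abs$s, p_abs$e)
  len <- genome$length[match(parent$chrom, genome$chrom)]
  off <- chrom_offsets(genome)[parent$chrom]
  out_s <- numeric(nrow(parent)); out_e <- numeric(nrow(parent))
  for (i in seq_len(nrow(parent))) {
    placed <- FALSE
    for (attempt in seq_len(200)) {
      w <- max(1, round(rnorm(1, wm, ws)))
      gap <- sample.int(max_gap, 1)
      side <- sample(c(-1, 1), 1)
      if (side > 0) {
        s <- parent$end[i] + gap
        e <- s + w
      } else {
        e <- parent$start[i] - gap
        s <- e - w
      }
      if (s < 0 || e > len[i]) next
      as <- unname(off[i]) + s
      ae <- unname(off[i]) + e
      # reject overlap with, or direct adjacency to, any parent region
      if (any(hits_merged(as - 1, ae + 1, pm$s, pm$e))) next
      out_s[i] <- as; out_e[i] <- ae
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(paste0("Could not place a flanking region for parent region ", i,
                   " within ", max_gap, " bp."))
    }
  }
  sort_regions(from_abs(out_s, out_e, genome), genome)
}

#' Build negative-control region sets
#'
#' Random regions rejected against a merged exclusion pool, guaranteeing zero
#' overlap with every excluded set — the null rows of the demonstration
#' dataset.
#'
#' @param genome Genome tibble.
#' @param exclude List of region sets the controls must not overlap.
#' @param n Number of regions.
#' @param width_mean,width_sd Width distribution (bp).
#' @return A region set of `n` rows overlapping none of the excluded sets.
#' @export
make_controls <- function(genome, exclude, n = 100, width_mean = 100,
                          width_sd = 50) {
  ex <- merge_sets(exclude, coalesce = TRUE, genome = genome)
  ex_abs <- to_abs(ex, genome)
  m <- merge_abs(ex_abs$s, ex_abs$e)
  got_s <- numeric(0); got_e <- numeric(0)
  for (iter in seq_len(200)) {
    w <- pmax(1, round(rnorm(n, width_mean, width_sd)))
    p <- place_uniform(w, NULL, genome, per_chromosome = FALSE)
    ok <- !hits_merged(p$s, p$e, m$s, m$e)
    got_s <- c(got_s, p$s[ok]); got_e <- c(got_e, p$e[ok])
    if (length(got_s) >= n) break
  }
  if (length(got_s) < n) {
    abort("Could not draw enough control regions outside the exclusion pool.")
  }
  sort_regions(from_abs(got_s[seq_len(n)], got_e[seq_len(n)], genome), genome)
}

#' Build the full demonstration dataset
#'
#' Generates the synthetic benchmark the package validates itself on: three
#' independent base sets (`regA`, `regB`, `regC`) of `n_regions` regions on
#' the four-chromosome demo genome; a composite set `regAB` sharing half its
#' regions with `regA` and half with `regB`; a flanking set `regD` of regions
#' within `flank_max` bp of `regA` without overlapping it; similarity ladders
#' (fractions `similarity_main` for the base sets, `similarity_derived` for
#' `regAB`/`regD`); and `n_controls` negative-control sets overlapping none
#' of regA/regB/regC/regAB. Set names carry the shared percentage, e.g.
#' `regA_90`.
#'
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param chrom_lengths Chromosome lengths in bp.
#' @param n_regions Regions per set (default 100).
#' @param width_mean,width_sd Region width distribution in bp (defaults 100
#'   and 50).
#' @param flank_max Maximum flanking distance in bp (default 300).
#' @param similarity_main Shared fractions for the regA/regB/regC ladders
#'   (default 0.9 down to 0.1).
#' @param similarity_derived Shared fractions for the regAB/regD ladders
#'   (default 0.8 down to 0.2).
#' @param n_controls Number of negative-control sets (default 3).
#' @param dir Optional directory: when given, every set is written as BED
#'   together with a chrom.sizes file and a JSON manifest.
#' @return A list with `genome` (tibble), `sets` (named list of region-set
#'   tibbles) and `params`.
#' @export
build_demo_dataset <- function(seed = 42,
                               chrom_lengths = c(1e5, 5e5, 1e6, 2e6),
                               n_regions = 100, width_mean = 100,
                               width_sd = 50, flank_max = 300,
                               similarity_main = seq(0.9, 0.1, by = -0.1),
                               similarity_derived = seq(0.8, 0.2, by = -0.1),
                               n_controls = 3, dir = NULL) {
  g <- genome(paste0("alien", seq_along(chrom_lengths)), chrom_lengths)
  set.seed(seed)
  sets <- list()
  for (nm in c("regA", "regB", "regC")) {
    sets[[nm]] <- create_random_regions(g, n_regions, width_mean, width_sd)
  }
  sets$regAB <- make_composite(sets$regA, sets$regB, g)
  sets$regD <- make_flanking(sets$regA, g, max_gap = flank_max)
  for (nm in c("regA", "regB", "regC")) {
    for (f in similarity_main) {
      sets[[paste0(nm, "_", round(100 * f))]] <-
        similar_region_set(sets[[nm]], f, g)
    }
  }
  for (nm in c("regAB", "regD")) {
    for (f in similarity_derived) {
      sets[[paste0(nm, "_", round(100 * f))]] <-
        similar_region_set(sets[[nm]], f, g)
    }
  }
  for (i in seq_len(n_controls)) {
    sets[[paste0("ctrl_", i)]] <-
      make_controls(g, sets[c("regA", "regB", "regC", "regAB")],
                    n_regions, width_mean, width_sd)
  }
  params <- list(seed = seed, chrom_lengths = chrom_lengths,
                 n_regions = n_regions, width_mean = width_mean,
                 width_sd = width_sd, flank_max = flank_max,
                 similarity_main = similarity_main,
                 similarity_derived = similarity_derived,
                 n_controls = n_controls)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_chrom_sizes(g, file.path(dir, "alien.chrom.sizes"))
    for (nm in names(sets)) {
      write_bed(sets[[nm]], file.path(dir, paste0(nm, ".bed")), genome = g)
    }
    jsonlite::write_json(c(params, list(sets = names(sets))),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genome = g, sets = sets, params = params)
}
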