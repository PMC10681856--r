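#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select bind_rows distinct group_by
#'   summarise ungroup left_join n
#' @importFrom stats sd cor quantile prcomp hclust cutree cophenetic dist
#'   p.adjust rnorm runif as.dendrogram order.dendrogram
#' @importFrom utils head modifyList
NULL

# ---- genomes ----------------------------------------------------------------

#' Define a genome from chromosome lengths
#'
#' A genome is the sampling space for every randomization: an ordered table of
#' chromosome names and lengths in base pairs.
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Integer-ish vector of strictly positive lengths (bp).
#' @return A tibble with columns `chrom` and `length`, one row per chromosome,
#'   in the order given.
#' @examples
#' genome(c("chr1", "chr2"), c(1e5, 2e5))
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    abort("Chromosome names must be non-empty.")
  }
  if (anyDuplicated(chrom)) {
    abort(paste0("Duplicate chromosome name: ",
                 chrom[duplicated(chrom)][1]))
  }
  if (any(is.na(length)) || any(length <= 0) || any(length != floor(length))) {
    abort("Chromosome lengths must be positive integers.")
  }
  tibble(chrom = chrom, length = length)
}

#' Read a chrom.sizes table
#'
#' Parses the standard two-column (name, length) tab-separated file used to
#' describe a reference genome.
#'
#' @param path Path to a TSV with at least two columns: chromosome name and
#'   length in bp. No header.
#' @return A genome tibble (see [genome()]) with chromosomes in file order.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                        progress = FALSE)
  if (ncol(df) < 2) abort("chrom.sizes file must have at least 2 columns.")
  len <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(len))) {
    abort(paste0("Non-numeric chromosome length at line ",
                 which(is.na(len))[1], "."))
  }
  genome(df[[1]], len)
}

#' @rdname read_chrom_sizes
#' @param genome Genome tibble to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  check_genome(genome)
  readr::write_tsv(genome, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

check_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "length") %in% names(genome))) {
    abort("`genome` must be a tibble with columns `chrom` and `length`.")
  }
  invisible(genome)
}

#' Total genome length
#' @param genome Genome tibble.
#' @return Total length in bp.
#' @export
genome_length <- function(genome) {
  check_genome(genome)
  sum(genome$length)
}

# Offsets mapping each chromosome onto one absolute number line; intervals are
# always within a chromosome, so overlap arithmetic on absolute coordinates is
# exact.
chrom_offsets <- function(genome) {
  stats::setNames(cumsum(c(0, head(genome$length, -1))), genome$chrom)
}

# ---- region sets ------------------------------------------------------------

#' Build or validate a region set
#'
#' Region sets are tibbles with columns `chrom`, `start`, `end` holding
#' 0-based half-open intervals (the BED convention). `region_set()` validates
#' coordinates against a genome and returns the set in canonical order
#' (genome chromosome order, then start, then end).
#'
#' @param x Data frame with columns `chrom`, `start`, `end` (extra columns are
#'   kept).
#' @param genome Genome tibble the regions must lie on.
#' @return A canonically sorted tibble.
#' @export
region_set <- function(x, genome) {
  check_genome(genome)
  x <- as_tibble(x)
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort("A region set needs columns `chrom`, `start`, `end`.")
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- !x$chrom %in% genome$chrom
  if (any(bad)) {
    abort(paste0("Unknown chromosome '", x$chrom[bad][1], "' (row ",
                 which(bad)[1], ")."))
  }
  len <- genome$length[match(x$chrom, genome$chrom)]
  bad <- x$start < 0 | x$end > len | x$start >= x$end
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("Invalid region at row ", i, ": ", x$chrom[i], ":",
                 x$start[i], "-", x$end[i],
                 " (need 0 <= start < end <= chromosome length)."))
  }
  sort_regions(x, genome)
}

sort_regions <- function(x, genome) {
  ord <- order(match(x$chrom, genome$chrom), x$start, x$end)
  as_tibble(x[ord, , drop = FALSE])
}

#' Region widths
#' @param x Region set tibble.
#' @return Numeric vector of widths (end - start) in bp.
#' @export
region_width <- function(x) {
  x$end - x$start
}

#' Read a BED file as a region set
#'
#' BED3+ input: tab-separated, 0-based half-open coordinates. Columns beyond
#' the third are ignored except column 5 (score), kept as `score` when
#' present so that score-based filtering ([filter_top_regions()]) can use it.
#'
#' @param path Path to a BED file.
#' @param genome Genome tibble; every region must fit its chromosome.
#' @return A canonically sorted region-set tibble.
#' @export
read_bed <- function(path, genome) {
  check_genome(genome)
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                        comment = "#", progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (ncol(df) < 3) abort("BED input needs at least 3 columns.")
  x <- tibble(chrom = as.character(df[[1]]),
              start = as.numeric(df[[2]]),
              end = as.numeric(df[[3]]))
  if (ncol(df) >= 5) {
    sc <- suppressWarnings(as.numeric(df[[5]]))
    if (!all(is.na(sc))) x$score <- sc
  }
  region_set(x, genome)
}

#' Write a region set as BED3
#'
#' @param x Region-set tibble.
#' @param path Output path.
#' @param genome Genome used for canonical ordering (optional; if omitted the
#'   rows are written as given).
#' @return The path, invisibly. `read_bed(write_bed(x))` round-trips exactly.
#' @export
write_bed <- function(x, path, genome = NULL) {
  if (!is.null(genome)) x <- sort_regions(x, genome)
  readr::write_tsv(x[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

# ---- absolute-coordinate kernels -------------------------------------------
#
# All overlap/distance arithmetic runs on absolute coordinates (chromosome
# offsets added) so the permutation hot loop is a handful of findInterval
# calls per evaluation instead of per-region work.

to_abs <- function(x, genome) {
  off <- chrom_offsets(genome)[x$chrom]
  list(s = unname(off + x$start), e = unname(off + x$end))
}

from_abs <- function(s, e, genome) {
  off <- chrom_offsets(genome)
  idx <- findInterval(s, unname(off))
  tibble(chrom = genome$chrom[idx],
         start = s - unname(off)[idx],
         end = e - unname(off)[idx])
}

# Coalesce possibly-overlapping intervals into disjoint sorted ones.
merge_abs <- function(s, e) {
  if (length(s) == 0) return(list(s = numeric(), e = numeric()))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cme <- cummax(e)
  new_grp <- c(TRUE, s[-1] > cme[-length(cme)])
  grp <- cumsum(new_grp)
  list(s = s[new_grp],
       e = as.numeric(tapply(e, grp, max)))
}

# Count-once: queries hitting >= 1 merged subject interval.
hits_merged <- function(qs, qe, ms, me) {
  if (length(ms) == 0 || length(qs) == 0) return(logical(length(qs)))
  idx <- findInterval(qe - 1, ms)  # number of subject starts < qe (integer coords)
  idx >= 1 & me[pmax(idx, 1L)] > qs
}

# Total overlapping (query, subject) pairs against *unmerged* subject.
pairs_count <- function(qs, qe, ss, se) {
  if (length(ss) == 0 || length(qs) == 0) return(0)
  sum(findInterval(qe - 1, sort(ss)) - findInterval(qs, sort(se)))
}

#' Count overlaps between two region sets
#'
#' The default evaluation statistic of the permutation framework: how many
#' query regions hit at least one subject region (`count_once = TRUE`), or the
#' total number of overlapping (query, subject) pairs. Intervals are half-open;
#' touching intervals do not overlap.
#'
#' @param query,subject Region-set tibbles on the same genome.
#' @param count_once Count each query region at most once (default) or count
#'   every overlapping pair.
#' @param genome Optional genome tibble; supplying it validates both sets.
#' @return A single non-negative number.
#' @examples
#' g <- genome("chr1", 1000)
#' a <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(50, 150))
#' count_overlaps(a, a)  # 2
#' @export
count_overlaps <- function(query, subject, count_once = TRUE, genome = NULL) {
  if (is.null(genome)) genome <- infer_genome(query, subject)
  q <- to_abs(query, genome)
  s <- to_abs(subject, genome)
  if (count_once) {
    m <- merge_abs(s$s, s$e)
    sum(hits_merged(q$s, q$e, m$s, m$e))
  } else {
    pairs_count(q$s, q$e, s$s, s$e)
  }
}

# A positional scaffold covering both sets when the caller passes no genome;
# only relative positions matter for pure interval arithmetic.
infer_genome <- function(...) {
  sets <- list(...)
  chroms <- unique(unlist(lapply(sets, function(x) x$chrom)))
  if (length(chroms) == 0) chroms <- "chr1"
  maxend <- vapply(chroms, function(cc) {
    m <- unlist(lapply(sets, function(x) x$end[x$chrom == cc]))
    if (length(m) == 0) 1 else max(m)
  }, numeric(1))
  genome(chroms, pmax(maxend, 1))
}

#' Distance from each query region to its nearest subject region
#'
#' The gap in bp between half-open intervals: 0 when they overlap, and
#' `c - b` for `[a, b)` followed by `[c, d)`. Distances are defined within a
#' chromosome; a query region whose chromosome carries no subject region gets
#' `NA`.
#'
#' @inheritParams count_overlaps
#' @return Numeric vector, one value per query region, in the row order of
#'   `query`.
#' @export
nearest_distance <- function(query, subject, genome = NULL) {
  if (nrow(subject) == 0) abort("`subject` must be non-empty.")
  if (is.null(genome)) genome <- infer_genome(query, subject)
  out <- rep(NA_real_, nrow(query))
  for (cc in unique(query$chrom)) {
    qi <- which(query$chrom == cc)
    si <- subject$chrom == cc
    if (!any(si)) next
    m <- merge_abs(subject$start[si], subject$end[si])
    qs <- query$start[qi]; qe <- query$end[qi]
    k <- findInterval(qe - 1, m$s)  # last subject interval starting before qe
    ov <- k >= 1 & m$e[pmax(k, 1L)] > qs
    left <- ifelse(k >= 1, qs - m$e[pmax(k, 1L)], Inf)
    right <- ifelse(k < length(m$s), m$s[pmin(k + 1L, length(m$s))] - qe, Inf)
    d <- pmin(pmax(left, 0), pmax(right, 0))
    d[ov] <- 0
    out[qi] <- d
  }
  out
}

#' Subtract one region set from another
#'
#' Returns the portions of `a` not covered by any region of `b`: fully covered
#' regions are dropped, partially covered ones are trimmed or split.
#'
#' @param a,b Region-set tibbles on the same genome.
#' @inheritParams count_overlaps
#' @return A region-set tibble (canonical order).
#' @export
subtract_regions <- function(a, b, genome = NULL) {
  if (is.null(genome)) genome <- infer_genome(a, b)
  A <- to_abs(a, genome)
  m <- with(to_abs(b, genome), merge_abs(s, e))
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(A$s)) {
    s <- A$s[i]; e <- A$e[i]
    # b intervals overlapping [s, e)
    j <- which(m$s < e & m$e > s)
    if (length(j) == 0) {
      out_s <- c(out_s, s); out_e <- c(out_e, e)
      next
    }
    cuts_s <- c(s, m$e[j]); cuts_e <- c(m$s[j], e)
    keep <- cuts_s < cuts_e & cuts_s >= s & cuts_e <= e
    out_s <- c(out_s, cuts_s[keep]); out_e <- c(out_e, cuts_e[keep])
  }
  sort_regions(from_abs(out_s, out_e, genome), genome)
}

#' Combine several region sets into one
#'
#' With `coalesce = FALSE` (the default) the sets are concatenated and exact
#' duplicate intervals collapsed, preserving every distinct interval — the
#' behaviour wanted when building a resampling universe whose membership
#' counts must not be distorted. With `coalesce = TRUE` overlapping intervals
#' are merged into their union.
#'
#' @param sets Non-empty list of region-set tibbles on one genome.
#' @param coalesce Merge overlapping intervals instead of only deduplicating.
#' @param genome Optional genome for canonical ordering.
#' @return A region-set tibble.
#' @export
merge_sets <- function(sets, coalesce = FALSE, genome = NULL) {
  if (length(sets) == 0) abort("`sets` must contain at least one region set.")
  all <- bind_rows(lapply(sets, function(x) x[, c("chrom", "start", "end")]))
  if (is.null(genome)) genome <- infer_genome(all)
  if (coalesce) {
    out <- bind_rows(lapply(split(all, all$chrom), function(d) {
      m <- merge_abs(d$start, d$end)
      tibble(chrom = d$chrom[1], start = m$s, end = m$e)
    }))
  } else {
    out <- distinct(all, .data$chrom, .data$start, .data$end)
  }
  sort_regions(out, genome)
}
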