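# Independent brute-force oracles and small fixtures shared across the suite.

toy_genome <- function() genome(c("chr1", "chr2"), c(10000, 20000))

random_toy_set <- function(g, n, max_w = 100) {
  ci <- sample.int(nrow(g), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  start <- floor(runif(n) * (g$length[ci] - w))
  region_set(tibble::tibble(chrom = g$chrom[ci], start = start,
                            end = start + w), g)
}

# O(n*m) overlap oracle on half-open intervals
bf_count_overlaps <- function(q, s, count_once = TRUE) {
  total <- 0
  for (i in seq_len(nrow(q))) {
    hits <- sum(s$chrom == q$chrom[i] & s$start < q$end[i] &
                  s$end > q$start[i])
    total <- total + if (count_once) as.numeric(hits > 0) else hits
  }
  total
}

# O(n*m) nearest-gap oracle (within chromosome; NA when none)
bf_nearest <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    j <- which(s$chrom == q$chrom[i])
    if (length(j) == 0) return(NA_real_)
    gaps <- vapply(j, function(k) {
      if (s$start[k] < q$end[i] && s$end[k] > q$start[i]) return(0)
      if (s$start[k] >= q$end[i]) s$start[k] - q$end[i] else
        q$start[i] - s$end[k]
    }, numeric(1))
    min(gaps)
  }, numeric(1))
}

# Textbook Benjamini-Hochberg step-up, written independently of p.adjust
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Total bp covered by a region set (union of its intervals)
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(unlist(lapply(split(x, x$chrom), function(d) {
    o <- order(d$start)
    s <- d$start[o]; e <- d$end[o]
    tot <- 0; cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e) { tot <- tot + cur_e - cur_s; cur_s <- s[i]; cur_e <- e[i] }
      else cur_e <- max(cur_e, e[i])
    }
    tot + cur_e - cur_s
  })))
}

region_keys <- function(x) paste(x$chrom, x$start, x$end)

quiet_permtest <- function(...) {
  suppressWarnings(permutation_test(...))
}
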