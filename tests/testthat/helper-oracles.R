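# Independent oracles the interval algebra and alignment code are checked
# against: per-base boolean arrays and a quadratic LCS dynamic program.
# These deliberately share no code with the package internals.

# boolean occupancy vector of one chromosome
oracle_vec <- function(x, chrom, len) {
  v <- logical(len)
  x <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(x)))
    if (x$end[i] > x$start[i]) v[(x$start[i] + 1):x$end[i]] <- TRUE
  v
}

oracle_total_bases <- function(x, index) {
  sum(vapply(seq_len(nrow(index)), function(k)
    sum(oracle_vec(x, index$chrom[k], index$length[k])), numeric(1)))
}

oracle_intersect_bases <- function(a, b, index) {
  sum(vapply(seq_len(nrow(index)), function(k)
    sum(oracle_vec(a, index$chrom[k], index$length[k]) &
        oracle_vec(b, index$chrom[k], index$length[k])), numeric(1)))
}

# merged intervals recovered from the boolean vector via run-length encoding
oracle_merge <- function(x, index) {
  out <- list()
  for (k in seq_len(nrow(index))) {
    v <- oracle_vec(x, index$chrom[k], index$length[k])
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    on <- r$values
    if (any(on))
      out[[k]] <- data.frame(chrom = index$chrom[k],
                             start = as.numeric(starts[on]),
                             end = as.numeric(ends[on]),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  do.call(rbind, out)
}

oracle_coverage_fraction <- function(target, mask, index) {
  chrom <- target$chrom[1]
  len <- index$length[index$chrom == chrom]
  v <- oracle_vec(mask, chrom, len)
  sum(v[(target$start[1] + 1):target$end[1]]) / (target$end[1] - target$start[1])
}

# textbook O(nm) LCS dynamic program on token vectors (length only)
oracle_lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n))
    for (j in seq_len(m))
      d[i + 1, j + 1] <- if (a[i] == b[j]) d[i, j] + 1L
                         else max(d[i, j + 1], d[i + 1, j])
  d[n + 1, m + 1]
}

# random interval fixture on a small genome
rand_intervals <- function(index, n_max = 50, max_len = 300) {
  n <- sample.int(n_max, 1)
  chrom <- sample(index$chrom, n, replace = TRUE)
  clen <- index$length[match(chrom, index$chrom)]
  start <- floor(runif(n) * (clen - 1))
  end <- pmin(clen, start + sample.int(max_len, n, replace = TRUE))
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

# small gene-model table builder
gm <- function(gene, tx, chrom, start, end, strand = "+") {
  data.frame(gene_id = gene, transcript_id = tx, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# small annotation builder
ra <- function(chrom, start, end, cls = "LINE", sf = "CR1", src = "toolA") {
  repeat_annotation(chrom, start, end, cls, sf, src)
}

# label of the singleton a tool is first merged with in an hclust tree,
# NA when its first merge is with a non-singleton cluster
first_merge_partner <- function(hc, tool) {
  lab <- hc$labels; m <- hc$merge
  for (r in seq_len(nrow(m))) {
    a <- m[r, 1]; b <- m[r, 2]
    hit_a <- a < 0 && lab[-a] == tool
    hit_b <- b < 0 && lab[-b] == tool
    if (hit_a || hit_b) {
      other <- if (hit_a) b else a
      return(if (other < 0) lab[-other] else NA_character_)
    }
  }
  NA_character_
}
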