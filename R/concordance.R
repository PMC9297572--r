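#' Binarize repeat masks over a window grid
#'
#' Encodes, for every window and every annotation source, whether the window
#' contains repeat-masked sequence: entry 1 when at least `min_bases` bases of
#' the window are masked (default 1, the plain any-overlap reading of
#' "contained repeats"), 0 otherwise. An element spanning a window boundary
#' sets both windows.
#'
#' @param sets list of repeat annotation data.frames (one per tool); names
#'   default to each set's `source` field.
#' @param grid window grid from [make_windows()].
#' @param index genome index the grid was built on.
#' @param min_bases minimum masked bases for a window to count as present.
#' @return List with `grid`, `methods` (sorted source names) and `values`, the
#'   window x method 0/1 integer matrix.
#' @export
binarize_windows <- function(sets, grid, index, min_bases = 1) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(sets, function(s)
      if (nrow(s)) s$source[1] else "unnamed", "")
  if (anyDuplicated(names(sets))) stop("duplicated method names")
  methods <- sort(names(sets), method = "radix")
  vals <- matrix(0L, nrow = nrow(grid), ncol = length(methods),
                 dimnames = list(NULL, methods))
  for (m in methods) {
    validate_annotation(sets[[m]], index)
    covered <- .window_covered_bases(grid, sets[[m]], index)
    vals[, m] <- as.integer(covered >= min_bases)
  }
  list(grid = grid, methods = methods, values = vals)
}

#' Cluster annotation methods by window presence profiles
#'
#' Agglomerative complete-linkage clustering of the methods on the Euclidean
#' distances between their binary window vectors. Methods are ordered
#' lexicographically before clustering so the result is deterministic and
#' invariant under permutation of the input.
#'
#' @param pm presence matrix from [binarize_windows()].
#' @return An [stats::hclust] object; `$height` holds the merge heights
#'   (Euclidean distances), non-decreasing under complete linkage.
#' @export
cluster_methods <- function(pm) {
  if (length(pm$methods) < 2) stop("need at least 2 methods to cluster")
  v <- pm$values[, sort(colnames(pm$values), method = "radix"), drop = FALSE]
  stats::hclust(stats::dist(t(v), method = "euclidean"), method = "complete")
}

#' Most abundant presence/absence patterns
#'
#' Counts the distinct 0/1 row patterns of the presence matrix and returns the
#' `top_k` most frequent ones, ties broken by lexicographic pattern order. The
#' all-zero pattern (windows masked by no method) is excluded: the comparison
#' concerns repeat-containing windows only.
#'
#' @param pm presence matrix from [binarize_windows()].
#' @param top_k number of patterns to report (default 20).
#' @return data.frame with columns `pattern` (string of 0/1 in method order,
#'   e.g. `"1100"`), one logical-ish column per method, and `count`.
#' @export
pattern_abundance <- function(pm, top_k = 20) {
  if (top_k < 1) stop("top_k must be >= 1")
  key <- apply(pm$values, 1, paste0, collapse = "")
  zero <- strrep("0", length(pm$methods))
  key <- key[key != zero]
  if (length(key) == 0)
    return(data.frame(pattern = character(), count = integer()))
  tab <- table(key)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  tab <- tab[ord][seq_len(min(top_k, length(tab)))]
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  bits <- do.call(rbind, strsplit(out$pattern, ""))
  for (j in seq_along(pm$methods))
    out[[pm$methods[j]]] <- as.integer(bits[, j])
  out[, c("pattern", pm$methods, "count")]
}

#' Agreement of one repeat mask with a reference mask
#'
#' Base-level mode (default): the fraction of the compared method's masked
#' bases that are also masked by the reference -- asymmetric by design, the
#' denominator is the compared method. Window-level mode: the fraction of the
#' compared method's presence windows that the reference also marks present
#' (requires `grid` and `index`).
#'
#' @param a repeat annotation data.frame (the compared method).
#' @param reference repeat annotation data.frame (the reference method).
#' @param mode `"base"` or `"window"`.
#' @param grid,index window grid and genome index, window mode only.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_agreement <- function(a, reference, mode = c("base", "window"),
                               grid = NULL, index = NULL) {
  mode <- match.arg(mode)
  if (mode == "base") {
    denom <- total_masked_bases(a)
    if (denom == 0) stop("compared annotation set is empty; agreement undefined")
    intersect_length(a[, c("chrom", "start", "end")],
                     reference[, c("chrom", "start", "end")]) / denom
  } else {
    if (is.null(grid) || is.null(index))
      stop("window mode requires grid and index")
    wa <- .window_covered_bases(grid, a, index) >= 1
    wr <- .window_covered_bases(grid, reference, index) >= 1
    if (!any(wa)) stop("compared annotation set is empty; agreement undefined")
    sum(wa & wr) / sum(wa)
  }
}

#' Per-method masked-base summary
#'
#' For each annotation set, the merged masked bases and the fraction of the
#' total genome they span.
#'
#' @param sets list of repeat annotation data.frames.
#' @param index genome index.
#' @return data.frame with columns `method`, `masked_bp`, `genome_fraction`,
#'   sorted by decreasing masked bases.
#' @export
coverage_summary <- function(sets, index) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(sets, function(s)
      if (nrow(s)) s$source[1] else "unnamed", "")
  gsize <- sum(index$length)
  bp <- vapply(sets, function(s) {
    validate_annotation(s, index)
    total_masked_bases(s)
  }, numeric(1))
  out <- data.frame(method = names(sets), masked_bp = unname(bp),
                    genome_fraction = unname(bp) / gsize,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$masked_bp, out$method, method = "radix"), ]
  rownames(out) <- NULL
  out
}
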