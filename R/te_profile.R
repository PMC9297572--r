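#' Per-class composition summary of an annotation set
#'
#' Two views of how the masked sequence splits across TE classes: merged
#' masked bases per class (overlapping or nested elements of one class are
#' counted once) and raw element counts per class. Classes are merged
#' independently, so the per-class base counts need not sum to the total
#' merged mask.
#'
#' @param aset repeat annotation data.frame.
#' @param merge_penelope collapse Penelope elements into LINE before
#'   summarizing (some classifiers cannot separate the two orders).
#' @return data.frame with columns `te_class`, `masked_bp`, `n_elements`,
#'   sorted by decreasing masked bases; empty for an empty set.
#' @export
composition_summary <- function(aset, merge_penelope = FALSE) {
  validate_annotation(aset)
  if (nrow(aset) == 0)
    return(data.frame(te_class = character(), masked_bp = numeric(),
                      n_elements = integer(), stringsAsFactors = FALSE))
  cls <- aset$te_class
  if (merge_penelope) cls[cls == "Penelope"] <- "LINE"
  out <- do.call(rbind, lapply(split(seq_len(nrow(aset)), cls), function(i) {
    data.frame(te_class = cls[i[1]],
               masked_bp = total_masked_bases(aset[i, , drop = FALSE]),
               n_elements = length(i), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$masked_bp, out$te_class, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Chromosomal density profile of one TE class
#'
#' For each window of the grid, the fraction of the window covered by the
#' merged elements of one TE class -- the per-window coverage-fraction view
#' used to examine arm/center enrichment along chromosomes.
#'
#' @param aset repeat annotation data.frame.
#' @param grid window grid from [make_windows()] (typically 5-kb windows).
#' @param te_class a single TE class name.
#' @param index genome index the grid was built on.
#' @param merge_penelope treat Penelope elements as LINEs.
#' @return data.frame `chrom`, `start`, `end`, `covered_bp`, `fraction`, one
#'   row per window in grid order. `sum(covered_bp)` equals the class's
#'   merged masked bases exactly.
#' @export
density_profile <- function(aset, grid, te_class, index, merge_penelope = FALSE) {
  validate_annotation(aset, index)
  if (length(te_class) != 1 || !(te_class %in% TE_CLASSES))
    stop("te_class must be one of: ", paste(TE_CLASSES, collapse = ", "))
  cls <- aset$te_class
  if (merge_penelope) cls[cls == "Penelope"] <- "LINE"
  sel <- aset[cls == te_class, c("chrom", "start", "end"), drop = FALSE]
  covered <- .window_covered_bases(grid, sel, index)
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             covered_bp = covered,
             fraction = covered / (grid$end - grid$start),
             stringsAsFactors = FALSE)
}
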