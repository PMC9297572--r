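#' Assign genes to phylostratigraphic age classes
#'
#' Given a gene x species table of homology hits over a species ladder ordered
#' from the nearest relative (index 1) to the most distant (index K), each
#' gene's age class is the largest species index with a qualifying hit, or 0
#' when no species has one (a focal-species-specific gene). Gaps in the hit
#' row do not matter: only the most distant hit counts.
#'
#' The table may be boolean (0/1, logical) or hold e-values, in which case a
#' hit is a value strictly below `evalue_threshold`.
#'
#' @param hits matrix or data.frame, rows = genes (rownames or a `gene_id`
#'   column), columns = species in ladder order.
#' @param species_order optional character vector naming the ladder order;
#'   defaults to the column order of `hits`.
#' @param evalue_threshold strict upper bound for an e-value to count as a
#'   hit (default 1e-5); ignored for boolean tables.
#' @return data.frame `gene_id`, `age_class` (integer in `[0, K]`).
#' @export
assign_age_classes <- function(hits, species_order = NULL,
                               evalue_threshold = 1e-5) {
  if (is.data.frame(hits)) {
    if ("gene_id" %in% names(hits)) {
      rn <- hits$gene_id
      hits <- as.matrix(hits[, setdiff(names(hits), "gene_id"), drop = FALSE])
      rownames(hits) <- rn
    } else hits <- as.matrix(hits)
  }
  if (is.null(rownames(hits))) rownames(hits) <- paste0("g", seq_len(nrow(hits)))
  if (!is.null(species_order)) {
    if (!setequal(species_order, colnames(hits)) ||
        anyDuplicated(species_order))
      stop("species_order must be a permutation of the hit-table columns")
    hits <- hits[, species_order, drop = FALSE]
  }
  if (anyNA(hits))
    stop("gene(s) with missing entries: ",
         paste(utils::head(rownames(hits)[rowSums(is.na(hits)) > 0], 5),
               collapse = ", "))
  is_hit <- if (is.logical(hits)) hits
            else if (all(hits %in% c(0, 1))) hits == 1
            else hits < evalue_threshold
  K <- ncol(hits)
  age <- apply(is_hit, 1, function(r) { w <- which(r); if (length(w)) max(w) else 0L })
  data.frame(gene_id = rownames(hits), age_class = as.integer(age),
             stringsAsFactors = FALSE)
}

#' Repeat contribution per age class
#'
#' Cross-tabulates gene age classes against the repeat classes their exons
#' overlap: for every age class and TE class, the number of genes with at
#' least one qualifying overlap and the fraction of the age class they
#' represent. A gene overlapping several TE classes counts once per class; an
#' empty age class reports `NA` fractions rather than 0.
#'
#' @param assign age-class assignment from [assign_age_classes()].
#' @param overlap_classes data.frame `gene_id`, `te_class` (one row per gene
#'   x overlapping class, e.g. distilled from [exon_coverage_overlaps()]
#'   records via `unique(records[, c("gene_id", "te_class")])`). Every gene id
#'   must be present in `assign`.
#' @param te_classes TE classes to tabulate; defaults to those observed.
#' @return data.frame `age_class`, `n_genes` (class size), `te_class`,
#'   `n_overlapping`, `fraction`, covering every age class 0..K present in
#'   `assign` crossed with every TE class.
#' @export
repeat_contribution_by_age <- function(assign, overlap_classes,
                                       te_classes = NULL) {
  unknown <- setdiff(overlap_classes$gene_id, assign$gene_id)
  if (length(unknown))
    stop("overlap gene id(s) missing from age-class assignment: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(te_classes))
    te_classes <- sort(unique(overlap_classes$te_class), method = "radix")
  ages <- sort(unique(assign$age_class))
  size <- table(factor(assign$age_class, levels = ages))
  age_of <- stats::setNames(assign$age_class, assign$gene_id)
  out <- expand.grid(age_class = ages, te_class = te_classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  oc <- unique(overlap_classes[, c("gene_id", "te_class")])
  oc$age_class <- age_of[oc$gene_id]
  key <- paste(out$age_class, out$te_class)
  cnt <- table(paste(oc$age_class, oc$te_class))
  out$n_genes <- as.integer(size[as.character(out$age_class)])
  out$n_overlapping <- as.integer(cnt[key])
  out$n_overlapping[is.na(out$n_overlapping)] <- 0L
  out$fraction <- ifelse(out$n_genes > 0, out$n_overlapping / out$n_genes, NA_real_)
  out <- out[order(out$age_class, out$te_class, method = "radix"),
             c("age_class", "n_genes", "te_class", "n_overlapping", "fraction")]
  rownames(out) <- NULL
  out
}

#' Read a gene x species hit table TSV
#'
#' First column `gene_id`, then one column per species in ladder order
#' (nearest relative first); entries 0/1 or e-values.
#'
#' @param path TSV file path.
#' @return data.frame suitable for [assign_age_classes()].
#' @export
read_hit_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
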