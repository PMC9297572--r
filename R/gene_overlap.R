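#' Merge isoforms of each gene into one non-redundant transcript
#'
#' Replaces every gene's transcripts with a single synthetic transcript
#' (`<gene_id>.merged`) whose exons are the merged union of all isoform
#' exons, the standard way to build a non-redundant exon set before overlap
#' analysis.
#'
#' @param genes gene-model data.frame (see [read_gene_gff3()]).
#' @return Gene-model data.frame with one transcript per gene.
#' @export
merge_isoforms <- function(genes) {
  validate_gene_models(genes)
  if (nrow(genes) == 0) return(genes)
  pieces <- lapply(split(seq_len(nrow(genes)), genes$gene_id), function(i) {
    g <- genes[i, , drop = FALSE]
    m <- merge_intervals(g[, c("chrom", "start", "end")])
    data.frame(gene_id = g$gene_id[1],
               transcript_id = paste0(g$gene_id[1], ".merged"),
               chrom = m$chrom, start = m$start, end = m$end,
               strand = g$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$gene_id, out$start, method = "radix"), ]
  rownames(out) <- NULL
  out
}

## Shared core: per (exon, te_class) coverage fractions plus superfamily
## attribution. Returns one row per exon x class with any overlap at all;
## callers filter by fraction. Superfamily is attributed to the raw element
## with the largest overlap (ties -> lexicographically first; all tied labels
## kept in superfamily_ties).
.exon_class_overlaps <- function(genes, aset, raw_elements = FALSE) {
  ex_gr <- .as_gr(genes)
  len <- genes$end - genes$start
  recs <- list()
  for (cls in sort(unique(aset$te_class), method = "radix")) {
    els <- aset[aset$te_class == cls, , drop = FALSE]
    el_gr <- .as_gr(els[, c("chrom", "start", "end")])
    if (raw_elements) {
      ## coverage against individual raw elements: per exon, the best single
      ## element determines the fraction
      hits <- GenomicRanges::findOverlaps(ex_gr, el_gr)
      if (length(hits) == 0) next
      ov <- GenomicRanges::width(IRanges::pintersect(
        ex_gr[S4Vectors::queryHits(hits)], el_gr[S4Vectors::subjectHits(hits)]))
      best_ov <- tapply(ov, S4Vectors::queryHits(hits), max)
      exon_idx <- as.integer(names(best_ov))
      frac <- as.numeric(best_ov) / len[exon_idx]
    } else {
      merged <- merge_intervals(els[, c("chrom", "start", "end")])
      mg <- .as_gr(merged)
      hits <- GenomicRanges::findOverlaps(ex_gr, mg)
      if (length(hits) == 0) next
      ov <- GenomicRanges::width(IRanges::pintersect(
        ex_gr[S4Vectors::queryHits(hits)], mg[S4Vectors::subjectHits(hits)]))
      covered <- tapply(ov, S4Vectors::queryHits(hits), sum)
      exon_idx <- as.integer(names(covered))
      frac <- as.numeric(covered) / len[exon_idx]
    }
    ## superfamily attribution from raw elements
    rhits <- GenomicRanges::findOverlaps(ex_gr[exon_idx], el_gr)
    sfam <- rep("", length(exon_idx))
    sties <- rep("", length(exon_idx))
    if (length(rhits)) {
      rov <- GenomicRanges::width(IRanges::pintersect(
        ex_gr[exon_idx][S4Vectors::queryHits(rhits)],
        el_gr[S4Vectors::subjectHits(rhits)]))
      for (k in unique(S4Vectors::queryHits(rhits))) {
        sel <- S4Vectors::queryHits(rhits) == k
        w <- rov[sel]
        fams <- els$superfamily[S4Vectors::subjectHits(rhits)[sel]]
        best <- sort(unique(fams[w == max(w)]), method = "radix")
        sfam[k] <- best[1]
        sties[k] <- paste(best, collapse = ",")
      }
    }
    recs[[cls]] <- data.frame(
      gene_id = genes$gene_id[exon_idx],
      transcript_id = genes$transcript_id[exon_idx],
      chrom = genes$chrom[exon_idx],
      start = genes$start[exon_idx], end = genes$end[exon_idx],
      te_class = cls, superfamily = sfam, superfamily_ties = sties,
      covered_fraction = frac, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      te_class = character(), superfamily = character(),
                      superfamily_ties = character(),
                      covered_fraction = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out <- out[order(out$te_class, out$gene_id, out$transcript_id, out$start,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Single-exon transcripts fully contained in repeats
#'
#' Finds exons of single-exon transcripts that are completely covered by the
#' repeat mask of a TE class -- the strictest overlap rule, used to nominate
#' actively transcribed transposons. By default containment is tested against
#' the merged per-class mask so fragmented annotations of one element still
#' count; `raw_elements = TRUE` instead requires containment within a single
#' raw element (the behaviour of an element-wise intersection with full
#' overlap required).
#'
#' @param genes gene-model data.frame restricted to single-exon transcripts;
#'   any multi-exon transcript is an error.
#' @param aset repeat annotation data.frame.
#' @param raw_elements test containment against raw elements rather than the
#'   merged per-class mask.
#' @return Overlap-record data.frame (one row per exon x class) with
#'   `covered_fraction == 1`; superfamily attributed to the element with the
#'   largest overlap, ties listed in `superfamily_ties`.
#' @export
fully_contained_overlaps <- function(genes, aset, raw_elements = FALSE) {
  validate_gene_models(genes)
  validate_annotation(aset)
  n_ex <- table(genes$transcript_id)
  if (any(n_ex > 1))
    stop("multi-exon transcript(s) in input: ",
         paste(utils::head(names(n_ex)[n_ex > 1], 5), collapse = ", "),
         "; full-containment analysis is defined for single-exon transcripts")
  recs <- .exon_class_overlaps(genes, aset, raw_elements = raw_elements)
  recs[recs$covered_fraction >= 1, , drop = FALSE]
}

#' Exons covered by repeats above a minimum fraction
#'
#' Finds (exon, class) pairs where the merged per-class repeat mask covers at
#' least `min_frac` of the exon; the boundary is inclusive ("at least 50%"
#' includes exactly 50%). Run on isoform-merged gene models
#' (see [merge_isoforms()]) for a non-redundant exon set.
#'
#' @param genes gene-model data.frame.
#' @param aset repeat annotation data.frame.
#' @param min_frac minimum covered fraction, in (0, 1] (default 0.5).
#' @param raw_elements require the coverage to come from a single raw element.
#' @return Overlap-record data.frame as in [fully_contained_overlaps()];
#'   a gene "overlaps repeats" when it contributes at least one record.
#' @export
exon_coverage_overlaps <- function(genes, aset, min_frac = 0.5,
                                   raw_elements = FALSE) {
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("min_frac must be in (0, 1]")
  validate_gene_models(genes)
  validate_annotation(aset)
  recs <- .exon_class_overlaps(genes, aset, raw_elements = raw_elements)
  recs[recs$covered_fraction >= min_frac, , drop = FALSE]
}

#' Gene ids flagged as overlapping repeats
#'
#' @param records overlap-record data.frame.
#' @return Sorted unique gene ids with at least one qualifying exon record.
#' @export
overlapping_genes <- function(records) {
  sort(unique(records$gene_id), method = "radix")
}

#' Tally transcripts per superfamily with an abundance cutoff
#'
#' Counts distinct transcripts per (class, superfamily) over a set of overlap
#' records -- each transcript counted once per superfamily however many
#' records support it -- and retains superfamilies with at least `min_count`
#' transcripts (default 20, the usual cutoff for calling a superfamily a
#' strong candidate for activity). Classes without superfamilies (simple
#' repeats, low-complexity) do not appear.
#'
#' @param records overlap-record data.frame.
#' @param min_count minimum number of distinct transcripts.
#' @return data.frame `te_class`, `superfamily`, `n_transcripts`, sorted by
#'   decreasing count then superfamily.
#' @export
superfamily_tally <- function(records, min_count = 20) {
  r <- records[nzchar(records$superfamily), , drop = FALSE]
  r <- unique(r[, c("transcript_id", "te_class", "superfamily")])
  if (nrow(r) == 0)
    return(data.frame(te_class = character(), superfamily = character(),
                      n_transcripts = integer(), stringsAsFactors = FALSE))
  key <- paste(r$te_class, r$superfamily, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(te_class = vapply(parts, `[`, "", 1),
                    superfamily = vapply(parts, `[`, "", 2),
                    n_transcripts = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[out$n_transcripts >= min_count, , drop = FALSE]
  out <- out[order(-out$n_transcripts, out$superfamily, method = "radix"), ]
  rownames(out) <- NULL
  out
}
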