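#' Construct a per-species gene order
#'
#' A gene order lists, per scaffold, genes in their physical order along with
#' the ortholog-family token each belongs to (`UNASSIGNED` for genes outside
#' any family). Family tokens, not gene ids, are the currency of gene-order
#' alignment.
#'
#' @param species species name.
#' @param scaffold,position,gene_id,family per-gene vectors; `position` is the
#'   ordinal rank within the scaffold.
#' @return data.frame `species`, `scaffold`, `position`, `gene_id`, `family`.
#' @export
gene_order <- function(species, scaffold, position, gene_id, family) {
  x <- data.frame(species = species, scaffold = as.character(scaffold),
                  position = as.integer(position),
                  gene_id = as.character(gene_id),
                  family = as.character(family), stringsAsFactors = FALSE)
  if (anyDuplicated(x$gene_id)) stop("gene ids must be unique within a species")
  x[order(x$scaffold, x$position, method = "radix"), ]
}

#' Read a per-species gene order TSV
#'
#' Columns: `scaffold`, `position`, `gene_id`, `family`.
#'
#' @param path TSV file path (header required).
#' @param species species name to attach.
#' @return Gene-order data.frame.
#' @export
read_gene_order <- function(path, species) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  gene_order(species, tab$scaffold, tab$position, tab$gene_id, tab$family)
}

## Longest strictly increasing subsequence of distinct integers, returning
## the element indices (patience sorting, O(n log n)).
.lis <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- integer(0)      # smallest tail value of an increasing subseq of each length
  tails_idx <- integer(0)  # index into x of that tail
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 1L, tails)  # tails < x[i]
    prev[i] <- if (j > 0) tails_idx[j] else 0L
    tails[j + 1] <- x[i]
    tails_idx[j + 1] <- i
    length(tails) <- length(tails_idx) <- max(length(tails), j + 1)
  }
  out <- integer(length(tails))
  k <- tails_idx[length(tails_idx)]
  for (p in rev(seq_along(out))) { out[p] <- k; k <- prev[k] }
  out
}

## Family tokens eligible as anchors on one scaffold: assigned families
## occurring exactly once.
.anchor_candidates <- function(fams) {
  fams <- fams[fams != "UNASSIGNED"]
  names(table(fams))[table(fams) == 1]
}

#' Align two gene orders on a scaffold pair
#'
#' Finds the longest common subsequence of anchor-candidate family tokens
#' between two scaffolds. Anchor candidates are families present exactly once
#' in each scaffold (multi-copy families, e.g. transposons, never anchor);
#' since candidates are single-copy in both orders, the LCS reduces to a
#' longest increasing subsequence of matched positions. Both the forward and
#' the reversed orientation of `b` are tried and the longer chain kept.
#'
#' @param a,b gene-order data.frames (one species each).
#' @param scaffold_a,scaffold_b scaffold names; default to the single
#'   scaffold present.
#' @return data.frame `family`, `pos_a`, `pos_b`, ordered along `a`, with
#'   attribute `orientation` (`"forward"` or `"reverse"`).
#' @export
align_gene_orders <- function(a, b, scaffold_a = NULL, scaffold_b = NULL) {
  pick <- function(x, sc) {
    if (is.null(sc)) {
      sc <- unique(x$scaffold)
      if (length(sc) != 1) stop("several scaffolds present; name one")
    }
    y <- x[x$scaffold == sc, , drop = FALSE]
    if (nrow(y) == 0) stop("empty scaffold: ", sc)
    y[order(y$position), , drop = FALSE]
  }
  sa <- pick(a, scaffold_a)
  sb <- pick(b, scaffold_b)
  cand <- intersect(.anchor_candidates(sa$family), .anchor_candidates(sb$family))
  fa <- sa$family[sa$family %in% cand]
  pa <- sa$position[sa$family %in% cand]
  chain_for <- function(pos_b_order) {
    m <- match(fa, pos_b_order)          # b-rank of each a-token
    idx <- .lis(m)
    idx
  }
  fb <- sb$family[sb$family %in% cand]
  pb <- stats::setNames(sb$position[sb$family %in% cand], fb)
  idx_f <- chain_for(fb)
  idx_r <- chain_for(rev(fb))
  if (length(idx_r) > length(idx_f)) {
    idx <- idx_r; orientation <- "reverse"
  } else {
    idx <- idx_f; orientation <- "forward"
  }
  out <- data.frame(family = fa[idx], pos_a = pa[idx],
                    pos_b = unname(pb[fa[idx]]), stringsAsFactors = FALSE)
  attr(out, "orientation") <- orientation
  out
}

#' Detect focal-lineage-specific insertions in conserved synteny
#'
#' Screens each focal scaffold for runs of genes from `target_families`
#' (typically a transposon family) that sit between two anchors adjacent in
#' both the focal-vs-outgroup-1 and focal-vs-outgroup-2 gene-order
#' alignments, with at most `max_gap` intervening non-target genes, while no
#' member of a target family lies between the corresponding anchors in either
#' outgroup -- i.e. synteny is conserved between the outgroups and broken
#' only by the focal insertion.
#'
#' @param focal,out1,out2 gene-order data.frames (one species each).
#' @param target_families character vector of family tokens to screen for.
#' @param max_gap maximum non-target, non-anchor genes tolerated between the
#'   flanking anchors (default 2, absorbing small local rearrangements).
#' @return data.frame with one row per call: `scaffold`, `gene_ids`
#'   (comma-separated focal genes of the run), `family` (their families),
#'   `left_anchor`, `right_anchor`, `supported_by` (comma-separated outgroup
#'   species). Scaffolds with fewer than two usable anchors are skipped with
#'   a warning.
#' @export
detect_lineage_specific_insertions <- function(focal, out1, out2,
                                               target_families, max_gap = 2) {
  calls <- list()
  for (sc in unique(focal$scaffold)) {
    fs <- focal[focal$scaffold == sc, , drop = FALSE]
    fs <- fs[order(fs$position), , drop = FALSE]
    ## pick, per outgroup, the scaffold sharing most anchor candidates
    pick_sc <- function(og) {
      cand_f <- .anchor_candidates(fs$family)
      shared <- vapply(split(og$family, og$scaffold), function(f)
        length(intersect(cand_f, .anchor_candidates(f))), integer(1))
      if (length(shared) == 0 || max(shared) == 0) return(NULL)
      names(shared)[which.max(shared)]
    }
    sc1 <- pick_sc(out1); sc2 <- pick_sc(out2)
    if (is.null(sc1) || is.null(sc2)) {
      warning("scaffold ", sc, ": no matching outgroup scaffold; skipped")
      next
    }
    al1 <- align_gene_orders(fs, out1, sc, sc1)
    al2 <- align_gene_orders(fs, out2, sc, sc2)
    common <- intersect(al1$family, al2$family)
    if (length(common) < 2) {
      warning("scaffold ", sc, ": fewer than 2 shared anchors; skipped")
      next
    }
    anch <- al1[al1$family %in% common, , drop = FALSE]
    anch <- anch[order(anch$pos_a), , drop = FALSE]
    o1 <- out1[out1$scaffold == sc1, , drop = FALSE]
    o2 <- out2[out2$scaffold == sc2, , drop = FALSE]
    pos_in <- function(og, fam) og$position[og$family == fam][1]
    for (k in seq_len(nrow(anch) - 1)) {
      L <- anch$family[k]; R <- anch$family[k + 1]
      between <- fs[fs$position > anch$pos_a[k] &
                    fs$position < anch$pos_a[k + 1], , drop = FALSE]
      run <- between[between$family %in% target_families, , drop = FALSE]
      if (nrow(run) == 0) next
      n_other <- nrow(between) - nrow(run)
      if (n_other > max_gap) next
      clean <- vapply(list(o1, o2), function(og) {
        p <- sort(c(pos_in(og, L), pos_in(og, R)))
        mid <- og$family[og$position > p[1] & og$position < p[2]]
        !any(mid %in% target_families)
      }, logical(1))
      if (!all(clean)) next
      calls[[length(calls) + 1]] <- data.frame(
        scaffold = sc,
        gene_ids = paste(run$gene_id, collapse = ","),
        family = paste(sort(unique(run$family), method = "radix"), collapse = ","),
        left_anchor = L, right_anchor = R,
        supported_by = paste(out1$species[1], out2$species[1], sep = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0)
    return(data.frame(scaffold = character(), gene_ids = character(),
                      family = character(), left_anchor = character(),
                      right_anchor = character(), supported_by = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
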