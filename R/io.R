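#' Read a genome index TSV
#'
#' Two-column tab-separated file `chrom<TAB>length`, the format written by
#' `samtools faidx` restricted to its first two columns. Lines starting with
#' `#` are skipped.
#'
#' @param path file path.
#' @return Genome index data.frame (see [genome_index()]).
#' @export
read_genome_index <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                           colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  genome_index(tab$chrom, tab$length)
}

#' Write a genome index TSV
#' @param index genome index data.frame.
#' @param path output path.
#' @export
write_genome_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Split a RepeatMasker-style "class/superfamily" name into its two parts.
## Names without a slash are a bare class; a slash inside the superfamily
## (rare) is kept verbatim.
.split_repeat_name <- function(name) {
  cls <- sub("/.*$", "", name)
  fam <- ifelse(grepl("/", name, fixed = TRUE), sub("^[^/]*/", "", name), "")
  list(te_class = cls, superfamily = fam)
}

#' Read repeat annotations from a BED file
#'
#' Expects a BED6-like dialect: chrom, start, end, name, score, strand, with
#' the name field carrying RepeatMasker-style `class/superfamily` labels
#' (e.g. `LINE/CR1`, or a bare class like `Simple_repeat`). Fewer than six
#' columns are tolerated down to BED3 (missing names become class `Unknown`).
#' Header lines starting with `#` and `track`/`browser` lines are skipped.
#' Coordinates are kept in the file's native 0-based half-open convention.
#'
#' @param path BED file path.
#' @param source tool name attached to every element; defaults to the file's
#'   base name without extension.
#' @param index optional genome index; elements beyond chromosome ends are
#'   rejected with the offending line numbers.
#' @return Repeat annotation data.frame.
#' @export
read_repeat_bed <- function(path, source = NULL, index = NULL) {
  if (is.null(source))
    source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(repeat_annotation(character(), numeric(), numeric(), source = source))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("malformed BED line (fewer than 3 fields) at line ",
         lnum[which(nf < 3)[1]], " of ", path)
  chrom <- vapply(parts, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric BED coordinate at line ",
         lnum[which(is.na(start) | is.na(end))[1]], " of ", path)
  name <- ifelse(nf >= 4, vapply(parts, function(p) p[4], ""), "Unknown")
  name[!nzchar(name) | name == "."] <- "Unknown"
  lab <- .split_repeat_name(name)
  bad <- !(lab$te_class %in% TE_CLASSES)
  lab$superfamily[bad] <- ""
  lab$te_class[bad] <- "Unknown"
  x <- repeat_annotation(chrom, start, end, lab$te_class, lab$superfamily,
                         source = source)
  validate_annotation(x, index)
  x
}

#' Write repeat annotations to a BED file
#'
#' Inverse of [read_repeat_bed()]: emits BED6 with `class/superfamily` (or a
#' bare class) in the name field, `.` score and `.` strand. `write` then
#' `read` is the identity on canonical records.
#'
#' @param aset repeat annotation data.frame.
#' @param path output path.
#' @export
write_repeat_bed <- function(aset, path) {
  validate_annotation(aset)
  name <- ifelse(nzchar(aset$superfamily),
                 paste0(aset$te_class, "/", aset$superfamily), aset$te_class)
  out <- data.frame(aset$chrom, format(aset$start, scientific = FALSE, trim = TRUE),
                    format(aset$end, scientific = FALSE, trim = TRUE),
                    name, ".", ".", stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features (via rtracklayer) into a flat exon table.
#' GFF3 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention at this boundary. Exons are attached to their
#' transcript through `Parent`, transcripts to their gene likewise; exons
#' whose parent transcript has no gene parent are grouped under the
#' transcript id itself.
#'
#' @param path GFF3 file path.
#' @param index optional genome index for validation.
#' @return Gene-model data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, one row per exon, exons sorted and
#'   non-overlapping within each transcript.
#' @export
read_gene_gff3 <- function(path, index = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  tx <- gr[typ %in% c("mRNA", "transcript")]
  tx_parent <- vapply(as.list(tx$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  tx2gene <- stats::setNames(tx_parent, as.character(tx$ID))
  ex <- gr[typ == "exon"]
  if (length(ex) == 0)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  ex_tx <- vapply(as.list(ex$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  if (anyNA(ex_tx)) stop("exon without Parent attribute in ", path)
  gene <- tx2gene[ex_tx]
  gene[is.na(gene)] <- ex_tx[is.na(gene)]
  out <- data.frame(gene_id = unname(gene), transcript_id = ex_tx,
                    chrom = as.character(GenomeInfoDb::seqnames(ex)),
                    start = GenomicRanges::start(ex) - 1,
                    end = as.numeric(GenomicRanges::end(ex)),
                    strand = as.character(GenomicRanges::strand(ex)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$transcript_id, out$start, method = "radix"), ]
  rownames(out) <- NULL
  validate_gene_models(out, index)
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA and exon features with ID/Parent attributes; internal
#' 0-based half-open exons are converted back to GFF3 1-based inclusive.
#'
#' @param genes gene-model data.frame (see [read_gene_gff3()]).
#' @param path output path.
#' @export
write_gene_gff3 <- function(genes, path) {
  validate_gene_models(genes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- character(0)
  ## span per gene / transcript
  for (gid in unique(genes$gene_id)) {
    gx <- genes[genes$gene_id == gid, , drop = FALSE]
    lines <- c(lines, paste(gx$chrom[1], "teconcord", "gene",
                            min(gx$start) + 1, max(gx$end), ".", gx$strand[1], ".",
                            paste0("ID=", gid), sep = "\t"))
    for (tid in unique(gx$transcript_id)) {
      tx <- gx[gx$transcript_id == tid, , drop = FALSE]
      lines <- c(lines, paste(tx$chrom[1], "teconcord", "mRNA",
                              min(tx$start) + 1, max(tx$end), ".", tx$strand[1], ".",
                              paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
      lines <- c(lines, paste(tx$chrom, "teconcord", "exon",
                              tx$start + 1, tx$end, ".", tx$strand, ".",
                              paste0("ID=", tid, ".exon", seq_len(nrow(tx)),
                                     ";Parent=", tid), sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Validate a gene-model table
#'
#' Enforces the gene-model invariants: valid exon intervals, each transcript
#' belonging to exactly one gene, and exons within a transcript sorted and
#' non-overlapping.
#'
#' @param genes gene-model data.frame.
#' @param index optional genome index.
#' @return `genes`, invisibly.
#' @export
validate_gene_models <- function(genes, index = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (nrow(genes) == 0) return(invisible(genes))
  validate_intervals(genes, index)
  tg <- unique(genes[, c("gene_id", "transcript_id")])
  if (anyDuplicated(tg$transcript_id))
    stop("transcript assigned to more than one gene")
  ov <- vapply(split(seq_len(nrow(genes)), genes$transcript_id), function(i) {
    s <- sort(genes$start[i]); e <- genes$end[i][order(genes$start[i])]
    length(i) > 1 && any(s[-1] < e[-length(e)])
  }, logical(1))
  if (any(ov))
    stop("overlapping exons within transcript(s): ",
         paste(utils::head(names(ov)[ov], 5), collapse = ", "))
  invisible(genes)
}
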