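## Order-level TE labels map deterministically onto the two class-level
## groups used for consensus voting; everything else is Other_Unknown.
.ORDER_TO_CLASS <- c(DNA = "DNA_transposon", RC_Helitron = "DNA_transposon",
                     LINE = "Retrotransposon", LTR = "Retrotransposon",
                     SINE = "Retrotransposon", Penelope = "Retrotransposon")

#' Map order-level TE labels to class level
#'
#' LINE/LTR/SINE/Penelope are retrotransposons (class I); DNA and
#' rolling-circle/Helitron are DNA transposons (class II); anything else
#' (including Unknown) maps to `Other_Unknown`.
#'
#' @param order_label character vector of order-level labels.
#' @return Character vector of `DNA_transposon`, `Retrotransposon`,
#'   `Other_Unknown`.
#' @export
order_to_class <- function(order_label) {
  out <- unname(.ORDER_TO_CLASS[order_label])
  out[is.na(out)] <- "Other_Unknown"
  out
}

## Validate and normalize a label table: element_id, method, order_label in
## long format; adds class_label.
.check_label_table <- function(lt) {
  need <- c("element_id", "method", "order_label")
  stopifnot(is.data.frame(lt), all(need %in% names(lt)))
  if (nrow(lt) == 0) stop("empty label table")
  if (anyDuplicated(lt[, c("element_id", "method")]))
    stop("duplicated (element, method) label")
  n_per <- table(lt$element_id)
  if (length(unique(n_per)) != 1)
    stop("element(s) missing a label from some method")
  lt$class_label <- order_to_class(lt$order_label)
  lt
}

#' Cross-classification matrix between two methods
#'
#' Contingency matrix of one method's labels (rows) against another's
#' (columns), with row-normalized fractions -- the standard way to ask where
#' one classifier's calls end up under another.
#'
#' @param lt label table: data.frame `element_id`, `method`, `order_label`.
#' @param method_a,method_b method names (rows, columns).
#' @param level `"order"` (default) or `"class"`.
#' @return List with `counts` (matrix, grand total = number of elements) and
#'   `fractions` (rows summing to 1 where nonempty).
#' @export
cross_classification_matrix <- function(lt, method_a, method_b,
                                        level = c("order", "class")) {
  level <- match.arg(level)
  lt <- .check_label_table(lt)
  if (!all(c(method_a, method_b) %in% lt$method))
    stop("unknown method name(s): ",
         paste(setdiff(c(method_a, method_b), lt$method), collapse = ", "))
  col <- if (level == "order") "order_label" else "class_label"
  a <- lt[lt$method == method_a, ]
  b <- lt[lt$method == method_b, ]
  lab_b <- stats::setNames(b[[col]], b$element_id)[a$element_id]
  lv <- sort(unique(c(a[[col]], lab_b)), method = "radix")
  counts <- table(factor(a[[col]], levels = lv), factor(lab_b, levels = lv))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c(method_a, method_b)
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, fractions = fractions)
}

#' Majority-vote consensus labels
#'
#' For each element, the label shared by at least two of the three voting
#' methods; `AMBIGUOUS` when all three disagree (at class level this can only
#' happen through `Other_Unknown`).
#'
#' @param lt label table with exactly three methods.
#' @param level voting granularity, `"class"` (default, the evaluation grain)
#'   or `"order"`.
#' @return data.frame `element_id`, `consensus`, `unanimous` (logical).
#' @export
majority_vote <- function(lt, level = c("class", "order")) {
  level <- match.arg(level)
  lt <- .check_label_table(lt)
  if (length(unique(lt$method)) != 3)
    stop("majority vote requires exactly 3 methods, got ",
         length(unique(lt$method)))
  col <- if (level == "class") "class_label" else "order_label"
  ids <- sort(unique(lt$element_id), method = "radix")
  votes <- split(lt[[col]], lt$element_id)[ids]
  consensus <- vapply(votes, function(v) {
    tab <- table(v)
    if (max(tab) >= 2) names(tab)[which.max(tab)] else "AMBIGUOUS"
  }, "")
  unanimous <- vapply(votes, function(v) length(unique(v)) == 1, logical(1))
  data.frame(element_id = ids, consensus = unname(consensus),
             unanimous = unname(unanimous), stringsAsFactors = FALSE)
}

#' Consensus evaluation report for three classifiers
#'
#' Computes the unanimity rate (fraction of elements on which all three
#' methods give the same class-level label) and a per-method error rate: the
#' fraction of elements where the method's class label differs from the
#' reference. The reference is external truth when supplied (e.g. labels
#' derived from protein-domain evidence), otherwise the majority-vote
#' consensus; elements whose consensus is `AMBIGUOUS` (or without a truth
#' label) are excluded from the error denominators.
#'
#' @param lt label table with exactly three methods.
#' @param truth optional named character vector, element_id -> class-level
#'   label.
#' @return List with `n_elements`, `unanimity_rate`, `error_rates` (named by
#'   method), `reference` (`"truth"` or `"consensus"`) and `n_evaluated`.
#' @export
consensus_report <- function(lt, truth = NULL) {
  lt <- .check_label_table(lt)
  methods <- sort(unique(lt$method), method = "radix")
  if (length(methods) != 3)
    stop("consensus report requires exactly 3 methods")
  mv <- majority_vote(lt, level = "class")
  if (is.null(truth)) {
    ref <- stats::setNames(mv$consensus, mv$element_id)
    ref <- ref[ref != "AMBIGUOUS"]
    ref_kind <- "consensus"
  } else {
    ref <- truth[names(truth) %in% mv$element_id]
    ref_kind <- "truth"
  }
  err <- vapply(methods, function(m) {
    x <- lt[lt$method == m & lt$element_id %in% names(ref), ]
    mean(x$class_label != ref[x$element_id])
  }, numeric(1))
  list(n_elements = nrow(mv),
       unanimity_rate = mean(mv$unanimous),
       error_rates = err,
       reference = ref_kind,
       n_evaluated = length(ref))
}

#' Read a classifier label table TSV
#'
#' Long format: `element_id`, `method`, `order_label`, one row per element
#' per method.
#'
#' @param path TSV file path.
#' @return Label table data.frame.
#' @export
read_label_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
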