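#' Score a single gene pair in one sample
#'
#' The elementary rank-based comparison: 1 when the first gene is expressed
#' strictly above the second within the same sample, 0 otherwise. Ties score
#' 0 (they fall under "otherwise"), which matters for clipped microarray
#' values.
#'
#' @param x_first,x_second finite expression values from the same sample.
#' @return integer 0 or 1.
#' @export
score_pair <- function(x_first, x_second) {
  if (!all(is.finite(x_first)) || !all(is.finite(x_second)))
    stop2("expression values must be finite")
  as.integer(x_first > x_second)
}

#' Enumerate candidate gene pairs
#'
#' Forms every pair whose first member is a prognostic gene and whose second
#' member is any other gene of the candidate universe. When both genes of an
#' unordered pair are prognostic the two orientations are redundant (their
#' score rows are complements, hence collinear), so exactly one is kept:
#' the orientation whose first gene has the smaller univariate Cox p-value
#' when `gene_pvalues` is supplied, with lexicographic order breaking
#' residual ties.
#'
#' For `|P|` prognostic genes inside `|G|` total genes the pair count is
#' `|P| * |G| - |P| - choose(|P|, 2)`.
#'
#' @param prognostic_genes character vector, subset of `all_genes`.
#' @param all_genes character vector, the full candidate gene universe.
#' @param gene_pvalues optional named numeric vector of per-gene screening
#'   p-values used to orient double-prognostic pairs.
#' @return data frame of class `gene_pair_set` with columns `first`,
#'   `second`.
#' @export
enumerate_candidate_pairs <- function(prognostic_genes, all_genes,
                                      gene_pvalues = NULL) {
  if (anyDuplicated(all_genes)) stop2("all_genes contains duplicates")
  missing <- setdiff(prognostic_genes, all_genes)
  if (length(missing))
    stop2("prognostic gene(s) absent from all_genes: ",
          paste(missing, collapse = ", "))
  if (!length(prognostic_genes))
    return(new_gene_pair_set(character(), character()))
  first <- rep(prognostic_genes, each = length(all_genes))
  second <- rep(all_genes, times = length(prognostic_genes))
  keep <- first != second
  first <- first[keep]; second <- second[keep]
  both_prog <- first %in% prognostic_genes & second %in% prognostic_genes
  # canonical orientation for double-prognostic pairs
  ord_first <- orient_first(first, second, gene_pvalues)
  dup <- both_prog & !ord_first
  new_gene_pair_set(first[!dup], second[!dup])
}

# TRUE when `a` should come first in the canonical orientation of {a, b}.
orient_first <- function(a, b, gene_pvalues) {
  if (!is.null(gene_pvalues)) {
    pa <- gene_pvalues[a]; pb <- gene_pvalues[b]
    cmp <- ifelse(is.na(pa) | is.na(pb) | pa == pb, a < b, pa < pb)
  } else {
    cmp <- a < b
  }
  as.logical(cmp)
}

new_gene_pair_set <- function(first, second) {
  structure(data.frame(first = as.character(first),
                       second = as.character(second),
                       stringsAsFactors = FALSE),
            class = c("gene_pair_set", "data.frame"))
}

pair_names <- function(pairs) paste(pairs$first, pairs$second, sep = "|")

# Parse "A|B" row names back into a gene_pair_set.
pairs_from_names <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  new_gene_pair_set(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Build the binary pair-score matrix
#'
#' Entry (p, s) is 1 when the first gene of pair p is expressed strictly
#' above the second in sample s. Because only within-sample orderings enter,
#' the result is invariant under any strictly increasing per-sample
#' transform of the expression matrix.
#'
#' @param expr genes x samples numeric matrix.
#' @param pairs a `gene_pair_set` (see [enumerate_candidate_pairs()]).
#' @return integer matrix (pairs x samples), rownames `"FIRST|SECOND"`.
#' @export
build_pair_matrix <- function(expr, pairs) {
  check_expression_matrix(expr)
  missing <- setdiff(unique(c(pairs$first, pairs$second)), rownames(expr))
  if (length(missing))
    stop2("gene(s) missing from expression matrix: ",
          paste(missing, collapse = ", "))
  if (!nrow(pairs)) {
    return(matrix(integer(), nrow = 0L, ncol = ncol(expr),
                  dimnames = list(character(), colnames(expr))))
  }
  if (any(!is.finite(expr[unique(c(pairs$first, pairs$second)), ])))
    stop2("expression values must be finite for all paired genes")
  m <- (expr[pairs$first, , drop = FALSE] >
          expr[pairs$second, , drop = FALSE]) * 1L
  storage.mode(m) <- "integer"
  dimnames(m) <- list(pair_names(pairs), colnames(expr))
  m
}

#' Remove near-constant gene pairs
#'
#' A pair whose score is the same in more than `threshold` of samples
#' carries almost no between-sample information and is removed ("abolished").
#' The inequality is strict: a pair whose majority class is exactly at the
#' threshold is retained. Row order of survivors is preserved, and the
#' filter is idempotent.
#'
#' @param m binary pair-score matrix (pairs x samples).
#' @param threshold majority-frequency cutoff in \[0.5, 1); default 0.70.
#' @return the filtered matrix; an empty input passes through unchanged.
#' @export
consistency_filter <- function(m, threshold = 0.70) {
  if (threshold < 0.5 || threshold >= 1)
    stop2("threshold must be in [0.5, 1)")
  if (!nrow(m)) return(m)
  ones <- rowMeans(m)
  majority <- pmax(ones, 1 - ones)
  m[majority <= threshold, , drop = FALSE]
}
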