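#' Build an alignment ensemble for functional-impact scoring
#'
#' Materializes, from a protein multiple alignment containing the query
#' (mutated) sequence, the per-column residue counts over the whole family
#' and within each subfamily. These counts — `n_i(alpha)` for column `i` and
#' residue type `alpha` over a 21-letter alphabet (20 amino acids + gap) —
#' are the sufficient statistics of the functional impact score. Residue
#' characters outside the 20 standard amino acids (X, B, Z, ...) are counted
#' as gaps.
#'
#' Subfamily labels may be supplied (the first-class path, e.g. from a
#' dedicated specificity-aware clustering tool). When absent, a baseline
#' clustering is computed: average-linkage hierarchical clustering on
#' pairwise sequence-identity distance, cut into `n_subfamilies` clusters
#' (capped at the number of sequences). This is deterministic given the
#' input order.
#'
#' @param alignment Named character vector of equal-length aligned sequences.
#' @param query_id Identifier of the query sequence within `alignment`.
#' @param subfamilies Optional vector of per-sequence subfamily labels, in
#'   alignment order (or named by sequence id).
#' @param n_subfamilies Cluster count for the baseline clustering when
#'   `subfamilies` is absent.
#' @return An object of class `fis_ensemble`.
#' @seealso [score_mutation()], [score_table()]
#' @export
build_ensemble <- function(alignment, query_id, subfamilies = NULL,
                           n_subfamilies = 4) {
  if (length(alignment) == 0) abort("alignment is empty")
  if (is.null(names(alignment))) abort("alignment sequences must be named")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) {
    abort("ragged alignment: sequences differ in length")
  }
  qi <- match(query_id, names(alignment))
  if (is.na(qi)) abort(paste0("query_id '", query_id, "' not found in alignment"))

  n <- length(alignment)
  L <- widths[1]
  seq_mat <- matrix(unlist(strsplit(toupper(alignment), "")), nrow = n, byrow = TRUE)
  seq_mat[!seq_mat %in% AA_ALPHABET] <- "-"

  if (is.null(subfamilies)) {
    labels <- baseline_subfamilies(seq_mat, min(n_subfamilies, n))
  } else {
    if (!is.null(names(subfamilies))) {
      subfamilies <- subfamilies[names(alignment)]
      if (anyNA(subfamilies)) abort("subfamily labels missing for some sequences")
    }
    if (length(subfamilies) != n) {
      abort("subfamilies must have one label per sequence")
    }
    labels <- match(subfamilies, unique(subfamilies))
  }

  counts <- column_counts(seq_mat)
  P <- max(labels)
  subfam <- array(0L, dim = c(length(AA_ALPHABET), L, P),
                  dimnames = list(AA_ALPHABET, NULL, NULL))
  for (p in seq_len(P)) {
    subfam[, , p] <- column_counts(seq_mat[labels == p, , drop = FALSE])
  }

  qchars <- seq_mat[qi, ]
  qmap <- which(qchars != "-") # ungapped query position -> alignment column

  structure(
    list(
      ids = names(alignment), n_seqs = n, n_cols = L,
      seq_mat = seq_mat,
      query_index = qi, query_map = qmap, query_res = qchars[qmap],
      labels = labels, query_subfamily = labels[qi],
      col_counts = counts, subfam_counts = subfam
    ),
    class = "fis_ensemble"
  )
}

column_counts <- function(seq_mat) {
  out <- vapply(
    seq_len(ncol(seq_mat)),
    function(j) tabulate(factor(seq_mat[, j], levels = AA_ALPHABET),
                         nbins = length(AA_ALPHABET)),
    integer(length(AA_ALPHABET))
  )
  rownames(out) <- AA_ALPHABET
  out
}

baseline_subfamilies <- function(seq_mat, k) {
  n <- nrow(seq_mat)
  if (n == 1 || k <= 1) return(rep(1L, n))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - mean(seq_mat[i, ] == seq_mat[j, ])
    }
  }
  hc <- hclust(as.dist(d), method = "average")
  unname(cutree(hc, k = min(k, n)))
}

#' @export
print.fis_ensemble <- function(x, ...) {
  cat("<fis_ensemble> ", x$n_seqs, " sequences x ", x$n_cols, " columns; ",
      max(x$labels), " subfamilies; query '", x$ids[x$query_index],
      "' (subfamily ", x$query_subfamily, ", ",
      length(x$query_map), " residues)\n", sep = "")
  invisible(x)
}
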