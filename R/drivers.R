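#' Rank genes by high-functional mutation burden
#'
#' Counts, per gene: `n_high` — high-functional mutations, i.e. missense
#' with FIS above `high_threshold` plus all truncating mutations (truncating
#' mutations are loss-of-function regardless of any score); `n_low` —
#' low-functional missense with FIS below `low_threshold`; and
#' `n_mm_tm` — all missense plus truncating mutations. Missense mutations
#' scoring inside the closed band `[low_threshold, high_threshold]` count in
#' neither `n_high` nor `n_low`: there the predicted impact is most
#' uncertain. A gene is flagged a potential passenger when
#' `n_low >= n_high` — evolutionarily selected genes should accumulate more
#' high- than low-functional mutations. (A gene with `n_high = n_low = 0`
#' is flagged by the literal rule; it also ranks last and cannot enter an
#' effective set.)
#'
#' @param records Scored mutation tibble.
#' @param high_threshold,low_threshold FIS thresholds (defaults 2.5 and 1.0,
#'   `low_threshold <= high_threshold`).
#' @return A tibble of class `gene_burden`, ordered by descending `n_high`,
#'   then descending `n_mm_tm`, then gene symbol: columns `gene`, `n_high`,
#'   `n_low`, `n_mm_tm`, `is_passenger_flagged`, `exceeds_long_gene_cutoff`
#'   (`NA` until [long_gene_filter()] is applied).
#' @export
rank_gene_burden <- function(records, high_threshold = 2.5, low_threshold = 1.0) {
  check_records(records)
  if (low_threshold > high_threshold) abort("low_threshold must be <= high_threshold")
  is_mm <- records$variant_class == "missense"
  is_tm <- records$variant_class == "truncating"
  if (!any(is_mm & !is.na(records$fis))) {
    abort("no scored missense records; run score_table() first")
  }
  scored <- !is.na(records$fis)
  df <- tibble(
    gene = records$gene,
    high = (is_mm & scored & records$fis > high_threshold) | is_tm,
    low = is_mm & scored & records$fis < low_threshold,
    mm_tm = is_mm | is_tm
  )
  out <- df |>
    filter(.data$mm_tm) |>
    group_by(.data$gene) |>
    summarise(n_high = sum(.data$high), n_low = sum(.data$low),
              n_mm_tm = sum(.data$mm_tm), .groups = "drop") |>
    mutate(is_passenger_flagged = .data$n_low >= .data$n_high,
           exceeds_long_gene_cutoff = NA) |>
    arrange(desc(.data$n_high), desc(.data$n_mm_tm), .data$gene)
  class(out) <- c("gene_burden", class(out))
  out
}

#' Nominate the effective gene set of candidate common drivers
#'
#' Computes the effective number of mutated genes \eqn{K = 1/\lambda} over a
#' chosen mutation basis — either all missense plus truncating mutations
#' (`"mm_tm"`) or high-FIS missense (FIS above `high_threshold`) plus
#' truncating (`"fis_tm"`) — rounds it half-up to an integer (floor 1), and
#' returns the top-\eqn{K} genes of the burden ranking as the nominated set
#' of candidate common drivers. Boundary ties are resolved by the ranking's
#' deterministic tie-break.
#'
#' @param records Scored mutation tibble.
#' @param basis `"fis_tm"` (default) or `"mm_tm"`.
#' @param high_threshold,low_threshold Passed to [rank_gene_burden()].
#' @param burdens Optional precomputed [rank_gene_burden()] result.
#' @return A `gene_burden` tibble of the nominated genes (in rank order),
#'   with attributes `k_eff` (real-valued \eqn{K}), `k_int` (the rounded
#'   set size) and `basis`.
#' @export
effective_gene_set <- function(records, basis = c("fis_tm", "mm_tm"),
                               high_threshold = 2.5, low_threshold = 1.0,
                               burdens = NULL) {
  basis <- match.arg(basis)
  check_records(records)
  fis_min <- if (basis == "fis_tm") high_threshold else NULL
  t <- tally_mutations(records, classes = c("missense", "truncating"),
                       fis_min = fis_min)
  if (attr(t, "M") < 1) {
    abort(paste0("basis '", basis, "' selects no mutations; cannot nominate"))
  }
  nu <- non_uniformity(t)
  k_int <- max(1L, as.integer(floor(nu$k_eff + 0.5))) # half-up, floor 1
  if (is.null(burdens)) {
    burdens <- rank_gene_burden(records, high_threshold, low_threshold)
  }
  out <- head(burdens, k_int)
  attr(out, "k_eff") <- nu$k_eff
  attr(out, "k_int") <- k_int
  attr(out, "basis") <- basis
  out
}

#' Percentage of passenger-flagged genes per gene set
#'
#' @param sets Named list of gene-symbol vectors (e.g. all mutated genes,
#'   the mm+tm effective set, the fis+tm effective set).
#' @param burdens A [rank_gene_burden()] result covering every set member.
#' @return Tibble with columns `set`, `size`, `n_flagged`, `pct`
#'   (`NA` for an empty set).
#' @export
passenger_summary <- function(sets, burdens) {
  stopifnot(is.list(sets), !is.null(names(sets)), inherits(burdens, "gene_burden"))
  flag <- setNames(burdens$is_passenger_flagged, burdens$gene)
  purrr::imap(sets, function(genes, nm) {
    genes <- normalize_gene(unique(genes))
    missing <- setdiff(genes, names(flag))
    if (length(missing) > 0) {
      abort(paste0("set '", nm, "' has genes without burden records: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    n_flag <- sum(flag[genes])
    tibble(set = nm, size = length(genes), n_flagged = n_flag,
           pct = if (length(genes) > 0) 100 * n_flag / length(genes) else NA_real_)
  }) |> bind_rows()
}

#' Flag (and optionally exclude) long genes
#'
#' Long genes accumulate high-functional mutations by chance and can be
#' falsely nominated as drivers. Genes with coding length strictly greater
#' than `cutoff` nucleotides are flagged. Flagging is the default; the
#' passenger rule, not removal, is the preferred guard, so exclusion is
#' opt-in.
#'
#' @param burdens A [rank_gene_burden()] result.
#' @param lengths Gene-length tibble ([read_gene_lengths()]).
#' @param cutoff Nucleotide cutoff (strict inequality).
#' @param exclude Drop flagged genes when `TRUE`.
#' @return `burdens` with `exceeds_long_gene_cutoff` filled. Genes without a
#'   length stay unflagged, with a warning.
#' @export
long_gene_filter <- function(burdens, lengths, cutoff = 15000, exclude = FALSE) {
  stopifnot(inherits(burdens, "gene_burden"))
  len <- setNames(lengths$coding_length, normalize_gene(lengths$gene))
  known <- burdens$gene %in% names(len)
  if (!all(known)) {
    warn(paste0(sum(!known), " gene(s) have no length; left unflagged: ",
                paste(head(burdens$gene[!known], 5), collapse = ", ")))
  }
  flag <- rep(FALSE, nrow(burdens))
  flag[known] <- len[burdens$gene[known]] > cutoff
  burdens$exceeds_long_gene_cutoff <- flag
  if (exclude) burdens <- filter(burdens, !.data$exceeds_long_gene_cutoff)
  burdens
}
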