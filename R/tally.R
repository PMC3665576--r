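#' Cumulative FIS bin specification
#'
#' Bins are cumulative lower bounds on the functional impact score:
#' `"all"` admits every scored missense mutation, `"FIS>2.5"` admits those
#' scoring above 2.5, and so on. The default unions the thresholds used
#' throughout the package's figures and tables.
#'
#' @param thresholds Strictly increasing numeric lower bounds.
#' @param include_all Prepend the `"all"` bin (lower bound `-Inf`).
#' @return A named numeric vector of lower bounds.
#' @export
fis_bins <- function(thresholds = c(1, 2, 2.5, 3, 3.5), include_all = TRUE) {
  thresholds <- as.numeric(thresholds)
  if (any(diff(thresholds) <= 0)) abort("bin thresholds must be strictly increasing")
  out <- thresholds
  names(out) <- paste0("FIS>", format(thresholds, trim = TRUE, drop0trailing = TRUE))
  if (include_all) out <- c(all = -Inf, out)
  out
}

#' Which genes belong to a gene group
#'
#' Groups are `all`, `TS` (tumor suppressors), `OG` (oncogenes), `CG`
#' (annotated cancer genes) and `nCG` (genes with no cancer annotation).
#' With no annotation table, every gene is `nCG`.
#'
#' @param genes Character vector of gene symbols.
#' @param group One of `"all"`, `"TS"`, `"OG"`, `"CG"`, `"nCG"`.
#' @param annotations A [read_gene_list()]-style tibble, or `NULL`.
#' @return Logical vector along `genes`.
#' @export
gene_in_group <- function(genes, group = c("all", "TS", "OG", "CG", "nCG"),
                          annotations = NULL) {
  group <- match.arg(group)
  if (group == "all") return(rep(TRUE, length(genes)))
  genes <- normalize_gene(genes)
  member <- function(col) {
    if (is.null(annotations)) rep(FALSE, length(genes))
    else genes %in% annotations$gene[annotations[[col]]]
  }
  switch(group,
         TS = member("ts"), OG = member("og"), CG = member("cg"),
         nCG = !member("cg"))
}

#' Tally mutations per gene
#'
#' Counts mutations per gene (`N_i`) for a filtered slice of a mutation
#' table: by mutation class, by a cumulative FIS lower bound, and by gene
#' group. The FIS bound applies only to missense records (truncating and
#' silent mutations carry no score); when a bound is given — including the
#' `"all"` bin's `-Inf` — unscored missense records are excluded rather than
#' imputed.
#'
#' @param records Mutation tibble.
#' @param classes Mutation classes to keep.
#' @param fis_min Lower FIS bound (exclusive) for missense records, or
#'   `NULL` for no score filtering.
#' @param gene_group,annotations See [gene_in_group()].
#' @return A `mutation_tally`: a tibble with columns `gene`, `n`, `p`
#'   (`p = N_i / M`), carrying attributes `M` (total mutations) and `Q`
#'   (number of mutated genes). An empty slice yields a valid zero-row tally
#'   with `M = 0`, which downstream statistics refuse.
#' @export
tally_mutations <- function(records, classes = "missense", fis_min = NULL,
                            gene_group = "all", annotations = NULL) {
  check_records(records)
  stopifnot(all(classes %in% MUTATION_CLASSES))
  keep <- records$variant_class %in% classes
  if (!is.null(fis_min)) {
    is_mm <- records$variant_class == "missense"
    keep <- keep & (!is_mm | (!is.na(records$fis) & records$fis > fis_min))
  }
  keep <- keep & gene_in_group(records$gene, gene_group, annotations)
  as_mutation_tally(count(tibble(gene = records$gene[keep]), .data$gene, name = "n"))
}

#' Construct a mutation tally from per-gene counts
#'
#' @param counts A tibble with columns `gene` and `n`, or a named numeric
#'   vector of per-gene counts.
#' @return A `mutation_tally` (see [tally_mutations()]). Genes with zero
#'   counts are dropped (they do not contribute to `Q`).
#' @export
as_mutation_tally <- function(counts) {
  if (is.numeric(counts)) {
    if (is.null(names(counts))) abort("counts vector must be named by gene")
    counts <- tibble(gene = names(counts), n = as.numeric(counts))
  }
  stopifnot(is.data.frame(counts), all(c("gene", "n") %in% names(counts)))
  if (any(counts$n < 0)) abort("mutation counts must be non-negative")
  counts <- filter(as_tibble(counts), .data$n > 0)
  m <- sum(counts$n)
  out <- mutate(counts[c("gene", "n")], p = if (m > 0) .data$n / m else numeric(0))
  structure(out, M = m, Q = nrow(out),
            class = c("mutation_tally", class(out)))
}

#' @export
print.mutation_tally <- function(x, ...) {
  cat("<mutation_tally> Q =", attr(x, "Q"), "genes, M =", attr(x, "M"),
      "mutations\n")
  NextMethod()
}
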