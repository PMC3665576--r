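#' Fraction of mutations hitting annotated cancer genes, by FIS bin
#'
#' For each cumulative FIS bin, the percentage of missense mutations in the
#' bin that affect genes of an annotation category (mutation-level counting).
#' Silent and truncating mutations provide unbinned reference percentages:
#' if high-scoring mutations are selected in cancer genes, the missense
#' percentages rise with the FIS threshold while the references stay flat.
#'
#' @param records Scored mutation tibble.
#' @param annotations [read_gene_list()] tibble.
#' @param category `"CG"`, `"TS"` or `"OG"`.
#' @param bins [fis_bins()] lower bounds.
#' @return A tibble of class `mutsel_fraction`: columns `class`, `bin`,
#'   `min_fis`, `n_mutations`, `n_in_category`, `pct`. Empty bins report
#'   `pct = NA` (absent), not zero.
#' @export
cancer_gene_fraction <- function(records, annotations,
                                 category = c("CG", "TS", "OG"),
                                 bins = fis_bins()) {
  check_records(records)
  category <- match.arg(category)
  in_cat <- gene_in_group(records$gene, category, annotations)

  one <- function(class, bin_label, fis_min) {
    keep <- records$variant_class == class
    if (!is.null(fis_min)) keep <- keep & !is.na(records$fis) & records$fis > fis_min
    n <- sum(keep)
    hit <- sum(keep & in_cat)
    tibble(class = class, bin = bin_label, min_fis = fis_min %||% NA_real_,
           n_mutations = n, n_in_category = hit,
           pct = if (n > 0) 100 * hit / n else NA_real_)
  }
  out <- bind_rows(
    bind_rows(unname(purrr::imap(bins, function(thr, lab) one("missense", lab, thr)))),
    one("silent", "silent", NULL),
    one("truncating", "truncating", NULL)
  )
  out$category <- category
  class(out) <- c("mutsel_fraction", class(out))
  out
}

#' Concurrency of high-FIS missense mutations with truncating mutations
#'
#' Gene-level counting: for each cumulative FIS bin, among genes of the
#' group carrying at least one missense mutation in the bin, the percentage
#' that also carry at least one truncating mutation detected in a different
#' tumor sample. A gene whose only missense and truncating hits come from
#' one and the same sample is not concurrent — concurrency is evidence of
#' recurrent, independent selection of loss of function.
#'
#' @param records Scored mutation tibble with `sample_id`.
#' @param bins [fis_bins()] lower bounds.
#' @param gene_group,annotations See [gene_in_group()].
#' @return A tibble of class `mutsel_concurrency`: columns `group`, `bin`,
#'   `min_fis`, `n_genes` (denominator), `n_concurrent`, `pct` (`NA` when
#'   the denominator is zero).
#' @export
truncating_concurrency <- function(records, bins = fis_bins(),
                                   gene_group = "all", annotations = NULL) {
  check_records(records)
  in_group <- gene_in_group(records$gene, gene_group, annotations)

  tm <- records[records$variant_class == "truncating" & in_group, c("gene", "sample_id")]
  tm_samples <- split(tm$sample_id, tm$gene)

  one <- function(bin_label, fis_min) {
    keep <- records$variant_class == "missense" & in_group &
      !is.na(records$fis) & records$fis > fis_min
    mm_samples <- split(records$sample_id[keep], records$gene[keep])
    n_genes <- length(mm_samples)
    conc <- purrr::imap_lgl(mm_samples, function(ms, g) {
      ts <- tm_samples[[g]]
      if (is.null(ts)) return(FALSE)
      ms <- unique(ms); ts <- unique(ts)
      # some missense/truncating pair must come from two different tumors
      !(length(ms) == 1 && length(ts) == 1 && ms == ts)
    })
    tibble(group = gene_group, bin = bin_label, min_fis = fis_min,
           n_genes = n_genes, n_concurrent = sum(conc),
           pct = if (n_genes > 0) 100 * sum(conc) / n_genes else NA_real_)
  }
  out <- bind_rows(unname(purrr::imap(bins, function(thr, lab) one(lab, thr))))
  class(out) <- c("mutsel_concurrency", class(out))
  out
}

#' Distribution of mutations over copy-number states, by class and FIS bin
#'
#' Joins each mutation to the discretized copy-number state of its (sample,
#' gene) pair and reports, per mutation class (and per cumulative FIS bin
#' for missense mutations), the percentage of the class's mutations falling
#' in genes of each state (-1 loss, 0 neutral, 1 gain, 2 amplification; the
#' four percentages sum to 100). Each class is compared with the silent
#' class — the no-selection control — by a two-sided Fisher exact test on
#' the 2x2 contingency of in-state vs out-of-state counts at state -1
#' (`p_loss`) and state +1 (`p_gain`).
#'
#' @param records Scored mutation tibble.
#' @param cna Long copy-number tibble from [read_cna_matrix()]
#'   (`sample_id`, `gene`, `state`).
#' @param bins [fis_bins()] lower bounds for the missense rows.
#' @return A tibble of class `mutsel_cna`: columns `class`, `bin`, `n`
#'   (joined mutations), `pct_loss`, `pct_neutral`, `pct_gain`, `pct_amp`,
#'   `p_loss`, `p_gain`. Mutations with no copy-number call are excluded
#'   (count reported via a message); with no joined records at all the
#'   computation is refused.
#' @export
cna_concurrency <- function(records, cna, bins = fis_bins()) {
  check_records(records)
  stopifnot(all(c("sample_id", "gene", "state") %in% names(cna)))
  joined <- inner_join(records, cna, by = c("sample_id", "gene"),
                       relationship = "many-to-one")
  n_dropped <- nrow(records) - nrow(joined)
  if (nrow(joined) == 0) abort("no mutation joins a copy-number call; check sample/gene ids")
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " mutation(s) without a copy-number call were excluded"))
  }

  state_counts <- function(keep) {
    vapply(c(-1L, 0L, 1L, 2L), function(s) sum(joined$state[keep] == s), 1L)
  }
  silent_counts <- state_counts(joined$variant_class == "silent")

  one <- function(class, bin_label, fis_min) {
    keep <- joined$variant_class == class
    if (!is.null(fis_min)) keep <- keep & !is.na(joined$fis) & joined$fis > fis_min
    cnt <- state_counts(keep)
    n <- sum(cnt)
    pvs <- c(NA_real_, NA_real_)
    if (class != "silent" && n > 0 && sum(silent_counts) > 0) {
      pvs <- vapply(c(1L, 3L), function(i) { # states -1 and +1
        tab <- matrix(c(cnt[i], n - cnt[i],
                        silent_counts[i], sum(silent_counts) - silent_counts[i]),
                      nrow = 2, byrow = TRUE)
        fisher.test(tab, alternative = "two.sided")$p.value
      }, 1.0)
    }
    tibble(class = class, bin = bin_label,
           min_fis = fis_min %||% NA_real_, n = n,
           pct_loss = if (n > 0) 100 * cnt[1] / n else NA_real_,
           pct_neutral = if (n > 0) 100 * cnt[2] / n else NA_real_,
           pct_gain = if (n > 0) 100 * cnt[3] / n else NA_real_,
           pct_amp = if (n > 0) 100 * cnt[4] / n else NA_real_,
           p_loss = pvs[1], p_gain = pvs[2])
  }
  out <- bind_rows(
    one("silent", "silent", NULL),
    one("truncating", "truncating", NULL),
    bind_rows(unname(purrr::imap(bins, function(thr, lab) one("missense", lab, thr))))
  )
  class(out) <- c("mutsel_cna", class(out))
  out
}
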