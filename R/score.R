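#' Functional impact score of a residue substitution
#'
#' Scores the substitution `ref_aa -> alt_aa` at 1-based protein position
#' `protein_pos` of the query sequence against the conservation pattern of
#' its protein family and of the query's subfamily:
#'
#' \deqn{FIS = -\frac{1}{2}\left[\ln\frac{n_i(\beta)+1}{n_i(\alpha)} +
#'   \ln\frac{n_{ip}(\beta)+1}{n_{ip}(\alpha)}\right]}
#'
#' where `n_i(.)` counts residue types in alignment column `i` over the whole
#' family and `n_ip(.)` within the query's subfamily `p`; natural logarithm;
#' the pseudocount applies to the alternate-residue counts only. Higher
#' scores mean the alternate residue is rarer, relative to the observed
#' reference residue, at an otherwise conserved position — a stronger
#' predicted functional impact. The score at a column depends only on that
#' column's counts.
#'
#' When the query's subfamily is a singleton, `n_ip(alpha) = 1` and the
#' subfamily term reduces to `-ln(n_ip(beta)+1)/2`; the score is computed as
#' written.
#'
#' @param ensemble A [build_ensemble()] result whose query carries `ref_aa`
#'   at the mapped column (a mismatch is a fatal data-integrity error, not a
#'   silent score).
#' @param protein_pos 1-based position in the ungapped query sequence.
#' @param ref_aa,alt_aa Single-letter residue codes; gaps cannot be scored.
#' @return A one-row tibble: `protein_pos`, `ref_aa`, `alt_aa`, `fis`,
#'   `family_term`, `subfamily_term` (the two halves of the score;
#'   `fis = family_term + subfamily_term`).
#' @export
score_mutation <- function(ensemble, protein_pos, ref_aa, alt_aa) {
  stopifnot(inherits(ensemble, "fis_ensemble"))
  res <- score_positions(ensemble, protein_pos, ref_aa, alt_aa)
  if (!is.na(res$error[1])) abort(res$error[1])
  tibble(protein_pos = as.integer(protein_pos),
         ref_aa = ref_aa, alt_aa = alt_aa,
         fis = res$fis, family_term = res$family, subfamily_term = res$subfamily)
}

# Vectorized core: returns fis/family/subfamily with per-element error
# messages (NA when scored). alpha counts carry no pseudocount; they are
# >= 1 whenever the query itself carries ref_aa at the column.
score_positions <- function(ensemble, protein_pos, ref_aa, alt_aa) {
  n <- length(protein_pos)
  fis <- family <- subfam <- rep(NA_real_, n)
  err <- rep(NA_character_, n)

  pos <- as.integer(protein_pos)
  bad_pos <- is.na(pos) | pos < 1L | pos > length(ensemble$query_map)
  err[bad_pos] <- paste0("position ", protein_pos[bad_pos],
                         " is outside the ungapped query (length ",
                         length(ensemble$query_map), ")")

  ref <- toupper(as.character(ref_aa))
  alt <- toupper(as.character(alt_aa))
  bad_res <- (!ref %in% setdiff(AA_ALPHABET, "-")) | (!alt %in% setdiff(AA_ALPHABET, "-"))
  err[!bad_pos & bad_res] <- "substitutions to or from a gap/unknown residue are not scored"

  ok <- !bad_pos & !bad_res
  if (any(ok)) {
    qres <- ensemble$query_res[pos[ok]]
    mism <- qres != ref[ok]
    if (any(mism)) {
      i <- which(ok)[mism]
      err[i] <- paste0("query residue mismatch at position ", pos[i],
                       ": expected ", ref[i], ", alignment has ",
                       ensemble$query_res[pos[i]])
      ok[i] <- FALSE
    }
  }
  if (any(ok)) {
    cols <- ensemble$query_map[pos[ok]]
    ri <- match(ref[ok], AA_ALPHABET)
    ai <- match(alt[ok], AA_ALPHABET)
    p <- ensemble$query_subfamily
    na  <- ensemble$col_counts[cbind(ri, cols)]
    nb  <- ensemble$col_counts[cbind(ai, cols)]
    npa <- ensemble$subfam_counts[cbind(ri, cols, p)]
    npb <- ensemble$subfam_counts[cbind(ai, cols, p)]
    family[ok] <- -0.5 * (log(nb + 1) - log(na))
    subfam[ok] <- -0.5 * (log(npb + 1) - log(npa))
    fis[ok] <- family[ok] + subfam[ok]
  }
  list(fis = fis, family = family, subfamily = subfam, error = err)
}

#' Score a mutation table against per-gene alignment ensembles
#'
#' Populates the `fis`, `family_term` and `subfamily_term` columns of
#' missense records whose gene has an ensemble. Silent, truncating and
#' `other` records keep `fis` absent (`NA`) — only amino-acid substitutions
#' are scorable. Missense records of genes without an ensemble, and records
#' that fail scoring (position out of range, reference-residue mismatch),
#' are skipped with warnings rather than errors; their `fis` stays `NA`.
#'
#' @param records A mutation tibble ([read_mutation_table()] layout).
#' @param ensembles Named list mapping gene symbol to [build_ensemble()]
#'   results.
#' @return `records` with score columns filled for scorable missense rows.
#'   Attribute `n_skipped` counts missense rows left unscored.
#' @export
score_table <- function(records, ensembles) {
  check_records(records)
  stopifnot(is.list(ensembles))
  names(ensembles) <- normalize_gene(names(ensembles))

  if (!"fis" %in% names(records)) records$fis <- NA_real_
  if (!"family_term" %in% names(records)) records$family_term <- NA_real_
  if (!"subfamily_term" %in% names(records)) records$subfamily_term <- NA_real_

  mm <- which(records$variant_class == "missense")
  no_ens <- mm[!records$gene[mm] %in% names(ensembles)]
  if (length(no_ens) > 0) {
    skipped <- count(tibble(gene = records$gene[no_ens]), .data$gene)
    warn(paste0("no alignment ensemble for ", nrow(skipped), " gene(s) (",
                sum(skipped$n), " missense record(s) left unscored): ",
                paste(head(skipped$gene, 5), collapse = ", ")))
  }
  todo <- setdiff(mm, no_ens)
  n_failed <- 0L
  for (g in unique(records$gene[todo])) {
    i <- todo[records$gene[todo] == g]
    res <- score_positions(ensembles[[g]], records$protein_pos[i],
                           records$ref_aa[i], records$alt_aa[i])
    records$fis[i] <- res$fis
    records$family_term[i] <- res$family
    records$subfamily_term[i] <- res$subfamily
    failed <- !is.na(res$error)
    if (any(failed)) {
      n_failed <- n_failed + sum(failed)
      warn(paste0("gene ", g, ": ", sum(failed), " missense record(s) not scored (",
                  res$error[which(failed)[1]], ")"))
    }
  }
  attr(records, "n_skipped") <- length(no_ens) + n_failed
  records
}
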