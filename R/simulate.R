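#' Specification of a synthetic tumor cohort
#'
#' Parameters of the cohort generator. Defaults emulate a mid-sized exome
#' cohort with a handful of strongly selected driver genes:
#' passenger mutations land on genes in proportion to coding length; driver
#' genes receive `selection_strength`-fold extra missense mutations placed
#' preferentially at conserved alignment positions (hence high FIS) and
#' extra truncating mutations; truncating mutations are up-weighted into
#' samples where the gene is in copy loss. Driver intensities are not
#' equal: relative rates follow a 1/rank power law (in real cohorts a few
#' genes dominate the driver burden), normalized so the mean driver
#' multiplier equals `selection_strength`.
#'
#' @param n_genes,n_driver_genes,n_samples Cohort dimensions.
#' @param muts_per_sample Mean somatic mutations per sample.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal coding-length
#'   distribution (nucleotides; floored at 300).
#' @param selection_strength Mean rate multiplier for driver-gene missense
#'   and truncating mutations (>= 1; 1 = no planted selection).
#' @param driver_rate_decay Exponent of the driver intensity power law.
#' @param driver_conserved_fraction Probability that a missense mutation in
#'   the strongest driver falls on a conserved alignment column. Each
#'   driver's conserved-placement probability scales with its relative
#'   selection intensity (its 1/rank weight), interpolating down towards
#'   `passenger_conserved_fraction`: strongly selected genes owe most of
#'   their burden to functional mutations, weakly selected ones mostly to
#'   background.
#' @param passenger_conserved_fraction Conserved-placement probability for
#'   non-driver genes; kept low (most passenger missense mutations score
#'   low).
#' @param silent_rate,truncating_rate Class proportions (remainder is
#'   missense).
#' @param driver_truncating_boost Extra loss-of-function multiplier applied
#'   on top of `selection_strength` for driver-gene truncating mutations
#'   (tumor-suppressor drivers are classically inactivated by truncation;
#'   their truncating excess exceeds their missense excess). Has no effect
#'   when `selection_strength = 1`.
#' @param cna_loss_enrichment Multiplier pulling truncating mutations into
#'   (gene, sample) pairs in copy loss (>= 1).
#' @param cna_state_probs Marginal probabilities of states -1, 0, 1, 2.
#' @param ts_extra_fraction,og_fraction,cg_fraction Annotation-list sizes as
#'   fractions of `n_genes`: tumor suppressors beyond the planted drivers
#'   (unselected TS, as in curated lists where few members are under
#'   selection in any one cancer), oncogenes, and total annotated cancer
#'   genes (a superset of TS and OG). Drivers are always annotated TS.
#' @param n_templates,template_n_seqs,template_n_cols,template_conserved_fraction,template_n_subfamilies
#'   Family-alignment templates reused across genes for scoring.
#' @param fis_mode `"score"` (score planted substitutions against the
#'   generated alignments — the end-to-end default) or `"sample"` (draw FIS
#'   from a calibrated mixture; fast path for large property sweeps).
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 1000, n_driver_genes = 10, n_samples = 100,
                        muts_per_sample = 50,
                        gene_length_meanlog = log(1500), gene_length_sdlog = 0.6,
                        selection_strength = 20,
                        driver_rate_decay = 1.25,
                        driver_conserved_fraction = 0.8,
                        passenger_conserved_fraction = 0.03,
                        silent_rate = 0.25, truncating_rate = 0.08,
                        driver_truncating_boost = 8,
                        cna_loss_enrichment = 2,
                        cna_state_probs = c(0.15, 0.65, 0.17, 0.03),
                        ts_extra_fraction = 0.04, og_fraction = 0.01,
                        cg_fraction = 0.15,
                        n_templates = 5, template_n_seqs = 80,
                        template_n_cols = 60,
                        template_conserved_fraction = 0.4,
                        template_n_subfamilies = 3,
                        fis_mode = c("score", "sample"),
                        seed = 1L) {
  spec <- list(
    n_genes = n_genes, n_driver_genes = n_driver_genes, n_samples = n_samples,
    muts_per_sample = muts_per_sample,
    gene_length_meanlog = gene_length_meanlog, gene_length_sdlog = gene_length_sdlog,
    selection_strength = selection_strength,
    driver_rate_decay = driver_rate_decay,
    driver_conserved_fraction = driver_conserved_fraction,
    passenger_conserved_fraction = passenger_conserved_fraction,
    silent_rate = silent_rate, truncating_rate = truncating_rate,
    driver_truncating_boost = driver_truncating_boost,
    cna_loss_enrichment = cna_loss_enrichment,
    cna_state_probs = cna_state_probs / sum(cna_state_probs),
    ts_extra_fraction = ts_extra_fraction, og_fraction = og_fraction,
    cg_fraction = cg_fraction,
    n_templates = n_templates, template_n_seqs = template_n_seqs,
    template_n_cols = template_n_cols,
    template_conserved_fraction = template_conserved_fraction,
    template_n_subfamilies = template_n_subfamilies,
    fis_mode = match.arg(fis_mode), seed = as.integer(seed)
  )
  with(spec, {
    stopifnot(n_genes >= 1, n_driver_genes >= 1, n_samples >= 1,
              muts_per_sample >= 1, n_driver_genes <= n_genes,
              selection_strength >= 1, driver_rate_decay >= 0,
              cna_loss_enrichment >= 1,
              driver_truncating_boost >= 1,
              silent_rate >= 0, truncating_rate >= 0,
              silent_rate + truncating_rate < 1,
              driver_conserved_fraction >= 0, driver_conserved_fraction <= 1,
              passenger_conserved_fraction >= 0, passenger_conserved_fraction <= 1,
              ts_extra_fraction >= 0, og_fraction >= 0, cg_fraction >= 0,
              cg_fraction <= 1,
              length(cna_state_probs) == 4, all(cna_state_probs >= 0),
              n_templates >= 1, template_n_subfamilies <= template_n_seqs)
  })
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic protein family alignment
#'
#' Columns come in three kinds: globally conserved (one consensus residue,
#' carried by at least 90% of sequences by construction), subfamily-specific
#' (a distinct consensus per subfamily), and variable (residues drawn
#' near-uniformly from a small per-column pool, with occasional gaps in
#' non-query sequences). The query is the first sequence, gap-free and
#' noise-free, so protein positions map 1:1 onto columns.
#'
#' @param n_seqs,n_cols Alignment dimensions.
#' @param conserved_fraction Fraction of globally conserved columns.
#' @param n_subfamilies Number of subfamilies (contiguous, near-equal).
#' @param subfamily_fraction Fraction of subfamily-specific columns.
#' @param gap_fraction Per-cell gap probability in variable columns
#'   (non-query sequences).
#' @param seed Integer seed (same seed, same bytes).
#' @return A list: `alignment` (named character vector, query first),
#'   `query_id`, `subfamilies` (integer labels), `conserved` (logical mask
#'   over columns), `column_type` (`"conserved"`, `"subfamily"`,
#'   `"variable"`).
#' @export
gen_alignment <- function(n_seqs = 60, n_cols = 60, conserved_fraction = 0.4,
                          n_subfamilies = 3, subfamily_fraction = 0.2,
                          gap_fraction = 0.03, seed = 1L) {
  if (n_subfamilies > n_seqs) abort("n_subfamilies cannot exceed n_seqs")
  if (conserved_fraction + subfamily_fraction > 1 + 1e-9) {
    abort("conserved_fraction + subfamily_fraction must be <= 1")
  }
  withr::local_seed(as.integer(seed))
  aa <- setdiff(AA_ALPHABET, "-")

  n_cons <- round(conserved_fraction * n_cols)
  n_sub <- min(n_cols - n_cons, round(subfamily_fraction * n_cols))
  type <- sample(c(rep("conserved", n_cons), rep("subfamily", n_sub),
                   rep("variable", n_cols - n_cons - n_sub)))
  labels <- sort(rep_len(seq_len(n_subfamilies), n_seqs))

  mat <- matrix("-", n_seqs, n_cols)
  max_noise <- max(0L, floor(0.08 * n_seqs)) # keeps conserved-majority >= 0.9
  for (j in seq_len(n_cols)) {
    if (type[j] == "conserved") {
      cons <- sample(aa, 1)
      col <- rep(cons, n_seqs)
      z <- min(max_noise, stats::rbinom(1, n_seqs, 0.04))
      if (z > 0) {
        i <- sample(2:n_seqs, z) # never the query
        col[i] <- sample(setdiff(aa, cons), z, replace = TRUE)
      }
    } else if (type[j] == "subfamily") {
      cons_p <- sample(aa, n_subfamilies)
      col <- cons_p[labels]
      z <- min(max_noise, stats::rbinom(1, n_seqs, 0.04))
      if (z > 0) {
        i <- sample(2:n_seqs, z)
        col[i] <- sample(aa, z, replace = TRUE)
      }
    } else {
      pool <- sample(aa, 15)
      col <- sample(pool, n_seqs, replace = TRUE)
      gapped <- which(stats::runif(n_seqs) < gap_fraction)
      col[setdiff(gapped, 1L)] <- "-"
    }
    mat[, j] <- col
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  ids <- c("query", sprintf("seq%03d", seq_len(n_seqs - 1) + 1))
  list(alignment = setNames(seqs, ids), query_id = "query",
       subfamilies = setNames(labels, ids),
       conserved = type == "conserved", column_type = type)
}

#' Generate a full synthetic cohort
#'
#' Draws every pipeline input from a [cohort_spec()]: a mutation table
#' (missense, silent, truncating), gene annotations (planted drivers
#' annotated TS, plus unenriched extra cancer genes), a discretized
#' copy-number matrix, a gene-length table, and the ground-truth driver set.
#' Missense FIS values are obtained by actually scoring the planted
#' substitutions against the template alignments (default), keeping the
#' scoring function in the loop end-to-end. Mutation protein positions live
#' on the template query (the per-gene protein model); coding lengths drive
#' only placement weights and the length table.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `mutations` (scored tibble), `annotations`, `cna` (long
#'   tibble), `cna_matrix` (genes x samples), `lengths`, `drivers`
#'   (ground-truth symbols), `templates`, `ensembles` (one per template),
#'   `gene_template` (template index per gene), `spec`.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)

  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- sprintf("S%04d", seq_len(spec$n_samples))
  lengths <- tibble(
    gene = genes,
    coding_length = pmax(300, round(rlnorm(spec$n_genes,
                                           spec$gene_length_meanlog,
                                           spec$gene_length_sdlog)))
  )

  drivers <- sort(sample(genes, spec$n_driver_genes))
  # power-law driver intensities interpolating from neutrality, so that the
  # mean driver multiplier is selection_strength and strength 1 is exactly null
  zipf <- seq_len(spec$n_driver_genes)^(-spec$driver_rate_decay)
  mult <- setNames(rep(1, spec$n_genes), genes)
  mult[drivers] <- 1 + (spec$selection_strength - 1) * zipf / mean(zipf)
  # conserved-placement probability per driver scales with relative intensity
  rel <- zipf / zipf[1]
  cons_prob <- setNames(rep(spec$passenger_conserved_fraction, spec$n_genes), genes)
  if (spec$selection_strength > 1) {
    cons_prob[drivers] <- spec$passenger_conserved_fraction +
      (spec$driver_conserved_fraction - spec$passenger_conserved_fraction) * rel
  }

  non_driver <- setdiff(genes, drivers)
  n_ts_extra <- min(length(non_driver), round(spec$ts_extra_fraction * spec$n_genes))
  ts_extra <- sample(non_driver, n_ts_extra)
  rest <- setdiff(non_driver, ts_extra)
  n_og <- min(length(rest), round(spec$og_fraction * spec$n_genes))
  og_genes <- sample(rest, n_og)
  rest <- setdiff(rest, og_genes)
  n_cg_extra <- min(length(rest), max(0, round(spec$cg_fraction * spec$n_genes) -
                                        spec$n_driver_genes - n_ts_extra - n_og))
  cg_extra <- sample(rest, n_cg_extra)
  ts_all <- c(drivers, ts_extra)
  annotations <- tibble(gene = sort(c(ts_all, og_genes, cg_extra))) |>
    mutate(ts = .data$gene %in% ts_all, og = .data$gene %in% og_genes, cg = TRUE)

  cna_matrix <- matrix(
    sample(c(-1L, 0L, 1L, 2L), spec$n_genes * spec$n_samples,
           replace = TRUE, prob = spec$cna_state_probs),
    nrow = spec$n_genes, dimnames = list(genes, samples)
  )
  cna <- tibble(
    sample_id = rep(samples, each = spec$n_genes),
    gene = rep(genes, spec$n_samples),
    state = as.integer(cna_matrix)
  )

  # template alignments + ensembles (supplied subfamily labels)
  templates <- purrr::map(seq_len(spec$n_templates), function(t) {
    gen_alignment(spec$template_n_seqs, spec$template_n_cols,
                  spec$template_conserved_fraction,
                  spec$template_n_subfamilies,
                  seed = spec$seed + 1000L + t)
  })
  ensembles <- purrr::map(templates, function(tpl) {
    build_ensemble(tpl$alignment, tpl$query_id, subfamilies = tpl$subfamilies)
  })
  gene_template <- ((seq_len(spec$n_genes) - 1L) %% spec$n_templates) + 1L
  names(gene_template) <- genes

  n_mut <- spec$n_samples * spec$muts_per_sample
  n_by_class <- as.integer(stats::rmultinom(
    1, n_mut, c(spec$silent_rate, spec$truncating_rate,
                1 - spec$silent_rate - spec$truncating_rate)
  ))
  len_w <- lengths$coding_length / sum(lengths$coding_length)

  # functional sites = family- or subfamily-conserved columns; background
  # mutations land on truly variable columns
  qres_of <- function(tpl) strsplit(tpl$alignment[[tpl$query_id]], "")[[1]]
  tpl_qres <- purrr::map(templates, qres_of)
  tpl_cons <- purrr::map(templates, function(t) which(t$column_type != "variable"))
  tpl_var <- purrr::map(templates, function(t) which(t$column_type == "variable"))
  aa <- setdiff(AA_ALPHABET, "-")

  draw_positions <- function(gene_idx, conserved_prob) {
    t_id <- gene_template[gene_idx]
    use_cons <- stats::runif(length(gene_idx)) < conserved_prob
    pos <- integer(length(gene_idx))
    for (i in seq_along(gene_idx)) {
      cand <- if (use_cons[i]) tpl_cons[[t_id[i]]] else tpl_var[[t_id[i]]]
      if (length(cand) == 0) cand <- seq_len(spec$template_n_cols)
      pos[i] <- cand[sample.int(length(cand), 1)]
    }
    pos
  }

  # silent: length-proportional, no enrichment, synonymous change
  n_sm <- n_by_class[1]
  sm_gene <- sample.int(spec$n_genes, n_sm, replace = TRUE, prob = len_w)
  sm_pos <- draw_positions(sm_gene, 0) # anywhere non-conserved-biased is fine
  sm_ref <- purrr::map2_chr(gene_template[sm_gene], sm_pos, function(t, p) tpl_qres[[t]][p])
  silent <- tibble(sample_id = sample(samples, n_sm, replace = TRUE),
                   gene = genes[sm_gene], protein_pos = sm_pos,
                   ref_aa = sm_ref, alt_aa = sm_ref, variant_class = "silent")

  # missense: drivers up-weighted by their intensity; conserved-column
  # placement probability differs for drivers vs passengers
  n_mm <- n_by_class[3]
  mm_w <- len_w * mult
  mm_gene <- sample.int(spec$n_genes, n_mm, replace = TRUE, prob = mm_w / sum(mm_w))
  mm_pos <- draw_positions(mm_gene, cons_prob[mm_gene])
  mm_ref <- purrr::map2_chr(gene_template[mm_gene], mm_pos, function(t, p) tpl_qres[[t]][p])
  mm_alt <- vapply(mm_ref, function(r) sample(setdiff(aa, r), 1), "",
                   USE.NAMES = FALSE)
  missense <- tibble(sample_id = sample(samples, n_mm, replace = TRUE),
                     gene = genes[mm_gene], protein_pos = mm_pos,
                     ref_aa = mm_ref, alt_aa = mm_alt, variant_class = "missense")

  # truncating: driver-enriched, pulled into copy-loss (gene, sample) pairs
  n_tm <- n_by_class[2]
  tm_w <- len_w * (1 + (mult - 1) * spec$driver_truncating_boost)
  tm_gene <- sample.int(spec$n_genes, n_tm, replace = TRUE, prob = tm_w / sum(tm_w))
  tm_sample <- vapply(tm_gene, function(g) {
    w <- ifelse(cna_matrix[g, ] == -1L, spec$cna_loss_enrichment, 1)
    sample.int(spec$n_samples, 1, prob = w)
  }, 1L)
  tm_pos <- draw_positions(tm_gene, 0)
  tm_ref <- purrr::map2_chr(gene_template[tm_gene], tm_pos, function(t, p) tpl_qres[[t]][p])
  truncating <- tibble(sample_id = samples[tm_sample], gene = genes[tm_gene],
                       protein_pos = tm_pos, ref_aa = tm_ref, alt_aa = "*",
                       variant_class = "truncating")

  mutations <- bind_rows(missense, silent, truncating) |>
    mutate(fis = NA_real_)

  if (spec$fis_mode == "score") {
    gene_ens <- setNames(ensembles[gene_template], genes)
    mutations <- score_table(mutations, gene_ens)
  } else {
    # calibrated two-component mixture standing in for column-level scoring
    mm_i <- which(mutations$variant_class == "missense")
    from_cons <- stats::runif(length(mm_i)) < cons_prob[mutations$gene[mm_i]]
    mutations$fis[mm_i] <- ifelse(from_cons,
                                  stats::rnorm(length(mm_i), 3.3, 0.5),
                                  stats::rnorm(length(mm_i), 0.1, 0.6))
  }

  list(mutations = mutations, annotations = annotations, cna = cna,
       cna_matrix = cna_matrix, lengths = lengths, drivers = drivers,
       templates = templates, ensembles = ensembles,
       gene_template = gene_template, spec = spec)
}

#' Write a miniature fixture bundle to disk
#'
#' Generates a small cohort and writes every input format the readers
#' accept: template alignments (FASTA) with a subfamily-label TSV, a
#' MAF-like mutation table (unscored), a gene list, a wide CNA matrix, a
#' gene-length table and the ground-truth driver list. Deterministic:
#' the same seed reproduces the directory byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param spec Optional [cohort_spec()]; the default is a miniature cohort
#'   that runs through the full pipeline in seconds.
#' @return Invisibly, a named list of the written paths.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L,
                               spec = cohort_spec(n_genes = 60, n_driver_genes = 5,
                                                  n_samples = 30, muts_per_sample = 20,
                                                  n_templates = 2,
                                                  template_n_seqs = 24,
                                                  seed = seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))
  co <- gen_cohort(spec)

  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  labels <- purrr::imap(co$templates, function(tpl, t) {
    fa <- file.path(aln_dir, sprintf("template%02d.fasta", t))
    writeLines(paste0(">", names(tpl$alignment), "\n", tpl$alignment), fa)
    tibble(template = sprintf("template%02d", t),
           seq_id = names(tpl$subfamilies), subfamily = unname(tpl$subfamilies))
  })
  readr::write_tsv(bind_rows(labels), file.path(out_dir, "subfamily_labels.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tibble(gene = names(co$gene_template),
           template = sprintf("template%02d", co$gene_template)),
    file.path(out_dir, "gene_templates.tsv"), progress = FALSE
  )

  unscored <- mutate(co$mutations, fis = NULL, family_term = NULL,
                     subfamily_term = NULL)
  write_mutation_table(unscored, file.path(out_dir, "mutations.tsv"))

  gl <- bind_rows(
    tibble(gene = co$annotations$gene[co$annotations$ts], category = "TS"),
    tibble(gene = co$annotations$gene[co$annotations$og], category = "OG"),
    tibble(gene = co$annotations$gene[co$annotations$cg], category = "CG")
  ) |> arrange(.data$gene, .data$category)
  readr::write_tsv(gl, file.path(out_dir, "gene_list.tsv"), progress = FALSE)

  wide <- as_tibble(co$cna_matrix, rownames = "gene")
  readr::write_tsv(wide, file.path(out_dir, "cna.tsv"), progress = FALSE)
  readr::write_tsv(co$lengths, file.path(out_dir, "gene_lengths.tsv"), progress = FALSE)
  readr::write_tsv(tibble(gene = co$drivers), file.path(out_dir, "true_drivers.tsv"),
                   progress = FALSE)

  invisible(list(
    alignments = aln_dir,
    subfamily_labels = file.path(out_dir, "subfamily_labels.tsv"),
    gene_templates = file.path(out_dir, "gene_templates.tsv"),
    mutations = file.path(out_dir, "mutations.tsv"),
    gene_list = file.path(out_dir, "gene_list.tsv"),
    cna = file.path(out_dir, "cna.tsv"),
    gene_lengths = file.path(out_dir, "gene_lengths.tsv"),
    true_drivers = file.path(out_dir, "true_drivers.tsv")
  ))
}
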