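small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_genes = 120, n_driver_genes = 5, n_samples = 40,
              muts_per_sample = 25, n_templates = 2, template_n_seqs = 30,
              seed = seed, ...)
}

test_that("generators are byte-deterministic given a seed", {
  a1 <- gen_alignment(seed = 99)
  a2 <- gen_alignment(seed = 99)
  expect_identical(a1, a2)
  expect_false(identical(a1$alignment, gen_alignment(seed = 100)$alignment))

  c1 <- suppressWarnings(gen_cohort(small_spec(5)))
  c2 <- suppressWarnings(gen_cohort(small_spec(5)))
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$cna_matrix, c2$cna_matrix)
})

test_that("fully conserved alignments have >= 90% majority in every column", {
  for (seed in 1:3) {
    a <- gen_alignment(n_seqs = 40, n_cols = 30, conserved_fraction = 1,
                       subfamily_fraction = 0, seed = seed)
    mat <- do.call(rbind, strsplit(unname(a$alignment), ""))
    maj <- apply(mat, 2, function(col) max(table(col)) / length(col))
    expect_true(all(maj >= 0.9))
  }
})

test_that("alignment invariants: dimensions, labels, gap-free query", {
  a <- gen_alignment(n_seqs = 25, n_cols = 40, n_subfamilies = 4, seed = 2)
  expect_length(a$alignment, 25)
  expect_true(all(nchar(a$alignment) == 40))
  expect_equal(sort(unique(unname(a$subfamilies))), 1:4)
  expect_false(grepl("-", a$alignment[[a$query_id]]))
  expect_error(gen_alignment(n_seqs = 3, n_subfamilies = 5), "exceed")
})

test_that("mutations at conserved columns outscore mutations at variable columns", {
  a <- gen_alignment(n_seqs = 60, n_cols = 60, conserved_fraction = 0.4, seed = 4)
  ens <- build_ensemble(a$alignment, a$query_id, subfamilies = a$subfamilies)
  qres <- strsplit(a$alignment[[a$query_id]], "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  score_cols <- function(cols) {
    withr::with_seed(1, vapply(cols, function(p) {
      score_mutation(ens, p, qres[p], sample(setdiff(aa, qres[p]), 1))$fis
    }, 1.0))
  }
  cons <- score_cols(which(a$column_type == "conserved"))
  var <- score_cols(which(a$column_type == "variable"))
  expect_gt(mean(cons), mean(var))
  expect_gt(mean(cons), 2.5) # conserved hits are high-impact by design
})

test_that("cohorts carry planted structure in every output table", {
  co <- suppressWarnings(gen_cohort(small_spec(11)))
  expect_setequal(unique(co$mutations$variant_class),
                  c("missense", "silent", "truncating"))
  expect_equal(nrow(co$mutations), 40 * 25)
  # all missense scored (every gene maps to a template)
  mm <- co$mutations[co$mutations$variant_class == "missense", ]
  expect_true(all(!is.na(mm$fis)))
  expect_true(all(is.na(co$mutations$fis[co$mutations$variant_class != "missense"])))
  # drivers are annotated tumor suppressors; containment holds
  expect_true(all(co$drivers %in% co$annotations$gene[co$annotations$ts]))
  expect_true(all(co$annotations$cg[co$annotations$ts | co$annotations$og]))
  expect_setequal(unique(co$cna$state), c(-1L, 0L, 1L, 2L))
  expect_equal(nrow(co$lengths), 120)
  expect_true(all(co$lengths$coding_length >= 300))
})

test_that("null configuration matches the finite-sample length null", {
  # With no planted selection, per-gene counts are multinomial with
  # length-proportional probabilities. At finite M the plug-in Simpson
  # estimator has expectation lambda + (1 - lambda)/M and the expected
  # number of mutated genes is sum(1 - (1 - p_i)^M); the seed-averaged mu
  # must sit within three standard errors of that expectation.
  nseeds <- 100
  mus <- vapply(seq_len(nseeds), function(s) {
    co <- suppressWarnings(gen_cohort(
      cohort_spec(n_genes = 150, n_driver_genes = 2, n_samples = 50,
                  muts_per_sample = 40, selection_strength = 1,
                  cna_loss_enrichment = 1, n_templates = 2,
                  template_n_seqs = 30, fis_mode = "sample", seed = s)
    ))
    t_sm <- tally_mutations(co$mutations, "silent")
    nul <- length_null_non_uniformity(co$lengths)
    p <- co$lengths$coding_length / sum(co$lengths$coding_length)
    m <- attr(t_sm, "M")
    expected <- (nul$lambda + (1 - nul$lambda) / m) * sum(1 - (1 - p)^m)
    c(non_uniformity(t_sm)$mu, expected)
  }, c(mu = 1.0, expected = 1.0))
  se <- stats::sd(mus["mu", ]) / sqrt(nseeds)
  expect_lt(abs(mean(mus["mu", ]) - mean(mus["expected", ])), 3 * se)
})

test_that("stronger planted selection raises the high-FIS non-uniformity", {
  mu_at <- function(strength) {
    mean(vapply(1:8, function(s) {
      co <- suppressWarnings(gen_cohort(
        small_spec(s, selection_strength = strength, fis_mode = "sample")))
      non_uniformity(tally_mutations(co$mutations, fis_min = 2.5))$mu
    }, 1.0))
  }
  m1 <- mu_at(1)
  m5 <- mu_at(5)
  m20 <- mu_at(20)
  expect_lt(m1, m5)
  expect_lt(m5, m20)
})

test_that("fixture suites are reproducible and feed the whole pipeline", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths <- make_fixture_suite(d1, seed = 3)
  make_fixture_suite(d2, seed = 3)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }

  rec <- read_mutation_table(paths$mutations)
  ann <- read_gene_list(paths$gene_list)
  cna <- read_cna_matrix(paths$cna)
  lens <- read_gene_lengths(paths$gene_lengths)
  truth <- readr::read_tsv(paths$true_drivers, col_types = "c", progress = FALSE)$gene

  # rebuild per-gene ensembles from the written alignments + label files
  labels <- readr::read_tsv(paths$subfamily_labels, col_types = "cci", progress = FALSE)
  g2t <- readr::read_tsv(paths$gene_templates, col_types = "cc", progress = FALSE)
  ens_by_template <- lapply(split(labels, labels$template), function(d) {
    aln <- read_alignment(file.path(paths$alignments, paste0(d$template[1], ".fasta")))
    build_ensemble(aln, "query", subfamilies = setNames(d$subfamily, d$seq_id))
  })
  ensembles <- setNames(ens_by_template[g2t$template], g2t$gene)

  scored <- score_table(rec, ensembles)
  expect_true(any(!is.na(scored$fis)))

  prof <- non_uniformity_profile(scored, fis_bins(thresholds = 2.5),
                                 gene_groups = c("all", "TS"), annotations = ann)
  expect_true(all(c("mu", "k_eff") %in% names(prof)))
  expect_s3_class(cancer_gene_fraction(scored, ann), "mutsel_fraction")
  expect_s3_class(suppressMessages(cna_concurrency(scored, cna)), "mutsel_cna")

  burdens <- long_gene_filter(rank_gene_burden(scored), lens)
  eff <- effective_gene_set(scored, basis = "fis_tm", burdens = burdens)
  recall <- mean(truth %in% eff$gene)
  rnd <- withr::with_seed(1, sample(unique(scored$gene), nrow(eff)))
  expect_gt(recall, mean(truth %in% rnd))
})
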