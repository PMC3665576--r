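test_that("non-uniformity reproduces its analytic limits and hand examples", {
  # perfectly uniform distribution: mu is exactly one
  uniform <- non_uniformity(setNames(rep(5, 100), sprintf("g%03d", 1:100)))
  expect_identical(uniform$mu, 1)
  expect_equal(uniform$k_eff, 100)

  # one dominant gene: K collapses towards one
  skew <- non_uniformity(c(g1 = 98, g2 = 1, g3 = 1))
  expect_equal(skew$lambda, 9606 / 10000, tolerance = 1e-12)
  expect_equal(skew$k_eff, 10000 / 9606, tolerance = 1e-12)
  expect_lt(abs(skew$k_eff - 1), 0.05)

  # intermediate case, all four statistics
  nu <- non_uniformity(c(g1 = 10, g2 = 1, g3 = 1, g4 = 1, g5 = 1))
  expect_equal(nu$lambda, 104 / 196, tolerance = 1e-12)
  expect_equal(nu$k_eff, 1.8846, tolerance = 1e-4)
  expect_equal(nu$mu, 2.6531, tolerance = 1e-4)
  expect_equal(nu$n_avg, 14 * 104 / 196, tolerance = 1e-12)
})

test_that("non-uniformity refuses empty tallies and obeys its bounds", {
  empty <- as_mutation_tally(tibble::tibble(gene = character(), n = numeric()))
  expect_equal(attr(empty, "M"), 0)
  expect_error(non_uniformity(empty), "M = 0")

  withr::with_seed(3, {
    for (i in 1:25) {
      counts <- sample(1:20, sample(2:12, 1), replace = TRUE)
      names(counts) <- paste0("g", seq_along(counts))
      nu <- non_uniformity(counts)
      q <- length(counts)
      expect_gte(nu$lambda, 1 / q - 1e-12)
      expect_lte(nu$lambda, 1)
      expect_gte(nu$k_eff, 1 - 1e-12)
      expect_lte(nu$k_eff, q + 1e-12)
      expect_gte(nu$mu, 1 - 1e-12)
      expect_lte(nu$mu, q + 1e-12)
      expect_equal(nu$mu, nu$q / nu$k_eff, tolerance = 1e-12)
      # invariance under relabeling and count scaling
      relab <- counts
      names(relab) <- paste0("x", rev(seq_along(counts)))
      expect_equal(non_uniformity(relab)$mu, nu$mu)
      expect_equal(non_uniformity(counts * 7)$mu, nu$mu, tolerance = 1e-12)
      # mu = 1 iff all counts equal
      expect_equal(isTRUE(all.equal(nu$mu, 1)), length(unique(counts)) == 1)
    }
  })
})

test_that("tallies filter by class, FIS bin and gene group", {
  ann <- tibble::tibble(gene = c("G01", "G02"), ts = TRUE, og = FALSE, cg = TRUE)
  rec <- withr::with_seed(5, random_records(60))
  t_ts <- tally_mutations(rec, gene_group = "TS", annotations = ann)
  manual <- sum(rec$variant_class == "missense" & rec$gene %in% c("G01", "G02"))
  expect_equal(attr(t_ts, "M"), manual)

  rec2 <- gene_records("G1", fis_values = c(3.1, 0.2, 2.6))
  expect_equal(attr(tally_mutations(rec2, fis_min = 2.5), "M"), 2)

  # FIS bound only gates missense; truncating records pass through
  rec3 <- dplyr::bind_rows(gene_records("G1", c(0.5)), gene_records("G2", n_trunc = 2))
  t3 <- tally_mutations(rec3, classes = c("missense", "truncating"), fis_min = 2.5)
  expect_equal(attr(t3, "M"), 2)
  expect_equal(t3$gene, "G2")

  # unscored missense are excluded from binned tallies, even at the all bin
  rec4 <- gene_records("G1", c(1.0, NA))
  expect_equal(attr(tally_mutations(rec4, fis_min = -Inf), "M"), 1)
  expect_equal(attr(tally_mutations(rec4), "M"), 2)
})

test_that("pipeline statistics match brute-force recomputation from raw records", {
  withr::with_seed(19, {
    for (i in 1:40) {
      rec <- random_records(sample(20:80, 1))
      keep <- rec$variant_class == "missense"
      if (!any(keep)) next
      t <- tally_mutations(rec, "missense")
      nu <- non_uniformity(t)
      bf <- brute_force_nu(rec$gene[keep])
      expect_equal(nu$lambda, bf$lambda, tolerance = 1e-12)
      expect_equal(nu$k_eff, bf$k_eff, tolerance = 1e-12)
      expect_equal(nu$mu, bf$mu, tolerance = 1e-12)
    }
  })
})

test_that("length null reproduces closed-form examples and realistic scale", {
  l4 <- length_null_non_uniformity(tibble::tibble(gene = letters[1:4],
                                                  coding_length = rep(4, 4)))
  expect_equal(l4$k_eff, 4)
  expect_identical(l4$mu, 1)

  l7 <- length_null_non_uniformity(tibble::tibble(gene = letters[1:4],
                                                  coding_length = c(7, 1, 1, 1)))
  expect_equal(l7$lambda, 0.52, tolerance = 1e-12)
  expect_equal(l7$k_eff, 1.923, tolerance = 1e-3)
  expect_equal(l7$mu, 2.08, tolerance = 1e-12)

  # genome-scale log-normal lengths: non-uniformity stays in low single digits
  lens <- withr::with_seed(8, tibble::tibble(
    gene = sprintf("g%05d", 1:18000),
    coding_length = stats::rlnorm(18000, log(1500), 0.6)
  ))
  nul <- length_null_non_uniformity(lens)
  expect_gt(nul$mu, 1)
  expect_lt(nul$mu, 5)

  expect_error(length_null_non_uniformity(
    tibble::tibble(gene = "a", coding_length = -1)), "positive")
})

test_that("cancer-gene fractions count mutations per bin, absent when empty", {
  ann <- tibble::tibble(gene = c("C1", "C2"), ts = FALSE, og = FALSE, cg = TRUE)
  rec <- dplyr::bind_rows(
    gene_records("C1", fis_values = rep(3, 2)),
    gene_records("C2", fis_values = c(3, 0.5)),
    gene_records("N1", fis_values = c(0.2, 0.1, 3, 0.4, 0.3, 0.1))
  )
  out <- cancer_gene_fraction(rec, ann, "CG", fis_bins(thresholds = c(2.5)))
  all_bin <- out[out$bin == "all", ]
  expect_equal(all_bin$pct, 100 * 4 / 10)
  hi <- out[out$bin == "FIS>2.5", ]
  expect_equal(hi$pct, 100 * 3 / 4)
  # empty bin reports NA, not zero
  out2 <- cancer_gene_fraction(rec, ann, "CG", fis_bins(thresholds = c(99)))
  expect_true(is.na(out2$pct[out2$bin == "FIS>99"]))
  expect_equal(out2$n_mutations[out2$bin == "FIS>99"], 0)
})

test_that("truncating concurrency requires hits from different tumors", {
  rec <- dplyr::bind_rows(
    gene_records("A", fis_values = 3, sample_prefix = "P"),
    gene_records("B", fis_values = 3, sample_prefix = "Q"),
    gene_records("C", fis_values = 3, sample_prefix = "R"),
    gene_records("A", n_trunc = 1, sample_prefix = "Z"),
    gene_records("D", n_trunc = 1, sample_prefix = "Z")
  )
  out <- truncating_concurrency(rec, fis_bins(thresholds = 2.5, include_all = FALSE))
  expect_equal(out$n_genes, 3)
  expect_equal(out$n_concurrent, 1) # only A; D has no missense
  expect_equal(out$pct, 100 / 3, tolerance = 1e-9)

  # missense and truncating from one and the same tumor only: not concurrent
  same <- dplyr::bind_rows(gene_records("A", fis_values = 3, sample_prefix = "S"),
                           gene_records("A", n_trunc = 1, sample_prefix = "S"))
  out2 <- truncating_concurrency(same, fis_bins(thresholds = 2.5, include_all = FALSE))
  expect_equal(out2$n_concurrent, 0)
  # a second, different tumor flips it
  flip <- dplyr::bind_rows(same, gene_records("A", n_trunc = 1, sample_prefix = "T"))
  out3 <- truncating_concurrency(flip, fis_bins(thresholds = 2.5, include_all = FALSE))
  expect_equal(out3$n_concurrent, 1)
})

test_that("CNA concurrency percentages and exact test match the enumeration oracle", {
  # 20 silent (2 in loss), 20 truncating (4 in loss), one gene per mutation
  mk <- function(class, n, n_loss, prefix) {
    tibble::tibble(
      sample_id = paste0(prefix, 1:n), gene = paste0(prefix, "G", 1:n),
      protein_pos = 1L, ref_aa = "A",
      alt_aa = ifelse(class == "truncating", "*", "A"),
      variant_class = class, fis = NA_real_
    )
  }
  rec <- dplyr::bind_rows(mk("silent", 20, 2, "s"), mk("truncating", 20, 4, "t"))
  cna <- tibble::tibble(sample_id = rec$sample_id, gene = rec$gene,
                        state = c(rep(-1L, 2), rep(0L, 18), rep(-1L, 4), rep(0L, 16)))
  out <- cna_concurrency(rec, cna, bins = fis_bins(thresholds = 2.5))
  expect_equal(out$pct_loss[out$class == "silent"], 10)
  expect_equal(out$pct_loss[out$class == "truncating"], 20)
  expect_equal(out$pct_loss[out$class == "silent"] + out$pct_neutral[out$class == "silent"] +
                 out$pct_gain[out$class == "silent"] + out$pct_amp[out$class == "silent"], 100)
  p_pkg <- out$p_loss[out$class == "truncating"]
  p_oracle <- enumerate_fisher_p(4, 16, 2, 18)
  expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  expect_true(is.na(out$p_loss[out$class == "silent"]))

  # unjoined records are excluded; joining nothing is refused
  expect_error(suppressMessages(
    cna_concurrency(rec, tibble::tibble(sample_id = "x", gene = "y", state = 0L))
  ), "no mutation joins")
})

test_that("exact-test oracle agrees with fisher.test across random 2x2 tables", {
  withr::with_seed(31, {
    for (i in 1:25) {
      tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(
        enumerate_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
        stats::fisher.test(tab)$p.value, tolerance = 1e-7
      )
    }
  })
})
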