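# Independent oracles, deliberately naive: literal recounting, full
# enumeration, closed forms. They never share code with the package paths
# they check.

# Simpson statistics straight from a raw record list: count occurrences of
# each gene name by table(), no tally intermediate.
brute_force_nu <- function(gene_names) {
  cnt <- as.numeric(table(gene_names))
  m <- sum(cnt)
  p <- cnt / m
  lambda <- sum(p * p)
  list(lambda = lambda, k_eff = 1 / lambda, mu = lambda * length(cnt))
}

# FIS by literal string scanning of the aligned sequences.
brute_force_fis <- function(seqs, labels, query_idx, protein_pos, ref, alt) {
  chars <- strsplit(seqs, "")
  q <- chars[[query_idx]]
  col <- which(q != "-")[protein_pos]
  n_a <- n_b <- np_a <- np_b <- 0
  p <- labels[query_idx]
  for (i in seq_along(chars)) {
    r <- chars[[i]][col]
    if (r == ref) n_a <- n_a + 1
    if (r == alt) n_b <- n_b + 1
    if (labels[i] == p) {
      if (r == ref) np_a <- np_a + 1
      if (r == alt) np_b <- np_b + 1
    }
  }
  -0.5 * (log((n_b + 1) / n_a) + log((np_b + 1) / np_a))
}

# Two-sided Fisher exact p-value for a 2x2 table by full hypergeometric
# enumeration: sum the probabilities of all tables (with the observed
# margins) no more probable than the observed one.
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  prob <- function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  ps <- vapply(xs, prob, 1.0)
  p_obs <- prob(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Random mutation tibble for property tests.
random_records <- function(n, n_genes = 8, n_samples = 6, scored = TRUE) {
  classes <- sample(c("missense", "silent", "truncating", "other"), n,
                    replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  fis <- ifelse(classes == "missense", round(stats::runif(n, -2, 4), 3), NA_real_)
  if (!scored) fis <- NA_real_
  tibble::tibble(
    sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n, replace = TRUE),
    gene = sample(sprintf("G%02d", seq_len(n_genes)), n, replace = TRUE),
    protein_pos = sample(1:50, n, replace = TRUE),
    ref_aa = sample(c("A", "R", "D", "K"), n, replace = TRUE),
    alt_aa = sample(c("G", "H", "W", "*"), n, replace = TRUE),
    variant_class = classes,
    fis = fis
  )
}

# A tiny hand-readable alignment: two conserved blocks over two subfamilies.
toy_alignment <- function() {
  c(q1 = "ARNDC", s2 = "ARNDC", s3 = "ARNDC",
    t4 = "GHILM", t5 = "GHILM", t6 = "GHILM")
}

# Minimal scored records builder for driver tests: one row per fis value,
# plus n_trunc truncating rows, all in `gene`.
gene_records <- function(gene, fis_values = numeric(), n_trunc = 0,
                         sample_prefix = "S") {
  n <- length(fis_values) + n_trunc
  tibble::tibble(
    sample_id = paste0(sample_prefix, seq_len(max(n, 1))[seq_len(n)]),
    gene = gene,
    protein_pos = seq_len(n),
    ref_aa = "A",
    alt_aa = c(rep("G", length(fis_values)), rep("*", n_trunc)),
    variant_class = c(rep("missense", length(fis_values)), rep("truncating", n_trunc)),
    fis = c(fis_values, rep(NA_real_, n_trunc))
  )
}
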