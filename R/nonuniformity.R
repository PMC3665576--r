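#' Non-uniformity of a per-gene mutation distribution
#'
#' Summarises how unevenly mutations are spread across genes. With per-gene
#' shares \eqn{p_i = N_i / M}:
#' \deqn{\lambda = \sum_i p_i^2 \qquad \bar N = M\lambda \qquad
#'   K = 1/\lambda \qquad \mu = \lambda Q = Q/K}
#' \eqn{\lambda} is the Simpson diversity index, \eqn{K} the effective
#' number of mutated genes (the equivalent number of equally mutated genes),
#' and \eqn{\mu} the non-uniformity: the ratio of the total number of
#' mutated genes \eqn{Q} to \eqn{K}. When mutations are spread evenly,
#' \eqn{p_i \approx 1/Q}, so \eqn{K \approx Q} and \eqn{\mu \approx 1};
#' when one gene carries the overwhelming majority, \eqn{\lambda \approx 1},
#' \eqn{K \approx 1} and \eqn{\mu \approx Q}. Large \eqn{\mu} is the
#' signature of selection: many mutations concentrated in few genes.
#'
#' @param tally A `mutation_tally` (from [tally_mutations()] or
#'   [as_mutation_tally()]), a tibble with `gene`/`n` columns, or a named
#'   count vector. Must contain at least one mutation; an empty tally is
#'   refused.
#' @return An object of class `non_uniformity` with fields `lambda`
#'   (Simpson index), `n_avg` (weighted average mutations per gene), `k_eff`
#'   (effective number of mutated genes), `mu` (non-uniformity), `q` (genes
#'   mutated) and `m` (total mutations). [glance()] returns these as a
#'   one-row tibble; [tidy()] in long form.
#' @examples
#' non_uniformity(c(g1 = 10, g2 = 1, g3 = 1, g4 = 1, g5 = 1))
#' @export
non_uniformity <- function(tally) {
  if (!inherits(tally, "mutation_tally")) tally <- as_mutation_tally(tally)
  m <- attr(tally, "M")
  q <- attr(tally, "Q")
  if (m < 1) abort("cannot compute non-uniformity of an empty tally (M = 0)")
  lambda <- sum(tally$p^2)
  new_non_uniformity(lambda = lambda, q = q, m = m, n_avg = m * lambda)
}

new_non_uniformity <- function(lambda, q, m, n_avg) {
  structure(
    list(lambda = lambda, n_avg = n_avg, k_eff = 1 / lambda,
         mu = lambda * q, q = q, m = m),
    class = "non_uniformity"
  )
}

#' Gene-length null of the non-uniformity statistic
#'
#' The non-uniformity expected when mutations fall on genes purely in
#' proportion to coding length: per-gene shares are
#' \eqn{p_i = \ell_i / \sum_j \ell_j}, from which \eqn{\lambda}, \eqn{K}
#' and \eqn{\mu} follow as in [non_uniformity()]. Reported as a separate
#' null rather than folded into the observed statistic: across large gene
#' groups, length effects average out.
#'
#' @param lengths A tibble with columns `gene` and `coding_length`
#'   (nucleotides, all positive).
#' @return A `non_uniformity` object (`m` and `n_avg` are `NA`: the null is
#'   a property of the length distribution, not of a mutation count).
#' @export
length_null_non_uniformity <- function(lengths) {
  stopifnot(is.data.frame(lengths), all(c("gene", "coding_length") %in% names(lengths)))
  len <- lengths$coding_length
  if (length(len) < 1) abort("need at least one gene length")
  if (any(is.na(len) | len <= 0)) abort("all coding lengths must be positive")
  p <- len / sum(len)
  lambda <- sum(p^2)
  new_non_uniformity(lambda = lambda, q = length(p), m = NA_real_, n_avg = NA_real_)
}

#' @export
print.non_uniformity <- function(x, ...) {
  cat("Non-uniformity of mutation distribution\n",
      "  genes mutated        Q  = ", format(x$q), "\n",
      "  total mutations      M  = ", format(x$m), "\n",
      "  Simpson diversity    lambda = ", format(x$lambda, digits = 4), "\n",
      "  effective genes      K  = ", format(x$k_eff, digits = 4), "\n",
      "  non-uniformity       mu = ", format(x$mu, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname non_uniformity
#' @param x A `non_uniformity` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.non_uniformity <- function(x, ...) {
  tibble(lambda = x$lambda, n_avg = x$n_avg, k_eff = x$k_eff,
         mu = x$mu, q = x$q, m = x$m)
}

#' @rdname non_uniformity
#' @exportS3Method generics::tidy
tidy.non_uniformity <- function(x, ...) {
  tidyr::pivot_longer(glance(x), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' Non-uniformity across FIS bins and gene groups
#'
#' Computes the non-uniformity \eqn{\mu} of missense-mutation distributions
#' for each cumulative FIS bin within each gene group, with silent and
#' truncating mutations of the same groups as unbinned references. Bins
#' whose tally is empty are dropped.
#'
#' @param records Scored mutation tibble.
#' @param bins [fis_bins()] lower bounds.
#' @param gene_groups Character vector of groups (see [gene_in_group()]).
#' @param annotations [read_gene_list()] tibble, or `NULL`.
#' @return A tibble of class `mutsel_profile`: one row per (group, class,
#'   bin) with columns `group`, `class`, `bin`, `min_fis`, `q`, `k_eff`,
#'   `mu`, `m`.
#' @export
non_uniformity_profile <- function(records, bins = fis_bins(),
                                   gene_groups = "all", annotations = NULL) {
  check_records(records)
  one <- function(group, class, bin_label, fis_min) {
    t <- tally_mutations(records, classes = class, fis_min = fis_min,
                         gene_group = group, annotations = annotations)
    if (attr(t, "M") < 1) return(NULL)
    nu <- non_uniformity(t)
    tibble(group = group, class = class, bin = bin_label,
           min_fis = fis_min %||% NA_real_,
           q = nu$q, k_eff = nu$k_eff, mu = nu$mu, m = nu$m)
  }
  rows <- purrr::map(gene_groups, function(g) {
    bind_rows(
      unname(purrr::imap(bins, function(thr, lab) one(g, "missense", lab, thr))),
      one(g, "silent", "silent", NULL),
      one(g, "truncating", "truncating", NULL)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("mutsel_profile", class(out))
  out
}
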