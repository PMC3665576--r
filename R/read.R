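#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated mutation table and returns one row per mutation with
#' the protein change parsed into reference residue, 1-based protein position
#' and alternate residue. Raw classification labels are mapped to the four
#' mutation classes with [classify_variant()]. Missense or silent rows whose
#' protein change cannot be parsed (or whose reference and alternate residues
#' are inconsistent with the class) are retained but reclassified `other`,
#' with a summary warning; the number of such rows is stored in the
#' `n_parse_warnings` attribute.
#'
#' @param path Path to a tab-separated file with a header.
#' @param dialect A [maf_dialect()] naming the columns and the class mapping.
#' @return A tibble with columns `sample_id`, `gene`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `variant_class`, `fis` (plus `family_term` and
#'   `subfamily_term` when present in the input). Gene symbols are trimmed
#'   and upper-cased.
#' @export
read_mutation_table <- function(path, dialect = maf_dialect()) {
  stopifnot(inherits(dialect, "maf_dialect"))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c(dialect$sample, dialect$gene, dialect$classification, dialect$protein_change)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("mutation table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  change <- parse_protein_change(raw[[dialect$protein_change]])
  out <- tibble(
    sample_id = as.character(raw[[dialect$sample]]),
    gene = normalize_gene(raw[[dialect$gene]]),
    protein_pos = change$pos,
    ref_aa = change$ref,
    alt_aa = change$alt,
    variant_class = classify_variant(raw[[dialect$classification]], dialect),
    fis = if ("fis" %in% names(raw)) suppressWarnings(as.numeric(raw$fis)) else NA_real_
  )
  for (col in c("family_term", "subfamily_term")) {
    if (col %in% names(raw)) out[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }

  # positional classes must carry a consistent parsed change
  bad <- (out$variant_class %in% c("missense", "silent")) &
    (is.na(out$protein_pos) |
       (out$variant_class == "missense" & out$ref_aa == out$alt_aa) |
       (out$variant_class == "silent" & out$ref_aa != out$alt_aa))
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    out$variant_class[bad] <- "other"
    warn(paste0(sum(bad), " missense/silent row(s) had an unparseable or ",
                "inconsistent protein change and were reclassified 'other'"))
  }
  attr(out, "n_parse_warnings") <- sum(bad)
  out
}

#' Write a mutation table as TSV
#'
#' Writes records in the package's canonical MAF-like dialect so that
#' [read_mutation_table()] on the output reproduces the records (scores
#' included, when present).
#'
#' @param records A mutation tibble as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, path) {
  check_records(records)
  change <- ifelse(is.na(records$protein_pos), "",
                   paste0(records$ref_aa, records$protein_pos, records$alt_aa))
  out <- tibble(
    Tumor_Sample_Barcode = records$sample_id,
    Hugo_Symbol = records$gene,
    Variant_Classification = records$variant_class,
    Protein_Change = change
  )
  for (col in c("fis", "family_term", "subfamily_term")) {
    if (col %in% names(records)) out[[col]] <- records[[col]]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

parse_protein_change <- function(x) {
  x <- sub("^p\\.", "", trimws(as.character(x)))
  m <- regmatches(x, regexec("^([A-Za-z*])([0-9]+)([A-Za-z*])$", x))
  ref <- vapply(m, function(g) if (length(g) == 4) toupper(g[2]) else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g) == 4) as.integer(g[3]) else NA_integer_, 1L)
  alt <- vapply(m, function(g) if (length(g) == 4) toupper(g[4]) else NA_character_, "")
  pos[!is.na(pos) & pos < 1L] <- NA_integer_
  ref[is.na(pos)] <- NA_character_
  alt[is.na(pos)] <- NA_character_
  list(ref = ref, pos = pos, alt = alt)
}

normalize_gene <- function(x) toupper(trimws(as.character(x)))

check_records <- function(records) {
  need <- c("sample_id", "gene", "protein_pos", "ref_aa", "alt_aa", "variant_class")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("mutation records are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(records)
}

#' Read a gene annotation list
#'
#' Reads a TSV with (at least) columns `gene` and `category`
#' (case-insensitive header), where category is one of `TS` (tumor
#' suppressor), `OG` (oncogene) or `CG` (annotated cancer gene). Duplicate
#' rows for a gene are merged by category union. Because tumor suppressors
#' and oncogenes are cancer genes by definition, `cg` is forced to contain
#' `ts` and `og`. Genes absent from the table are non-cancer genes (nCG).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `ts`, `og`, `cg` (logical).
#' @export
read_gene_list <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("gene", "category") %in% names(raw))) {
    abort("gene list must have 'gene' and 'category' columns")
  }
  cat <- toupper(trimws(raw$category))
  bad <- setdiff(unique(cat), c("TS", "OG", "CG"))
  if (length(bad) > 0) {
    abort(paste0("unknown gene categories: ", paste(bad, collapse = ", "),
                 " (expected TS, OG or CG)"))
  }
  tibble(gene = normalize_gene(raw$gene), category = cat) |>
    distinct() |>
    group_by(.data$gene) |>
    summarise(ts = "TS" %in% .data$category,
              og = "OG" %in% .data$category,
              cg = TRUE, # any listed category implies cancer-gene membership
              .groups = "drop") |>
    arrange(.data$gene)
}

#' Read a discretized copy-number matrix
#'
#' Reads a genes-by-samples TSV whose first column holds gene symbols and
#' whose remaining columns hold discretized copy-number states: -1
#' (heterozygous loss), 0 (neutral), 1 (gain), 2 (amplification). Any other
#' value is a fatal error naming the offending gene and sample.
#'
#' @param path Path to the TSV.
#' @return A long tibble with columns `sample_id`, `gene`, `state`.
#' @export
read_cna_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("CNA matrix needs a gene column plus >= 1 sample column")
  genes <- normalize_gene(raw[[1]])
  long <- tidyr::pivot_longer(
    mutate(raw[-1], gene = genes),
    -"gene", names_to = "sample_id", values_to = "state_raw"
  )
  state <- suppressWarnings(as.integer(long$state_raw))
  bad <- is.na(state) | !state %in% c(-1L, 0L, 1L, 2L)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("CNA state '", long$state_raw[i], "' for gene ", long$gene[i],
                 ", sample ", long$sample_id[i],
                 " is not one of -1, 0, 1, 2"))
  }
  tibble(sample_id = long$sample_id, gene = long$gene, state = state)
}

#' Read a gene coding-length table
#'
#' TSV with columns `gene` and `coding_length` (nucleotides). Duplicate gene
#' rows with identical length are collapsed; conflicting lengths are fatal,
#' as are non-positive lengths.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `coding_length`.
#' @export
read_gene_lengths <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("gene", "coding_length") %in% names(raw))) {
    abort("gene length table must have 'gene' and 'coding_length' columns")
  }
  out <- tibble(gene = normalize_gene(raw$gene),
                coding_length = suppressWarnings(as.numeric(raw$coding_length))) |>
    distinct()
  if (any(is.na(out$coding_length) | out$coding_length <= 0)) {
    abort(paste0("non-positive or non-numeric coding length for gene(s): ",
                 paste(head(out$gene[is.na(out$coding_length) | out$coding_length <= 0]),
                       collapse = ", ")))
  }
  dup <- out$gene[duplicated(out$gene)]
  if (length(dup) > 0) {
    abort(paste0("conflicting coding lengths for gene(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Read a protein multiple alignment
#'
#' FASTA is read with Biostrings; Stockholm (single- or multi-block) with a
#' minimal built-in parser. Sequences are upper-cased and `.` gap characters
#' normalized to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (sniff by extension, then content), `"fasta"` or
#'   `"stockholm"`.
#' @return A named character vector of aligned sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sto", "stk", "stockholm")) "stockholm"
    else if (ext %in% c("fa", "fasta", "afa", "aln", "mfa")) "fasta"
    else {
      first <- readLines(path, n = 1L)
      if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
    }
  }
  seqs <- if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    setNames(as.character(aa), names(aa))
  } else {
    read_stockholm(path)
  }
  if (length(seqs) == 0) abort(paste0("no sequences in alignment: ", path))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  # take identifier up to first whitespace, as alignment tools do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

read_stockholm <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    abort(paste0("not a Stockholm file: ", path))
  }
  seqs <- list()
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || startsWith(ln, "#") || startsWith(ln, "//")) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) abort(paste0("malformed Stockholm sequence line: ", ln))
    seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "", parts[2])
  }
  unlist(seqs)
}
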