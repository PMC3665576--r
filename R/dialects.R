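#' MAF dialect: column names and variant-class mapping
#'
#' A mutation table "dialect" names the columns of a MAF-like tab-separated
#' file and maps its raw variant-classification labels onto the three mutation
#' classes the selection statistics distinguish: `missense`, `silent` and
#' `truncating` (everything else is `other`). Defaults cover standard MAF
#' labels; the truncating set is the usual loss-of-function classes
#' (nonsense, frameshift, splice site, nonstop).
#'
#' @param sample,gene,classification,protein_change Column names in the input
#'   file.
#' @param class_map Named character vector mapping raw classification labels
#'   (case-insensitive) to one of `"missense"`, `"silent"`, `"truncating"`,
#'   `"other"`. Labels absent from the map become `"other"`.
#' @return A list of class `maf_dialect`.
#' @examples
#' d <- maf_dialect()
#' classify_variant(c("Missense_Mutation", "Frame_Shift_Del", "Weird"), d)
#' @export
maf_dialect <- function(sample = "Tumor_Sample_Barcode",
                        gene = "Hugo_Symbol",
                        classification = "Variant_Classification",
                        protein_change = "Protein_Change",
                        class_map = default_class_map()) {
  stopifnot(is.character(class_map), !is.null(names(class_map)))
  bad <- setdiff(unique(class_map), c("missense", "silent", "truncating", "other"))
  if (length(bad) > 0) {
    abort(paste0("class_map targets must be one of the four mutation classes; got: ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(sample = sample, gene = gene, classification = classification,
         protein_change = protein_change,
         class_map = setNames(unname(class_map), tolower(names(class_map)))),
    class = "maf_dialect"
  )
}

#' @rdname maf_dialect
#' @export
default_class_map <- function() {
  c(
    Missense_Mutation = "missense",
    Silent            = "silent",
    Synonymous        = "silent",
    Nonsense_Mutation = "truncating",
    Frame_Shift_Del   = "truncating",
    Frame_Shift_Ins   = "truncating",
    Splice_Site       = "truncating",
    Nonstop_Mutation  = "truncating",
    missense          = "missense",
    silent            = "silent",
    truncating        = "truncating",
    other             = "other"
  )
}

#' Read a dialect from a YAML config file
#'
#' The file may define any of the fields of [maf_dialect()]; `class_map` is
#' given as a mapping from raw label to class. Missing fields keep defaults.
#'
#' @param path Path to a YAML file.
#' @return A `maf_dialect`.
#' @export
read_dialect_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), c("sample", "gene", "classification", "protein_change"))]
  if (!is.null(cfg$class_map)) {
    args$class_map <- unlist(cfg$class_map)
  }
  do.call(maf_dialect, args)
}

#' Map raw variant-classification labels to mutation classes
#'
#' Total and deterministic: every input label maps to exactly one of
#' `missense`, `silent`, `truncating`, `other`; unknown labels map to `other`.
#' The mapping is idempotent over its own output labels.
#'
#' @param x Character vector of raw classification labels.
#' @param dialect A [maf_dialect()].
#' @return Character vector of mutation classes, same length as `x`.
#' @export
classify_variant <- function(x, dialect = maf_dialect()) {
  stopifnot(inherits(dialect, "maf_dialect"))
  out <- unname(dialect$class_map[tolower(as.character(x))])
  out[is.na(out)] <- "other"
  out
}

MUTATION_CLASSES <- c("missense", "silent", "truncating", "other")
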