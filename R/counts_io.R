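# Closed design vocabularies. The experiment is a 4 x 3 factorial:
# Apoer2 genotype (wild type, conditional KO, cleavage-resistant knockins
# with/without exon 19) crossed with lentiviral treatment (Cre only, or
# Cre plus one of the two Apoer2-ICD splice variants).
GENOTYPES <- c("WT", "cKO", "D16p19", "D16d19")
TREATMENTS <- c("Cre", "ICD19", "ICDd19")
MUTANT_GENOTYPES <- c("cKO", "D16p19", "D16d19")
ICD_TREATMENTS <- c("ICD19", "ICDd19")
REFERENCE_GROUP <- "WT:Cre"

# featureCounts annotation columns that are tolerated and dropped on read
FEATURECOUNTS_ANNOT <- c("Chr", "Start", "End", "Strand", "Length")

#' Genotype and treatment vocabularies of the factorial design
#'
#' @return A list with elements `genotypes`, `treatments`, `mutant_genotypes`,
#'   `icd_treatments` and `reference_group` (the `"WT:Cre"` baseline every
#'   other group is ultimately compared against).
#' @export
design_levels <- function() {
  list(
    genotypes = GENOTYPES,
    treatments = TREATMENTS,
    mutant_genotypes = MUTANT_GENOTYPES,
    icd_treatments = ICD_TREATMENTS,
    reference_group = REFERENCE_GROUP
  )
}

#' Construct a validated count matrix with sample metadata
#'
#' The central container of the pipeline: an integer gene x sample matrix
#' plus a sample sheet assigning every sample a genotype and a treatment
#' from the closed design vocabularies.
#'
#' @param counts Integer matrix (genes x samples) with unique rownames
#'   (gene ids, treated as opaque strings) and colnames matching
#'   `samples$sample_id`.
#' @param samples Data frame with at least `sample_id`, `genotype`,
#'   `treatment`; extra columns (batch, sex, ...) are carried along.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix, columns in sample-sheet order) and
#'   `samples` (the sample sheet).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts))
    stop("missing values are not permitted in counts")
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("counts must be non-negative integers; offending entry at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  samples <- validate_sample_sheet(samples)
  missing_in_counts <- setdiff(samples$sample_id, colnames(counts))
  extra_in_counts <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_in_counts) || length(extra_in_counts))
    stop("sample sheet / count column mismatch; missing from counts: [",
         paste(missing_in_counts, collapse = ", "), "]; absent from sheet: [",
         paste(extra_in_counts, collapse = ", "), "]")
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "treatment")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyNA(samples[req]))
    stop("every sample needs sample_id, genotype and treatment")
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup))
    stop("duplicate sample id(s) in sheet: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(samples$genotype), GENOTYPES)
  if (length(bad))
    stop("unknown genotype(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(GENOTYPES, collapse = ", "))
  bad <- setdiff(unique(samples$treatment), TREATMENTS)
  if (length(bad))
    stop("unknown treatment(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(TREATMENTS, collapse = ", "))
  rownames(samples) <- NULL
  samples
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(group = group_keys(x))
  cat("groups:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Per-sample group keys ("genotype:treatment")
#'
#' @param x A `count_matrix`.
#' @return Character vector, one `"genotype:treatment"` key per sample.
#' @export
group_keys <- function(x) {
  paste(x$samples$genotype, x$samples$treatment, sep = ":")
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "\"")
}

#' Read a sample sheet (CSV or TSV)
#'
#' @param path File with columns `sample_id`, `genotype`, `treatment` and
#'   optional extras; genotype/treatment must come from the closed design
#'   vocabularies (see [design_levels()]).
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  validate_sample_sheet(read_table_auto(path))
}

#' Read a featureCounts-style count table plus its sample sheet
#'
#' Accepts the featureCounts TSV dialect: `#`-prefixed comment lines, a
#' `Geneid` column, optional annotation columns (`Chr`, `Start`, `End`,
#' `Strand`, `Length`, dropped silently) and one column per sample.
#' Columns are reordered to sample-sheet order.
#'
#' @param path Count table TSV.
#' @param sample_sheet_path Sample sheet (CSV/TSV), or a data frame.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(path, sample_sheet_path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  samples <- if (is.character(sample_sheet_path)) {
    read_sample_sheet(sample_sheet_path)
  } else {
    validate_sample_sheet(sample_sheet_path)
  }
  tab <- read_table_auto(path)
  if (!"Geneid" %in% names(tab))
    stop("count table lacks a 'Geneid' column: ", path)
  gene_ids <- as.character(tab$Geneid)
  keep <- setdiff(names(tab), c("Geneid", FEATURECOUNTS_ANNOT))
  mat <- tab[, keep, drop = FALSE]
  for (j in seq_along(mat)) {
    col <- mat[[j]]
    if (!is.numeric(col) || anyNA(col) || any(col != round(col)) || any(col < 0)) {
      bad <- which(!is.numeric(col) | is.na(col) | col != round(col) | col < 0)[1]
      stop(sprintf("non-integer count at row %d (gene '%s'), column '%s'",
                   bad, gene_ids[bad], keep[j]))
    }
  }
  mat <- as.matrix(mat)
  rownames(mat) <- gene_ids
  count_matrix(mat, samples)
}

#' Write a count matrix as featureCounts-style TSV
#'
#' First column `Geneid`, then one column per sample in sheet order;
#' deterministic, bit-exact round trip with [read_counts()].
#'
#' @param x A `count_matrix`.
#' @param path Output TSV path.
#' @param sample_sheet_path Optional path to also write the sample sheet.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(Geneid = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  if (!is.null(sample_sheet_path)) write_tsv(x$samples, sample_sheet_path)
  invisible(path)
}

# Deterministic TSV writer shared by all result tables.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
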