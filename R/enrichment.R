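# Database-free downstream summaries: exclusive-region counts of up to six
# gene sets (the numbers behind supervenn-style figures) and hypergeometric
# over-representation against user-supplied annotation sets. This is a
# deliberately generic stand-in for web enrichment tools, not a
# reimplementation of any of them.

#' Exclusive-region partition of 2-6 gene sets
#'
#' Counts, for m named sets, how many genes fall in each of the 2^m - 1
#' nonempty membership patterns (exclusive regions of the Venn diagram).
#'
#' @param sets Named list of 2-6 character vectors (gene ids; duplicates
#'   within a set are ignored).
#' @return Data frame with one row per nonempty pattern, in deterministic
#'   binary order over the input set order: `pattern` (e.g. `"101"`,
#'   leftmost digit = first set), `sets` (e.g. `"A&C"`), `count`. Counts
#'   sum to the size of the union.
#' @export
overlap_partition <- function(sets) {
  m <- length(sets)
  if (m < 2 || m > 6)
    stop("overlap_partition needs between 2 and 6 sets, got ", m)
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("sets must have unique non-empty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe), ncol = m)
  # pattern id: first set = most significant bit
  weights <- 2^((m - 1):0)
  code <- as.vector(member %*% weights)
  codes <- seq_len(2^m - 1)
  counts <- tabulate(code, nbins = 2^m - 1)
  bit <- function(x, j) bitwAnd(x, 2^(m - j)) > 0
  pattern <- vapply(codes, function(x)
    paste(as.integer(vapply(seq_len(m), bit, logical(1), x = x)),
          collapse = ""), "")
  labels <- vapply(codes, function(x)
    paste(names(sets)[vapply(seq_len(m), bit, logical(1), x = x)],
          collapse = "&"), "")
  data.frame(pattern = pattern, sets = labels, count = counts,
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test P(X >= k) of the overlap between a query
#' gene set and each annotation set, restricted to a stated gene universe,
#' with Benjamini-Hochberg adjustment across the tested sets.
#'
#' @param query Character vector of gene ids (intersected with `universe`).
#' @param sets Named list of annotation gene sets (each intersected with
#'   `universe`).
#' @param universe Character vector: the background gene universe
#'   (non-empty after deduplication).
#' @return Data frame ordered by `p` then `set_id`: `set_id`, `overlap` (k),
#'   `set_size` (K), `query_size` (n), `universe_size` (N), `p`, `padj`.
#' @export
hypergeom_enrichment <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty gene universe")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("annotation sets must have unique names")
  query <- intersect(unique(as.character(query)), universe)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(id) {
    S <- intersect(unique(as.character(sets[[id]])), universe)
    K <- length(S)
    k <- length(intersect(query, S))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)[1]
  if (!is.na(bad))
    stop("GMT line ", bad, " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate set id(s) in GMT")
  stats::setNames(sets, ids)
}

#' Read gene sets from a two-column gene-to-set table
#'
#' @param path TSV/CSV with columns `gene_id` and `set_id` (header
#'   required); extra columns ignored.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  tab <- read_table_auto(path)
  req <- c("gene_id", "set_id")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("gene-set table lacks column(s): ", paste(miss, collapse = ", "))
  lapply(split(as.character(tab$gene_id), tab$set_id), unique)
}
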