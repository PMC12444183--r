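#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT dialect (one set per line: name, description,
#' then one or more gene identifiers). Lines starting with `#` are ignored.
#' Gene identifiers are trimmed of surrounding whitespace and matched as exact
#' strings downstream; no symbol/alias resolution is attempted.
#'
#' @param path Path to a GMT file (UTF-8).
#' @return A tibble of class `lipo_gene_sets` with one row per set and columns
#'   `name`, `description`, and a list-column `genes` of character vectors.
#' @details Duplicate genes within a line are removed with a warning; duplicate
#'   set names across lines are an error, as are lines with fewer than three
#'   fields (the error names the offending line).
#' @export
#' @examples
#' gmt <- system.file("extdata", "example_lipid_sets.gmt", package = "lipostrat")
#' read_gmt(gmt)
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("GMT file contains no gene-set lines: ", path, call. = FALSE)
  }
  sets <- purrr::map(idx, function(i) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L) {
      stop("Malformed GMT line ", i, " (need name, description, >=1 gene): ",
           substr(lines[[i]], 1L, 60L), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      dup <- unique(genes[duplicated(genes)])
      warning("Gene set '", fields[[1]], "' (line ", i, ") contains duplicate gene(s): ",
              paste(dup, collapse = ", "), "; deduplicated.", call. = FALSE)
      genes <- unique(genes)
    }
    tibble::tibble(name = fields[[1]], description = fields[[2]], genes = list(genes))
  })
  out <- dplyr::bind_rows(sets)
  if (anyDuplicated(out$name)) {
    stop("Duplicate gene-set name(s) in GMT: ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         call. = FALSE)
  }
  new_gene_sets(out)
}

new_gene_sets <- function(df) {
  stopifnot(all(c("name", "description", "genes") %in% names(df)))
  class(df) <- c("lipo_gene_sets", class(tibble::as_tibble(df)))
  df
}

#' Construct gene sets from named character vectors
#'
#' Programmatic counterpart of [read_gmt()], mostly useful with simulated
#' cohorts where the signal genes are known by construction.
#'
#' @param ... Named character vectors, one per gene set.
#' @param description Description string recycled across sets.
#' @return A `lipo_gene_sets` tibble.
#' @export
gene_sets <- function(..., description = "user-defined") {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) && !is.character(lst[[1]])) {
    lst <- lst[[1]]
  }
  if (is.null(names(lst)) || any(!nzchar(names(lst)))) {
    stop("All gene sets must be named.", call. = FALSE)
  }
  if (anyDuplicated(names(lst))) stop("Duplicate gene-set names.", call. = FALSE)
  genes <- purrr::map(lst, function(g) {
    g <- unique(trimws(as.character(g)))
    if (length(g) == 0L) stop("Empty gene set.", call. = FALSE)
    g
  })
  new_gene_sets(tibble::tibble(
    name = names(lst),
    description = rep_len(description, length(lst)),
    genes = unname(genes)
  ))
}

#' Combine gene sets into a single set by membership union
#'
#' Used to ask whether metabolic programs act synergistically: clustering is
#' repeated with, say, the fatty-acid-degradation set combined with the
#' cholesterol-synthesis set.
#'
#' @param sets A `lipo_gene_sets` tibble with at least two rows (optionally
#'   subset via `which`).
#' @param new_name Name of the combined set.
#' @param which Optional character vector of set names to combine; default all.
#' @return A one-row `lipo_gene_sets` tibble whose `genes` are the
#'   deduplicated union, in first-appearance order.
#' @export
combine_sets <- function(sets, new_name, which = NULL) {
  stopifnot(inherits(sets, "lipo_gene_sets") || is.data.frame(sets))
  if (!is.null(which)) {
    missing <- setdiff(which, sets$name)
    if (length(missing)) {
      stop("Unknown gene set(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    sets <- sets[match(which, sets$name), ]
  }
  if (nrow(sets) == 0L) stop("No gene sets to combine.", call. = FALSE)
  if (nrow(sets) < 2L) stop("combine_sets() needs at least two sets.", call. = FALSE)
  genes <- unique(unlist(sets$genes, use.names = FALSE))
  new_gene_sets(tibble::tibble(
    name = new_name,
    description = paste0("union of ", paste(sets$name, collapse = "+")),
    genes = list(genes)
  ))
}

#' Restrict a gene set to the rows of an expression matrix
#'
#' Clustering and scoring can only use genes present in the matrix; this
#' intersects the set with the matrix rows (order follows the matrix row
#' order) and reports what was missing.
#'
#' @param set A one-row `lipo_gene_sets` tibble (or a row selected by name).
#' @param expr A genes x samples numeric matrix with rownames.
#' @return A list with `set` (the restricted one-row `lipo_gene_sets`) and
#'   `missing` (character vector of identifiers absent from the matrix).
#' @export
restrict_to_matrix <- function(set, expr) {
  set <- as_single_set(set)
  if (is.null(rownames(expr))) {
    stop("Expression matrix has no row identifiers.", call. = FALSE)
  }
  members <- set$genes[[1]]
  present <- intersect(rownames(expr), members)  # matrix row order
  missing <- setdiff(members, rownames(expr))
  if (length(present) == 0L) {
    stop("Gene set '", set$name, "' shares no genes with the expression matrix; ",
         "clustering/scoring impossible.", call. = FALSE)
  }
  restricted <- new_gene_sets(tibble::tibble(
    name = set$name, description = set$description, genes = list(present)
  ))
  list(set = restricted, missing = missing)
}

# Accept either a one-row lipo_gene_sets tibble or (sets, name) selection done
# upstream; errors on multi-row input to keep operation contracts unambiguous.
as_single_set <- function(set) {
  if (is.data.frame(set)) {
    if (nrow(set) != 1L) {
      stop("Expected a single gene set (one row), got ", nrow(set), ".", call. = FALSE)
    }
    return(set)
  }
  stop("Not a gene set object.", call. = FALSE)
}

#' Select one gene set by name
#'
#' @param sets A `lipo_gene_sets` tibble.
#' @param name Set name.
#' @return The matching one-row `lipo_gene_sets` tibble.
#' @export
get_set <- function(sets, name) {
  i <- match(name, sets$name)
  if (is.na(i)) stop("Unknown gene set: ", name, call. = FALSE)
  sets[i, ]
}
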