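#' Gene set collections
#'
#' Gene sets are kept in a tibble with one row per set: `set` (unique name),
#' `description`, `direction` (`"up"`, `"down"` or `"unsigned"`) and a
#' `genes` list-column. Direction is encoded on disk by a `_UP` / `_DN`
#' suffix on the set name, the convention used when deriving per-cluster
#' up/down signatures.
#'
#' @param set Character vector of set names.
#' @param genes List of character vectors, one per set.
#' @param description Optional descriptions.
#' @param direction Optional directions; inferred from `_UP`/`_DN` suffixes
#'   when `NULL`.
#' @return A gene-set tibble.
#' @export
gene_sets <- function(set, genes, description = "", direction = NULL) {
  if (anyDuplicated(set)) {
    abort(sprintf("duplicate gene set name: %s", set[duplicated(set)][1L]))
  }
  if (length(genes) != length(set)) abort("`genes` must have one entry per set")
  if (any(lengths(genes) == 0L)) abort("gene sets must be non-empty")
  if (is.null(direction)) {
    direction <- dplyr::case_when(
      grepl("_UP$", set) ~ "up",
      grepl("_DN$", set) ~ "down",
      TRUE ~ "unsigned"
    )
  }
  tibble(set = as.character(set),
         description = rep_len(as.character(description), length(set)),
         direction = rep_len(direction, length(set)),
         genes = purrr::map(genes, as.character))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path Path to a GMT file.
#' @return A gene-set tibble (see [gene_sets()]).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_sets(character(), list(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  gene_sets(
    set = purrr::map_chr(fields, 1L),
    description = purrr::map_chr(fields, 2L),
    genes = purrr::map(fields, ~ .x[-(1:2)])
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets Gene-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets[c("set", "description", "genes")],
                           function(set, description, genes) {
                             paste(c(set, description, genes), collapse = "\t")
                           })
  readr::write_lines(lines, path)
  invisible(path)
}

# intersect each set with the genes present in a matrix; drop sets outside
# [min_size, max_size] with a warning (the evaluated-size rule)
restrict_sets <- function(sets, gene_ids, min_size = 5L, max_size = 500L) {
  sets$genes <- purrr::map(sets$genes, intersect, y = gene_ids)
  n <- lengths(sets$genes)
  drop <- n < min_size | n > max_size
  if (any(drop)) {
    warn(sprintf("skipping %d gene set(s) outside %d-%d expressed genes: %s",
                 sum(drop), min_size, max_size,
                 paste(head(sets$set[drop], 5L), collapse = ", ")))
  }
  sets[!drop, , drop = FALSE]
}
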