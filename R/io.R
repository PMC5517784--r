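#' Read and write expression matrices as TSV
#'
#' Expression values are written as a tab-separated table with an `id`
#' column followed by one column per sample, at 15 significant digits so a
#' write/read round trip is lossless well beyond 12 significant digits.
#' The sample-to-condition design travels in a companion TSV
#' (`sample<TAB>condition`); by default it sits next to the expression file
#' with a `.design.tsv` suffix.
#'
#' @param x an [expression_matrix()].
#' @param path path of the expression TSV.
#' @param design_path path of the companion design TSV.
#' @return `write_expression()` returns `c(path, design_path)` invisibly;
#'   `read_expression()` returns an `expr_matrix`.
#' @export
write_expression <- function(x, path, design_path = default_design_path(path)) {
  v <- as_values(x)
  df <- data.frame(id = rownames(v),
                   apply(v, 2L, function(col) sprintf("%.15g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", colnames(v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_design(as_condition(x), design_path)
  invisible(c(path, design_path))
}

default_design_path <- function(path) sub("(\\.tsv)?$", ".design.tsv", path)

#' @rdname write_expression
#' @export
read_expression <- function(path, design_path = default_design_path(path)) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "id")
    stopf("malformed expression TSV '%s': expected header 'id<TAB>sample...'", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("malformed expression TSV '%s': duplicated row id '%s'",
          path, ids[duplicated(ids)][1L])
  if (anyDuplicated(names(df)[-1L]))
    stopf("malformed expression TSV '%s': duplicated sample id '%s'",
          path, names(df)[-1L][duplicated(names(df)[-1L])][1L])
  v <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(v)) stopf("malformed expression TSV '%s': non-numeric values", path)
  rownames(v) <- ids
  cond <- read_design(design_path)
  expression_matrix(v, cond)
}

#' Read and write a sample-to-condition design TSV
#'
#' @param condition character vector named by sample id, or a data.frame
#'   with columns `sample` and `condition`.
#' @param path file path.
#' @return `read_design()` returns a character vector named by sample id.
#' @export
write_design <- function(condition, path) {
  cond <- as_condition(NULL, design = condition)
  write.table(data.frame(sample = names(cond), condition = unname(cond)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stopf("malformed design TSV '%s': expected columns sample, condition", path)
  if (anyDuplicated(df$sample))
    stopf("malformed design TSV '%s': duplicated sample id '%s'",
          path, df$sample[duplicated(df$sample)][1L])
  setNames(as.character(df$condition), df$sample)
}

#' Read and write a probe-to-gene map (`probe_id<TAB>gene_id`)
#'
#' Every probe must map to exactly one gene (many probes per gene allowed).
#'
#' @param probe_map data.frame with columns `probe_id` and `gene_id`.
#' @param path file path.
#' @return `read_probe_map()` returns the validated data.frame.
#' @export
write_probe_map <- function(probe_map, path) {
  validate_probe_map(probe_map)
  write.table(probe_map[, c("probe_id", "gene_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_probe_map(df)
  df
}

validate_probe_map <- function(df) {
  if (!is.data.frame(df) || !all(c("probe_id", "gene_id") %in% names(df)))
    stopf("probe map must have columns probe_id, gene_id")
  if (anyDuplicated(df$probe_id))
    stopf("probe '%s' maps to more than one gene",
          df$probe_id[duplicated(df$probe_id)][1L])
  invisible(df)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @param pathways named list of character vectors of member gene ids.
#' @param descriptions optional character vector of set descriptions.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stopf("malformed GMT line: '%s'", l)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L))
  if (anyDuplicated(names(sets)))
    stopf("duplicated gene-set name '%s'", names(sets)[duplicated(names(sets))][1L])
  if (any(lengths(sets) == 0L)) stopf("empty gene set in '%s'", path)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stopf("pathways must be a named list")
  desc <- descriptions %||% rep("na", length(pathways))
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(pathways), desc, pathways)
  writeLines(unname(lines), path)
  invisible(path)
}
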