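#' Cumulative Flux Index (CFI) of one pathway in one condition
#'
#' The CFI treats each significantly changed enzyme of a pathway as a
#' multiplicative brake (or boost) on the pathway's flux — a simplified
#' cumulative form of flux control coefficients. It is the product of the
#' relative expression `r` over pathway members whose differential-
#' expression call is not `none`; unchanged members contribute a factor of
#' 1 (so an untouched pathway has CFI = 1), and upregulated members
#' contribute their `r > 1`. The more members are downregulated, and the
#' stronger each downregulation, the smaller the index.
#'
#' @param fc fold-change table from [fold_change()].
#' @param calls call table from [call_de()].
#' @param pathway character vector of member gene ids (non-empty, unique).
#' @param condition condition label to score.
#' @return a single positive number.
#' @examples
#' fc <- data.frame(gene = c("a", "b", "c"), condition = "t",
#'                  r = c(0.5, 0.5, 0.9))
#' calls <- data.frame(gene = c("a", "b", "c"), condition = "t",
#'                     call = c("down", "down", "none"))
#' pathway_cfi(fc, calls, c("a", "b", "c"), "t")  # 0.25
#' @export
pathway_cfi <- function(fc, calls, pathway, condition) {
  if (!length(pathway)) stopf("pathway must be non-empty")
  if (anyDuplicated(pathway))
    stopf("duplicated pathway member '%s'", pathway[duplicated(pathway)][1L])
  fc_c <- fc[fc$condition == condition, , drop = FALSE]
  calls_c <- calls[calls$condition == condition, , drop = FALSE]
  missing <- setdiff(pathway, fc_c$gene)
  if (length(missing))
    stopf("pathway member(s) missing from fold-change table for '%s': %s",
          condition, paste(missing, collapse = ", "))
  r <- setNames(fc_c$r, fc_c$gene)[pathway]
  call <- setNames(calls_c$call, calls_c$gene)[pathway]
  call[is.na(call)] <- "none"
  prod(r[call != "none"])
}

#' Total CFI across pathways
#'
#' The total index of a condition is the product of its pathway-level CFI
#' values — downstream pathways compound the impairment of upstream ones.
#'
#' @param pathway_cfis numeric vector (>= 1 value, all > 0) of pathway CFI
#'   values.
#' @return a single positive number.
#' @examples
#' total_cfi(c(0.0047, 0.0024, 0.017))  # 1.9e-07 to 2 significant figures
#' @export
total_cfi <- function(pathway_cfis) {
  if (!length(pathway_cfis)) stopf("at least one pathway CFI is required")
  if (any(!is.finite(pathway_cfis) | pathway_cfis <= 0))
    stopf("pathway CFI values must be finite and > 0")
  prod(pathway_cfis)
}

#' CFI table over all conditions and pathways
#'
#' @param fc fold-change table from [fold_change()].
#' @param calls call table from [call_de()].
#' @param pathways named list of pathway member vectors (e.g. from
#'   [read_gmt()]).
#' @param conditions conditions to score; defaults to those in `calls`.
#' @return data.frame with columns `condition`, `pathway`, `cfi`,
#'   `n_down`, `n_up`; attribute `"totals"` holds a data.frame
#'   (`condition`, `total_cfi`) with per-condition products.
#' @export
cfi_table <- function(fc, calls, pathways, conditions = NULL) {
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stopf("pathways must be a named list")
  conditions <- conditions %||% unique(calls$condition)
  res <- do.call(rbind, lapply(conditions, function(cc) {
    calls_c <- calls[calls$condition == cc, , drop = FALSE]
    do.call(rbind, lapply(names(pathways), function(pw) {
      members <- pathways[[pw]]
      call <- setNames(calls_c$call, calls_c$gene)[members]
      data.frame(condition = cc, pathway = pw,
                 cfi = pathway_cfi(fc, calls, members, cc),
                 n_down = sum(call == "down", na.rm = TRUE),
                 n_up = sum(call == "up", na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL
  totals <- do.call(rbind, lapply(conditions, function(cc)
    data.frame(condition = cc,
               total_cfi = total_cfi(res$cfi[res$condition == cc]),
               stringsAsFactors = FALSE)))
  attr(res, "totals") <- totals
  res
}

#' Rank conditions by total CFI (most impaired first)
#'
#' Ascending order of total CFI; a lower index means a stronger inferred
#' bioenergetic impairment. Ties are broken lexicographically by condition
#' label.
#'
#' @param totals data.frame with columns `condition`, `total_cfi` (e.g.
#'   `attr(cfi_table(...), "totals")`), or a named numeric vector.
#' @return the data.frame ordered ascending, with a `rank` column (dense).
#' @export
rank_conditions <- function(totals) {
  if (is.numeric(totals))
    totals <- data.frame(condition = names(totals), total_cfi = unname(totals),
                         stringsAsFactors = FALSE)
  if (!all(c("condition", "total_cfi") %in% names(totals)))
    stopf("totals needs columns condition, total_cfi")
  out <- totals[order(totals$total_cfi, totals$condition), , drop = FALSE]
  out$rank <- dense_rank(out$total_cfi)
  rownames(out) <- NULL
  out
}

#' Gene-name aliases between summary-table names and panel gene ids
#'
#' Published summary tables abbreviate some panel gene names (e.g. "Eno"
#' for the enolase panel entries, "Pdh" for Pdha1, "Sdhaf2" for the Sdh
#' panel member, "Hprt1" for Hprt, "Pgam" for Pgam1). This map reconciles
#' such labels with the ids used by the expression panels.
#'
#' @return named character vector: alias -> panel gene id.
#' @export
gene_aliases <- function() {
  c(Eno = "Eno1", Pgam = "Pgam1", Pdh = "Pdha1",
    Sdhaf2 = "Sdh", Hprt1 = "Hprt")
}

#' @rdname gene_aliases
#' @param ids character vector of gene labels to canonicalize.
#' @export
apply_aliases <- function(ids) {
  al <- gene_aliases()
  ifelse(ids %in% names(al), unname(al[ids]), ids)
}

#' Format a total CFI the way summary tables print it
#'
#' Two significant figures in scientific notation, e.g. `1.9E-07`.
#'
#' @param x numeric vector of positive values.
#' @return character vector.
#' @export
format_cfi_total <- function(x) formatC(x, format = "E", digits = 1)
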