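#' Expression matrix with sample-to-condition design
#'
#' The central container of the package: a numeric matrix of strictly
#' positive intensities (rows = probes or genes, columns = samples) bundled
#' with the mapping from each sample to its experimental condition. The
#' first condition encountered in `condition` is treated as the control
#' group by downstream fold-change and differential-expression steps unless
#' they are told otherwise.
#'
#' @param values numeric matrix, strictly positive and finite, with unique
#'   non-empty rownames (probe/gene ids) and colnames (sample ids).
#' @param condition character vector mapping samples to conditions; either
#'   named by sample id or given in column order.
#' @return an object of class `expr_matrix` with elements `values` and
#'   `condition` (a character vector named by sample id).
#' @examples
#' m <- matrix(c(10, 20, 12, 24), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' x <- expression_matrix(m, c(s1 = "ctrl", s2 = "treated"))
#' x
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("values must be a numeric matrix")
  rid <- rownames(values); sid <- colnames(values)
  if (is.null(rid) || anyNA(rid) || any(rid == ""))
    stopf("values must have non-empty rownames (probe/gene ids)")
  if (is.null(sid) || anyNA(sid) || any(sid == ""))
    stopf("values must have non-empty colnames (sample ids)")
  if (anyDuplicated(rid))
    stopf("duplicated row id: %s", rid[duplicated(rid)][1L])
  if (anyDuplicated(sid))
    stopf("duplicated sample id: %s", sid[duplicated(sid)][1L])
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("non-positive or non-finite intensity at row '%s', sample '%s'",
          rid[bad[1L, 1L]], sid[bad[1L, 2L]])
  if (is.null(names(condition))) {
    if (length(condition) != ncol(values))
      stopf("condition must have one entry per sample")
    names(condition) <- sid
  }
  if (!all(sid %in% names(condition)))
    stopf("sample '%s' has no condition assigned",
          setdiff(sid, names(condition))[1L])
  condition <- condition[sid]
  structure(list(values = values, condition = as.character(setNames(condition, sid))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d rows x %d samples, %d conditions (%s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$condition)),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, x$condition[colnames(v)])
}

# Accept either an expr_matrix or a bare named matrix (condition optional).
as_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x)) x
  else stopf("expected an expr_matrix or a numeric matrix")
}

as_condition <- function(x, design = NULL) {
  if (!is.null(design)) {
    if (is.data.frame(design)) {
      if (!all(c("sample", "condition") %in% names(design)))
        stopf("design must have columns 'sample' and 'condition'")
      return(setNames(as.character(design$condition), design$sample))
    }
    return(design)
  }
  if (inherits(x, "expr_matrix")) return(setNames(x$condition, colnames(x$values)))
  stopf("a sample-to-condition design is required")
}

#' Distinct conditions of an expression matrix, in first-appearance order
#' @param x an `expr_matrix`.
#' @return character vector of condition labels; the first is the control.
#' @export
conditions <- function(x) unique(as_condition(x))
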