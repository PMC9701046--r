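#' Construct an expression matrix with an ordered group design
#'
#' Bundles a genes x samples matrix of positive linear-scale signals
#' (e.g. RMA-normalized microarray intensities back-transformed to linear
#' scale) with an ordered condition design. The order of `design$group`
#' levels is the analysis order: the first group is the anchor for log-ratio
#' transformation and the reference condition of trend profiles.
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames matching `design$sample`). All values must be > 0.
#' @param design data.frame with columns `sample` and `group`; `group` may be
#'   a factor whose level order defines the condition order, otherwise the
#'   order of first appearance is used.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `design` (data.frame with `group` as an ordered-level
#'   factor).
#' @examples
#' m <- matrix(2^rnorm(12, 8), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' d <- data.frame(sample = paste0("s", 1:6),
#'                 group = rep(c("control", "treated"), each = 3))
#' em <- expr_matrix(m, d)
#' @export
expr_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("'values' must have gene ids as rownames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0)
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite expression values present")
  if (any(values <= 0)) {
    bad <- rownames(values)[which(rowSums(values <= 0) > 0)]
    stop("non-positive signal for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.data.frame(design) || !all(c("sample", "group") %in% names(design)))
    stop("'design' must be a data.frame with columns 'sample' and 'group'")
  design$sample <- as.character(design$sample)
  if (is.null(colnames(values)))
    stop("'values' must have sample ids as colnames")
  if (!setequal(colnames(values), design$sample) ||
      anyDuplicated(design$sample) || anyDuplicated(colnames(values)))
    stop("sample ids in matrix and design do not match one-to-one")
  # align design rows to matrix column order
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  if (!is.factor(design$group))
    design$group <- factor(design$group, levels = unique(design$group))
  design$group <- droplevels(design$group)
  if (nlevels(design$group) < 2)
    stop("design must have at least 2 groups")
  structure(list(values = values, design = design), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$design$group)
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("Groups (ordered):",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Ordered group levels of an expression matrix
#' @param em an `expr_matrix`
#' @return character vector of group labels in analysis order
#' @export
groups_of <- function(em) levels(em$design$group)

# log2 signal matrix (internal)
log2_values <- function(em) log2(em$values)

# per-gene group means of log2 signals, columns in group-level order
group_log2_means <- function(em) {
  L <- log2_values(em)
  g <- em$design$group
  out <- matrix(0, nrow(L), nlevels(g),
                dimnames = list(rownames(L), levels(g)))
  for (lev in levels(g))
    out[, lev] <- rowMeans(L[, g == lev, drop = FALSE])
  out
}

#' Restrict an expression matrix to a subset of genes
#' @param em an `expr_matrix`
#' @param genes character vector of gene ids (all must be present)
#' @return an `expr_matrix` over `genes`, in the given order
#' @export
subset_genes <- function(em, genes) {
  missing <- setdiff(genes, rownames(em$values))
  if (length(missing) > 0)
    stop("genes not in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  expr_matrix(em$values[genes, , drop = FALSE], em$design)
}
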