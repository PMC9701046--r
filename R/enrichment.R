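#' Over-representation test of one gene set
#'
#' Tests whether a gene list overlaps a gene set more than expected given the
#' universe. With `nf` list genes in the set, `n` list genes, `Nf` universe
#' genes in the set and `N` universe genes:
#' * enrichment ratio `Re = (nf/n) / (Nf/N)`, the list frequency of the set
#'   relative to its background frequency (higher = more specific);
#' * Fisher p = one-sided hypergeometric upper-tail probability of observing
#'   at least `nf` overlaps;
#' * chi-squared p from the 2x2 table without continuity correction (NA when
#'   a margin is empty).
#'
#' @param list character vector of gene ids (must be a subset of `universe`)
#' @param set character vector of gene ids (intersected with the universe)
#' @param universe character vector of background gene ids
#' @param id optional set id used in the output row
#' @param description optional set description
#' @return one-row data.frame: `set`, `description`, `nf`, `n`, `Nf`, `N`,
#'   `Re`, `fisher_p`, `chi2_p`
#' @examples
#' test_gene_set(c("a", "b", "c", "d"), c("a", "b", "c", "x"),
#'               c(letters[1:4], "w", "x", "y", "z"))  # Fisher p = 17/70
#' @export
test_gene_set <- function(list, set, universe, id = "set",
                          description = "") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  list <- unique(as.character(list))
  offenders <- setdiff(list, universe)
  if (length(offenders) > 0)
    stop("list genes not in universe: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  set <- intersect(unique(as.character(set)), universe)
  if (length(set) == 0) stop("gene set has no overlap with the universe")
  nf <- length(intersect(list, set))
  n <- length(list)
  Nf <- length(set)
  N <- length(universe)
  re <- if (n == 0) NA_real_ else (nf / n) / (Nf / N)
  fisher_p <- stats::phyper(nf - 1, Nf, N - Nf, n, lower.tail = FALSE)
  tab <- matrix(c(nf, n - nf, Nf - nf, N - n - Nf + nf), nrow = 2,
                byrow = TRUE)
  chi2_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    NA_real_
  else
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  data.frame(set = id, description = description, nf = nf, n = n, Nf = Nf,
             N = N, Re = re, fisher_p = fisher_p, chi2_p = chi2_p,
             stringsAsFactors = FALSE)
}

#' Run over-representation analysis over a gene-set collection
#'
#' Harmonizes the collection to the universe (set members outside the
#' universe are ignored; empty sets dropped), drops list genes absent from
#' the universe with a message, tests every set with [test_gene_set()], and
#' returns rows sorted by Fisher p ascending. Significance is driven by the
#' raw Fisher p-value at `alpha` (the chi-squared p and a Benjamini-Hochberg
#' column are reported alongside, not used for the flag).
#'
#' @param list character vector of gene ids
#' @param collection a [gene_set_collection()]
#' @param alpha significance threshold on the Fisher p (default 0.05)
#' @param universe optional override of the collection's universe (e.g. the
#'   genes present on the expression matrix)
#' @return object of class `enrichment_table`: data.frame of
#'   [test_gene_set()] rows plus `fdr` and `significant`
#' @export
run_enrichment <- function(list, collection, alpha = 0.05, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(universe)) universe <- collection$universe
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  list <- unique(as.character(list))
  dropped <- setdiff(list, universe)
  if (length(dropped) > 0) {
    message(length(dropped), " list gene(s) absent from the universe dropped")
    list <- intersect(list, universe)
  }
  empty <- structure(
    data.frame(set = character(0), description = character(0),
               nf = integer(0), n = integer(0), Nf = integer(0),
               N = integer(0), Re = numeric(0), fisher_p = numeric(0),
               chi2_p = numeric(0), fdr = numeric(0),
               significant = logical(0)),
    class = c("enrichment_table", "data.frame"))
  if (length(list) == 0) {
    warning("empty gene list; returning no enrichment rows")
    return(empty)
  }
  keep <- vapply(collection$sets,
                 function(s) length(intersect(s$genes, universe)) > 0,
                 logical(1))
  sets <- collection$sets[keep]
  if (length(sets) == 0) return(empty)
  rows <- lapply(names(sets), function(id) {
    test_gene_set(list, sets[[id]]$genes, universe, id = id,
                  description = sets[[id]]$description)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$fisher_p)
  out$significant <- out$fisher_p < alpha
  out <- out[order(out$fisher_p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_table", "data.frame"),
            n_list = length(list), n_universe = length(universe))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Enrichment:", nrow(x), "sets tested against a list of",
      attr(x, "n_list"), "genes (universe", attr(x, "n_universe"), ")\n")
  cat("Significant (Fisher p):", sum(x$significant), "\n")
  NextMethod()
}
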