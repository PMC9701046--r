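#' Read a sample-to-group design table
#'
#' Two-column tab-separated text: header `sample<TAB>group`, one row per
#' sample. Group order is the order of first appearance and defines the
#' ordered conditions of the analysis (the first group is the log-ratio
#' anchor).
#'
#' @param path file path
#' @return data.frame with columns `sample`, `group` (factor, ordered levels)
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  if (!all(c("sample", "group") %in% names(d)))
    stop("design file must have columns 'sample' and 'group': ", path)
  if (anyDuplicated(d$sample))
    stop("duplicate sample id in design: ",
         d$sample[duplicated(d$sample)][1])
  d$group <- factor(d$group, levels = unique(d$group))
  d
}

#' Write a design table
#' @param design data.frame with `sample` and `group`
#' @param path output path
#' @export
write_design <- function(design, path) {
  out <- data.frame(sample = as.character(design$sample),
                    group = as.character(design$group))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table with its design
#'
#' Tab-separated text: first column gene id (header field arbitrary,
#' conventionally `gene`), remaining columns one per sample, header row of
#' sample ids. All cells must be numeric, positive, linear-scale signals.
#'
#' @param path expression table path
#' @param design a design data.frame (from [read_design()]) or a path to one
#' @return an [expr_matrix()]
#' @export
read_expression_table <- function(path, design) {
  if (is.character(design) && length(design) == 1) design <- read_design(design)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("expression table needs a gene-id column plus sample columns: ", path)
  ids <- tab[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  num <- tab[, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(num, as.numeric, numeric(nrow(num))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, names(num)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at gene '", ids[bad[1]],
         "', sample '", colnames(vals)[bad[2]], "'")
  }
  if (!setequal(colnames(vals), as.character(design$sample)))
    stop("sample ids in ", path, " do not match the design")
  expr_matrix(vals, design)
}

#' Write an expression matrix as tab-separated text
#' @param em an `expr_matrix`
#' @param path output path
#' @param digits significant digits used for signals (default 15, enough for
#'   lossless round trip of doubles in practice at this precision)
#' @export
write_expression_table <- function(em, path, digits = 15) {
  df <- data.frame(gene = rownames(em$values),
                   signif(em$values, digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-set collections
#'
#' @param sets named list; each element a list with `description` (string)
#'   and `genes` (character vector)
#' @param universe character vector of background gene ids
#' @return object of class `gene_set_collection`
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) && length(sets) > 0)
    stop("sets must be named")
  universe <- unique(as.character(universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x$sets), "sets,",
      length(x$universe), "universe genes\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set-id <TAB> description <TAB> member1 <TAB> member2 ...`. Lines need at
#' least three fields (id, description, one member). Duplicate members within
#' a set are dropped with a warning.
#'
#' @param path GMT file path
#' @param universe optional background gene ids; defaults to the union of all
#'   set members
#' @return a [gene_set_collection()]
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    id <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate members in set '", id, "' (GMT line ", i,
              ") deduplicated")
      genes <- unique(genes)
    }
    if (id %in% names(sets))
      stop("duplicate set id '", id, "' at GMT line ", i)
    sets[[id]] <- list(description = fields[2], genes = genes)
  }
  if (is.null(universe))
    universe <- unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
  gene_set_collection(sets, universe)
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`
#' @param path output path
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# deterministic TSV writer for result tables (internal)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
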