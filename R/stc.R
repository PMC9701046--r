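#' Enumerate unit-change model expression profiles
#'
#' A model profile describes how expression may move between `m` ordered
#' conditions when each transition is restricted to at most `c` units up or
#' down: a change vector of `m - 1` integers in `[-c, c]`, anchored at 0 in
#' the first condition. The all-constant profile is excluded, giving
#' `(2c + 1)^(m - 1) - 1` profiles. Profiles are ordered lexicographically
#' (changes compared left to right, `-c < ... < 0 < ... < +c`) and assigned
#' dense ids `0 .. K-1` in that order. For the canonical three-condition
#' design with `c = 1` this yields 8 profiles:
#' ids 0-2 go down at the first transition, 3-4 stay flat first, and 5-7 go
#' up first; e.g. profile 5 has positions (0, 1, 0) — up then back down — and
#' profile 6 has positions (0, 1, 1) — up then sustained.
#'
#' @param m number of ordered conditions (>= 2)
#' @param c unit-change limit per transition (>= 1)
#' @return object of class `stc_profiles`: data.frame with `id`, one
#'   `change_<k>` column per transition, and one `pos_<k>` column per
#'   condition (cumulative positions, first always 0)
#' @examples
#' enumerate_profiles(3, 1)  # the 8 canonical profiles
#' @export
enumerate_profiles <- function(m, c = 1) {
  if (m < 2) stop("need m >= 2 ordered groups")
  if (c < 1) stop("unit-change limit c must be >= 1")
  steps <- seq.int(-c, c)
  # expand.grid varies the first factor fastest; feed transitions in reverse
  # so the FIRST transition is the slowest-varying (lexicographic order)
  grid <- as.matrix(expand.grid(rev(replicate(m - 1, steps,
                                              simplify = FALSE))))
  changes <- grid[, rev(seq_len(m - 1)), drop = FALSE]
  changes <- changes[rowSums(changes != 0) > 0, , drop = FALSE]
  positions <- cbind(0, t(apply(changes, 1, cumsum)))
  if (m == 2) positions <- cbind(0, changes)  # apply() drops dims at m = 2
  out <- data.frame(id = seq_len(nrow(changes)) - 1L)
  colnames(changes) <- paste0("change_", seq_len(m - 1))
  colnames(positions) <- paste0("pos_", seq_len(m))
  out <- cbind(out, changes, positions)
  structure(out, class = c("stc_profiles", "data.frame"), m = m, c = c)
}

#' @export
print.stc_profiles <- function(x, ...) {
  cat(nrow(x), "model profiles (m =", attr(x, "m"), ", c =", attr(x, "c"),
      ")\n")
  NextMethod()
}

# valid profile ids for a design (internal)
profile_ids <- function(m, c = 1) enumerate_profiles(m, c)$id

# K x m matrix of position vectors (internal)
profile_positions <- function(profiles) {
  as.matrix(profiles[, grep("^pos_", names(profiles)), drop = FALSE])
}

#' Transform expression to first-group-anchored log2 ratios
#'
#' Each condition is summarized by the geometric mean of the linear signals
#' of its replicates (equivalently, the arithmetic mean of log2 signals); the
#' per-gene trajectory is then expressed as log2 ratios to the first group,
#' so the first entry is always 0.
#'
#' @param em an [expr_matrix()] (typically restricted to DEG via
#'   [subset_genes()])
#' @return numeric matrix, genes x groups, first column all zero
#' @export
transform_to_log_ratios <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  gm <- group_log2_means(em)
  ratios <- gm - gm[, 1]
  colnames(ratios) <- groups_of(em)
  ratios
}

#' Assign genes to their best-correlated model profile
#'
#' Each gene's log2-ratio trajectory is matched against every profile's
#' position vector by Pearson correlation (computed over all `m` entries,
#' including the anchored zero); the gene is assigned to the profile with
#' the highest correlation, ties broken by lowest profile id. Genes with a
#' constant ratio vector (no change at all) have undefined correlation and
#' are left unassigned.
#'
#' @param ratios genes x groups log2-ratio matrix from
#'   [transform_to_log_ratios()]
#' @param profiles an `stc_profiles` enumerated for the same number of groups
#' @return object of class `stc_assignment`: data.frame with `gene`,
#'   `profile` (id, NA if unassigned), `cor`; the ratio matrix and profiles
#'   are kept as attributes for downstream permutation testing
#' @export
assign_profiles <- function(ratios, profiles) {
  stopifnot(inherits(profiles, "stc_profiles"))
  pv <- profile_positions(profiles)
  if (ncol(ratios) != ncol(pv))
    stop("ratio vectors have ", ncol(ratios), " groups but profiles were ",
         "enumerated for m = ", ncol(pv))
  res <- assign_to_positions(ratios, pv)
  out <- data.frame(gene = rownames(ratios),
                    profile = ifelse(is.na(res$idx), NA_integer_,
                                     profiles$id[res$idx]),
                    cor = res$cor, row.names = NULL)
  structure(out, class = c("stc_assignment", "data.frame"),
            ratios = ratios, profiles = profiles)
}

# core assignment: ratio rows vs position-vector rows (internal)
assign_to_positions <- function(ratios, pv) {
  n <- nrow(ratios)
  constant <- apply(ratios, 1, function(r) max(r) == min(r))
  idx <- rep(NA_integer_, n)
  best <- rep(NA_real_, n)
  if (any(!constant)) {
    cc <- suppressWarnings(stats::cor(t(ratios[!constant, , drop = FALSE]),
                                      t(pv)))
    idx[!constant] <- apply(cc, 1, which.max)  # which.max -> lowest id on tie
    best[!constant] <- cc[cbind(seq_len(nrow(cc)), idx[!constant])]
  }
  list(idx = idx, cor = best)
}

#' @export
print.stc_assignment <- function(x, ...) {
  cat("Profile assignment:", nrow(x), "genes,",
      sum(is.na(x$profile)), "unassigned\n")
  print(table(profile = x$profile, useNA = "ifany"))
  invisible(x)
}

#' Plot assigned trajectories per model profile
#'
#' Base-graphics panel per profile: member gene log2-ratio trajectories in
#' grey with the profile's position vector overlaid.
#'
#' @param x an `stc_assignment`
#' @param max_genes at most this many gene trajectories drawn per profile
#' @param ... passed to [graphics::matplot()]
#' @export
plot.stc_assignment <- function(x, max_genes = 50, ...) {
  ratios <- attr(x, "ratios")
  profiles <- attr(x, "profiles")
  pv <- profile_positions(profiles)
  ids <- profiles$id
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)),
                      mar = c(2, 2, 2, 0.5))
  on.exit(graphics::par(op))
  for (k in seq_along(ids)) {
    members <- which(!is.na(x$profile) & x$profile == ids[k])
    n_mem <- length(members)
    members <- utils::head(members, max_genes)
    sub <- ratios[members, , drop = FALSE]
    ylim <- range(c(sub, pv[k, ]))
    graphics::matplot(t(sub), type = "l", lty = 1, col = "grey70",
                      ylim = ylim, xlab = "", ylab = "",
                      main = paste0("profile ", ids[k], " (n=", n_mem, ")"),
                      ...)
    graphics::lines(pv[k, ], lwd = 2)
  }
  invisible(x)
}

# all permutations of 1..n, rows = permutations (internal; n is tiny)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# round half away from zero (Fisher tables need integer cells)
round_half_up <- function(x) floor(x + 0.5)

#' Permutation significance of model profiles
#'
#' Under every ordering of the condition columns (all `m!` permutations,
#' identity included), gene trajectories are re-anchored to the permuted
#' first group and re-assigned to profiles; a profile's expected count is the
#' mean of its counts over the orderings. A profile is significant when the
#' observed count under the true ordering exceeds the expected count by more
#' than chance: one-sided Fisher's exact test on the 2x2 table
#' `[observed, n - observed; round(expected), n - round(expected)]`
#' (expected counts rounded half-up), alternative "greater". A binomial test
#' of the observed count against the expected proportion is available as an
#' alternative that avoids rounding.
#'
#' @param assignment an `stc_assignment`
#' @param alpha significance level (default 0.05; raw p-values, no
#'   multiplicity correction across profiles)
#' @param method "fisher" (default) or "binomial"
#' @return object of class `stc_significance`: data.frame with `profile`,
#'   `observed`, `expected`, `p`, `significant`; attributes `n` (genes
#'   tested), `n_orderings`, `unassigned`
#' @export
profile_significance <- function(assignment, alpha = 0.05,
                                 method = c("fisher", "binomial")) {
  method <- match.arg(method)
  ratios <- attr(assignment, "ratios")
  profiles <- attr(assignment, "profiles")
  n <- nrow(assignment)
  if (n == 0) stop("no genes in assignment")
  pv <- profile_positions(profiles)
  m <- ncol(pv)
  perms <- all_permutations(m)
  counts <- matrix(0, nrow(profiles), nrow(perms))
  for (j in seq_len(nrow(perms))) {
    perm <- perms[j, ]
    r <- ratios[, perm, drop = FALSE] - ratios[, perm[1]]
    idx <- assign_to_positions(r, pv)$idx
    tab <- tabulate(idx[!is.na(idx)], nbins = nrow(profiles))
    counts[, j] <- tab
  }
  expected <- rowMeans(counts)
  observed <- tabulate(match(assignment$profile, profiles$id),
                       nbins = nrow(profiles))
  p <- vapply(seq_len(nrow(profiles)), function(k) {
    if (method == "fisher") {
      e <- round_half_up(expected[k])
      stats::fisher.test(rbind(c(observed[k], n - observed[k]),
                               c(e, n - e)),
                         alternative = "greater")$p.value
    } else {
      p0 <- min(max(expected[k] / n, .Machine$double.eps), 1)
      stats::binom.test(observed[k], n, p = p0,
                        alternative = "greater")$p.value
    }
  }, numeric(1))
  out <- data.frame(profile = profiles$id, observed = observed,
                    expected = expected, p = p, significant = p < alpha)
  structure(out, class = c("stc_significance", "data.frame"),
            n = n, n_orderings = nrow(perms),
            unassigned = sum(is.na(assignment$profile)))
}

#' @export
print.stc_significance <- function(x, ...) {
  cat("Profile significance over", attr(x, "n_orderings"),
      "orderings of", attr(x, "n"), "genes (",
      attr(x, "unassigned"), "unassigned )\n")
  NextMethod()
}
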