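#' Simulation configuration
#'
#' Describes a synthetic short-series expression experiment: `n_genes` genes
#' over `length(groups)` ordered conditions with `replicates_per_group`
#' arrays each. A fraction of genes is planted on unit-change trend profiles
#' (see [enumerate_profiles()]); the remainder are null (flat). Per-gene
#' variances of log2 signals are drawn from an inverse-gamma prior — the
#' reciprocal of a Gamma(shape `variance_prior_shape`, scale
#' `variance_prior_scale`) draw — matching the random-variance model used by
#' the moderated F-test. Signals are generated in log2 space and
#' exponentiated, so the per-group geometric mean of linear signals has an
#' analytically known log2 value (`baseline_log2_mean` + `effect_size` times
#' the profile position).
#'
#' An optional hub module plants a correlated gene group inside one profile,
#' emulating a tightly co-regulated module organized around one regulator.
#' The first `1 + hub_size` genes planted on `hub_profile` form the module;
#' all share a latent sample-level factor that is centered within each
#' condition (so the module's co-fluctuation rides on top of the trend
#' without distorting per-group means). The hub's log2 noise IS the latent
#' factor; each spoke's noise is `hub_cor` times the factor plus
#' `sqrt(1 - hub_cor^2)` independent noise, giving hub-spoke noise
#' correlation `hub_cor` and spoke-spoke correlation `hub_cor^2` — a
#' correlation-through-the-hub design in which the designated hub is the
#' best-connected module gene. Module genes use a fixed noise sd `hub_sd`
#' (default 0.2 log2 units): small enough that module genes remain clearly
#' differentially expressed, yet large enough that near the top of the
#' correlation range the hub-spoke correlation separates from the
#' spoke-spoke correlation (about 0.993 vs 0.985 under the defaults).
#'
#' @param n_genes number of genes (>= 1)
#' @param groups ordered condition labels (length >= 2)
#' @param replicates_per_group arrays per condition (>= 1; >= 2 needed
#'   downstream for variance estimation)
#' @param profile_fractions named numeric vector, names = profile ids (as
#'   characters) valid for this `m` with unit-change limit 1, values =
#'   fraction of genes planted on that profile; must sum to <= 1
#' @param effect_size log2 units of expression change per unit profile step
#'   (>= 0)
#' @param variance_prior_shape,variance_prior_scale shape `a` and scale `b`
#'   of the gamma prior on inverse variance (both > 0)
#' @param baseline_log2_mean log2 expression of the anchor condition
#' @param hub_size number of spoke genes in the planted hub module (0 = no
#'   module)
#' @param hub_cor hub-spoke noise correlation in (0, 1)
#' @param hub_profile profile id (character or integer) hosting the module
#' @param hub_sd fixed log2 noise sd of module genes (> 0)
#' @param seed integer RNG seed
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_genes = 2000,
                       groups = c("control", "OVA", "4w_after"),
                       replicates_per_group = 3,
                       profile_fractions = c("5" = 0.10, "2" = 0.05,
                                             "6" = 0.05),
                       effect_size = 1.0,
                       variance_prior_shape = 2,
                       variance_prior_scale = 10,
                       baseline_log2_mean = 8,
                       hub_size = 40,
                       hub_cor = 0.95,
                       hub_profile = "5",
                       hub_sd = 0.2,
                       seed = 1L) {
  m <- length(groups)
  if (m < 2) stop("need at least 2 ordered groups")
  if (n_genes < 1 || replicates_per_group < 1)
    stop("n_genes and replicates_per_group must be >= 1")
  if (variance_prior_shape <= 0 || variance_prior_scale <= 0)
    stop("variance prior parameters must be positive")
  if (effect_size < 0) stop("effect_size must be >= 0")
  pf <- profile_fractions
  if (length(pf) > 0) {
    if (is.null(names(pf))) stop("profile_fractions must be named by profile id")
    if (any(pf < 0) || sum(pf) > 1)
      stop("profile fractions must be >= 0 and sum to <= 1")
    valid <- as.character(profile_ids(m, 1))
    bad <- setdiff(names(pf), valid)
    if (length(bad) > 0)
      stop("invalid profile id(s) for m=", m, ", c=1: ",
           paste(bad, collapse = ", "))
  }
  if (hub_size < 0) stop("hub_size must be >= 0")
  if (hub_size > 0) {
    if (hub_cor <= 0 || hub_cor >= 1) stop("hub_cor must be in (0,1)")
    if (hub_sd <= 0) stop("hub_sd must be > 0")
    if (replicates_per_group < 2)
      stop("the hub module needs >= 2 replicates per group")
    hub_profile <- as.character(hub_profile)
    if (!hub_profile %in% names(pf))
      stop("hub_profile must be one of the planted profiles")
  }
  structure(list(n_genes = as.integer(n_genes), groups = as.character(groups),
                 replicates_per_group = as.integer(replicates_per_group),
                 profile_fractions = pf, effect_size = effect_size,
                 variance_prior_shape = variance_prior_shape,
                 variance_prior_scale = variance_prior_scale,
                 baseline_log2_mean = baseline_log2_mean,
                 hub_size = as.integer(hub_size), hub_cor = hub_cor,
                 hub_profile = as.character(hub_profile), hub_sd = hub_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_genes, "genes;",
      length(x$groups), "groups x", x$replicates_per_group, "replicates\n")
  if (length(x$profile_fractions) > 0)
    cat("Planted profiles:",
        paste(sprintf("%s (%.0f%%)", names(x$profile_fractions),
                      100 * x$profile_fractions), collapse = ", "), "\n")
  cat("Effect:", x$effect_size, "log2/step; variance prior a =",
      x$variance_prior_shape, ", b =", x$variance_prior_scale, "\n")
  if (x$hub_size > 0)
    cat("Hub module:", x$hub_size, "spokes on profile", x$hub_profile,
        "(noise correlation", x$hub_cor, ")\n")
  invisible(x)
}

# variance floor avoiding degenerate zero-variance genes
.VAR_FLOOR <- 1e-6

#' Simulate an expression dataset with known ground truth
#'
#' Draws per-gene variances from the inverse-gamma prior, plants trend
#' profiles and the optional hub module described in [sim_config()], and
#' returns strictly positive linear-scale signals together with a truth
#' table for recovery tests.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_dataset`: `matrix` (an [expr_matrix()]),
#'   `truth` (data.frame: `gene`, `profile` (id or NA for null genes),
#'   `variance`, `is_hub`, `is_spoke`, plus one `mean_<group>` column of true
#'   group log2 means), and `config`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 100, seed = 7, hub_size = 5))
#' table(ds$truth$profile, useNA = "ifany")
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- length(config$groups)
  n_rep <- config$replicates_per_group
  S <- m * n_rep
  G <- config$n_genes
  profiles <- enumerate_profiles(m, 1)

  # planted profile per gene (NA = null/flat), planted blocks first
  counts <- if (length(config$profile_fractions) > 0)
    round(config$profile_fractions * G) else numeric(0)
  if (sum(counts) > G) stop("profile fractions leave no room at this n_genes")
  truth_profile <- rep(NA_integer_, G)
  pos <- 1L
  for (pid in names(counts)) {
    k <- counts[[pid]]
    if (k > 0) truth_profile[pos:(pos + k - 1L)] <- as.integer(pid)
    pos <- pos + as.integer(k)
  }

  genes <- sprintf("gene_%05d", seq_len(G))
  samples <- paste0(rep(config$groups, each = n_rep), "_r",
                    rep(seq_len(n_rep), times = m))
  design <- data.frame(sample = samples,
                       group = factor(rep(config$groups, each = n_rep),
                                      levels = config$groups))

  # true group log2 means: baseline + effect * profile position
  pos_mat <- matrix(0, G, m)
  planted <- !is.na(truth_profile)
  if (any(planted)) {
    pv <- profile_positions(profiles)
    pos_mat[planted, ] <- pv[match(truth_profile[planted], profiles$id), ,
                             drop = FALSE]
  }
  mu <- config$baseline_log2_mean + config$effect_size * pos_mat

  sigma2 <- pmax(1 / stats::rgamma(G, shape = config$variance_prior_shape,
                                   scale = config$variance_prior_scale),
                 .VAR_FLOOR)

  z <- matrix(stats::rnorm(G * S), G, S)
  is_hub <- rep(FALSE, G)
  is_spoke <- rep(FALSE, G)
  if (config$hub_size > 0) {
    members <- which(truth_profile == as.integer(config$hub_profile))
    if (length(members) < config$hub_size + 1L)
      stop("hub module needs ", config$hub_size + 1L,
           " genes on profile ", config$hub_profile, "; only ",
           length(members), " planted")
    hub <- members[1L]
    spokes <- members[seq(2L, config$hub_size + 1L)]
    is_hub[hub] <- TRUE
    is_spoke[spokes] <- TRUE
    rho <- config$hub_cor
    # latent module factor: the hub's noise, centered within each condition
    # so module co-fluctuation does not shift group means, rescaled to unit
    # variance (centering n replicates removes 1 df)
    u <- z[hub, ]
    for (lev in config$groups) {
      sel <- design$group == lev
      u[sel] <- u[sel] - mean(u[sel])
    }
    u <- u * sqrt(n_rep / (n_rep - 1))
    z[hub, ] <- u
    z[spokes, ] <- rho * matrix(u, length(spokes), S, byrow = TRUE) +
      sqrt(1 - rho^2) * z[spokes, , drop = FALSE]
    sigma2[c(hub, spokes)] <- config$hub_sd^2
  }

  log2_vals <- mu[, rep(seq_len(m), each = n_rep)] + sqrt(sigma2) * z
  vals <- 2^log2_vals
  dimnames(vals) <- list(genes, samples)

  truth <- data.frame(gene = genes, profile = truth_profile,
                      variance = sigma2, is_hub = is_hub,
                      is_spoke = is_spoke)
  mu_df <- as.data.frame(mu)
  names(mu_df) <- paste0("mean_", config$groups)
  truth <- cbind(truth, mu_df)

  structure(list(matrix = expr_matrix(vals, design), truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset (seed", x$config$seed, ")\n")
  print(x$matrix)
  cat("Planted genes:", sum(!is.na(x$truth$profile)), "of",
      nrow(x$truth), "\n")
  invisible(x)
}

#' Simulate gene-set collections with planted enriched sets
#'
#' Builds `n_sets` random gene sets over the simulated universe plus, for
#' each requested profile id, one planted set drawn predominantly (90% of
#' its members, at least 80% guaranteed) from genes whose true profile is
#' that id.
#'
#' @param truth truth table from [simulate_dataset()]
#' @param n_sets number of random sets
#' @param set_size members per set (<= number of genes)
#' @param planted profile ids (integer/character) to plant sets for
#' @param seed integer RNG seed
#' @param planted_fraction fraction of a planted set drawn from the profile's
#'   genes (default 0.9, must be >= 0.8)
#' @return a [gene_set_collection()]; planted sets are named
#'   `planted_profile_<id>`
#' @export
simulate_gene_sets <- function(truth, n_sets, set_size, planted = integer(0),
                               seed = 1L, planted_fraction = 0.9) {
  if (nrow(truth) == 0) stop("empty truth table")
  if (set_size > nrow(truth)) stop("set_size exceeds number of genes")
  if (planted_fraction < 0.8 || planted_fraction > 1)
    stop("planted_fraction must be in [0.8, 1]")
  set.seed(seed)
  universe <- truth$gene
  sets <- list()
  if (n_sets > 0) {
    for (i in seq_len(n_sets)) {
      sets[[sprintf("random_set_%03d", i)]] <-
        list(description = "random background set",
             genes = sort(sample(universe, set_size)))
    }
  }
  for (pid in as.character(planted)) {
    members <- truth$gene[!is.na(truth$profile) &
                            truth$profile == as.integer(pid)]
    if (length(members) == 0)
      stop("no genes planted on profile ", pid)
    n_in <- min(round(planted_fraction * set_size), length(members))
    if (n_in < ceiling(0.8 * set_size))
      stop("profile ", pid, " has too few genes (", length(members),
           ") for a planted set of size ", set_size)
    inside <- sample(members, n_in)
    outside <- sample(setdiff(universe, members), set_size - n_in)
    sets[[paste0("planted_profile_", pid)]] <-
      list(description = paste("set enriched for profile", pid, "genes"),
           genes = sort(c(inside, outside)))
  }
  gene_set_collection(sets, universe)
}

#' Simulate an Erdős–Rényi random graph as a network object
#'
#' Each of the `choose(n_nodes, 2)` unordered node pairs becomes an edge
#' independently with probability `edge_prob`. Useful as a fixture with
#' brute-force-checkable metrics.
#'
#' @param n_nodes number of nodes (>= 1)
#' @param edge_prob edge probability in \[0, 1\]
#' @param seed integer RNG seed
#' @return a `coexpr_network` (see [build_network()]) with unit edge weights
#' @export
simulate_random_graph <- function(n_nodes, edge_prob, seed = 1L) {
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]")
  set.seed(seed)
  nodes <- sprintf("node_%03d", seq_len(n_nodes))
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < edge_prob
  edges <- data.frame(from = nodes[idx[keep, 1]], to = nodes[idx[keep, 2]],
                      r = rep(1, sum(keep)))
  new_coexpr_network(nodes, edges, threshold = NA_real_)
}
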