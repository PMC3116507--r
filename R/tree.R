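# Pairwise maximum-likelihood distances under the substitution model,
# neighbor-joining tree construction, and nonparametric bootstrap support.

# Precomputed log site-probability grid: column g holds, flattened row-major
# over residue pairs (a, b), log[p_inv pi_a 1(a=b) + (1-p_inv) pi_a
# Pmix_ab(t_g)] for log-spaced t_g. Shared by all pairs and all bootstrap
# replicates of an alignment.
.dist_grid <- function(model, t_max = 10, n_grid = 160) {
  log_t <- seq(log(2e-4), log(t_max), length.out = n_grid)
  pi <- unname(model$freq)
  inv <- model$p_inv * diag(pi)
  logP <- vapply(log_t, function(lt) {
    P <- prob_matrix_mix(model, exp(lt))
    sp <- inv + (1 - model$p_inv) * (pi * P)
    as.vector(t(log(pmax(sp, 1e-300))))
  }, numeric(400))
  list(logP = logP, log_t = log_t, t_max = t_max)
}

#' Pairwise maximum-likelihood distance
#'
#' Branch length maximizing the two-sequence likelihood under the model
#' (gamma categories and invariant class included), found by golden-section
#' search. Identical pairs have distance 0; pairs with no shared ungapped
#' columns get `max_dist` (flagged).
#'
#' @param a,b Aligned sequences (equal length, gaps `-`).
#' @param model An [subst_model()].
#' @param max_dist Distance ceiling and no-overlap fallback.
#' @return Tibble: `distance`, `shared_sites`, `no_overlap`.
#' @export
ml_distance <- function(a, b, model = subst_model(), max_dist = 10) {
  stopifnot(nchar(a) == nchar(b))
  codes <- do.call(rbind, aa_to_int(c(a, b)))
  rownames(codes) <- c("a", "b")
  grid <- .dist_grid(model, max_dist)
  D <- .mldist_grid(codes, rep(1, ncol(codes)), grid$logP, grid$log_t,
                    max_dist)
  shared <- sum(codes[1, ] >= 0 & codes[2, ] >= 0)
  tibble::tibble(distance = D[1, 2], shared_sites = shared,
                 no_overlap = shared == 0)
}

#' Maximum-likelihood distance matrix of an alignment
#'
#' @param x An [msa()] object.
#' @param model An [subst_model()].
#' @param weights Optional per-site weights (bootstrap resampling).
#' @param max_dist Distance ceiling.
#' @param grid Optional precomputed probability grid (internal reuse across
#'   bootstrap replicates).
#' @return Symmetric matrix with zero diagonal, dimnames = sequence ids.
#' @export
ml_distance_matrix <- function(x, model = subst_model(), weights = NULL,
                               max_dist = 10, grid = NULL) {
  stopifnot(inherits(x, "hgt_msa"))
  w <- weights %||% rep(1, x$n_sites)
  stopifnot(length(w) == x$n_sites)
  grid <- grid %||% .dist_grid(model, max_dist)
  D <- .mldist_grid(x$codes, as.numeric(w), grid$logP, grid$log_t, max_dist)
  dimnames(D) <- list(x$ids, x$ids)
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix; negative branch
#' lengths are clamped to zero.
#'
#' @param d Symmetric distance matrix (n >= 3) with dimnames.
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' NJ-on-ML-distances tree for each replicate, and reports for each
#' internal edge of the original tree the percentage of replicates whose
#' tree contains the same bipartition.
#'
#' @param x An [msa()] object (>= 4 sequences).
#' @param model An [subst_model()].
#' @param n_reps Bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @return List: `tree` (the original NJ tree with `node.label` set to
#'   integer percent support; root label empty), `support` (named vector by
#'   internal node), `n_reps`.
#' @export
bootstrap_support <- function(x, model = subst_model(), n_reps = 1000,
                              seed = 1) {
  stopifnot(inherits(x, "hgt_msa"), length(x$ids) >= 4)
  grid <- .dist_grid(model)
  tree <- nj_tree(ml_distance_matrix(x, model, grid = grid))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    w <- tabulate(sample.int(x$n_sites, x$n_sites, replace = TRUE),
                  nbins = x$n_sites)
    reps[[r]] <- nj_tree(ml_distance_matrix(x, model, weights = w,
                                            grid = grid))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps)
  tree$node.label <- as.character(support)
  tree$node.label[1] <- ""   # root of the unrooted representation
  names(support) <- length(x$ids) + seq_along(support)
  list(tree = tree, support = support, n_reps = n_reps)
}

#' Edge support lookup for a bipartition defined by a node
#'
#' @param bs Result of [bootstrap_support()].
#' @param node Internal node number.
#' @return Support percentage (NA for the root pseudo-node).
#' @export
node_support <- function(bs, node) {
  s <- bs$support[as.character(node)]
  unname(s)
}
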