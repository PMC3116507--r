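# Felsenstein pruning log-likelihood under JTT+Gamma+I, model-parameter
# estimation by nested golden-section searches, and coarse per-branch
# length optimization used before topology testing.
#
# Trees are ape `phylo` objects; alignments are `hgt_msa`. Gaps/unknowns
# are treated as missing data (partial vector of ones).

# site pattern compression: returns list(codes = taxa x npat, weights,
# map = site -> pattern index)
.site_patterns <- function(codes) {
  key <- apply(codes, 2, paste, collapse = ",")
  u <- !duplicated(key)
  map <- match(key, key[u])
  list(codes = codes[, u, drop = FALSE],
       weights = as.vector(table(factor(map, levels = seq_len(sum(u))))),
       map = map)
}

# Pruning engine: caches pattern compression, tip partials and traversal
# order for one (topology, alignment) so repeated evaluations (model fits,
# per-branch optimization) pay only the per-category matrix work. The
# returned closure takes a model and optionally replacement edge lengths
# (in the original tree's edge order).
.ll_engine <- function(tree, codes) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  pat <- .site_patterns(codes)
  npat <- ncol(pat$codes)
  post <- ape::reorder.phylo(tree, "postorder")
  key <- function(e) paste(e[, 1], e[, 2])
  orig_to_post <- match(key(post$edge), key(tree$edge))
  tip_part <- vector("list", n_tip)
  for (i in seq_len(n_tip)) {
    v <- pat$codes[tree$tip.label[i], ]
    m <- matrix(1, 20, npat)
    ok <- v >= 0
    m[, ok] <- 0
    m[cbind(v[ok] + 1L, which(ok))] <- 1
    tip_part[[i]] <- m
  }
  inv <- apply(pat$codes, 2, function(v) {
    obs <- unique(v[v >= 0])
    if (length(obs) == 1) .jtt_freq[obs + 1L] / sum(.jtt_freq) else 0
  })
  edges <- post$edge
  n_edge <- nrow(edges)
  root <- edges[n_edge, 1]
  function(model, el = NULL) {
    el_post <- (el %||% tree$edge.length)[orig_to_post]
    lv <- matrix(0, npat, length(model$rates))
    for (kc in seq_along(model$rates)) {
      rate <- model$rates[kc]
      partial <- vector("list", n_node)
      for (k in seq_len(n_edge)) {
        child <- edges[k, 2]
        cp <- if (child <= n_tip) tip_part[[child]] else partial[[child]]
        contrib <- prob_matrix(model, el_post[k], rate) %*% cp
        parent <- edges[k, 1]
        partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                             else partial[[parent]] * contrib
      }
      lv[, kc] <- as.vector(model$freq %*% partial[[root]])
    }
    lik <- (1 - model$p_inv) * rowMeans(lv)
    if (model$p_inv > 0) lik <- lik + model$p_inv * inv
    site_ll <- log(pmax(lik, 1e-300))[pat$map]
    list(loglik = sum(site_ll), site_loglik = site_ll)
  }
}

#' Pruning log-likelihood of a tree given an alignment
#'
#' Felsenstein pruning under the model's JTT+Gamma+I mixture: the site
#' likelihood is `p_inv * [site invariant] * pi(constant residue) +
#' (1 - p_inv) * mean over gamma categories` of the variable-class
#' likelihood. Gaps are missing data. The tree may be rooted or unrooted
#' (likelihood is root-invariant for this reversible model); it must be
#' binary.
#'
#' @param tree `phylo` with branch lengths; leaf set must equal the MSA ids.
#' @param x An [msa()] object.
#' @param model An [subst_model()].
#' @return List: `loglik` (total), `site_loglik` (per original site,
#'   natural log).
#' @export
tree_loglik <- function(tree, x, model) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "hgt_msa"))
  if (!setequal(tree$tip.label, x$ids)) {
    stop("tree leaves must match alignment ids")
  }
  if (!ape::is.binary(tree)) stop("tree must be binary")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(!is.finite(tree$edge.length))) {
    stop("tree must have finite branch lengths")
  }
  .ll_engine(tree, x$codes)(model)
}

#' Estimate gamma shape and invariant proportion
#'
#' Maximizes the pruning likelihood over `(alpha, p_inv)` on a fixed
#' topology with branch lengths, via nested 1-D golden-section searches
#' (outer in `log(alpha)`, inner in `p_inv`), to a parameter tolerance of
#' `tol`.
#'
#' @param x An [msa()] object.
#' @param tree Fixed `phylo` with branch lengths; by default an NJ tree on
#'   ML distances under a fixed starting model.
#' @param n_cat Gamma categories.
#' @param alpha_range,p_inv_range Search intervals.
#' @param tol Convergence tolerance in the parameter.
#' @param max_iter Golden-section iteration cap per search; exceeding it is
#'   an error carrying the best-so-far values.
#' @return Object of class `hgt_subst_fit`: the fitted [subst_model()] plus
#'   `alpha`, `p_inv`, `loglik`, `n_sites`, `n_taxa`, `tree`.
#' @export
fit_model <- function(x, tree = NULL, n_cat = 4L,
                      alpha_range = c(0.05, 20), p_inv_range = c(0, 0.8),
                      tol = 1e-4, max_iter = 200) {
  stopifnot(inherits(x, "hgt_msa"))
  if (is.null(tree)) {
    m0 <- subst_model(alpha = 1, p_inv = 0, n_cat = n_cat)
    tree <- nj_tree(ml_distance_matrix(x, m0))
  }
  engine <- .ll_engine(tree, x$codes)
  ll_at <- function(alpha, p_inv) {
    engine(subst_model(alpha = alpha, p_inv = p_inv, n_cat = n_cat))$loglik
  }
  inner <- function(alpha) {
    o <- .golden_max(function(p) ll_at(alpha, p), p_inv_range[1],
                     p_inv_range[2], tol, max_iter)
    list(p_inv = o$x, ll = o$f)
  }
  outer <- .golden_max(function(la) inner(exp(la))$ll,
                       log(alpha_range[1]), log(alpha_range[2]),
                       tol, max_iter)
  alpha <- exp(outer$x)
  pin <- inner(alpha)
  model <- subst_model(alpha = alpha, p_inv = pin$p_inv, n_cat = n_cat)
  structure(list(model = model, alpha = alpha, p_inv = pin$p_inv,
                 loglik = pin$ll, n_sites = x$n_sites,
                 n_taxa = length(x$ids), tree = tree),
            class = "hgt_subst_fit")
}

.golden_max <- function(f, a, b, tol, max_iter) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  it <- 0
  while ((b - a) > tol) {
    if (it >= max_iter) {
      stop("golden-section search did not converge; best so far x = ",
           format((a + b) / 2), ", f = ", format(max(f1, f2)))
    }
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
    it <- it + 1
  }
  if (f1 >= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' @export
print.hgt_subst_fit <- function(x, ...) {
  cat("JTT+Gamma+I fit:", x$n_taxa, "taxa,", x$n_sites, "sites\n")
  cat("  alpha =", format(x$alpha, digits = 4),
      " p_inv =", format(x$p_inv, digits = 4),
      " logLik =", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Tidy a substitution-model fit
#'
#' @param x An `hgt_subst_fit`.
#' @param ... Unused.
#' @return Tibble with one row per estimated parameter.
#' @export
tidy.hgt_subst_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "p_inv"),
                 estimate = c(x$alpha, x$p_inv))
}

#' One-line summary of a substitution-model fit
#'
#' @param x An `hgt_subst_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `n_sites`, `n_taxa`, `alpha`, `p_inv`.
#' @export
glance.hgt_subst_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_sites = x$n_sites, n_taxa = x$n_taxa,
                 alpha = x$alpha, p_inv = x$p_inv)
}

# ---------------------------------------------------------------------------
# Coarse branch-length optimization: one pass of per-branch Brent using
# cached partials on both sides of each edge.
# ---------------------------------------------------------------------------

#' Optimize branch lengths on a fixed topology
#'
#' One (or more) sweeps of per-branch 1-D optimization of the pruning
#' likelihood, each branch optimized by `stats::optimize` with the others
#' held fixed. Intended as the coarse optimization before topology tests.
#'
#' @param tree `phylo` with starting branch lengths.
#' @param x An [msa()] object.
#' @param model An [subst_model()].
#' @param passes Sweeps over all branches.
#' @param tol Optimizer tolerance on each branch length.
#' @param max_bl Upper bound for any branch length.
#' @return The tree with updated branch lengths.
#' @export
optim_branch_lengths <- function(tree, x, model, passes = 1, tol = 1e-3,
                                 max_bl = 10) {
  stopifnot(inherits(tree, "phylo"))
  engine <- .ll_engine(tree, x$codes)
  el <- tree$edge.length
  for (p in seq_len(passes)) {
    for (k in seq_along(el)) {
      f <- function(t) {
        e2 <- el
        e2[k] <- t
        engine(model, e2)$loglik
      }
      o <- stats::optimize(f, c(1e-8, max_bl), maximum = TRUE, tol = tol)
      if (o$objective > f(el[k])) el[k] <- o$maximum
    }
  }
  tree$edge.length <- el
  tree
}
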