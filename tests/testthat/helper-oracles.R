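# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route (enumeration, plain DP, closed form) so a
# defect in the package's path cannot cancel in the comparison.

# All maximal local alignments by explicit recursion over matched index
# pairs: a local alignment is an increasing sequence of matched positions;
# internal skips on either sequence cost open + (len-1) * extend. Feasible
# for sequences up to ~8 residues.
oracle_local_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  gap_cost <- function(len) if (len <= 0) 0 else gap_open + (len - 1) * gap_extend
  best <- 0
  recurse <- function(i, j, score) {
    # (i, j) last matched pair; try every later pair
    best <<- max(best, score)
    if (i >= m || j >= n) return()
    for (ii in (i + 1):m) {
      for (jj in (j + 1):n) {
        s2 <- score + S[ca[ii], cb[jj]] -
          gap_cost(ii - i - 1) - gap_cost(jj - j - 1)
        recurse(ii, jj, s2)
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      recurse(i, j, S[ca[i], cb[j]])
    }
  }
  best
}

# Plain linear-gap Smith-Waterman DP in R (no affine machinery): an
# independent route for the case gap_open == gap_extend.
oracle_sw_linear <- function(a, b, S, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  H <- matrix(0, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + S[ca[i], cb[j]],
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
    }
  }
  max(H)
}

# Global affine-gap Needleman-Wunsch optimum in R, end gaps penalized
# (same convention as the package's profile aligner).
oracle_nw_global <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in seq_len(n)) Y[1, j + 1] <- -gap_open - (j - 1) * gap_extend
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open,
                             Y[i, j + 1] - gap_open,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open,
                             X[i + 1, j] - gap_open,
                             Y[i + 1, j] - gap_extend)
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + S[ca[i], cb[j]]
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# score of a given 2-row alignment under the same affine convention
score_pairwise_alignment <- function(row_a, row_b, S, gap_open, gap_extend) {
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  sc <- 0
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      sc <- sc - if (in_gap_a) gap_extend else gap_open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      sc <- sc - if (in_gap_b) gap_extend else gap_open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      sc <- sc + S[ca[k], cb[k]]
      in_gap_a <- in_gap_b <- FALSE
    }
  }
  sc
}

# Tree log-likelihood by brute-force enumeration over all internal-node
# state assignments (rooted at the internal node adjacent to the last
# edge), averaging over gamma categories and adding the invariant class.
oracle_tree_loglik <- function(tree, codes, model) {
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1]))
  k <- length(internal)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  nsites <- ncol(codes)
  site_lik <- numeric(nsites)
  for (s in seq_len(nsites)) {
    lik_var <- 0
    for (rate in model$rates) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e)
        prob_matrix(model, tree$edge.length[e], rate))
      total <- 0
      grid <- do.call(expand.grid, rep(list(1:20), k))
      for (g in seq_len(nrow(grid))) {
        st <- integer(n_tip + k)
        st[internal] <- as.integer(grid[g, ])
        for (i in seq_len(n_tip)) st[i] <- codes[tree$tip.label[i], s] + 1L
        pr <- model$freq[st[root]]
        for (e in seq_len(nrow(tree$edge))) {
          pr <- pr * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
        }
        total <- total + pr
      }
      lik_var <- lik_var + total / length(model$rates)
    }
    obs <- codes[, s]
    inv <- if (length(unique(obs[obs >= 0])) == 1)
      model$freq[unique(obs[obs >= 0]) + 1L] else 0
    site_lik[s] <- (1 - model$p_inv) * lik_var + model$p_inv * inv
  }
  sum(log(site_lik))
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws.
oracle_hyper_enum <- function(k, K, n, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(pop[idx]))
  mean(hits >= k)
}

# simulate an alignment of n sequences along a tree under the plain JTT
# model (optionally with gamma/invariant classes via the model argument)
simulate_alignment <- function(tree, n_sites, model = subst_model(),
                               seed = 1) {
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  n_node <- max(tree$edge)
  # per-site rate draws: invariant class + gamma category
  rates <- model$rates[sample.int(length(model$rates), n_sites,
                                  replace = TRUE)]
  if (model$p_inv > 0) {
    rates[stats::runif(n_sites) < model$p_inv] <- 0
  }
  states <- matrix(NA_integer_, n_node, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$freq) - 1L
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    out <- states[par, ]
    for (rr in unique(rates)) {
      idx <- which(rates == rr)
      if (rr == 0) { out[idx] <- states[par, idx]; next }
      P <- prob_matrix(model, t_e, rr)
      for (st in unique(states[par, idx])) {
        ii <- idx[states[par, idx] == st]
        out[ii] <- sample.int(20L, length(ii), replace = TRUE,
                              prob = P[st + 1L, ]) - 1L
      }
    }
    states[ch, ] <- out
  }
  rows <- apply(states[seq_len(n_tip), , drop = FALSE] + 1L, 1, function(v)
    paste(hgtscan:::AA_ORDER[v], collapse = ""))
  msa(stats::setNames(rows, tree$tip.label))
}

# small synthetic benchmark shared by several test files (cached)
tiny_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(
        n_species_per_group = c(arthropod_insect = 3, other_metazoan = 3,
                                plant = 4, fungus = 3, other_eukaryote = 3,
                                bacterium = 4),
        n_families = 20, n_insect_only = 3, n_hgt_implants = 2,
        n_transposons = 2, seed = 11)
      cache <<- simulate_hgt_data(cfg)
    }
    cache
  }
})
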