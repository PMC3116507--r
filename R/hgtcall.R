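# Turning a supported gene tree plus taxon labels into an HGT verdict:
# nested-clade classification with support thresholds, SH confirmation
# against the constrained vertical topology, donor assignment and
# transfer-direction evidence.

NATIVE_GROUPS <- c("arthropod_insect", "other_metazoan")

group_class <- function(group) {
  dplyr::case_when(
    group %in% NATIVE_GROUPS ~ "native",
    group %in% c("bacterium", "archaeon") ~ "prokaryote",
    group == "plant" ~ "plant",
    group == "fungus" ~ "fungus",
    TRUE ~ "other_eukaryote")
}

# nested clades containing the query: walk from the query's attachment
# node, at each step absorbing the smaller child subtree and descending
# into the larger. Each clade is an edge bipartition side; its support is
# looked up by the complement leaf set.
.query_clades <- function(tree, query) {
  rt <- ape::root(ape::unroot(tree), outgroup = query, resolve.root = TRUE)
  n_tip <- length(rt$tip.label)
  qi <- match(query, rt$tip.label)
  root <- n_tip + 1L
  kids <- function(v) rt$edge[rt$edge[, 1] == v, 2]
  # descendant tips per node, computed once
  desc <- vector("list", n_tip + rt$Nnode)
  post <- ape::reorder.phylo(rt, "postorder")
  for (i in seq_len(n_tip)) desc[[i]] <- rt$tip.label[i]
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  rk <- kids(root)
  cur <- rk[rk != qi][1]
  clade <- query
  out <- list()
  while (cur > n_tip) {
    ch <- kids(cur)
    sizes <- vapply(ch, function(v) length(desc[[v]]), integer(1))
    o <- order(sizes)
    small <- ch[o[1]]; large <- ch[o[2]]
    clade <- c(clade, desc[[small]])
    out[[length(out) + 1]] <- list(members = clade,
                                   complement = desc[[large]])
    cur <- large
  }
  out
}

# support lookup keyed by canonical bipartition side
.support_table <- function(bs) {
  tree <- bs$tree
  n_tip <- length(tree$tip.label)
  keys <- character(0); vals <- numeric(0)
  pp <- ape::prop.part(tree)
  for (i in seq_along(pp)) {
    node <- n_tip + i
    tips <- tree$tip.label[pp[[i]]]
    comp <- setdiff(tree$tip.label, tips)
    s <- bs$support[as.character(node)]
    if (is.na(s) || !nzchar(tree$node.label[i])) s <- NA_real_
    keys <- c(keys, paste(sort(tips), collapse = "|"),
              paste(sort(comp), collapse = "|"))
    vals <- c(vals, s, s)
  }
  stats::setNames(vals, keys)
}

.lookup_support <- function(tbl, members) {
  tbl[paste(sort(members), collapse = "|")]
}

#' Classify a supported gene tree as HGT or vertical
#'
#' Finds the smallest clade (edge bipartition side, over all rootings of
#' the unrooted tree) containing the query plus at least one other leaf.
#' The verdict is `hgt` when all non-query members of that clade belong to
#' a single foreign group-class (prokaryote, or plant; optionally fungus /
#' other eukaryote) and the clade's edge support meets the threshold(s).
#' Mixed foreign clades tolerate at most one minority leaf (majority class
#' assigned); otherwise the gene is `untestable`. `nested_depth` counts the
#' successively larger clades beyond the first whose non-query members
#' remain foreign-only.
#'
#' @param bs Result of [bootstrap_support()] for the gene's alignment.
#' @param leaf_groups Named character vector mapping every non-query leaf
#'   to its taxonomic group.
#' @param query Query leaf label (must appear exactly once).
#' @param support_threshold Minimum percent support (ML bootstrap gate,
#'   default 80).
#' @param bayes_threshold Second gate applied to the same support value
#'   when `dual_threshold` (default 85, emulating agreement of two
#'   inference methods).
#' @param dual_threshold Apply both gates.
#' @param allow_other_donors Also accept fungus / other-eukaryote donor
#'   classes.
#' @return One-row tibble: `gene_id`, `verdict`, `donor_group`,
#'   `clade_support`, `clade_size`, `nested_depth`.
#' @export
classify_hgt <- function(bs, leaf_groups, query, support_threshold = 80,
                         bayes_threshold = 85, dual_threshold = TRUE,
                         allow_other_donors = FALSE) {
  tree <- bs$tree
  if (sum(tree$tip.label == query) != 1) {
    stop("query must appear exactly once in the tree")
  }
  others <- setdiff(tree$tip.label, query)
  if (!all(others %in% names(leaf_groups))) {
    stop("every non-query leaf needs a group label")
  }
  donor_classes <- c("prokaryote", "plant",
                     if (allow_other_donors) c("fungus", "other_eukaryote"))
  clades <- .query_clades(tree, query)
  stbl <- .support_table(bs)
  cl1 <- clades[[1]]
  mem <- setdiff(cl1$members, query)
  cls <- group_class(unname(leaf_groups[mem]))
  tab <- sort(table(cls), decreasing = TRUE)
  majority <- names(tab)[1]
  n_min <- length(cls) - tab[1]
  support <- unname(.lookup_support(stbl, cl1$members))
  if (length(support) != 1 || is.na(support)) support <- 0
  thr <- if (dual_threshold) max(support_threshold, bayes_threshold)
         else support_threshold
  verdict <- "not_hgt"
  donor_group <- NA_character_
  if (!"native" %in% cls) {
    if (n_min >= 2) {
      verdict <- "untestable"               # impure foreign clade
    } else if (n_min == 1 && !majority %in% donor_classes) {
      verdict <- "untestable"
    } else if (majority %in% donor_classes && support >= thr) {
      verdict <- "hgt"
      grp <- leaf_groups[mem][group_class(unname(leaf_groups[mem])) ==
                                majority]
      donor_group <- names(sort(table(grp), decreasing = TRUE))[1]
    }
  }
  depth <- 0L
  if (length(clades) > 1) {
    for (k in 2:length(clades)) {
      mk <- setdiff(clades[[k]]$members, query)
      if (all(group_class(unname(leaf_groups[mk])) != "native")) {
        depth <- depth + 1L
      } else break
    }
  }
  tibble::tibble(gene_id = query, verdict = verdict,
                 donor_group = donor_group, clade_support = support,
                 clade_size = length(cl1$members), nested_depth = depth)
}

#' SH confirmation of an HGT call
#'
#' Builds the constrained vertical topology (query forced monophyletic
#' with all native-group leaves) via [constrain_monophyly()] and tests it
#' against the observed tree with [sh_test()]. Confirmation means the
#' constrained topology is rejected at `alpha`.
#'
#' @param x The gene's trimmed [msa()].
#' @param model An [subst_model()].
#' @param tree Observed (supported) tree.
#' @param leaf_groups Named group vector for non-query leaves.
#' @param query Query leaf.
#' @param n_rell,seed,alpha SH parameters.
#' @return One-row tibble: `sh_p`, `sh_confirmed`, `has_native` (FALSE when
#'   the tree carries no native-group leaf, leaving nothing to constrain;
#'   `sh_p` is NA then).
#' @export
confirm_sh <- function(x, model, tree, leaf_groups, query, n_rell = 1000,
                       seed = 1, alpha = 0.05) {
  natives <- names(leaf_groups)[group_class(unname(leaf_groups)) ==
                                  "native"]
  natives <- intersect(natives, tree$tip.label)
  if (length(natives) == 0) {
    return(tibble::tibble(sh_p = NA_real_, sh_confirmed = NA,
                          has_native = FALSE))
  }
  constrained <- constrain_monophyly(tree, c(query, natives), query = query)
  res <- sh_test(x, model, tree, constrained, n_rell = n_rell, seed = seed)
  tibble::tibble(sh_p = res$p_value, sh_confirmed = res$p_value < alpha,
                 has_native = TRUE)
}

#' Assign the donor species from a hit table
#'
#' The donor is the subject species of the maximal-bit-score foreign
#' (non-native-group) hit; ties break by percent identity then subject id.
#'
#' @param hits Hit table rows for one gene (from [best_hits()]).
#' @return One-row tibble: `donor_top_species`, `donor_subject`,
#'   `e_value`, `pct_identity`, `query_coverage`.
#' @export
assign_donor <- function(hits) {
  f <- hits[group_class(hits$group) != "native", ]
  if (nrow(f) == 0) stop("no foreign hits: donor cannot be assigned")
  f <- dplyr::arrange(f, dplyr::desc(.data$bit_score),
                      dplyr::desc(.data$pct_identity), .data$subject_id)
  tibble::tibble(donor_top_species = f$species_id[1],
                 donor_subject = f$subject_id[1], e_value = f$e_value[1],
                 pct_identity = f$pct_identity[1],
                 query_coverage = f$query_coverage[1])
}

#' Direction-of-transfer evidence
#'
#' Transfer into the recipient is supported when the gene is intronless
#' and nested inside the foreign clade (at least one successively larger
#' foreign-only clade); otherwise the direction is ambiguous.
#'
#' @param intronless Logical.
#' @param nested_depth Integer from [classify_hgt()].
#' @return `"to_recipient"` or `"ambiguous"`.
#' @export
direction_evidence <- function(intronless, nested_depth) {
  if (isTRUE(intronless) && nested_depth >= 1) "to_recipient" else "ambiguous"
}
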