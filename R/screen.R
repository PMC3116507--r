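# The filter cascade: every exclusion rule between the raw proteome and the
# candidate set sent to phylogenetics, the post-tree EST / transposon /
# duplicate / intron screens, and the stage-count ledger whose conservation
# identities mirror the study flowchart.

#' Exclude genes with homologs only in insect genomes
#'
#' A gene is excluded when every qualifying hit outside its own proteome
#' belongs to group `arthropod_insect`, or when it has no qualifying hits at
#' all (a gene without foreign homologs cannot evidence transfer).
#'
#' @param hits Hit table from [best_hits()] (self species excluded or
#'   labeled); must carry a `group` column.
#' @param gene_ids All query gene ids entering the stage (genes absent from
#'   `hits` have no qualifying hits and are excluded).
#' @param self_species Species id of the query proteome; hits to it are
#'   ignored when judging the taxon profile.
#' @return List with `retained` and `excluded` character vectors.
#' @export
insect_only_filter <- function(hits, gene_ids, self_species = "recipient") {
  h <- hits[hits$species_id != self_species, ]
  by_gene <- split(h$group, h$query_id)
  non_insect <- names(by_gene)[vapply(by_gene, function(g)
    any(g != "arthropod_insect"), logical(1))]
  retained <- intersect(gene_ids, non_insect)
  list(retained = retained, excluded = setdiff(gene_ids, retained))
}

#' Cluster homologs by reciprocal best hits
#'
#' Builds a graph whose nodes are genes and whose edges connect reciprocal
#' best hits between species (each direction judged from the hit rows
#' present in the table; alignment scores are symmetric, so a single
#' query-vs-database table supports both directions for query-subject
#' pairs). Clusters are the connected components. Genes in `singletons` that
#' carry no edge form their own cluster of size one.
#'
#' @param hits Hit table with `query_id`, `subject_id`, `species_id` (of the
#'   subject), `bit_score`; the query's species given by `query_species`
#'   (single id or named vector by query).
#' @param singletons Optional gene ids guaranteed a cluster even without
#'   edges.
#' @param query_species Species of the query genes.
#' @return Tibble `cluster_id`, `gene_id`.
#' @export
cluster_orthologs <- function(hits, singletons = character(0),
                              query_species = "recipient") {
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      cluster_id = if (length(singletons)) paste0("cluster_",
                                                  seq_along(singletons))
                   else character(0),
      gene_id = singletons))
  }
  qsp <- if (length(query_species) == 1)
    stats::setNames(rep(query_species, length(unique(hits$query_id))),
                    unique(hits$query_id))
  else query_species
  # best hit of each query in each subject species
  h <- dplyr::group_by(hits, .data$query_id, .data$species_id)
  h <- dplyr::slice_max(h, .data$bit_score, n = 1, with_ties = FALSE)
  h <- dplyr::ungroup(h)
  # reciprocal: subject's best counter-hit within the query's species.
  # By score symmetry the subject-to-query scores are the transposed table.
  rev_tbl <- tibble::tibble(query_id = hits$subject_id,
                            subject_id = hits$query_id,
                            species_id = unname(qsp[hits$query_id]),
                            bit_score = hits$bit_score)
  r <- dplyr::group_by(rev_tbl, .data$query_id, .data$species_id)
  r <- dplyr::slice_max(r, .data$bit_score, n = 1, with_ties = FALSE)
  r <- dplyr::ungroup(r)
  edges <- dplyr::inner_join(
    h[, c("query_id", "subject_id")],
    r[, c("query_id", "subject_id")],
    by = c("query_id" = "subject_id", "subject_id" = "query_id"))
  nodes <- unique(c(edges$query_id, edges$subject_id, singletons))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  tibble::tibble(cluster_id = paste0("cluster_", comp$membership),
                 gene_id = names(comp$membership))
}

#' Taxon-profile filter
#'
#' Retains a query gene when its best hit outside Arthropoda beats its best
#' Arthropoda hit by bit score (insect cluster members other than the query
#' itself are disregarded upstream; a gene with no Arthropoda hits at all is
#' retained).
#'
#' @param hits Hit table with `group` labels; hits to the query's own
#'   species should already be absent or are ignored via `self_species`.
#' @param gene_ids Gene ids entering the stage.
#' @param self_species Query proteome species id.
#' @return List with `retained` and `excluded`.
#' @export
taxon_profile_filter <- function(hits, gene_ids, self_species = "recipient") {
  h <- hits[hits$species_id != self_species & hits$query_id %in% gene_ids, ]
  verdict <- vapply(split(h, h$query_id), function(d) {
    ins <- d$bit_score[d$group == "arthropod_insect"]
    out <- d$bit_score[d$group != "arthropod_insect"]
    if (length(out) == 0) return(FALSE)
    length(ins) == 0 || max(out) > max(ins)
  }, logical(1))
  retained <- intersect(gene_ids, names(verdict)[verdict])
  list(retained = retained, excluded = setdiff(gene_ids, retained))
}

#' Few-hit filter
#'
#' Drops candidates whose homolog cluster is too small to support a
#' phylogeny.
#'
#' @param cluster_sizes Named integer vector: total sequences available for
#'   each candidate's phylogeny (query included).
#' @param min_taxa Minimum sequences required (default 5).
#' @return List with `retained` and `excluded` gene ids.
#' @export
few_hit_filter <- function(cluster_sizes, min_taxa = 5) {
  keep <- names(cluster_sizes)[cluster_sizes >= min_taxa]
  list(retained = keep,
       excluded = setdiff(names(cluster_sizes), keep))
}

#' Transposon similarity filter
#'
#' Drops a gene when its best local alignment against the transposon
#' library is both significant and long relative to the query.
#'
#' @param genes Tibble `gene_id`, `seq` (protein) or named character vector.
#' @param te_library Named character vector of library protein sequences.
#' @param model An [scoring_model()].
#' @param e_cutoff,min_coverage Drop thresholds (E-value of the best library
#'   hit, query coverage in percent).
#' @return Tibble `gene_id`, `best_e`, `best_coverage`, `drop`.
#' @export
transposon_filter <- function(genes, te_library, model = scoring_model(),
                              e_cutoff = 1e-10, min_coverage = 50) {
  stopifnot(length(te_library) > 0)
  genes <- .as_seq_tbl(genes)
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), best_e = numeric(),
                          best_coverage = numeric(), drop = logical()))
  }
  n_lib <- sum(nchar(te_library))
  S <- .aug_matrix(model$matrix)
  gc <- .aug_codes(aa_to_int(genes$seq))
  lc <- .aug_codes(aa_to_int(unname(te_library)))
  scores <- .sw_score_batch(gc, lc, S, model$gap_open, model$gap_extend)
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    j <- which.max(scores[i, ])
    ev <- evalue(scores[i, j], nchar(genes$seq[i]), n_lib, model)
    cov <- 0
    if (ev <= e_cutoff) {
      tb <- .sw_traceback(gc[[i]], lc[[j]], S, model$gap_open,
                          model$gap_extend)
      cov <- 100 * (tb$a_end - tb$a_start + 1) / nchar(genes$seq[i])
    }
    tibble::tibble(gene_id = genes$gene_id[i], best_e = ev,
                   best_coverage = cov,
                   drop = ev <= e_cutoff && cov >= min_coverage)
  })
  purrr::list_rbind(out)
}

# nucleotide scoring matrix for EST-vs-CDS local alignment (match/mismatch)
.dna_matrix <- function(match = 2L, mismatch = -3L) {
  m <- matrix(mismatch, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  diag(m) <- match
  m
}

dna_to_int <- function(x) {
  lapply(strsplit(toupper(x), ""), function(ch) {
    i <- match(ch, c("A", "C", "G", "T"))
    ifelse(is.na(i), 4L, i - 1L)  # unknowns -> extra state
  })
}

#' EST expression filter
#'
#' A gene is expressed when some EST aligns to its CDS at or above
#' `min_identity` percent over at least `min_length` nucleotides in any of
#' the supplied sets.
#'
#' @param cds Tibble `gene_id`, `cds`.
#' @param est_sets List of EST tibbles (`est_id`, `seq`), e.g. the two
#'   domestic sets.
#' @param min_identity Percent identity threshold (default 95).
#' @param min_length Minimum alignment length in nt (default 100).
#' @return Tibble `gene_id`, `expressed`.
#' @export
est_filter <- function(cds, est_sets, min_identity = 95, min_length = 100) {
  stopifnot(length(est_sets) >= 1)
  ests <- dplyr::bind_rows(est_sets)
  S4 <- .aug_matrix(.dna_matrix())
  go <- 5L; ge <- 2L
  if (nrow(ests) == 0) {
    return(tibble::tibble(gene_id = cds$gene_id, expressed = FALSE))
  }
  cc <- dna_to_int(cds$cds)
  ec <- dna_to_int(ests$seq)
  scores <- .sw_score_batch(cc, ec, S4, go, ge)
  # qualifying alignments need >= min_length columns at >= min_identity%;
  # with match 2 / mismatch -3 the score of such an alignment is at least
  smin <- ceiling(min_length * (2 * min_identity / 100 - 3 *
                                  (1 - min_identity / 100)))
  expressed <- vapply(seq_len(nrow(cds)), function(i) {
    cand <- order(scores[i, ], decreasing = TRUE)
    cand <- cand[scores[i, cand] >= smin]
    for (j in cand) {
      tb <- .sw_traceback(cc[[i]], ec[[j]], S4, go, ge)
      if (tb$align_length >= min_length &&
          100 * tb$n_ident / tb$align_length >= min_identity) return(TRUE)
    }
    FALSE
  }, logical(1))
  tibble::tibble(gene_id = cds$gene_id, expressed = expressed)
}

#' Self-duplication check
#'
#' Counts proteome genes other than the candidate itself with a qualifying
#' alignment to it (putative within-genome duplicates).
#'
#' @param gene_id Candidate id (must be in `proteome`).
#' @param proteome Tibble `gene_id`, `seq`.
#' @param model An [scoring_model()].
#' @param e_cutoff Qualifying E-value.
#' @return Integer count of non-self homologs.
#' @export
self_duplicate_check <- function(gene_id, proteome,
                                 model = scoring_model(),
                                 e_cutoff = 1e-20) {
  proteome <- .as_seq_tbl(proteome)
  i <- match(gene_id, proteome$gene_id)
  if (is.na(i)) stop("candidate not in proteome: ", gene_id)
  S <- .aug_matrix(model$matrix)
  qc <- .aug_codes(aa_to_int(proteome$seq[i]))
  sc <- .aug_codes(aa_to_int(proteome$seq[-i]))
  if (length(sc) == 0) return(0L)
  scores <- .sw_score_batch(qc, sc, S, model$gap_open, model$gap_extend)
  n_db <- sum(nchar(proteome$seq[-i]))
  ev <- evalue(as.vector(scores), nchar(proteome$seq[i]), n_db, model)
  sum(ev <= e_cutoff)
}

#' Intron count from exon records
#'
#' Under a single-transcript assumption the intron count of a gene is its
#' exon count minus one.
#'
#' @param gene_id Gene id.
#' @param gene_models Tibble of exon records with `gene_id`, `type`.
#' @return Integer intron count.
#' @export
intronless_check <- function(gene_id, gene_models) {
  ex <- gene_models[gene_models$gene_id == gene_id &
                      gene_models$type == "exon", ]
  if (nrow(ex) == 0) stop("gene absent from gene models: ", gene_id)
  nrow(ex) - 1L
}

#' Absence screen against wild-relative EST sets
#'
#' Uses the EST match criterion: a gene is absent when no qualifying match
#' exists in any wild set.
#'
#' @param cds Tibble `gene_id`, `cds` for the candidates.
#' @param wild_sets List of EST tibbles from wild relatives.
#' @inheritParams est_filter
#' @return Tibble `gene_id`, `absent`.
#' @export
absence_screen <- function(cds, wild_sets, min_identity = 95,
                           min_length = 100) {
  res <- est_filter(cds, wild_sets, min_identity, min_length)
  tibble::tibble(gene_id = res$gene_id, absent = !res$expressed)
}

# ---------------------------------------------------------------------------
# FilterReport: the ordered stage ledger
# ---------------------------------------------------------------------------

#' Build a filter-stage ledger
#'
#' Each stage records `(name, n_in, n_excluded, n_out)`; the constructor
#' enforces `n_out = n_in - n_excluded` within stages and chaining between
#' consecutive stages (`n_in` of stage k+1 equals `n_out` of stage k).
#' Inconsistent counts are an error, never silently repaired.
#'
#' @param stages Tibble (or data frame) with columns `name`, `n_in`,
#'   `n_excluded`, and optionally `n_out` (recomputed and checked when
#'   present).
#' @param excluded_ids Optional named list of per-stage excluded-id vectors.
#' @return An object of class `hgt_filter_report` (a tibble).
#' @examples
#' filter_report(data.frame(name = c("screen", "few_hit"),
#'                          n_in = c(229, NA), n_excluded = c(122, 0)))
#' @export
filter_report <- function(stages, excluded_ids = NULL) {
  stages <- tibble::as_tibble(stages)
  if (nrow(stages) == 0) {
    out <- tibble::tibble(name = character(), n_in = numeric(),
                          n_excluded = numeric(), n_out = numeric())
    return(structure(out, excluded_ids = list(), class =
                       c("hgt_filter_report", class(out))))
  }
  stopifnot(all(c("name", "n_in", "n_excluded") %in% names(stages)))
  for (k in seq_len(nrow(stages))) {
    if (k > 1 && is.na(stages$n_in[k])) {
      stages$n_in[k] <- stages$n_in[k - 1] - stages$n_excluded[k - 1]
    }
  }
  n_out <- stages$n_in - stages$n_excluded
  if ("n_out" %in% names(stages) && !all(is.na(stages$n_out))) {
    bad <- which(!is.na(stages$n_out) & stages$n_out != n_out)
    if (length(bad) > 0) {
      stop("inconsistent ledger at stage '", stages$name[bad[1]],
           "': n_out != n_in - n_excluded")
    }
  }
  stages$n_out <- n_out
  if (nrow(stages) > 1 &&
      any(stages$n_in[-1] != stages$n_out[-nrow(stages)])) {
    stop("ledger stages do not chain: n_in of a stage must equal n_out of ",
         "the previous stage")
  }
  if (any(stages$n_out < 0) || any(stages$n_excluded < 0)) {
    stop("negative counts in ledger")
  }
  structure(stages, excluded_ids = excluded_ids %||% list(),
            class = c("hgt_filter_report", class(stages)))
}

#' @export
print.hgt_filter_report <- function(x, ...) {
  cat("Filter cascade ledger\n")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  if (nrow(df) > 0) cat("final candidates:", df$n_out[nrow(df)], "\n")
  invisible(x)
}

#' Tidy a filter report
#'
#' @param x An `hgt_filter_report`.
#' @param ... Unused.
#' @return A plain tibble of stages.
#' @export
tidy.hgt_filter_report <- function(x, ...) {
  cols <- intersect(c("name", "n_in", "n_excluded", "n_out", "skipped"),
                    names(x))
  tibble::as_tibble(unclass(x)[cols])
}

#' Serialize a filter report to JSON
#'
#' @param report An `hgt_filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(
    list(stages = tidy.hgt_filter_report(report),
         excluded_ids = attr(report, "excluded_ids")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Waterfall plot of a filter cascade
#'
#' @param object An `hgt_filter_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hgt_filter_report <- function(object, ...) {
  df <- tidy.hgt_filter_report(object)
  df$name <- factor(df$name, levels = df$name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_in), fill = "grey80") +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_out), fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(y = .data$n_in,
                                    label = paste0("-", .data$n_excluded)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Filter cascade: entering (grey) and surviving (blue)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
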