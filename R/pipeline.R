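# End-to-end orchestration: search -> filter cascade -> phylogenetics ->
# HGT calls -> functional analysis, with a stage ledger, deterministic
# seeding and serializable outputs.

#' Pipeline configuration
#'
#' Houses every numeric threshold of the cascade. Defaults: E-value cutoff
#' 1e-20 for the homology screen, minimum 5 sequences per phylogeny,
#' support gates 80 (bootstrap) and 85 (second gate when
#' `dual_threshold`), SH significance 0.05, EST match >= 95% identity over
#' >= 100 nt, transposon drop at E <= 1e-10 and coverage >= 50%,
#' coexpression |r| > 0.5 with top-300 lists.
#'
#' @param e_cutoff,min_taxa,support_threshold,bayes_threshold,dual_threshold
#'   Screening and support thresholds.
#' @param sh_alpha,n_rell SH test significance and RELL replicates.
#' @param bootstrap_reps Bootstrap replicates per gene tree.
#' @param est_min_identity,est_min_length EST match criterion.
#' @param te_e_cutoff,te_min_coverage Transposon filter thresholds.
#' @param r_min,n_top Coexpression list parameters.
#' @param estimate_model Estimate (alpha, p_inv) per gene tree; otherwise
#'   use `alpha = 1, p_inv = 0`.
#' @param skip_stages Post-tree stages to toggle off (any of `"sh_test"`,
#'   `"est_filter"`, `"transposon_filter"`); a skipped stage appears in the
#'   ledger with `n_excluded = 0` and `skipped = TRUE`.
#' @param run_function Run the functional-analysis stage.
#' @param run_absence Run the wild-relative absence screen when wild EST
#'   sets are available.
#' @param seed Master seed; per-stage seeds derive from it
#'   deterministically.
#' @return List of class `hgt_config`.
#' @export
hgt_config <- function(e_cutoff = 1e-20, min_taxa = 5,
                       support_threshold = 80, bayes_threshold = 85,
                       dual_threshold = TRUE, sh_alpha = 0.05,
                       n_rell = 1000, bootstrap_reps = 1000,
                       est_min_identity = 95, est_min_length = 100,
                       te_e_cutoff = 1e-10, te_min_coverage = 50,
                       r_min = 0.5, n_top = 300, estimate_model = TRUE,
                       skip_stages = character(0), run_function = TRUE,
                       run_absence = TRUE, seed = 1) {
  stopifnot(e_cutoff > 0, min_taxa >= 3, support_threshold >= 0,
            support_threshold <= 100, sh_alpha > 0, sh_alpha < 1,
            r_min >= 0, r_min < 1, n_top >= 1, bootstrap_reps >= 1,
            all(skip_stages %in% c("sh_test", "est_filter",
                                   "transposon_filter")))
  structure(as.list(environment()), class = "hgt_config")
}

# deterministic per-stage child seeds, kept well below 2^31
stage_seed <- function(seed, k) {
  (seed * 97L + k * 1009L) %% 1000000007L
}

#' Run the full HGT-detection pipeline on a synthetic benchmark
#'
#' Stages, in order: homology search against the labeled database;
#' insect-only exclusion; ortholog clustering (reciprocal best hits);
#' taxon-profile filter; few-hit filter; per-candidate alignment,
#' trimming, NJ tree with bootstrap support and nested-clade
#' classification; SH confirmation against the constrained vertical
#' topology; EST expression filter; transposon filter; duplication and
#' intron annotation (plus the wild-relative absence screen); functional
#' analysis of the final candidates. The ledger records every stage.
#'
#' @param data An `hgt_synth_data` (or a list with the same fields).
#' @param config An [hgt_config()].
#' @param model An [scoring_model()] for alignment scoring.
#' @param progress Print one line per stage.
#' @return Object of class `hgt_run`: `report` (ledger), `calls` (per
#'   candidate reaching phylogenetics), `final` (gene ids), `trees`,
#'   `hits`, `functional` (list), `config`.
#' @export
run_hgt_pipeline <- function(data, config = hgt_config(),
                             model = scoring_model(), progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  genes <- data$proteome$gene_id
  n0 <- length(genes)

  say("search: %d queries vs %d database sequences", n0, nrow(data$database))
  hits <- best_hits(data$proteome, data$database, data$taxa, model,
                    e_cutoff = config$e_cutoff)

  s1 <- insect_only_filter(hits, genes, self_species = "recipient")
  say("insect_only: excluded %d", length(s1$excluded))

  clusters <- cluster_orthologs(
    hits[hits$query_id %in% s1$retained, ], singletons = s1$retained)

  s2 <- taxon_profile_filter(hits, s1$retained)
  say("taxon_profile: excluded %d", length(s2$excluded))

  # sequences available for each candidate's phylogeny: the query plus its
  # per-species best hits, insect sequences removed except the query itself
  tree_sets <- lapply(s2$retained, function(g) {
    h <- hits[hits$query_id == g & hits$group != "arthropod_insect", ]
    c(g, h$subject_id)
  })
  names(tree_sets) <- s2$retained
  sizes <- vapply(tree_sets, length, integer(1))
  s3 <- few_hit_filter(sizes, min_taxa = config$min_taxa)
  say("few_hit: excluded %d", length(s3$excluded))

  leaf_groups <- stats::setNames(data$database$group, data$database$gene_id)
  seqs_all <- stats::setNames(c(data$proteome$seq, data$database$seq),
                              c(data$proteome$gene_id, data$database$gene_id))

  trees <- list()
  call_rows <- list()
  for (g in s3$retained) {
    ids <- tree_sets[[g]]
    aln <- progressive_align(seqs_all[ids], model, cluster_id = g)
    mask <- trim_blocks(aln)
    if (mask$empty) {
      call_rows[[g]] <- tibble::tibble(
        gene_id = g, verdict = "untestable", donor_group = NA_character_,
        clade_support = NA_real_, clade_size = NA_integer_,
        nested_depth = NA_integer_, sh_p = NA_real_, sh_confirmed = NA)
      next
    }
    trimmed <- apply_mask(aln, mask)
    sm <- if (config$estimate_model) {
      fit_model(trimmed)$model
    } else {
      subst_model(alpha = 1, p_inv = 0)
    }
    bs <- bootstrap_support(trimmed, sm, n_reps = config$bootstrap_reps,
                            seed = stage_seed(config$seed,
                                              match(g, s3$retained)))
    trees[[g]] <- bs
    cl <- classify_hgt(bs, leaf_groups, g,
                       support_threshold = config$support_threshold,
                       bayes_threshold = config$bayes_threshold,
                       dual_threshold = config$dual_threshold)
    sh <- if (cl$verdict == "hgt") {
      confirm_sh(trimmed, sm, bs$tree, leaf_groups, g,
                 n_rell = config$n_rell,
                 seed = stage_seed(config$seed, 5000 +
                                     match(g, s3$retained)),
                 alpha = config$sh_alpha)
    } else {
      tibble::tibble(sh_p = NA_real_, sh_confirmed = NA, has_native = NA)
    }
    call_rows[[g]] <- dplyr::bind_cols(cl, sh[, c("sh_p", "sh_confirmed")])
  }
  calls <- purrr::list_rbind(call_rows)
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(
      gene_id = character(), verdict = character(),
      donor_group = character(), clade_support = numeric(),
      clade_size = integer(), nested_depth = integer(),
      sh_p = numeric(), sh_confirmed = logical())
  }
  tree_pass <- calls$gene_id[calls$verdict == "hgt"]
  say("tree_support: %d of %d classified hgt", length(tree_pass),
      length(s3$retained))
  skip <- config$skip_stages
  sh_pass <- if ("sh_test" %in% skip) tree_pass else {
    calls$gene_id[calls$verdict == "hgt" &
                    (is.na(calls$sh_confirmed) | calls$sh_confirmed)]
  }
  say("sh_test: %d confirmed", length(sh_pass))

  est_pass <- if ("est_filter" %in% skip) sh_pass else {
    est <- est_filter(data$cds[data$cds$gene_id %in% sh_pass, ],
                      data$est_sets,
                      min_identity = config$est_min_identity,
                      min_length = config$est_min_length)
    est$gene_id[est$expressed]
  }
  say("est_filter: %d expressed", length(est_pass))

  final <- if ("transposon_filter" %in% skip) est_pass else {
    te <- transposon_filter(
      data$proteome[data$proteome$gene_id %in% est_pass,
                    c("gene_id", "seq")],
      data$te_library, model, e_cutoff = config$te_e_cutoff,
      min_coverage = config$te_min_coverage)
    te$gene_id[!te$drop]
  }
  say("transposon_filter: %d final candidates", length(final))

  # annotations on the final candidates (verification, not exclusion)
  ann <- purrr::map(final, function(g) {
    introns <- intronless_check(g, data$gene_models)
    dups <- self_duplicate_check(g, data$proteome, model,
                                 e_cutoff = config$e_cutoff)
    donor <- assign_donor(hits[hits$query_id == g, ])
    depth <- calls$nested_depth[match(g, calls$gene_id)]
    tibble::tibble(gene_id = g, introns = introns, self_duplicates = dups,
                   donor_top_species = donor$donor_top_species,
                   donor_pct_identity = donor$pct_identity,
                   direction = direction_evidence(introns == 0, depth))
  }) |> purrr::list_rbind()
  if (nrow(ann) == 0) {
    ann <- tibble::tibble(
      gene_id = character(), introns = integer(),
      self_duplicates = integer(), donor_top_species = character(),
      donor_pct_identity = numeric(), direction = character())
  }
  if (config$run_absence && length(final) > 0 &&
      !is.null(data$wild_est_sets)) {
    ab <- absence_screen(data$cds[data$cds$gene_id %in% final, ],
                         data$wild_est_sets,
                         min_identity = config$est_min_identity,
                         min_length = config$est_min_length)
    ann$absent_in_wild <- ab$absent[match(ann$gene_id, ab$gene_id)]
  }
  calls <- dplyr::left_join(calls, ann, by = "gene_id")

  report <- filter_report(tibble::tibble(
    name = c("insect_only", "taxon_profile", "few_hit", "tree_support",
             "sh_test", "est_filter", "transposon_filter"),
    n_in = c(n0, rep(NA_real_, 6)),
    n_excluded = c(length(s1$excluded), length(s2$excluded),
                   length(s3$excluded),
                   length(s3$retained) - length(tree_pass),
                   length(tree_pass) - length(sh_pass),
                   length(sh_pass) - length(est_pass),
                   length(est_pass) - length(final)),
    skipped = c(FALSE, FALSE, FALSE, FALSE, "sh_test" %in% skip,
                "est_filter" %in% skip, "transposon_filter" %in% skip)),
    excluded_ids = list(insect_only = s1$excluded,
                        taxon_profile = s2$excluded,
                        few_hit = s3$excluded,
                        tree_support = setdiff(s3$retained, tree_pass),
                        sh_test = setdiff(tree_pass, sh_pass),
                        est_filter = setdiff(sh_pass, est_pass),
                        transposon_filter = setdiff(est_pass, final)))

  functional <- NULL
  if (config$run_function && length(final) > 0 && !is.null(data$expr)) {
    nexp <- normalize_expression(data$expr)
    coex <- lapply(intersect(final, rownames(nexp)), function(g) {
      cl <- coexpression_list(g, nexp, r_min = config$r_min,
                              n_top = config$n_top)
      pw <- if (nrow(cl) > 0) pathway_scores(cl, data$pathway_map)
            else tibble::tibble(pathway_id = character(), G = integer(),
                                score = numeric(), members = list())
      list(list = cl, pathways = pw)
    })
    names(coex) <- intersect(final, rownames(nexp))
    functional <- list(
      coexpression = coex,
      enrichment = enrichment(final, data$truth$gene_id, data$go_map),
      snp = snp_overlap(final, data$snp_genes),
      tissue = tissue_profile(intersect(final, rownames(nexp)), nexp,
                              data$samples))
  }

  structure(list(report = report, calls = calls, final = final,
                 trees = trees, hits = hits, functional = functional,
                 config = config, n_input = n0),
            class = "hgt_run")
}

#' @export
print.hgt_run <- function(x, ...) {
  cat("HGT pipeline run:", x$n_input, "input genes ->", length(x$final),
      "final candidates\n")
  print(x$report)
  invisible(x)
}

#' Summarize a pipeline run
#'
#' Final candidate count, per-donor-group counts and the fraction of the
#' input proteome they represent (in percent).
#'
#' @param run An `hgt_run`.
#' @return List: `n_final`, `by_donor_group` (tibble), `fraction_pct`.
#' @export
report_summary <- function(run) {
  stopifnot(inherits(run, "hgt_run"))
  calls <- run$calls[run$calls$gene_id %in% run$final, ]
  by_grp <- dplyr::count(calls, .data$donor_group, name = "n")
  list(n_final = length(run$final), by_donor_group = by_grp,
       fraction_pct = if (run$n_input > 0)
         100 * length(run$final) / run$n_input else 0)
}

#' Tidy pipeline calls
#'
#' @param x An `hgt_run`.
#' @param ... Unused.
#' @return The calls tibble with a `final` flag.
#' @export
tidy.hgt_run <- function(x, ...) {
  dplyr::mutate(x$calls, final = .data$gene_id %in% x$final)
}

#' One-row summary of a pipeline run
#'
#' @param x An `hgt_run`.
#' @param ... Unused.
#' @return Tibble: `n_input`, `n_final`, `fraction_pct`.
#' @export
glance.hgt_run <- function(x, ...) {
  s <- report_summary(x)
  tibble::tibble(n_input = x$n_input, n_final = s$n_final,
                 fraction_pct = s$fraction_pct)
}
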