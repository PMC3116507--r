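# Functional analysis of candidate transfers: expression normalization,
# Pearson coexpression lists with the strict |r| cutoff and top-N
# truncation, the rank-weighted pathway score, hypergeometric
# overrepresentation and SNP-list overlap.

#' Normalize a raw expression matrix
#'
#' `log2(x + 1)` followed by quantile normalization across samples
#' (limma's implementation); rows with no gene id (poorly annotated
#' probes) are dropped and duplicate probe rows for a gene are collapsed
#' to their mean.
#'
#' @param raw Nonnegative numeric matrix, probes/genes x samples, with
#'   rownames (empty or NA rownames mark unannotated probes).
#' @return Normalized matrix, one row per gene.
#' @export
normalize_expression <- function(raw) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)))
  if (any(raw < 0, na.rm = TRUE)) stop("raw intensities must be nonnegative")
  if (any(colSums(raw, na.rm = TRUE) == 0)) {
    stop("all-zero sample column")
  }
  keep <- !is.na(rownames(raw)) & nzchar(rownames(raw))
  raw <- raw[keep, , drop = FALSE]
  lg <- log2(raw + 1)
  qn <- limma::normalizeQuantiles(lg)
  rownames(qn) <- rownames(raw)
  if (anyDuplicated(rownames(qn))) {
    # rowsum and table both order groups by sorted name
    qn <- rowsum(qn, group = rownames(qn)) /
      as.vector(table(rownames(qn)))
  }
  qn
}

#' Ranked coexpression list for a focal gene
#'
#' Pearson correlation of the focal gene against every other gene; genes
#' with `|r|` strictly above `r_min` are kept, sorted by `|r|` descending,
#' truncated to `n_top`, and ranked from 1.
#'
#' @param focal Focal gene id (row of `expr`).
#' @param expr Normalized expression matrix (genes x samples, >= 3
#'   samples).
#' @param r_min Strict absolute-correlation cutoff (default 0.5).
#' @param n_top Truncation size (default 300).
#' @return Object of class `hgt_coexpr_list`: a tibble `gene_id`, `r`,
#'   `abs_r`, `rank`, with attributes `focal` and `n_top`.
#' @export
coexpression_list <- function(focal, expr, r_min = 0.5, n_top = 300) {
  stopifnot(focal %in% rownames(expr), ncol(expr) >= 3)
  v <- expr[focal, ]
  if (stats::sd(v) == 0) stop("zero-variance focal gene: ", focal)
  others <- setdiff(rownames(expr), focal)
  r <- suppressWarnings(as.vector(stats::cor(t(expr[others, , drop = FALSE]),
                                             v)))
  ok <- !is.na(r) & abs(r) > r_min
  rk <- r[ok]
  out <- tibble::tibble(gene_id = others[ok], r = rk, abs_r = abs(rk))
  out <- dplyr::arrange(out, dplyr::desc(.data$abs_r), .data$gene_id)
  out <- utils::head(out, n_top)
  out$rank <- seq_len(nrow(out))
  structure(out, focal = focal, n_top = n_top,
            class = c("hgt_coexpr_list", class(out)))
}

#' Rank-weighted pathway scores from a coexpression list
#'
#' For each pathway with `G >= 1` genes in the list, the score is the
#' rank-weighted mean absolute correlation
#' `S = (1/G) * sum_i r_i * (N_top + 1 - R_i) / N_top`, where `R_i` is the
#' rank and `r_i` the absolute correlation of the pathway's i-th listed
#' gene. Pathways absent from the list are omitted; output is sorted by
#' `S` descending.
#'
#' @param x An `hgt_coexpr_list`.
#' @param pathway_map Tibble `gene_id`, `pathway_id`.
#' @return Tibble: `pathway_id`, `G`, `score`, plus a list-column
#'   `members` of contributing (gene, rank, r) tibbles.
#' @export
pathway_scores <- function(x, pathway_map) {
  stopifnot(inherits(x, "hgt_coexpr_list"), nrow(x) > 0)
  n_top <- attr(x, "n_top")
  joined <- dplyr::inner_join(tibble::as_tibble(x), pathway_map,
                              by = "gene_id", relationship = "many-to-many")
  if (nrow(joined) == 0) {
    return(tibble::tibble(pathway_id = character(), G = integer(),
                          score = numeric(), members = list()))
  }
  out <- joined |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      G = dplyr::n(),
      score = mean(.data$abs_r * (n_top + 1 - .data$rank) / n_top),
      members = list(dplyr::pick("gene_id", "rank", "r")),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pathway_id)
  out
}

#' Hypergeometric overrepresentation of annotation terms
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k`
#' term-annotated genes among `n` candidates drawn from a background of
#' `N` genes of which `K` carry the term.
#'
#' @param candidates Candidate gene ids (must be a subset of `background`).
#' @param background Background gene ids.
#' @param term_map Tibble `gene_id`, `term`.
#' @return Tibble per term occurring among the candidates: `term`, `k`,
#'   `K`, `n`, `N`, `p`.
#' @export
enrichment <- function(candidates, background, term_map) {
  stopifnot(all(candidates %in% background))
  tm <- term_map[term_map$gene_id %in% background, ]
  miss <- setdiff(unique(term_map$term), unique(tm$term))
  if (length(miss) > 0) {
    stop("term(s) absent from background: ", paste(miss, collapse = ", "))
  }
  N <- length(unique(background))
  n <- length(unique(candidates))
  terms <- unique(tm$term[tm$gene_id %in% candidates])
  out <- purrr::map(terms, function(t) {
    withg <- unique(tm$gene_id[tm$term == t])
    K <- length(withg)
    k <- length(intersect(withg, candidates))
    tibble::tibble(term = t, k = k, K = K, n = n, N = N,
                   p = stats::phyper(k - 1, K, N - K, n,
                                     lower.tail = FALSE))
  })
  dplyr::arrange(purrr::list_rbind(out), .data$p)
}

#' Overlap of candidates with a SNP gene list
#'
#' @param candidates Candidate gene ids.
#' @param snp_genes SNP-list gene ids.
#' @return Tibble `gene_id`, `in_snp_list`; the intersection is the rows
#'   with `in_snp_list = TRUE`.
#' @export
snp_overlap <- function(candidates, snp_genes) {
  tibble::tibble(gene_id = candidates,
                 in_snp_list = candidates %in% snp_genes)
}

#' Per-tissue mean expression profile
#'
#' Mean normalized expression per (gene, tissue), optionally row-scaled to
#' a maximum of 1 (heatmap-ready).
#'
#' @param genes Gene ids (rows of `expr`).
#' @param expr Normalized expression matrix.
#' @param samples Tibble `sample_id`, `tissue` covering every column.
#' @param row_scale Divide each row by its maximum.
#' @return Object of class `hgt_tissue_profile` (tibble: `gene_id`,
#'   `tissue`, `mean_expr`).
#' @export
tissue_profile <- function(genes, expr, samples, row_scale = FALSE) {
  stopifnot(all(genes %in% rownames(expr)))
  unknown <- setdiff(colnames(expr), samples$sample_id)
  if (length(unknown) > 0) {
    stop("samples without tissue label: ", paste(unknown, collapse = ", "))
  }
  tiss <- samples$tissue[match(colnames(expr), samples$sample_id)]
  out <- purrr::map(genes, function(g) {
    m <- tapply(expr[g, ], tiss, mean)
    tibble::tibble(gene_id = g, tissue = names(m),
                   mean_expr = as.vector(m))
  }) |> purrr::list_rbind()
  if (row_scale) {
    out <- out |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(mean_expr = .data$mean_expr / max(.data$mean_expr)) |>
      dplyr::ungroup()
  }
  structure(out, class = c("hgt_tissue_profile", class(out)))
}

#' Heatmap of a tissue profile
#'
#' @param object An `hgt_tissue_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hgt_tissue_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tissue, y = .data$gene_id,
                                       fill = .data$mean_expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "expression") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tissue expression of candidate genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
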