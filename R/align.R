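# Local protein alignment and Karlin-Altschul statistics: the homology
# search engine behind the taxon-profile screen. Smith-Waterman with affine
# gaps (compiled kernel), E-values from the standard E = K m n exp(-lambda S).

#' Scoring model for local alignment
#'
#' BLOSUM62 with affine gap penalties and fixed Karlin-Altschul parameters
#' (published gapped BLOSUM62 values). Opening a gap costs `gap_open`; each
#' additional gapped residue costs `gap_extend`.
#'
#' @param matrix 20 x 20 integer substitution matrix in the package's
#'   amino-acid order, or `"BLOSUM62"` (default).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Karlin-Altschul scale and prefactor used for E-values and
#'   bit scores.
#' @return An object of class `hgt_scoring_model`.
#' @export
scoring_model <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          lambda = 0.267, K = 0.041) {
  if (is.character(matrix) && identical(matrix, "BLOSUM62")) {
    matrix <- blosum62_matrix()
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == 20, ncol(matrix) == 20,
            isTRUE(all.equal(matrix, t(matrix))),
            gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "hgt_scoring_model")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ORDER, AA_ORDER]
  storage.mode(m) <- "integer"
  m
}

# Extend a 20x20 matrix with a 21st "unknown" state scored at the matrix
# minimum (ambiguity codes as mismatch floor); recode unknowns to state 20.
.aug_matrix <- function(S) {
  A <- nrow(S)
  out <- matrix(as.integer(min(S)), A + 1L, A + 1L)
  out[seq_len(A), seq_len(A)] <- S
  out
}

.aug_codes <- function(codes, A = 20L) {
  lapply(codes, function(v) ifelse(v < 0L, A, v))
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps. Identity and coverage are computed over
#' the optimal local alignment; coverage is relative to the first (query)
#' sequence. Spans are 1-based inclusive.
#'
#' @param a,b Protein sequences (single character strings).
#' @param model An [scoring_model()].
#' @return One-row tibble: `raw_score`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `n_ident`, `align_length`, `pct_identity`, `query_coverage`.
#' @examples
#' local_align("MKVLITA", "MKVLITA")
#' @export
local_align <- function(a, b, model = scoring_model()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("local_align: sequences must be non-empty")
  }
  S <- .aug_matrix(model$matrix)
  ca <- .aug_codes(aa_to_int(a))[[1]]
  cb <- .aug_codes(aa_to_int(b))[[1]]
  r <- .sw_traceback(ca, cb, S, model$gap_open, model$gap_extend)
  span <- if (r$score > 0) r$a_end - r$a_start + 1L else 0L
  tibble::tibble(
    raw_score = r$score, a_start = r$a_start, a_end = r$a_end,
    b_start = r$b_start, b_end = r$b_end, n_ident = r$n_ident,
    align_length = r$align_length,
    pct_identity = if (r$align_length > 0) 100 * r$n_ident / r$align_length else 0,
    query_coverage = 100 * span / nchar(a))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and database residue count `n`.
#'
#' @param raw_score Raw alignment score(s).
#' @param m Query length (residues).
#' @param n Total residue count of the searched database.
#' @param model An [scoring_model()].
#' @return E-value(s), same length as `raw_score`.
#' @export
evalue <- function(raw_score, m, n, model = scoring_model()) {
  stopifnot(m > 0, n > 0)
  model$K * m * n * exp(-model$lambda * raw_score)
}

bit_score <- function(raw_score, model = scoring_model()) {
  (model$lambda * raw_score - log(model$K)) / log(2)
}

#' Per-species best hits of queries against a labeled database
#'
#' Aligns every query against every database sequence, applies the E-value
#' cutoff, and retains the single best hit per (query, species), ranked by
#' bit score with ties broken by percent identity then subject id. Queries
#' with no qualifying hit are absent from the result.
#'
#' @param query Tibble with columns `gene_id`, `seq` (protein), or a named
#'   character vector.
#' @param database Tibble with columns `gene_id`, `species_id`, `seq`.
#' @param taxa Tibble mapping `species_id` to `group` (and optionally
#'   `domain`); every database species must appear.
#' @param model An [scoring_model()].
#' @param e_cutoff Maximum E-value for a hit to qualify.
#' @param exclude_self Drop subject records whose `gene_id` equals the query
#'   id (a query aligned against a database containing itself).
#' @return Tibble: `query_id`, `subject_id`, `species_id`, `group`,
#'   `raw_score`, `bit_score`, `e_value`, `pct_identity`, `query_coverage`.
#' @export
best_hits <- function(query, database, taxa, model = scoring_model(),
                      e_cutoff = 1e-20, exclude_self = TRUE) {
  query <- .as_seq_tbl(query)
  stopifnot(all(c("gene_id", "species_id", "seq") %in% names(database)))
  missing_sp <- setdiff(unique(database$species_id), taxa$species_id)
  if (length(missing_sp) > 0) {
    stop("best_hits: species missing from taxon table: ",
         paste(missing_sp, collapse = ", "))
  }
  S <- .aug_matrix(model$matrix)
  qc <- .aug_codes(aa_to_int(query$seq))
  sc <- .aug_codes(aa_to_int(database$seq))
  scores <- .sw_score_batch(qc, sc, S, model$gap_open, model$gap_extend)
  n_db <- sum(nchar(database$seq))
  qlen <- nchar(query$seq)

  hits <- tibble::tibble(
    qi = rep(seq_len(nrow(query)), times = nrow(database)),
    si = rep(seq_len(nrow(database)), each = nrow(query)),
    raw_score = as.vector(scores))
  hits$query_id <- query$gene_id[hits$qi]
  hits$subject_id <- database$gene_id[hits$si]
  hits$species_id <- database$species_id[hits$si]
  hits$e_value <- evalue(hits$raw_score, qlen[hits$qi], n_db, model)
  hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  if (exclude_self) hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          species_id = character(), group = character(),
                          raw_score = integer(), bit_score = numeric(),
                          e_value = numeric(), pct_identity = numeric(),
                          query_coverage = numeric()))
  }
  # keep per-(query, species) rows attaining the max raw score, then break
  # remaining ties by identity / subject id after traceback
  hits <- dplyr::group_by(hits, .data$query_id, .data$species_id)
  hits <- dplyr::filter(hits, .data$raw_score == max(.data$raw_score))
  hits <- dplyr::ungroup(hits)

  tb <- purrr::map2(hits$qi, hits$si, function(i, j) {
    .sw_traceback(qc[[i]], sc[[j]], S, model$gap_open, model$gap_extend)
  })
  hits$n_ident <- purrr::map_int(tb, "n_ident")
  hits$align_length <- purrr::map_int(tb, "align_length")
  hits$pct_identity <- ifelse(hits$align_length > 0,
                              100 * hits$n_ident / hits$align_length, 0)
  span <- purrr::map_int(tb, "a_end") - purrr::map_int(tb, "a_start") + 1L
  hits$query_coverage <- 100 * span / qlen[hits$qi]
  hits$bit_score <- bit_score(hits$raw_score, model)

  hits <- dplyr::arrange(hits, .data$query_id, .data$species_id,
                         dplyr::desc(.data$pct_identity), .data$subject_id)
  hits <- dplyr::distinct(hits, .data$query_id, .data$species_id,
                          .keep_all = TRUE)
  dplyr::select(hits, "query_id", "subject_id", "species_id", "raw_score",
                "bit_score", "e_value", "pct_identity", "query_coverage") |>
    .join_group(taxa)
}

.join_group <- function(hits, taxa) {
  out <- dplyr::left_join(hits, dplyr::select(taxa, "species_id", "group"),
                          by = "species_id")
  dplyr::relocate(out, "group", .after = "species_id")
}

.as_seq_tbl <- function(x) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    x <- tibble::tibble(gene_id = names(x), seq = unname(x))
  }
  stopifnot(all(c("gene_id", "seq") %in% names(x)), all(nchar(x$seq) > 0))
  tibble::as_tibble(x[, c("gene_id", setdiff(names(x), "gene_id"))])
}
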