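# Progressive multiple alignment (k-mer guide tree + profile-profile
# Needleman-Wunsch) and conserved-block trimming in the Gblocks tradition.

#' Construct an MSA object
#'
#' @param rows Named character vector of aligned rows (equal length; `-`
#'   for gaps).
#' @param cluster_id Optional source cluster id.
#' @return Object of class `hgt_msa`: fields `ids`, `rows`, `codes`
#'   (taxa x sites integer matrix, -1 for gap), `cluster_id`.
#' @export
msa <- function(rows, cluster_id = NA_character_) {
  stopifnot(length(rows) >= 1, !is.null(names(rows)),
            !anyDuplicated(names(rows)))
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("aligned rows must have equal length")
  codes <- do.call(rbind, aa_to_int(rows))
  rownames(codes) <- names(rows)
  structure(list(ids = names(rows), rows = rows, codes = codes,
                 n_sites = w, cluster_id = cluster_id),
            class = "hgt_msa")
}

#' @export
print.hgt_msa <- function(x, ...) {
  cat("MSA:", length(x$ids), "sequences x", x$n_sites, "columns\n")
  invisible(x)
}

# k-mer (default 3) fractional distance used for the guide tree
kmer_distance <- function(seqs, k = 3) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- intersect(names(ci), names(cj))
      common <- sum(pmin(ci[shared], cj[shared]))
      denom <- min(sum(ci), sum(cj))
      d[i, j] <- d[j, i] <- 1 - if (denom > 0) common / denom else 0
    }
  }
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

# residue-count profile of a set of aligned rows (20 x L; gaps contribute 0)
.profile_counts <- function(code_rows) {
  L <- ncol(code_rows)
  cnt <- matrix(0, 20, L)
  for (i in seq_len(nrow(code_rows))) {
    v <- code_rows[i, ]
    ok <- which(v >= 0)
    idx <- cbind(v[ok] + 1L, ok)
    cnt[idx] <- cnt[idx] + 1
  }
  cnt
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from k-mer distances clustered by UPGMA; groups are merged
#' along the tree by profile-profile global alignment (affine gaps,
#' BLOSUM62 expected column scores).
#'
#' @param seqs Named character vector (>= 2 protein sequences) or a tibble
#'   with `gene_id`, `seq`.
#' @param model An [scoring_model()] supplying the substitution matrix and
#'   gap penalties.
#' @param cluster_id Stored on the result.
#' @return An [msa()] object.
#' @export
progressive_align <- function(seqs, model = scoring_model(),
                              cluster_id = NA_character_) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$gene_id)
  if (length(seqs) < 2) stop("progressive_align needs at least 2 sequences")
  if (length(unique(nchar(seqs))) == 1 && length(unique(seqs)) == 1) {
    return(msa(seqs, cluster_id))  # identical sequences: trivial alignment
  }
  S <- model$matrix
  ids <- names(seqs)
  if (length(seqs) == 2) {
    merged <- .merge_profiles(do.call(rbind, aa_to_int(seqs[1])),
                              do.call(rbind, aa_to_int(seqs[2])), S, model)
    rows <- stats::setNames(int_to_aa(asplit(merged, 1)), ids)
    return(msa(rows, cluster_id))
  }
  d <- kmer_distance(seqs)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  merge <- hc$merge
  sub <- vector("list", nrow(merge))
  leaf <- function(i) {
    m <- do.call(rbind, aa_to_int(seqs[ids[i]]))
    rownames(m) <- ids[i]
    m
  }
  for (k in seq_len(nrow(merge))) {
    a <- if (merge[k, 1] < 0) leaf(-merge[k, 1]) else sub[[merge[k, 1]]]
    b <- if (merge[k, 2] < 0) leaf(-merge[k, 2]) else sub[[merge[k, 2]]]
    sub[[k]] <- .merge_profiles(a, b, S, model)
  }
  aln <- sub[[nrow(merge)]]
  rows <- stats::setNames(int_to_aa(asplit(aln, 1)), rownames(aln))
  msa(rows[ids], cluster_id)
}

# align two blocks of aligned rows via the compiled profile DP, then expand
.merge_profiles <- function(a, b, S, model) {
  pa <- .profile_counts(a); pb <- .profile_counts(b)
  path <- .profile_nw(pa, pb, nrow(a), nrow(b), S,
                      model$gap_open, model$gap_extend)
  la <- sum(path != 2L); lb <- sum(path != 1L)
  stopifnot(la == ncol(a), lb == ncol(b))
  out <- matrix(-1L, nrow(a) + nrow(b), length(path))
  ai <- 0L; bi <- 0L
  acol <- integer(length(path)); bcol <- integer(length(path))
  for (p in seq_along(path)) {
    if (path[p] != 2L) { ai <- ai + 1L; acol[p] <- ai }
    if (path[p] != 1L) { bi <- bi + 1L; bcol[p] <- bi }
  }
  out[seq_len(nrow(a)), acol > 0] <- a[, acol[acol > 0], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), bcol > 0] <- b[, bcol[bcol > 0], drop = FALSE]
  rownames(out) <- c(rownames(a), rownames(b))
  out
}

#' Conserved-block trimming
#'
#' Classifies columns as gap, nonconserved, conserved or highly conserved,
#' then keeps maximal blocks satisfying: no gap columns, at most
#' `max_noncons` contiguous nonconserved columns inside a block, block
#' flanks highly conserved, and block length at least `min_block`.
#'
#' Column classes: a column containing any gap is a gap column and is never
#' kept; otherwise let f be the frequency of the most common residue —
#' `f > cons` makes it conserved, `f > flank` highly conserved.
#'
#' @param x An [msa()] object.
#' @param cons,flank Conservation fractions (defaults 0.5 and 0.85).
#' @param max_noncons Maximum run of nonconserved columns inside a block.
#' @param min_block Minimum kept block length.
#' @return Object of class `hgt_block_mask`: `kept` (sorted 1-based column
#'   indices), `classes` (per-column classification), `params`, and `empty`
#'   flag (all columns removed; such alignments are untestable downstream).
#' @export
trim_blocks <- function(x, cons = 0.5, flank = 0.85, max_noncons = 8,
                        min_block = 10) {
  stopifnot(inherits(x, "hgt_msa"))
  n <- length(x$ids)
  cls <- character(x$n_sites)
  for (j in seq_len(x$n_sites)) {
    col <- x$codes[, j]
    if (any(col < 0)) { cls[j] <- "gap"; next }
    f <- max(tabulate(col + 1L, nbins = 20)) / n
    cls[j] <- if (f > flank) "high" else if (f > cons) "cons" else "noncons"
  }
  keep <- rep(FALSE, x$n_sites)
  # candidate segments between gap columns and long nonconserved runs
  ok <- cls != "gap"
  r <- rle(cls == "noncons" & ok)
  # positions of runs of nonconserved longer than max_noncons become breaks
  breaks <- rep(FALSE, x$n_sites)
  pos <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > max_noncons) {
      breaks[(pos[k] - r$lengths[k] + 1):pos[k]] <- TRUE
    }
  }
  seg_ok <- ok & !breaks
  rr <- rle(seg_ok)
  end <- cumsum(rr$lengths)
  start <- end - rr$lengths + 1
  for (k in seq_along(rr$lengths)) {
    if (!rr$values[k]) next
    s <- start[k]; e <- end[k]
    while (s <= e && cls[s] != "high") s <- s + 1
    while (e >= s && cls[e] != "high") e <- e - 1
    if (s <= e && (e - s + 1) >= min_block) keep[s:e] <- TRUE
  }
  structure(list(kept = which(keep), classes = cls,
                 params = list(cons = cons, flank = flank,
                               max_noncons = max_noncons,
                               min_block = min_block),
                 empty = !any(keep)),
            class = "hgt_block_mask")
}

#' @export
print.hgt_block_mask <- function(x, ...) {
  cat("Block mask:", length(x$kept), "of", length(x$classes),
      "columns kept\n")
  invisible(x)
}

#' Apply a block mask to an MSA
#'
#' @param x An [msa()] object.
#' @param mask An `hgt_block_mask` from [trim_blocks()].
#' @return A new, column-subset [msa()] object.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(inherits(x, "hgt_msa"), inherits(mask, "hgt_block_mask"))
  if (length(mask$kept) == 0) stop("empty block mask: nothing to keep")
  rows <- vapply(x$rows, function(r)
    paste(strsplit(r, "")[[1]][mask$kept], collapse = ""), character(1))
  msa(rows, x$cluster_id)
}
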