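blosum <- function() {
  m <- hgtscan:::blosum62_matrix()
  m
}

test_that("self-alignment gives full identity and coverage, and the raw
           score is symmetric", {
  a <- "MKVLITAGPTREPLDPVRYISNHSSGKMGFAIA"
  r <- local_align(a, a)
  expect_equal(r$pct_identity, 100)
  expect_equal(r$query_coverage, 100)
  expect_equal(r$a_start, 1L)
  expect_equal(r$a_end, nchar(a))
  set.seed(3)
  for (i in 1:10) {
    x <- paste(sample(hgtscan:::AA_ORDER, 30, TRUE), collapse = "")
    y <- paste(sample(hgtscan:::AA_ORDER, 25, TRUE), collapse = "")
    expect_equal(local_align(x, y)$raw_score, local_align(y, x)$raw_score)
  }
  expect_error(local_align("", "MKV"), "non-empty")
})

test_that("affine local score equals exhaustive enumeration of local
           alignments on tiny peptides", {
  S <- blosum()
  model <- scoring_model(gap_open = 11, gap_extend = 1)
  set.seed(7)
  for (i in 1:8) {
    a <- paste(sample(hgtscan:::AA_ORDER, 7, TRUE), collapse = "")
    b <- paste(sample(hgtscan:::AA_ORDER, 6, TRUE), collapse = "")
    got <- local_align(a, b, model)$raw_score
    want <- oracle_local_score(a, b, S, 11, 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("with linear gap costs the DP matches a plain Smith-Waterman
           oracle on 12-mer / 15-mer peptides", {
  S <- blosum()
  model <- scoring_model(gap_open = 4, gap_extend = 4)
  set.seed(11)
  for (i in 1:12) {
    a <- paste(sample(hgtscan:::AA_ORDER, 12, TRUE), collapse = "")
    b <- paste(sample(hgtscan:::AA_ORDER, 15, TRUE), collapse = "")
    expect_equal(local_align(a, b, model)$raw_score,
                 oracle_sw_linear(a, b, S, 4))
  }
})

test_that("scores agree with Biostrings' local aligner as an independent
           cross-check", {
  model <- scoring_model()
  set.seed(19)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  for (i in 1:6) {
    a <- paste(sample(hgtscan:::AA_ORDER, 60, TRUE), collapse = "")
    b <- paste(sample(hgtscan:::AA_ORDER, 55, TRUE), collapse = "")
    # Biostrings charges gapOpening + gapExtension at gap start; the
    # package charges gap_open for the first gapped residue
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = e$BLOSUM62,
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(local_align(a, b, model)$raw_score, ref)
  }
})

test_that("E-values follow the Karlin-Altschul closed form and scale
           linearly in database size", {
  model <- scoring_model(lambda = 0.267, K = 0.041)
  expect_equal(evalue(200, 300, 1e6, model),
               0.041 * 300 * 1e6 * exp(-0.267 * 200))
  expect_equal(evalue(150, 250, 2e6, model),
               2 * evalue(150, 250, 1e6, model))
  e <- evalue(c(100, 200, 300), 300, 1e6, model)
  expect_true(all(diff(e) < 0))
})

test_that("best_hits keeps one hit per species, honors the E-value
           cutoff, and a verbatim self-match ranks its species first", {
  set.seed(23)
  mkseq <- function(n) paste(sample(hgtscan:::AA_ORDER, n, TRUE),
                             collapse = "")
  q <- mkseq(80)
  db <- tibble::tibble(
    gene_id = c("s1_g1", "s1_g2", "s2_g1", "s3_g1"),
    species_id = c("sp1", "sp1", "sp2", "sp3"),
    seq = c(q, substr(q, 1, 40), mkseq(80), mkseq(80)))
  taxa <- tibble::tibble(species_id = c("sp1", "sp2", "sp3"),
                         group = c("bacterium", "plant", "fungus"))
  hits <- best_hits(c(query = q), db, taxa, e_cutoff = 1e-5)
  expect_true(all(table(hits$species_id) == 1))
  expect_equal(hits$subject_id[hits$species_id == "sp1"], "s1_g1")
  expect_equal(hits$pct_identity[hits$species_id == "sp1"], 100)
  # every retained hit satisfies the cutoff
  expect_true(all(hits$e_value <= 1e-5))
  # unknown species label is an error
  expect_error(best_hits(c(query = q), db, taxa[1:2, ]), "missing")
})

test_that("retained hit set equals an exhaustive all-pairs scan on a toy
           database", {
  set.seed(29)
  mkseq <- function(n) paste(sample(hgtscan:::AA_ORDER, n, TRUE),
                             collapse = "")
  base <- mkseq(70)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- sample(hgtscan:::AA_ORDER, k, TRUE)
    paste(ch, collapse = "")
  }
  db <- tibble::tibble(
    gene_id = paste0("sp", rep(1:5, each = 2), "_g", rep(1:2, 5)),
    species_id = paste0("sp", rep(1:5, each = 2)),
    seq = vapply(c(2, 6, 4, 9, 3, 8, 5, 7, 1, 10), function(k)
      mut(base, k), character(1)))
  taxa <- tibble::tibble(species_id = paste0("sp", 1:5),
                         group = "bacterium")
  model <- scoring_model()
  cutoff <- 1e-12
  hits <- best_hits(c(q = base), db, taxa, model, e_cutoff = cutoff)
  # brute force: align query against every db sequence independently
  n_db <- sum(nchar(db$seq))
  brute <- vapply(db$seq, function(s)
    local_align(base, s, model)$raw_score, numeric(1))
  ev <- evalue(brute, nchar(base), n_db, model)
  keep <- tapply(seq_len(nrow(db)), db$species_id, function(idx) {
    idx <- idx[ev[idx] <= cutoff]
    if (length(idx) == 0) return(NA_character_)
    db$gene_id[idx[which.max(brute[idx])]]
  })
  keep <- keep[!is.na(keep)]
  expect_setequal(hits$subject_id, unname(keep))
})
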