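test_that("quantile normalization equalizes sample distributions and a
           3-gene, 2-sample toy matches the hand-computed result", {
  raw <- matrix(c(0, 3, 7, 1, 15, 31), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  nx <- normalize_expression(raw)
  # log2(x+1): col1 = 0,2,3; col2 = 1,4,5; rank-wise means: (0+1)/2,
  # (2+4)/2, (3+5)/2 = 0.5, 3, 4 assigned by rank in each column
  expect_equal(unname(nx[, 1]), c(0.5, 3, 4))
  expect_equal(unname(nx[, 2]), c(0.5, 3, 4))
  expect_equal(colMeans(nx)[1], colMeans(nx)[2], ignore_attr = TRUE)

  # identical value multisets give identical columns
  raw2 <- matrix(c(5, 1, 9, 9, 5, 1), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
  nx2 <- normalize_expression(raw2)
  expect_setequal(unname(nx2[, 1]), unname(nx2[, 2]))

  # unannotated probes dropped, duplicates averaged
  raw3 <- matrix(c(4, 8, 2, 4, 8, 2), 3, 2,
                 dimnames = list(c("gA", "gA", ""), c("a", "b")))
  nx3 <- normalize_expression(raw3)
  expect_equal(rownames(nx3), "gA")
  expect_error(normalize_expression(matrix(0, 2, 2,
                                           dimnames = list(c("a", "b"),
                                                           NULL))),
               "all-zero")
})

test_that("coexpression lists honor the strict |r| cutoff, rank by
           absolute correlation, and match a brute-force scan", {
  # focal x plus a partner with exactly r = 0.5: excluded by strict >
  expr <- rbind(focal = c(1, 0, -1),
                exact_half = c(0, 1, -1),
                anti = c(-2, 0, 2),
                dup = c(2, 1, 0),
                weak = c(0.1, -0.2, 0.1))
  colnames(expr) <- paste0("s", 1:3)
  expect_equal(stats::cor(expr["focal", ], expr["exact_half", ]), 0.5)
  cl <- coexpression_list("focal", expr, r_min = 0.5, n_top = 10)
  expect_false("exact_half" %in% cl$gene_id)
  expect_equal(cl$gene_id[1:2] %in% c("anti", "dup"), c(TRUE, TRUE))
  expect_equal(cl$rank, seq_len(nrow(cl)))
  expect_equal(abs(cl$r[cl$gene_id == "anti"]), 1)

  # brute force on a random 10-gene matrix
  set.seed(41)
  m <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  cl2 <- coexpression_list("g1", m, r_min = 0.3, n_top = 4)
  brute <- vapply(paste0("g", 2:10), function(g)
    stats::cor(m["g1", ], m[g, ]), numeric(1))
  brute <- brute[abs(brute) > 0.3]
  brute <- sort(abs(brute), decreasing = TRUE)[seq_len(min(4, length(brute)))]
  expect_equal(cl2$abs_r, unname(brute))
  expect_equal(nrow(cl2), min(4, length(brute)))
  expect_error(coexpression_list("g1", rbind(g1 = c(1, 1, 1),
                                             g2 = c(1, 2, 3))),
               "zero-variance")
})

test_that("truncation to the top N and the focal gene's self-exclusion
           hold", {
  set.seed(43)
  m <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  m["g2", ] <- m["g1", ] * 2 + 1e-8 * rnorm(10)  # near-duplicate
  cl <- coexpression_list("g1", m, r_min = 0, n_top = 5)
  expect_equal(nrow(cl), 5)
  expect_false("g1" %in% cl$gene_id)
  expect_equal(cl$gene_id[1], "g2")
  expect_equal(cl$rank, 1:5)
})

test_that("pathway scores implement the rank-weighted mean and omit
           pathways absent from the list", {
  expr <- rbind(f = c(1, 2, 3, 4),
                dup = c(2, 4, 6, 8),
                other = c(1, -1, 1, -1))
  colnames(expr) <- paste0("s", 1:4)
  cl <- coexpression_list("f", expr, r_min = 0.1, n_top = 300)
  pm <- tibble::tibble(gene_id = c("dup", "unseen"),
                       pathway_id = c("pwA", "pwB"))
  ps <- pathway_scores(cl, pm)
  expect_equal(ps$pathway_id, "pwA")
  # single gene at rank 1 with r = 1: S = 1 * (300 + 1 - 1)/300 = 1
  expect_equal(ps$score, 1.0)
  expect_equal(ps$G, 1L)

  # two genes: S = mean of the rank-weighted terms
  expr2 <- rbind(f = c(1, 2, 3, 4),
                 a = c(2, 4, 6, 8),
                 b = c(4, 3, 2, 1.5))
  colnames(expr2) <- paste0("s", 1:4)
  cl2 <- coexpression_list("f", expr2, r_min = 0.1, n_top = 300)
  pm2 <- tibble::tibble(gene_id = c("a", "b"), pathway_id = "pw")
  ps2 <- pathway_scores(cl2, pm2)
  want <- mean(cl2$abs_r * (300 + 1 - cl2$rank) / 300)
  expect_equal(ps2$score, want)
})

test_that("hypergeometric enrichment matches exhaustive enumeration and
           the exact combinatorial example", {
  # C(5,5) C(15,0) / C(20,5) = 1/15504
  term_map <- tibble::tibble(gene_id = paste0("g", 1:5), term = "T")
  bg <- paste0("g", 1:20)
  r <- enrichment(paste0("g", 1:5), bg, term_map)
  expect_equal(r$p, 1 / 15504)
  expect_equal(r$k, 5L)

  # exhaustive enumeration for population sizes <= 12
  set.seed(47)
  for (i in 1:5) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    bg <- paste0("x", seq_len(N))
    tm <- tibble::tibble(gene_id = bg[seq_len(K)], term = "T")
    cand <- sample(bg, n)
    k <- sum(cand %in% tm$gene_id)
    if (k == 0) next
    got <- enrichment(cand, bg, tm)$p
    expect_equal(got, oracle_hyper_enum(k, K, n, N), tolerance = 1e-12,
                 info = paste(N, K, n, k))
  }

  # certain event: all candidates and all background annotated
  tm_all <- tibble::tibble(gene_id = paste0("g", 1:6), term = "T")
  r2 <- enrichment(paste0("g", 1:3), paste0("g", 1:6), tm_all)
  expect_equal(r2$p, 1)
  expect_error(enrichment(paste0("g", 1:3), paste0("g", 1:6),
                          tibble::tibble(gene_id = "zzz", term = "gone")),
               "absent")
})

test_that("SNP overlap is a plain intersection with per-gene flags", {
  r <- snp_overlap(c("a", "b", "c"), c("x", "y"))
  expect_false(any(r$in_snp_list))
  r2 <- snp_overlap(c("a", "b"), c("a", "b", "z"))
  expect_true(all(r2$in_snp_list))
  d <- tiny_synth()
  hg <- d$truth$gene_id[d$truth$origin == "hgt"]
  expect_false(any(snp_overlap(hg, d$snp_genes)$in_snp_list))
})

test_that("tissue profiles average per tissue, respect row scaling, and
           reject unknown samples", {
  expr <- rbind(g1 = c(1, 3, 10, 10), g2 = c(4, 4, 2, 2))
  colnames(expr) <- c("t1_a", "t1_b", "t2_a", "t2_b")
  samples <- tibble::tibble(sample_id = colnames(expr),
                            tissue = c("t1", "t1", "t2", "t2"))
  tp <- tissue_profile(c("g1", "g2"), expr, samples)
  expect_equal(tp$mean_expr[tp$gene_id == "g1" & tp$tissue == "t1"], 2)
  expect_equal(tp$mean_expr[tp$gene_id == "g1" & tp$tissue == "t2"], 10)
  tps <- tissue_profile(c("g1", "g2"), expr, samples, row_scale = TRUE)
  mx <- tapply(tps$mean_expr, tps$gene_id, max)
  expect_true(all(mx == 1))
  # single-sample tissues reproduce the matrix columns
  s1 <- tibble::tibble(sample_id = colnames(expr),
                       tissue = colnames(expr))
  tp1 <- tissue_profile("g1", expr, s1)
  expect_equal(tp1$mean_expr[match(colnames(expr), tp1$tissue)],
               unname(expr["g1", ]))
  expect_error(tissue_profile("g1", expr, samples[1:2, ]), "without")
  p <- autoplot(tp)
  expect_s3_class(p, "ggplot")
})
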