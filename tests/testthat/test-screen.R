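mk_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, character(1), 1),
    subject_id = vapply(rows, `[[`, character(1), 2),
    species_id = vapply(rows, `[[`, character(1), 3),
    group = vapply(rows, `[[`, character(1), 4),
    bit_score = vapply(rows, function(r) as.numeric(r[[5]]), numeric(1)))
}

test_that("insect-only exclusion removes genes whose only homologs are
           insect (or none at all)", {
  h <- mk_hits(
    list("g1", "a", "ins1", "arthropod_insect", 100),
    list("g1", "b", "ins2", "arthropod_insect", 90),
    list("g2", "c", "bac1", "bacterium", 50),
    list("g2", "d", "ins1", "arthropod_insect", 200))
  r <- insect_only_filter(h, c("g1", "g2", "g3"), self_species = "rec")
  expect_setequal(r$excluded, c("g1", "g3"))   # g3 has no hits at all
  expect_setequal(r$retained, "g2")
  # idempotence: filtering the retained set again changes nothing
  r2 <- insect_only_filter(h, r$retained, self_species = "rec")
  expect_setequal(r2$retained, r$retained)
})

test_that("taxon-profile filter compares best foreign and best insect bit
           scores with the stated tie semantics", {
  h <- mk_hits(
    list("keep", "a", "ins1", "arthropod_insect", 250),
    list("keep", "b", "bac1", "bacterium", 310),
    list("drop", "c", "ins1", "arthropod_insect", 310),
    list("drop", "d", "bac1", "bacterium", 250),
    list("noins", "e", "bac1", "bacterium", 40))
  r <- taxon_profile_filter(h, c("keep", "drop", "noins"),
                            self_species = "rec")
  expect_setequal(r$retained, c("keep", "noins"))
  expect_setequal(r$excluded, "drop")
})

test_that("reciprocal-best-hit clustering groups mutual best hits and
           leaves unrelated singletons alone", {
  h <- mk_hits(
    list("q1", "s1", "spA", "bacterium", 300),
    list("q1", "s2", "spB", "bacterium", 100),
    list("q2", "s2", "spB", "bacterium", 280))
  cl <- cluster_orthologs(h, singletons = c("q1", "q2", "lonely"),
                          query_species = "rec")
  grp <- split(cl$gene_id, cl$cluster_id)
  sizes <- sort(vapply(grp, length, integer(1)))
  # q1-s1 and q2-s2 mutual best; s2's best counter-hit is q2 (280 > 100)
  expect_true(any(vapply(grp, function(g) setequal(g, c("q1", "s1")),
                         logical(1))))
  expect_true(any(vapply(grp, function(g) setequal(g, c("q2", "s2")),
                         logical(1))))
  expect_true(any(vapply(grp, function(g) identical(g, "lonely"),
                         logical(1))))
})

test_that("a simulated one-family instance with no paralogs clusters into
           a single component", {
  d <- tiny_synth()
  fam <- "fam001"
  genes <- d$database[d$database$family == fam, ]
  rec_gene <- d$proteome[d$proteome$family == fam &
                           grepl("_fam", d$proteome$gene_id), ]
  hits <- best_hits(rec_gene, genes, d$taxa, e_cutoff = 1e-5)
  cl <- cluster_orthologs(hits, singletons = rec_gene$gene_id)
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_setequal(cl$gene_id, c(rec_gene$gene_id, hits$subject_id))
})

test_that("the few-hit rule drops below five sequences and keeps five", {
  sizes <- c(a = 4, b = 5, c = 12, d = 2)
  r <- few_hit_filter(sizes)
  expect_setequal(r$excluded, c("a", "d"))
  expect_setequal(r$retained, c("b", "c"))
  # brute-force recount on synthetic-style random sizes
  set.seed(9)
  sz <- stats::setNames(sample(1:12, 30, TRUE), paste0("g", 1:30))
  r2 <- few_hit_filter(sz, min_taxa = 5)
  expect_setequal(r2$excluded, names(sz)[sz < 5])
})

test_that("transposon filter drops library-derived genes and keeps
           implants", {
  d <- tiny_synth()
  te_genes <- d$proteome[d$truth$origin == "transposon", c("gene_id", "seq")]
  hg_genes <- d$proteome[d$truth$origin == "hgt", c("gene_id", "seq")]
  r <- transposon_filter(rbind(te_genes, hg_genes), d$te_library)
  expect_true(all(r$drop[r$gene_id %in% te_genes$gene_id]))
  expect_false(any(r$drop[r$gene_id %in% hg_genes$gene_id]))
})

test_that("EST filter calls expression exactly for substrings and absence
           for unmatched genes", {
  set.seed(13)
  cds <- tibble::tibble(
    gene_id = c("gA", "gB"),
    cds = c(paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = ""),
            paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")))
  est <- tibble::tibble(est_id = "e1", gene_id = "gA",
                        seq = substr(cds$cds[1], 101, 400))
  r <- est_filter(cds, list(est))
  expect_true(r$expressed[r$gene_id == "gA"])
  expect_false(r$expressed[r$gene_id == "gB"])
  # synthetic truth agreement
  d <- tiny_synth()
  res <- est_filter(d$cds, d$est_sets)
  expect_equal(res$expressed[match(d$truth$gene_id, res$gene_id)],
               d$truth$expressed)
})

test_that("self-duplication counts match an all-pairs brute force on a
           toy proteome", {
  set.seed(17)
  mkseq <- function(n) paste(sample(hgtscan:::AA_ORDER, n, TRUE),
                             collapse = "")
  base <- mkseq(120)
  prot <- tibble::tibble(
    gene_id = c("dup1", "dup2", "solo", paste0("bg", 1:5)),
    seq = c(base, base, mkseq(120),
            vapply(1:5, function(i) mkseq(100 + i), character(1))))
  model <- scoring_model()
  expect_gte(self_duplicate_check("dup1", prot, model, 1e-10), 1)
  expect_equal(self_duplicate_check("solo", prot, model, 1e-10), 0L)
  # brute-force cross-check for every gene
  n_tot <- sum(nchar(prot$seq))
  for (g in prot$gene_id) {
    i <- match(g, prot$gene_id)
    ev <- vapply(prot$seq[-i], function(s)
      evalue(local_align(prot$seq[i], s, model)$raw_score,
             nchar(prot$seq[i]), n_tot - nchar(prot$seq[i]), model),
      numeric(1))
    expect_equal(self_duplicate_check(g, prot, model, 1e-10),
                 sum(ev <= 1e-10))
  }
})

test_that("intron counts follow the exon records", {
  gm <- tibble::tibble(
    seqid = "chr1", source = "x", type = "exon",
    start = c(1, 101, 301, 501, 1),
    end = c(50, 200, 400, 600, 900),
    strand = "+",
    gene_id = c("g4", "g4", "g4", "g4", "g1"),
    exon_number = c(1:4, 1))
  expect_equal(intronless_check("g4", gm), 3L)
  expect_equal(intronless_check("g1", gm), 0L)
  expect_error(intronless_check("missing", gm), "absent")
})

test_that("the wild-relative absence screen flags implants as absent and
           conserved natives as present", {
  d <- tiny_synth()
  hg <- d$truth$gene_id[d$truth$origin == "hgt"]
  nat <- d$truth$gene_id[d$truth$origin == "native" & d$truth$expressed]
  wild_cov <- unique(unlist(lapply(d$wild_est_sets, function(s) s$gene_id)))
  nat <- intersect(nat, wild_cov)[1]
  cds <- d$cds[d$cds$gene_id %in% c(hg, nat), ]
  r <- absence_screen(cds, d$wild_est_sets)
  expect_true(all(r$absent[r$gene_id %in% hg]))
  expect_false(r$absent[r$gene_id == nat])
  # empty wild sets: everything absent
  r0 <- absence_screen(cds, list(tibble::tibble(est_id = character(),
                                                gene_id = character(),
                                                seq = character())))
  expect_true(all(r0$absent))
})

test_that("the filter ledger enforces its conservation identities and
           rejects inconsistencies", {
  r <- filter_report(data.frame(name = c("screen", "few_hit"),
                                n_in = c(229, NA), n_excluded = c(122, 0)))
  expect_equal(r$n_out[1], 107)
  expect_equal(r$n_in[2], 107)
  expect_error(
    filter_report(data.frame(name = "s", n_in = 10, n_excluded = 3,
                             n_out = 8)),
    "inconsistent")
  expect_error(
    filter_report(data.frame(name = c("a", "b"), n_in = c(10, 9),
                             n_excluded = c(2, 1))),
    "chain")
  # empty pipeline is a valid, empty report
  r0 <- filter_report(data.frame(name = character(), n_in = numeric(),
                                 n_excluded = numeric()))
  expect_s3_class(r0, "hgt_filter_report")
  expect_equal(nrow(r0), 0)
  # JSON round trip preserves the stage table
  path <- tempfile(fileext = ".json")
  write_filter_report(r, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$stages$n_out, c(107, 107))
})
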