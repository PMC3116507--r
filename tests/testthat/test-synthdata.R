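small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_species_per_group = c(arthropod_insect = 2, other_metazoan = 2,
                                 plant = 2, fungus = 2, other_eukaryote = 2,
                                 bacterium = 2),
         n_families = 8, n_insect_only = 2, n_hgt_implants = 2,
         n_transposons = 1, n_coexpr_modules = 2, module_size = 4,
         seed = 5),
    list(...))
  do.call(synth_config, args)
}

test_that("identical seeds give identical outputs and the truth table
           partitions the recipient proteome", {
  d1 <- simulate_hgt_data(small_cfg())
  d2 <- simulate_hgt_data(small_cfg())
  expect_identical(d1$proteome, d2$proteome)
  expect_identical(d1$est_sets, d2$est_sets)
  expect_identical(d1$expr, d2$expr)
  # partition: every recipient gene exactly once, known origins
  expect_setequal(d1$truth$gene_id, d1$proteome$gene_id)
  expect_false(anyDuplicated(d1$truth$gene_id) > 0)
  expect_true(all(d1$truth$origin %in%
                    c("native", "insect_only", "hgt", "transposon")))
  # hgt entries name donors present in the database
  hg <- d1$truth[d1$truth$origin == "hgt", ]
  expect_true(all(hg$donor_species %in% d1$database$species_id))
})

test_that("zero implants, zero divergence and zero-rate evolution behave
           as the limiting cases require", {
  d0 <- simulate_hgt_data(small_cfg(n_hgt_implants = 0,
                                    donor_groups = character(0)))
  expect_equal(sum(d0$truth$origin == "hgt"), 0)

  cfg <- small_cfg(hgt_divergence = 0)
  db <- generate_database(cfg)
  imp <- implant_hgt(db, cfg)
  hg <- imp$truth[imp$truth$origin == "hgt", ]
  for (i in seq_len(nrow(hg))) {
    donor_gene <- db$proteins$seq[
      db$proteins$species_id == hg$donor_species[i] &
        db$proteins$family == hg$family[i]]
    expect_equal(imp$proteome$seq[match(hg$gene_id[i],
                                        imp$proteome$gene_id)],
                 donor_gene)
  }
  # zero-rate limit of the evolution kernel
  m <- subst_model()
  codes <- hgtscan:::random_codes(100, m)
  expect_identical(hgtscan:::evolve_codes(codes, 0, m), codes)
})

test_that("implant-donor identity matches the substitution-model
           expectation within Monte-Carlo error", {
  m <- subst_model()
  div <- 0.15
  set.seed(31)
  obs <- replicate(50, {
    codes <- hgtscan:::random_codes(300, m)
    mut <- hgtscan:::evolve_codes(codes, div, m)
    mean(codes == mut)
  })
  want <- expected_identity(m, div)
  mc_se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - want), 4 * mc_se + 0.005)
})

test_that("mean implant-donor identity is non-increasing in divergence", {
  m <- subst_model()
  ids <- vapply(c(0.05, 0.3, 1.0), function(div) {
    set.seed(77)
    mean(replicate(10, {
      codes <- hgtscan:::random_codes(250, m)
      mean(codes == hgtscan:::evolve_codes(codes, div, m))
    }))
  }, numeric(1))
  expect_true(all(diff(ids) < 0))
})

test_that("implants are intronless while native genes may carry introns", {
  d <- tiny_synth()
  hg <- d$truth$gene_id[d$truth$origin == "hgt"]
  for (g in hg) expect_equal(intronless_check(g, d$gene_models), 0L)
  natives <- d$truth$gene_id[d$truth$origin == "native"]
  intr <- vapply(natives, intronless_check, integer(1),
                 gene_models = d$gene_models)
  expect_true(any(intr > 0))
})

test_that("EST sets cover exactly the expressed genes and implants are
           always expressed", {
  d <- tiny_synth()
  est_genes <- unique(c(d$est_sets$set_a$gene_id, d$est_sets$set_b$gene_id))
  expect_setequal(est_genes, d$truth$gene_id[d$truth$expressed])
  expect_true(all(d$truth$expressed[d$truth$origin == "hgt"]))
  # zero coverage: both sets empty
  cfg0 <- small_cfg(est_coverage = 0, implants_expressed = FALSE)
  db0 <- generate_database(cfg0)
  imp0 <- implant_hgt(db0, cfg0)
  ests0 <- generate_est_sets(imp0$cds, imp0$truth, cfg0)
  expect_equal(nrow(ests0$set_a) + nrow(ests0$set_b), 0)
})

test_that("full EST coverage is recovered end-to-end by the expression
           filter", {
  cfg <- small_cfg(est_coverage = 1)
  db <- generate_database(cfg)
  imp <- implant_hgt(db, cfg)
  ests <- generate_est_sets(imp$cds, imp$truth, cfg)
  res <- est_filter(imp$cds, ests)
  expect_true(all(res$expressed))
})

test_that("planted modules produce the expected coexpression structure
           and the SNP list never contains implants", {
  cfg <- small_cfg(expr_noise_sd = 0)
  db <- generate_database(cfg)
  imp <- implant_hgt(db, cfg)
  fn <- generate_expression(imp$truth, cfg)
  lg <- log2(fn$expr)
  mod1 <- fn$modules$gene_id[fn$modules$module == 1]
  cors <- stats::cor(t(lg[mod1, ]))
  expect_equal(unname(cors[upper.tri(cors)]),
               rep(1, sum(upper.tri(cors))), tolerance = 1e-9)
  implants <- imp$truth$gene_id[imp$truth$origin == "hgt"]
  expect_length(intersect(fn$snp_genes, implants), 0)

  # moderate noise: within-module correlation beats between-module
  fn2 <- generate_expression(imp$truth, small_cfg())
  lg2 <- log2(fn2$expr)
  m1 <- fn2$modules$gene_id[fn2$modules$module == 1]
  m2 <- fn2$modules$gene_id[fn2$modules$module == 2]
  within <- abs(stats::cor(t(lg2[m1, ])))
  between <- abs(stats::cor(t(lg2[m1, ]), t(lg2[m2, ])))
  expect_gt(mean(within[upper.tri(within)]), mean(between))
})
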