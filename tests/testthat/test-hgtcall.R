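# handcrafted "bootstrap result": supports are the internal-node labels
# written in the newick itself, so ordering follows ape's parser
fake_bs <- function(nwk, supports_ignored = NULL) {
  tree <- ape::read.tree(text = nwk)
  n_tip <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  names(support) <- n_tip + seq_len(tree$Nnode)
  list(tree = tree, support = support, n_reps = 100)
}

groups_for <- function(tree, query = "q") {
  leaves <- setdiff(tree$tip.label, query)
  g <- dplyr::case_when(
    grepl("^b", leaves) ~ "bacterium",
    grepl("^p", leaves) ~ "plant",
    grepl("^f", leaves) ~ "fungus",
    grepl("^m", leaves) ~ "other_metazoan",
    grepl("^i", leaves) ~ "arthropod_insect",
    TRUE ~ "other_eukaryote")
  stats::setNames(g, leaves)
}

test_that("a query sister to bacteria inside a bacterial clade is called
           hgt with the right donor group and nesting depth", {
  bs <- fake_bs("((m1:1,m2:1)100:1,(b1:1,(b2:1,(q:0.1,b3:0.2)92:0.2)90:0.2)95:1);",
                c(100, 95, 90, 92))
  lg <- groups_for(bs$tree)
  r <- classify_hgt(bs, lg, "q")
  expect_equal(r$verdict, "hgt")
  expect_equal(r$donor_group, "bacterium")
  expect_equal(r$clade_support, 92)
  expect_gte(r$nested_depth, 1)
  expect_equal(direction_evidence(TRUE, r$nested_depth), "to_recipient")
})

test_that("a query sister to metazoans is not called, and sitting outside
           the whole foreign clade gives nesting depth zero", {
  bs <- fake_bs("((q:1,(m1:1,m2:1)98:1)99:1,(b1:1,b2:1)97:1);",
                c(99, 98, 97))
  r <- classify_hgt(bs, groups_for(bs$tree), "q")
  expect_equal(r$verdict, "not_hgt")

  # query attaches outside the bacterial clade: first clade is pure
  # foreign but nothing larger stays foreign-only
  bs2 <- fake_bs("((m1:1,m2:1)99:1,(q:1,(b1:1,b2:1)95:1)98:1);",
                 c(99, 98, 95))
  r2 <- classify_hgt(bs2, groups_for(bs2$tree), "q")
  expect_equal(r2$nested_depth, 0L)
  expect_equal(direction_evidence(TRUE, r2$nested_depth), "ambiguous")
  expect_equal(direction_evidence(FALSE, 3L), "ambiguous")
})

test_that("support thresholds gate the call at the stated boundaries and
           raising them never enlarges the verdict set", {
  nwk <- "((m1:1,m2:1)100:1,(b1:1,(q:0.1,b2:0.2)%d:0.2)100:1);"
  for (s in c(79, 80, 84, 85, 92)) {
    bs <- fake_bs(sprintf(nwk, s), c(100, 100, s))
    r_single <- classify_hgt(bs, groups_for(bs$tree), "q",
                             dual_threshold = FALSE)
    r_dual <- classify_hgt(bs, groups_for(bs$tree), "q",
                           dual_threshold = TRUE)
    expect_equal(r_single$verdict == "hgt", s >= 80, info = s)
    expect_equal(r_dual$verdict == "hgt", s >= 85, info = s)
  }
  # monotonicity across a threshold sweep
  bs <- fake_bs(sprintf(nwk, 83), c(100, 100, 83))
  lg <- groups_for(bs$tree)
  called <- vapply(c(50, 70, 80, 83, 84, 90), function(thr)
    classify_hgt(bs, lg, "q", support_threshold = thr,
                 dual_threshold = FALSE)$verdict == "hgt", logical(1))
  expect_true(all(diff(as.integer(called)) <= 0))
})

test_that("impure foreign clades follow the one-minority-leaf rule", {
  # one fungus among bacteria: majority prokaryote, tolerated
  bs <- fake_bs("((m1:1,m2:1)100:1,((q:0.1,b1:0.2)96:0.1,(b2:1,f1:1)90:1)100:1);",
                c(100, 100, 96, 90))
  lg <- groups_for(bs$tree)
  r <- classify_hgt(bs, lg, "q")
  expect_equal(r$verdict, "hgt")

  # clade with two minority leaves is untestable
  bs2 <- fake_bs("((m1:1,m2:1)100:1,((b1:1,q:1)95:1,(f1:1,f2:1)94:1)100:1);",
                 c(100, 100, 95, 94))
  lg2 <- groups_for(bs2$tree)
  r2 <- classify_hgt(bs2, lg2, "q")
  # smallest clade is pure (q + b1); walk up meets the mixed clade
  expect_equal(r2$verdict, "hgt")
  # mixed nearest clade with a two-leaf majority that is not a donor
  # class: untestable
  bs3 <- fake_bs("(((m1:1,m2:1)98:1,(m3:1,m4:1)97:1)100:1,(q:1,(b1:1,(f1:1,f2:1)94:1)96:1)98:1);")
  r3 <- classify_hgt(bs3, groups_for(bs3$tree), "q")
  expect_equal(r3$verdict, "untestable")
})

test_that("queries must appear exactly once and every leaf needs a
           group", {
  bs <- fake_bs("((a:1,b:1)90:1,(c:1,d:1)91:1);", c(90, 91))
  expect_error(classify_hgt(bs, c(a = "bacterium"), "missing"),
               "exactly once")
  expect_error(classify_hgt(bs, c(a = "bacterium"), "a"), "group label")
})

test_that("donor assignment picks the top foreign bit score with
           deterministic tie-breaking", {
  hits <- tibble::tibble(
    query_id = "q",
    subject_id = c("x1", "x2", "x3", "i1"),
    species_id = c("spA", "spB", "spC", "insect1"),
    group = c("bacterium", "bacterium", "plant", "arthropod_insect"),
    bit_score = c(300, 300, 250, 500),
    e_value = c(1e-80, 1e-80, 1e-60, 1e-120),
    pct_identity = c(88, 91, 70, 99),
    query_coverage = c(95, 92, 80, 100))
  r <- assign_donor(hits)
  expect_equal(r$donor_top_species, "spB")  # tie on bits, higher identity
  expect_error(assign_donor(hits[hits$group == "arthropod_insect", ]),
               "foreign")
  # synthetic truth: implant's donor species tops its hit list
  d <- tiny_synth()
  hg <- d$truth[d$truth$origin == "hgt", ][1, ]
  h <- best_hits(d$proteome[d$proteome$gene_id == hg$gene_id, ],
                 d$database, d$taxa)
  expect_equal(assign_donor(h)$donor_top_species, hg$donor_species)
})
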