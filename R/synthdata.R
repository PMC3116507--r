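# Synthetic benchmark generator: taxon-labeled proteomes evolved along a
# fixed species tree under JTT, with implanted horizontally transferred
# genes, transposon-derived genes, EST sets and an expression matrix with
# planted coexpression modules. Every downstream stage of the pipeline is
# testable against the ground truth this module records.

TAXON_GROUPS <- c("arthropod_insect", "other_metazoan", "plant", "fungus",
                  "other_eukaryote", "bacterium")

group_domain <- function(group) {
  ifelse(group %in% c("bacterium", "archaeon"), "prokaryote", "eukaryote")
}

#' Configuration for the synthetic benchmark
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 6 taxonomic groups with 4 database species each, 200 shared gene
#' families, 8 implanted transfers at divergence 0.1 (one plant donor, the
#' rest bacterial), all implants expressed.
#'
#' @param n_species_per_group Named counts of database species per group.
#' @param n_families Gene families shared across all groups.
#' @param n_insect_only Families restricted to insect species (recipient
#'   included).
#' @param n_hgt_implants Number of implanted transfer events.
#' @param hgt_divergence Expected substitutions/site between donor gene and
#'   implant.
#' @param donor_groups Donor group per implant; default one `"plant"` and
#'   the rest `"bacterium"` when two or more implants are requested.
#' @param n_transposons Transposon-derived genes in the recipient.
#' @param te_library_size Sequences in the transposon library.
#' @param est_coverage Fraction of recipient genes that are expressed (and
#'   hence covered by ESTs). Implants are always expressed when
#'   `implants_expressed` is `TRUE`.
#' @param implants_expressed Force implants to be expressed.
#' @param est_error Per-base EST error rate (substitutions and rare indels).
#' @param expr_tissues,expr_reps Tissue labels and replicates per tissue for
#'   the expression matrix.
#' @param n_coexpr_modules,module_size Planted coexpression modules (each
#'   tied to one pathway; implants are distributed among modules).
#' @param expr_noise_sd Independent log-scale noise within modules.
#' @param n_pathways,n_snp_genes Pathway-map and SNP-list sizes.
#' @param length_range Protein length range (uniform).
#' @param group_depth,species_depth Species-tree depths: groups diverge at
#'   `group_depth` substitutions/site from the family root, species within a
#'   group at `species_depth` from the group ancestor.
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return An object of class `hgt_synth_config`.
#' @export
synth_config <- function(n_species_per_group = c(arthropod_insect = 4,
                                                 other_metazoan = 4,
                                                 plant = 4, fungus = 4,
                                                 other_eukaryote = 4,
                                                 bacterium = 4),
                         n_families = 200, n_insect_only = 20,
                         n_hgt_implants = 8, hgt_divergence = 0.1,
                         donor_groups = NULL, n_transposons = 5,
                         te_library_size = 10, est_coverage = 0.9,
                         implants_expressed = TRUE, est_error = 0.01,
                         expr_tissues = c("integument", "fat_body", "midgut",
                                          "malpighian_tubule", "head",
                                          "silk_gland", "testis", "ovary",
                                          "hemocyte", "epidermis"),
                         expr_reps = 3, n_coexpr_modules = 3,
                         module_size = 20, expr_noise_sd = 0.5,
                         n_pathways = 25, n_snp_genes = 30,
                         length_range = c(150, 500), group_depth = 0.6,
                         species_depth = 0.2, seed = 101) {
  stopifnot(all(n_species_per_group >= 0), n_families >= 0,
            n_insect_only >= 0, n_hgt_implants >= 0, hgt_divergence >= 0,
            n_transposons >= 0, est_coverage >= 0, est_coverage <= 1,
            length(length_range) == 2, group_depth > 0, species_depth > 0)
  if (is.null(names(n_species_per_group)) ||
      !all(names(n_species_per_group) %in% TAXON_GROUPS)) {
    stop("n_species_per_group must be named with known taxonomic groups")
  }
  if (is.null(donor_groups)) {
    donor_groups <- if (n_hgt_implants >= 2) {
      c("plant", rep("bacterium", n_hgt_implants - 1))
    } else {
      rep("bacterium", n_hgt_implants)
    }
  }
  stopifnot(length(donor_groups) == n_hgt_implants)
  bad <- setdiff(unique(donor_groups),
                 names(n_species_per_group)[n_species_per_group > 0])
  if (length(bad) > 0) {
    stop("implants target group(s) with zero species: ",
         paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "hgt_synth_config")
}

#' @export
print.hgt_synth_config <- function(x, ...) {
  cat("Synthetic benchmark configuration\n")
  cat("  database species:", sum(x$n_species_per_group), "in",
      sum(x$n_species_per_group > 0), "groups (+ recipient)\n")
  cat("  families:", x$n_families, " insect-only:", x$n_insect_only,
      " implants:", x$n_hgt_implants, "@", x$hgt_divergence, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# site-wise evolution of an integer-coded sequence along a branch ------------
evolve_codes <- function(codes, t, model) {
  if (t == 0) return(codes)
  P <- prob_matrix(model, t)
  out <- codes
  for (s in unique(codes)) {
    idx <- which(codes == s)
    out[idx] <- sample.int(20L, length(idx), replace = TRUE,
                           prob = P[s + 1L, ]) - 1L
  }
  out
}

random_codes <- function(len, model) {
  sample.int(20L, len, replace = TRUE, prob = model$freq) - 1L
}

species_ids <- function(config) {
  grp <- names(config$n_species_per_group)
  short <- c(arthropod_insect = "insect", other_metazoan = "metazoan",
             plant = "plant", fungus = "fungus", other_eukaryote = "euk",
             bacterium = "bact")
  purrr::map2(grp, config$n_species_per_group, function(g, n) {
    if (n == 0) return(NULL)
    tibble::tibble(species_id = paste0(short[[g]], "_", seq_len(n)),
                   group = g)
  }) |> purrr::list_rbind()
}

#' Generate the taxon-labeled proteome database
#'
#' Evolves `n_families` root sequences along a fixed species tree: group
#' ancestors diverge from the family root at `group_depth`, species within a
#' group at `species_depth` from their ancestor. Insect-only families are
#' present in insect species (and the recipient) exclusively. The recipient
#' is an additional insect species named `"recipient"`; its rows are part of
#' the returned proteins table but are excluded when the collection is used
#' as a search database. Transposon-derived recipient genes (related to a
#' random transposon library, unrelated to any family) are also created
#' here.
#'
#' @param config An [synth_config()].
#' @return A list of class `hgt_synth_db`: `proteins` (tibble `gene_id`,
#'   `species_id`, `group`, `family`, `seq`), `taxa` (species taxon table
#'   with `domain`), `te_library` (named character), and internal family
#'   ancestors used by [implant_hgt()].
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "hgt_synth_config"))
  set.seed(config$seed)
  model <- subst_model()   # plain JTT for simulation: oracle-checkable
  sp <- species_ids(config)
  taxa <- dplyr::bind_rows(
    sp, tibble::tibble(species_id = "recipient", group = "arthropod_insect"))
  taxa$domain <- group_domain(taxa$group)
  groups_present <- unique(sp$group)

  fam_branch <- config$group_depth
  sp_branch <- config$species_depth
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 config$n_families, replace = TRUE)

  rows <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    root <- random_codes(lens[f], model)
    fam <- sprintf("fam%03d", f)
    per_group <- lapply(groups_present, function(g) {
      anc <- evolve_codes(root, fam_branch, model)
      members <- sp[sp$group == g, ]
      ids <- c(members$species_id,
               if (g == "arthropod_insect") "recipient")
      tibble::tibble(
        gene_id = paste0(ids, "_", fam), species_id = ids, group = g,
        family = fam,
        seq = vapply(ids, function(s)
          int_to_aa(list(evolve_codes(anc, sp_branch, model))), character(1),
          USE.NAMES = FALSE))
    })
    rows[[f]] <- purrr::list_rbind(per_group)
  }
  proteins <- purrr::list_rbind(rows)

  # insect-only families: independent roots, insect species + recipient only
  if (config$n_insect_only > 0) {
    ins <- c(sp$species_id[sp$group == "arthropod_insect"], "recipient")
    io_lens <- sample(seq(config$length_range[1], config$length_range[2]),
                      config$n_insect_only, replace = TRUE)
    io <- lapply(seq_len(config$n_insect_only), function(k) {
      root <- random_codes(io_lens[k], model)
      anc <- evolve_codes(root, sp_branch, model)
      fam <- sprintf("io%03d", k)
      tibble::tibble(
        gene_id = paste0(ins, "_", fam), species_id = ins,
        group = "arthropod_insect", family = fam,
        seq = vapply(ins, function(s)
          int_to_aa(list(evolve_codes(anc, sp_branch, model))), character(1),
          USE.NAMES = FALSE))
    })
    proteins <- dplyr::bind_rows(proteins, purrr::list_rbind(io))
  }

  # transposon library and recipient transposon-derived genes
  te_lens <- sample(seq(config$length_range[1], config$length_range[2]),
                    max(config$te_library_size, 1), replace = TRUE)
  te_library <- stats::setNames(
    vapply(seq_len(config$te_library_size), function(k)
      int_to_aa(list(random_codes(te_lens[k], model))), character(1)),
    paste0("te_lib_", seq_len(config$te_library_size)))
  if (config$n_transposons > 0) {
    stopifnot(config$te_library_size > 0)
    src <- sample(config$te_library_size, config$n_transposons, replace = TRUE)
    te <- tibble::tibble(
      gene_id = sprintf("recipient_te%02d", seq_len(config$n_transposons)),
      species_id = "recipient", group = "arthropod_insect",
      family = names(te_library)[src],
      seq = vapply(src, function(k)
        int_to_aa(list(evolve_codes(aa_to_int(te_library[[k]])[[1]], 0.05,
                                    model))), character(1), USE.NAMES = FALSE))
    proteins <- dplyr::bind_rows(proteins, te)
  }

  structure(list(proteins = proteins, taxa = tibble::as_tibble(taxa),
                 te_library = te_library, model = model, config = config),
            class = "hgt_synth_db")
}

#' Implant horizontally transferred genes into the recipient
#'
#' Copies one gene from each chosen donor species (distinct families),
#' mutates it to the configured expected divergence, and appends it to the
#' recipient proteome with a single-exon (intronless) gene model; native
#' recipient genes receive multi-exon models. Builds the ground-truth table
#' partitioning every recipient gene into native / insect-only / hgt /
#' transposon, with the expression flag used by the EST and expression
#' generators.
#'
#' @param db An `hgt_synth_db` from [generate_database()].
#' @param config The same [synth_config()].
#' @return List: `proteome` (recipient tibble including implants), `truth`
#'   (tibble `gene_id`, `origin`, `donor_species`, `donor_group`, `family`,
#'   `expressed`), `gene_models` (tibble of exon records, 1-based inclusive),
#'   `cds` (tibble `gene_id`, `cds` nucleotide string).
#' @export
implant_hgt <- function(db, config = db$config) {
  stopifnot(inherits(db, "hgt_synth_db"))
  set.seed(config$seed + 1L)
  model <- db$model
  donors_pool <- db$proteins[db$proteins$group %in% config$donor_groups &
                             db$proteins$species_id != "recipient" &
                             grepl("^fam", db$proteins$family), ]
  n <- config$n_hgt_implants
  implants <- NULL
  if (n > 0) {
    if (n > length(unique(donors_pool$family))) {
      stop("more implants requested than donor families available")
    }
    fams <- sample(unique(donors_pool$family), n)
    implants <- purrr::map2(seq_len(n), fams, function(k, fam) {
      g <- config$donor_groups[k]
      cand <- donors_pool[donors_pool$family == fam & donors_pool$group == g, ]
      if (nrow(cand) == 0) stop("no donor gene available in group ", g)
      donor <- cand[sample(nrow(cand), 1), ]
      seq <- int_to_aa(list(evolve_codes(aa_to_int(donor$seq)[[1]],
                                         config$hgt_divergence, model)))
      tibble::tibble(gene_id = sprintf("recipient_hgt%02d", k),
                     species_id = "recipient", group = "arthropod_insect",
                     family = fam, seq = seq,
                     donor_species = donor$species_id,
                     donor_gene = donor$gene_id, donor_group = g)
    }) |> purrr::list_rbind()
  }

  rec <- db$proteins[db$proteins$species_id == "recipient", ]
  proteome <- dplyr::bind_rows(
    rec, if (!is.null(implants)) implants[, names(rec)])

  origin <- dplyr::case_when(
    grepl("_te\\d+$", proteome$gene_id) ~ "transposon",
    grepl("_hgt\\d+$", proteome$gene_id) ~ "hgt",
    grepl("_io\\d+$", proteome$gene_id) ~ "insect_only",
    TRUE ~ "native")
  truth <- tibble::tibble(
    gene_id = proteome$gene_id, origin = origin,
    donor_species = NA_character_, donor_group = NA_character_,
    family = proteome$family)
  if (!is.null(implants)) {
    i <- match(implants$gene_id, truth$gene_id)
    truth$donor_species[i] <- implants$donor_species
    truth$donor_group[i] <- implants$donor_group
  }
  truth$expressed <- stats::runif(nrow(truth)) < config$est_coverage
  if (config$implants_expressed) {
    truth$expressed[truth$origin == "hgt"] <- TRUE
  }

  cds <- tibble::tibble(
    gene_id = proteome$gene_id,
    cds = vapply(proteome$seq, back_translate, character(1), USE.NAMES = FALSE))

  gene_models <- make_gene_models(cds, origin)
  list(proteome = proteome, truth = truth, gene_models = gene_models,
       cds = cds)
}

# reverse translation with uniformly random synonymous codons
back_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

# exon records: implants and transposon genes single-exon; natives 2-5 exons
make_gene_models <- function(cds, origin) {
  pos <- 1000L
  rows <- vector("list", nrow(cds))
  for (i in seq_len(nrow(cds))) {
    len <- nchar(cds$cds[i])
    n_exon <- if (origin[i] %in% c("hgt", "transposon")) 1L
              else sample(2:5, 1)
    n_exon <- min(n_exon, len %/% 60L)  # keep exons non-trivial
    n_exon <- max(n_exon, 1L)
    cuts <- if (n_exon > 1) sort(sample(seq(30L, len - 30L), n_exon - 1L))
            else integer(0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    ex_start <- integer(n_exon)
    ex_end <- integer(n_exon)
    p <- pos
    for (e in seq_len(n_exon)) {
      ex_start[e] <- p
      ex_end[e] <- p + (ends[e] - starts[e])
      p <- ex_end[e] + sample(50:200, 1)   # intron
    }
    rows[[i]] <- tibble::tibble(
      seqid = "chr1", source = "hgtscan_sim", type = "exon",
      start = ex_start, end = ex_end, strand = "+",
      gene_id = cds$gene_id[i], exon_number = seq_len(n_exon))
    pos <- p + 500L
  }
  purrr::list_rbind(rows)
}

#' Generate EST sets for expressed recipient genes
#'
#' Every expressed gene receives 1-3 ESTs, each a subsequence of its CDS
#' (200-600 nt, or the full CDS if shorter) with a low simulated error rate,
#' assigned to one of two sets; at least one EST per expressed gene is
#' guaranteed across the two sets. Unexpressed genes are absent from both.
#'
#' @param cds Tibble `gene_id`, `cds` from [implant_hgt()].
#' @param truth Truth table with the `expressed` flag.
#' @param config An [synth_config()].
#' @param seed_offset Internal offset so domestic and wild sets differ.
#' @param include Optional character vector restricting source genes (used
#'   for wild-relative sets, which carry no implants).
#' @return List of two tibbles `set_a`, `set_b` (`est_id`, `gene_id`, `seq`).
#' @export
generate_est_sets <- function(cds, truth, config, seed_offset = 2L,
                              include = NULL) {
  set.seed(config$seed + seed_offset)
  genes <- truth$gene_id[truth$expressed]
  if (!is.null(include)) genes <- intersect(genes, include)
  a <- list(); b <- list()
  for (g in genes) {
    s <- cds$cds[match(g, cds$gene_id)]
    n_est <- sample(1:3, 1)
    dest <- sample(c("a", "b"), n_est, replace = TRUE)
    for (k in seq_len(n_est)) {
      est <- mutate_est(subseq_est(s), config$est_error)
      id <- paste0(g, "_est", k)
      if (dest[k] == "a") a[[id]] <- est else b[[id]] <- est
    }
  }
  to_tbl <- function(x, set) tibble::tibble(
    est_id = paste0(names(x), "_", set),
    gene_id = sub("_est\\d+$", "", names(x)),
    seq = unlist(x) %||% character(0))
  list(set_a = to_tbl(a, "a"), set_b = to_tbl(b, "b"))
}

subseq_est <- function(cds_seq) {
  len <- nchar(cds_seq)
  want <- sample(200:600, 1)
  if (len <= want) return(cds_seq)
  start <- sample.int(len - want + 1L, 1)
  substr(cds_seq, start, start + want - 1L)
}

mutate_est <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  nt <- strsplit(seq, "")[[1]]
  n_err <- stats::rbinom(1, length(nt), error_rate)
  if (n_err == 0) return(seq)
  pos <- sample.int(length(nt), n_err)
  kind <- sample(c("sub", "del", "ins"), n_err, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  for (i in seq_len(n_err)) {
    p <- pos[i]
    if (kind[i] == "sub") {
      nt[p] <- sample(setdiff(c("A", "C", "G", "T"), nt[p]), 1)
    } else if (kind[i] == "del") {
      nt[p] <- ""
    } else {
      nt[p] <- paste0(nt[p], sample(c("A", "C", "G", "T"), 1))
    }
  }
  paste(nt, collapse = "")
}

#' Generate the expression matrix, pathway/GO maps and SNP list
#'
#' Planted coexpression modules share a latent tissue profile plus
#' independent noise; each module's genes carry one common pathway id, and
#' implants are distributed among modules so their coexpression lists
#' recover the planted pathway. GO terms are assigned at a background rate,
#' with one term enriched among implants. The SNP list is a random subset of
#' non-implant genes.
#'
#' @param truth Truth table from [implant_hgt()].
#' @param config An [synth_config()].
#' @return List: `expr` (raw nonnegative matrix, genes x samples),
#'   `samples` (tibble `sample_id`, `tissue`), `pathway_map`, `go_map`
#'   (tibbles `gene_id`, term id), `snp_genes` (character),
#'   `modules` (tibble `gene_id`, `module`, `pathway_id`).
#' @export
generate_expression <- function(truth, config) {
  set.seed(config$seed + 4L)
  stopifnot(length(config$expr_tissues) > 0, config$expr_reps >= 1)
  genes <- truth$gene_id
  samples <- tibble::tibble(
    tissue = rep(config$expr_tissues, each = config$expr_reps),
    rep = rep(seq_len(config$expr_reps), times = length(config$expr_tissues)))
  samples$sample_id <- paste0(samples$tissue, "_r", samples$rep)

  n_mod <- config$n_coexpr_modules
  implants <- truth$gene_id[truth$origin == "hgt"]
  others <- setdiff(genes, implants)
  modules <- NULL
  module_of <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  if (n_mod > 0) {
    # spread non-implant genes evenly so every module has co-members even
    # when the gene pool is small
    free <- sample(others)
    shares <- split(free, rep(seq_len(n_mod), length.out = length(free)))
    for (m in seq_len(n_mod)) {
      mem_imp <- implants[seq_along(implants) %% n_mod + 1L == m]
      n_need <- max(config$module_size - length(mem_imp), 0)
      mem <- c(mem_imp, utils::head(shares[[m]], n_need))
      module_of[mem] <- m
    }
    modules <- tibble::tibble(gene_id = names(module_of)[!is.na(module_of)],
                              module = module_of[!is.na(module_of)],
                              pathway_id = sprintf("pw_module%02d",
                                                   module_of[!is.na(module_of)]))
  }

  base <- stats::rnorm(length(genes), mean = 6, sd = 1)
  lat <- matrix(stats::rnorm(n_mod * length(config$expr_tissues), 0, 2),
                nrow = max(n_mod, 1))
  logm <- matrix(0, length(genes), nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  t_idx <- match(samples$tissue, config$expr_tissues)
  for (i in seq_along(genes)) {
    m <- module_of[i]
    prof <- if (!is.na(m)) lat[m, t_idx]
            else stats::rnorm(length(config$expr_tissues), 0, 2)[t_idx]
    logm[i, ] <- base[i] + prof +
      stats::rnorm(nrow(samples), 0, config$expr_noise_sd)
  }
  expr <- 2^logm   # strictly positive raw intensities; exact log-scale
                   # module structure survives the round trip

  # pathway map: module pathways plus random background pathways
  pw_ids <- sprintf("pw_bg%02d", seq_len(config$n_pathways))
  pathway_map <- tibble::tibble(
    gene_id = genes, pathway_id = sample(pw_ids, length(genes), replace = TRUE))
  if (!is.null(modules)) {
    pathway_map <- dplyr::bind_rows(
      pathway_map[!pathway_map$gene_id %in% modules$gene_id, ],
      modules[, c("gene_id", "pathway_id")])
  }

  # GO map: background rates, one term enriched among implants
  go_terms <- c("go_catalytic", "go_hydrolase", "go_binding", "go_transport")
  go_map <- purrr::map(go_terms, function(tm) {
    p <- if (tm == "go_hydrolase") 0.08 else 0.2
    hit <- genes[stats::runif(length(genes)) < p]
    if (tm %in% c("go_hydrolase", "go_catalytic")) hit <- union(hit, implants)
    tibble::tibble(gene_id = hit, term = tm)
  }) |> purrr::list_rbind()

  snp_pool <- setdiff(genes, implants)
  snp_genes <- sort(sample(snp_pool, min(config$n_snp_genes,
                                         length(snp_pool))))
  list(expr = expr, samples = samples[, c("sample_id", "tissue")],
       pathway_map = pathway_map, go_map = go_map, snp_genes = snp_genes,
       modules = modules)
}

#' Simulate a complete synthetic benchmark
#'
#' Runs [generate_database()], [implant_hgt()], [generate_est_sets()] (a
#' domestic pair of sets plus three wild-relative sets carrying no
#' implants), and [generate_expression()], returning everything the
#' pipeline consumes with ground truth attached.
#'
#' @param config An [synth_config()].
#' @return An object of class `hgt_synth_data`.
#' @export
simulate_hgt_data <- function(config = synth_config()) {
  db <- generate_database(config)
  imp <- implant_hgt(db, config)
  ests <- generate_est_sets(imp$cds, imp$truth, config, seed_offset = 2L)
  wild_src <- imp$truth$gene_id[imp$truth$origin %in%
                                  c("native", "insect_only")]
  wild <- lapply(1:3, function(k) {
    s <- generate_est_sets(imp$cds, imp$truth, config,
                           seed_offset = 10L + k, include = wild_src)
    dplyr::bind_rows(s$set_a, s$set_b)
  })
  names(wild) <- paste0("wild_", 1:3)
  fn <- generate_expression(imp$truth, config)
  database <- db$proteins[db$proteins$species_id != "recipient", ]
  structure(
    list(config = config, database = database, taxa = db$taxa,
         te_library = db$te_library, proteome = imp$proteome,
         truth = imp$truth, gene_models = imp$gene_models, cds = imp$cds,
         est_sets = ests, wild_est_sets = wild, expr = fn$expr,
         samples = fn$samples, pathway_map = fn$pathway_map,
         go_map = fn$go_map, snp_genes = fn$snp_genes, modules = fn$modules),
    class = "hgt_synth_data")
}

#' @export
print.hgt_synth_data <- function(x, ...) {
  cat("Synthetic HGT benchmark\n")
  cat("  database:", nrow(x$database), "proteins,",
      length(unique(x$database$species_id)), "species\n")
  cat("  recipient proteome:", nrow(x$proteome), "genes (",
      sum(x$truth$origin == "hgt"), "implants )\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
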