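test_that("generator truth is recovered exactly by detection", {
  sim <- generate_genome(genome_sim_params(n_genes = 300L,
                                           frac_overlapping = 0.2,
                                           eh_fraction = 0.5,
                                           n_clusters = 2L, seed = 7L))
  validate_gene_table(sim$genes)
  res <- find_overlaps(sim$genes)
  expect_equal(nrow(res$pairs), nrow(sim$truth$pairs))
  got <- res$pairs[order(res$pairs$gene_a), ]
  want <- sim$truth$pairs[order(sim$truth$pairs$gene_a), ]
  expect_equal(got$gene_a, want$gene_a)
  expect_equal(got$gene_b, want$gene_b)
  expect_equal(got$category, want$category)
  expect_equal(got$orientation, want$orientation)
  expect_equal(got$overlap_len, as.integer(want$overlap_len))
  eh <- got$category == "EH"
  expect_equal(got$host[eh], want$host[eh])
  # cluster truth
  expect_equal(sort(vapply(res$clusters$members, paste, character(1),
                           collapse = ",")),
               sort(sim$truth$clusters$members))
  # intron-embedding truth agrees with the classifier
  ann <- annotate_intron_embedding(got, sim$genes)
  expect_equal(ann$embedded_in_intron[eh], want$in_intron[eh])
})

test_that("fraction_overlapping = 0 yields no pairs", {
  sim <- generate_genome(genome_sim_params(n_genes = 80L,
                                           frac_overlapping = 0,
                                           seed = 3L))
  res <- find_overlaps(sim$genes)
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(nrow(sim$truth$pairs), 0L)
})

test_that("intron-embedding and orientation fractions track their targets", {
  sim <- generate_genome(genome_sim_params(n_genes = 1200L,
                                           frac_overlapping = 0.5,
                                           eh_fraction = 1,
                                           frac_eh_intronic = 0.87,
                                           frac_opposite = 0.7, seed = 21L))
  tp <- sim$truth$pairs
  n <- nrow(tp)
  phat <- mean(tp$in_intron)
  expect_gt(phat, 0.87 - 3 * sqrt(0.87 * 0.13 / n))
  expect_lt(phat, 0.87 + 3 * sqrt(0.87 * 0.13 / n))
  opp <- mean(tp$orientation == "opposite")
  expect_gt(opp, 0.7 - 3 * sqrt(0.21 / n))
  expect_lt(opp, 0.7 + 3 * sqrt(0.21 / n))
})

test_that("generators are deterministic under a fixed seed", {
  p <- genome_sim_params(n_genes = 100L, seed = 5L)
  expect_identical(generate_genome(p), generate_genome(p))
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  fp <- family_sim_params(tr, genome_sim_params(n_genes = 60L,
                                                frac_overlapping = 0.3),
                          seed = 9L)
  f1 <- generate_family(fp)
  f2 <- generate_family(fp)
  expect_identical(f1$truth$pair_status, f2$truth$pair_status)
  expect_identical(f1$genomes$A, f2$genomes$A)
})

test_that("family truth matches localization analysis per species", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  fp <- family_sim_params(tr,
                          genome_sim_params(n_genes = 120L,
                                            frac_overlapping = 0.4,
                                            seed = 1L),
                          p_rearrange = 0.3, birth_pairs = 1L,
                          birth_singles = 2L, seed = 13L)
  fam <- generate_family(fp)
  st <- fam$truth$pair_status
  # rearrangement probability 0.3/branch: both retained and NOV must occur
  expect_true(any(st == "NOV"))
  expect_true(any(st %in% c("EH", "PO")))
  # per species, the detected overlap of ancestral pair orthologs matches
  for (sp in c("A", "D")) {
    gt <- fam$genomes[[sp]]
    for (i in seq_len(nrow(st))) {
      ids <- paste(sp, strsplit(rownames(st)[i], "|", fixed = TRUE)[[1L]],
                   sep = "_")
      rel <- pair_relation(ids[1L], ids[2L], gt)
      if (st[i, sp] == "NOV") expect_equal(rel, "NOV")
      else expect_equal(rel, st[i, sp])
    }
  }
})

test_that("rearrangement probability zero retains every pair everywhere", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  fp <- family_sim_params(tr,
                          genome_sim_params(n_genes = 60L,
                                            frac_overlapping = 0.4,
                                            seed = 2L),
                          p_rearrange = 0, birth_pairs = 0L,
                          birth_singles = 0L, seed = 4L)
  fam <- generate_family(fp)
  expect_true(all(fam$truth$pair_status %in% c("EH", "PO")))
  # with no births, ortholog maps cover all genes of both species
  m <- fam$maps[["A|B"]]
  expect_equal(nrow(m), nrow(fam$genomes$A))
})

test_that("implanted SSRs are constructed as stated", {
  imp <- implant_ssrs(4000L, density = 0.04, seed = 31L)
  expect_gt(nrow(imp$truth), 0L)
  expect_true(all(imp$truth$n_mismatches <= 2L))
  expect_equal(nchar(imp$sequence), 4000L)
  # a clean 30 bp AC run in an otherwise repeat-free background is
  # recovered as exactly one covering hit
  set.seed(99)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  seq2 <- paste0(substr(bg, 1, 150), strrep("AC", 15),
                 substr(bg, 181, 400))
  hits <- scan_ssrs(seq2)
  cover <- hits[hits$start <= 151 & hits$end >= 180, ]
  expect_equal(nrow(cover), 1L)
  expect_equal(cover$motif, "AC")
})

test_that("expression generator implants orientation-dependent correlation", {
  pairs <- data.frame(
    gene_a = sprintf("a%03d", 1:120), gene_b = sprintf("b%03d", 1:120),
    orientation = rep(c("same", "opposite"), each = 60L),
    stringsAsFactors = FALSE)
  expect_error(generate_expression(pairs, n_conditions = 1L), "condition")
  expr <- generate_expression(pairs, orientation_effect = 0.8,
                              n_conditions = 5L, seed = 17L)
  res <- expression_correlation_by_orientation(pairs, expr)
  expect_lt(res$same$p_value, 0.01)
  expect_gt(res$opposite$p_value, 0.05)
  expect_gt(res$same$rho, 0.5)
})

test_that("logit generator recovers its coefficients and flags separation", {
  beta <- c(-0.3, 0.4, -0.9, 0.5, -1.2)
  d <- generate_logit_data(beta, n = 1500L, seed = 23L)
  fit <- logit_fit(d)
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients - beta) < 2 * fit$se))
  # tiny, cleanly separable data is flagged
  set.seed(1)
  sep <- dnds_table(data.frame(
    pair_id = sprintf("p%d", 1:10), species = "s",
    gene1_dS = c(1:5, 11:15), gene1_dN = runif(10), gene2_dS = runif(10),
    gene2_dN = runif(10), overlap_status = rep(c(0L, 1L), each = 5L)))
  fit2 <- logit_fit(sep)
  expect_true(fit2$separated)
  expect_false(fit2$converged)
})
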