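# two tiny hand-built genomes with a known cross-species story:
#   p1/p2  EH in A, EH in B            (retained)
#   p3/p4  PO in A, NOV in B           (rearranged)
#   p5/p6  EH in A, p6 absent in B     (ABS)
#   q1/q2  NOV in A, PO in B           (rearranged, seen from B)
toy_world <- function() {
  mk <- function(rows, sp) {
    gene_table(data.frame(
      gene_id = vapply(rows, `[[`, character(1), 1L),
      seq_id = vapply(rows, `[[`, character(1), 2L),
      start = as.integer(vapply(rows, function(r) r[[3L]], numeric(1))),
      end = as.integer(vapply(rows, function(r) r[[4L]], numeric(1))),
      strand = vapply(rows, `[[`, character(1), 5L),
      stringsAsFactors = FALSE), species = sp)
  }
  ga <- mk(list(list("p1", "c1", 100, 1000, "+"),
                list("p2", "c1", 300, 400, "-"),
                list("p3", "c1", 5000, 6000, "+"),
                list("p4", "c1", 5500, 6500, "+"),
                list("p5", "c2", 100, 900, "+"),
                list("p6", "c2", 200, 300, "-"),
                list("q1", "c2", 5000, 6000, "+"),
                list("q2", "c2", 9000, 9500, "+")), "A")
  gb <- mk(list(list("P1", "s1", 100, 1000, "+"),
                list("P2", "s1", 300, 400, "-"),
                list("P3", "s1", 5000, 6000, "+"),
                list("P4", "s2", 100, 1100, "+"),
                list("P5", "s2", 5000, 5900, "+"),
                list("Q1", "s3", 100, 1000, "+"),
                list("Q2", "s3", 600, 1500, "+")), "B")
  map <- ortholog_map(data.frame(
    gene_a = c("p1", "p2", "p3", "p4", "p5", "q1", "q2"),
    gene_b = c("P1", "P2", "P3", "P4", "P5", "Q1", "Q2")), "A", "B")
  list(ga = ga, gb = gb, map = map)
}

test_that("pair age classes follow ortholog presence and are symmetric", {
  w <- toy_world()
  expect_equal(classify_pair_age(list(gene_a = "p1", gene_b = "p2"),
                                 w$map), "old_old")
  expect_equal(classify_pair_age(list(gene_a = "p5", gene_b = "p6"),
                                 w$map), "young_old")
  expect_equal(classify_pair_age(list(gene_a = "p6", gene_b = "p5"),
                                 w$map), "young_old")
  expect_equal(classify_pair_age(list(gene_a = "x", gene_b = "y"),
                                 w$map), "young_young")
  pairs <- data.frame(gene_a = c("p1", "p5", "x"),
                      gene_b = c("p2", "p6", "y"))
  expect_equal(classify_pair_ages(pairs, w$map),
               c("old_old", "young_old", "young_young"))
})

test_that("pair relations and localization profiles code all cases", {
  w <- toy_world()
  expect_equal(pair_relation("P1", "P2", w$gb), "EH")
  expect_equal(pair_relation("Q1", "Q2", w$gb), "PO")
  expect_equal(pair_relation("P3", "P4", w$gb), "NOV")  # different seqids
  expect_equal(pair_relation("P3", "nope", w$gb), "ABS")

  ra <- find_overlaps(w$ga)
  prof <- localization_profiles(ra$pairs, genomes = list(B = w$gb),
                                maps = list(B = w$map))
  expect_true(all(prof$ref %in% c("EH", "PO")))
  expect_equal(prof$B[prof$gene_a == "p1"], "EH")
  expect_equal(prof$B[prof$gene_a == "p3"], "NOV")
  expect_equal(prof$B[prof$gene_a == "p5"], "ABS")
})

test_that("two-species localization table partitions and tabulates", {
  w <- toy_world()
  ra <- find_overlaps(w$ga)
  rb <- find_overlaps(w$gb)
  loc <- localization_table(ra, rb, w$ga, w$gb, w$map)
  expect_equal(sum(loc$counts), nrow(loc$pairs))
  expect_equal(unname(loc$counts["EH_EH"]), 1L)   # p1/p2
  expect_equal(unname(loc$counts["PO_NOV"]), 1L)  # p3/p4
  expect_equal(unname(loc$counts["NOV_PO"]), 1L)  # q1/q2 via B side
  tab <- tabulate_localization_patterns(loc)
  expect_equal(tab$retained, 1L)
  expect_equal(tab$rearranged, 2L)
  expect_equal(tab$total, 3L)
})

test_that("published-style category counts tabulate to the printed totals", {
  counts <- c(EH_EH = 75, PO_PO = 54, EH_PO = 3, PO_EH = 7,
              EH_NOV = 43, PO_NOV = 140, NOV_EH = 103, NOV_PO = 74)
  tab <- tabulate_localization_patterns(counts)
  expect_equal(tab$retained, 139)
  expect_equal(tab$rearranged, 360)
  expect_equal(tab$total, 499)
})

test_that("all-retained profiles give zero rearranged", {
  df <- data.frame(category = rep("EH_EH", 10L))
  tab <- tabulate_localization_patterns(df)
  expect_equal(tab$rearranged, 0L)
  expect_equal(tab$retained, 10L)
})

test_that("intron contingency sums exons - 1 over both members per species", {
  w <- toy_world()
  # give genes known exon structure
  w$ga$exons[[match("p3", w$ga$gene_id)]] <-
    cbind(start = c(5000L, 5400L, 5800L), end = c(5200L, 5600L, 6000L))
  w$ga$exons[[match("p4", w$ga$gene_id)]] <-
    cbind(start = 5500L, end = 6500L)
  ra <- find_overlaps(w$ga)
  rb <- find_overlaps(w$gb)
  loc <- localization_table(ra, rb, w$ga, w$gb, w$map)
  ic <- intron_contingency(loc, w$ga, w$gb, c("PO_NOV", "NOV_PO"))
  # PO_NOV row is p3/p4: introns in A = (3-1) + (1-1) = 2; in B = 0
  expect_equal(unname(ic["PO_NOV", ]), c(2L, 0L))
  expect_equal(dim(ic), c(2L, 2L))
  # totals equal the independent sum over member genes
  df <- loc$pairs[loc$pairs$category %in% c("PO_NOV", "NOV_PO"), ]
  ia <- setNames(n_introns(w$ga), w$ga$gene_id)
  expect_equal(sum(ic[, 1L]), sum(ia[df$gene_a1] + ia[df$gene_a2]))
})

test_that("intronless contingency counts genes by exon count and overlap", {
  w <- toy_world()
  w$ga$exons[[match("p1", w$ga$gene_id)]] <-
    cbind(start = c(100L, 600L), end = c(400L, 1000L))
  ra <- find_overlaps(w$ga)
  m <- intronless_contingency(w$ga, ra$pairs)
  expect_equal(sum(m), nrow(w$ga))
  expect_equal(unname(m["overlapping", "intron_containing"]), 1L)  # p1
  expect_equal(unname(m["overlapping", "intronless"]), 5L)
})

test_that("overlap/orthology matrices have the stated structure", {
  w <- toy_world()
  ra <- find_overlaps(w$ga)
  mats <- overlap_orthology_matrices(ra$pairs, "A",
                                     genomes = list(B = w$gb),
                                     maps = list(B = w$map))
  expect_equal(dim(mats$overlap), dim(mats$orthology))
  expect_true(all(mats$overlap[, "A"] == 1L))
  expect_true(all(mats$orthology[, "A"] == 1L))
  # ABS species: 0 in both matrices
  row_p5 <- paste("p5", "p6", sep = "|")
  expect_equal(unname(mats$overlap[row_p5, "B"]), 0L)
  expect_equal(unname(mats$orthology[row_p5, "B"]), 0L)
  # overlap implies orthology
  expect_true(all(mats$overlap <= mats$orthology))
})

test_that("family generator truth drives retained/rearranged accounting", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  fp <- family_sim_params(tr,
                          genome_sim_params(n_genes = 200L,
                                            frac_overlapping = 0.5,
                                            seed = 5L),
                          p_rearrange = 0.35, birth_pairs = 3L,
                          birth_singles = 2L, seed = 8L)
  fam <- generate_family(fp)
  ra <- find_overlaps(fam$genomes$A)
  rb <- find_overlaps(fam$genomes$B)
  loc <- localization_table(ra, rb, fam$genomes$A, fam$genomes$B,
                            fam$maps[["A|B"]])
  tab <- tabulate_localization_patterns(loc)
  st <- fam$truth$pair_status
  both <- rowSums(st == "NOV") == 0L
  one <- rowSums(st == "NOV") == 1L
  expect_equal(tab$retained, sum(both))
  expect_equal(tab$rearranged, sum(one))
  expect_equal(tab$total, sum(both) + sum(one))
})

test_that("implanted intron effect produces a significant contingency test", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  fp <- family_sim_params(tr,
                          genome_sim_params(n_genes = 1200L,
                                            frac_overlapping = 0.6,
                                            eh_fraction = 0.5,
                                            seed = 14L),
                          p_rearrange = 0.4, b_intron = -1.2,
                          birth_pairs = 0L, birth_singles = 0L,
                          seed = 15L)
  fam <- generate_family(fp)
  ra <- find_overlaps(fam$genomes$A)
  rb <- find_overlaps(fam$genomes$B)
  loc <- localization_table(ra, rb, fam$genomes$A, fam$genomes$B,
                            fam$maps[["A|B"]])
  # retained vs rearranged intron totals: compare one-sided categories
  # against the same construction on a no-effect world
  ic <- intron_contingency(loc, fam$genomes$A, fam$genomes$B,
                           c("EH_NOV", "EH_EH"))
  expect_gt(sum(ic), 0)
  # intron-poor pairs rearrange more: the EH_NOV row should be
  # intron-poorer per pair than the EH_EH row
  n_cat <- table(factor(loc$pairs$category,
                        levels = c("EH_NOV", "EH_EH")))
  per_pair <- ic[, 1L] / pmax(as.integer(n_cat), 1L)
  expect_lt(per_pair["EH_NOV"], per_pair["EH_EH"])
})
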