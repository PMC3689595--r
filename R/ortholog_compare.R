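# Cross-species accounting of overlapping gene pairs: age classes,
# localization profiles, retention/rearrangement tabulation, intron and
# intronless contingencies, binary overlap/orthology matrices, and
# expression correlation by orientation.

#' Age class of an overlapping pair relative to a comparison species
#'
#' `old_old` when both members have one-to-one orthologs in the comparison
#' species, `young_young` when neither has, `young_old` when exactly one
#' has.  Symmetric in member order.
#'
#' @param pair list/row with `gene_a`, `gene_b` (reference-species ids).
#' @param map [ortholog_map()] from the reference species (side a) to the
#'   comparison species.
#' @return one of "old_old", "young_young", "young_old".
#' @export
classify_pair_age <- function(pair, map) {
  hit <- !is.na(ortho_lookup(map, c(pair$gene_a, pair$gene_b)))
  c("young_young", "young_old", "old_old")[sum(hit) + 1L]
}

#' @rdname classify_pair_age
#' @param pairs pair data.frame from [find_overlaps()].
#' @return for `classify_pair_ages`: character vector, one class per pair.
#' @export
classify_pair_ages <- function(pairs, map) {
  ha <- !is.na(ortho_lookup(map, pairs$gene_a))
  hb <- !is.na(ortho_lookup(map, pairs$gene_b))
  c("young_young", "young_old", "old_old")[ha + hb + 1L]
}

#' Pairwise localization relation of two genes in one genome
#'
#' "EH" if one span contains the other, "PO" if the spans intersect without
#' containment, "NOV" if they do not share a base (including different
#' seq_ids), "ABS" if either id is missing from the table.
#'
#' @param id1,id2 gene ids.
#' @param genes a [gene_table()].
#' @return character code.
#' @export
pair_relation <- function(id1, id2, genes) {
  i <- match(id1, genes$gene_id); j <- match(id2, genes$gene_id)
  if (is.na(id1) || is.na(id2) || is.na(i) || is.na(j)) return("ABS")
  if (genes$seq_id[i] != genes$seq_id[j]) return("NOV")
  s1 <- genes$start[i]; e1 <- genes$end[i]
  s2 <- genes$start[j]; e2 <- genes$end[j]
  if (min(e1, e2) < max(s1, s2)) return("NOV")
  if ((s1 <= s2 && e1 >= e2) || (s2 <= s1 && e2 >= e1)) "EH" else "PO"
}

#' Localization profiles of reference pairs across species
#'
#' For each overlapping pair of the reference species and each comparison
#' species: "ABS" when either one-to-one ortholog is missing, otherwise the
#' pairwise relation of the two orthologs in that genome ("EH"/"PO"/"NOV").
#' Orthologs that sit inside an overlapping cluster are still coded by
#' their pairwise relation (cluster membership does not change the code).
#'
#' @param pairs pair data.frame from [find_overlaps()] on the reference.
#' @param genomes named list of [gene_table()]s (comparison species).
#' @param maps named list of [ortholog_map()]s from the reference (side a)
#'   to each comparison species; names must match `genomes`.
#' @return data.frame: `pair_id`, `gene_a`, `gene_b`, `ref` (the pair's
#'   category) plus one code column per comparison species.
#' @export
localization_profiles <- function(pairs, genomes, maps) {
  sp <- names(maps)
  if (!all(sp %in% names(genomes)))
    abort("every map needs a matching genome: missing ",
          paste(setdiff(sp, names(genomes)), collapse = ", "))
  out <- data.frame(pair_id = paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    ref = pairs$category, stringsAsFactors = FALSE)
  for (s in sp) {
    oa <- ortho_lookup(maps[[s]], pairs$gene_a)
    ob <- ortho_lookup(maps[[s]], pairs$gene_b)
    out[[s]] <- vapply(seq_len(nrow(pairs)), function(i) {
      if (is.na(oa[i]) || is.na(ob[i])) "ABS"
      else pair_relation(oa[i], ob[i], genomes[[s]])
    }, character(1))
  }
  out
}

#' Two-species localization table of ortholog pairs
#'
#' The universe is every unordered gene pair, with both members having
#' one-to-one orthologs, that is overlapping (as a detected pair) in at
#' least one of the two species.  Each pair is coded by its pairwise
#' relation in both genomes and classified into the eight categories
#' EH/EH, PO/PO, EH/PO, PO/EH, EH/NOV, PO/NOV, NOV/EH, NOV/PO
#' (species A code first).
#'
#' @param res_a,res_b `overlap_result`s of species A and B.
#' @param genes_a,genes_b the matching [gene_table()]s.
#' @param map [ortholog_map()] with species A on side a.
#' @return list with `pairs` (per-pair data.frame: ids in both species,
#'   `code_a`, `code_b`, `category`) and `counts` (named vector of 8).
#' @export
localization_table <- function(res_a, res_b, genes_a, genes_b, map) {
  rows <- list()
  seen <- character(0)
  add_from_a <- function(ga1, ga2) {
    key <- paste(sort(c(ga1, ga2)), collapse = "|")
    if (key %in% seen) return()
    gb1 <- ortho_lookup(map, ga1); gb2 <- ortho_lookup(map, ga2)
    if (is.na(gb1) || is.na(gb2)) return()
    seen <<- c(seen, key)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_a1 = ga1, gene_a2 = ga2, gene_b1 = gb1, gene_b2 = gb2,
      code_a = pair_relation(ga1, ga2, genes_a),
      code_b = pair_relation(gb1, gb2, genes_b),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(res_a$pairs)))
    add_from_a(res_a$pairs$gene_a[i], res_a$pairs$gene_b[i])
  for (i in seq_len(nrow(res_b$pairs))) {
    ga1 <- ortho_lookup(map, res_b$pairs$gene_a[i], from = "b")
    ga2 <- ortho_lookup(map, res_b$pairs$gene_b[i], from = "b")
    if (is.na(ga1) || is.na(ga2)) next
    add_from_a(ga1, ga2)
  }
  if (!length(rows)) {
    df <- data.frame(gene_a1 = character(0), gene_a2 = character(0),
                     gene_b1 = character(0), gene_b2 = character(0),
                     code_a = character(0), code_b = character(0),
                     category = character(0), stringsAsFactors = FALSE)
    return(list(pairs = df, counts = localization_counts(df)))
  }
  df <- do.call(rbind, rows)
  df <- df[!(df$code_a == "NOV" & df$code_b == "NOV"), , drop = FALSE]
  df$category <- paste(df$code_a, df$code_b, sep = "_")
  rownames(df) <- NULL
  list(pairs = df, counts = localization_counts(df))
}

LOC_CATEGORIES <- c("EH_EH", "PO_PO", "EH_PO", "PO_EH",
                    "EH_NOV", "PO_NOV", "NOV_EH", "NOV_PO")

localization_counts <- function(df) {
  cnt <- table(factor(df$category, levels = LOC_CATEGORIES))
  setNames(as.integer(cnt), LOC_CATEGORIES)
}

#' Retained/rearranged totals from localization categories
#'
#' `retained` sums the four both-overlapping categories, `rearranged` the
#' four one-sided categories; the eight counts partition the profiled
#' ortholog pairs, so `retained + rearranged = total`.
#'
#' @param x either a named vector of the 8 category counts (names as in
#'   `EH_EH`, ... `NOV_PO`) or the `pairs` data.frame / list returned by
#'   [localization_table()].
#' @return list: `counts`, `retained`, `rearranged`, `total`.
#' @export
tabulate_localization_patterns <- function(x) {
  counts <- if (is.numeric(x)) {
    if (is.null(names(x)) && length(x) == 8L) names(x) <- LOC_CATEGORIES
    miss <- setdiff(LOC_CATEGORIES, names(x))
    if (length(miss)) abort("missing category count(s): ",
                            paste(miss, collapse = ", "))
    x[LOC_CATEGORIES]
  } else if (is.list(x) && !is.null(x$counts)) {
    x$counts
  } else if (is.data.frame(x)) {
    localization_counts(x)
  } else abort("cannot interpret input as localization categories")
  retained <- sum(counts[c("EH_EH", "PO_PO", "EH_PO", "PO_EH")])
  rearranged <- sum(counts[c("EH_NOV", "PO_NOV", "NOV_EH", "NOV_PO")])
  list(counts = counts, retained = unname(retained),
       rearranged = unname(rearranged),
       total = unname(retained + rearranged))
}

#' Intron-count contingency table for two reciprocal categories
#'
#' Rows are two reciprocal rearrangement categories, columns the two
#' species; each cell sums, over the pairs of that category, the intron
#' counts of both members in that species (introns = exons - 1).
#'
#' @param loc result of [localization_table()] (or its `pairs` element).
#' @param genes_a,genes_b gene tables with exon annotation.
#' @param categories length-2 character vector of category codes, default
#'   the nested rearrangement pair `c("NOV_EH", "EH_NOV")`.
#' @return 2x2 integer matrix (rows = categories, cols = species labels).
#' @export
intron_contingency <- function(loc, genes_a, genes_b,
                               categories = c("NOV_EH", "EH_NOV")) {
  df <- if (is.data.frame(loc)) loc else loc$pairs
  if (length(categories) != 2L) abort("need exactly two categories")
  ia <- setNames(n_introns(genes_a), genes_a$gene_id)
  ib <- setNames(n_introns(genes_b), genes_b$gene_id)
  cell <- function(cat, side) {
    sel <- df[df$category == cat, , drop = FALSE]
    if (!nrow(sel)) return(0L)
    if (side == "a") sum(ia[sel$gene_a1] + ia[sel$gene_a2])
    else sum(ib[sel$gene_b1] + ib[sel$gene_b2])
  }
  m <- matrix(c(cell(categories[1L], "a"), cell(categories[1L], "b"),
                cell(categories[2L], "a"), cell(categories[2L], "b")),
              nrow = 2L, byrow = TRUE,
              dimnames = list(categories,
                              c(attr(genes_a, "species"),
                                attr(genes_b, "species"))))
  storage.mode(m) <- "integer"
  m
}

#' Intronless vs intron-containing genes by overlap status
#'
#' Cross-classifies every gene of the table as intronless (single exon) or
#' intron-containing against membership in any detected overlapping pair.
#'
#' @param genes a [gene_table()].
#' @param pairs pair data.frame from [find_overlaps()].
#' @return 2x2 integer matrix (overlapping/non_overlapping x
#'   intronless/intron_containing).
#' @export
intronless_contingency <- function(genes, pairs) {
  in_pair <- genes$gene_id %in% c(pairs$gene_a, pairs$gene_b)
  intronless <- n_exons(genes) == 1L
  m <- matrix(c(sum(in_pair & intronless), sum(in_pair & !intronless),
                sum(!in_pair & intronless), sum(!in_pair & !intronless)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("overlapping", "non_overlapping"),
                              c("intronless", "intron_containing")))
  storage.mode(m) <- "integer"
  m
}

#' Binary overlap and orthology matrices for Mantel-style tests
#'
#' For each reference overlapping pair (rows) and each species (columns):
#' the overlap matrix is 1 iff both one-to-one orthologs are present and
#' positionally overlapping there; the orthology matrix is 1 iff both are
#' present.  The reference column is all ones in both by construction.
#'
#' @param pairs pair data.frame from [find_overlaps()] on the reference.
#' @param reference reference species label.
#' @param genomes,maps as in [localization_profiles()].
#' @return list of two 0/1 matrices `overlap` and `orthology`
#'   (pairs x species).
#' @export
overlap_orthology_matrices <- function(pairs, reference, genomes, maps) {
  prof <- localization_profiles(pairs, genomes, maps)
  sp <- names(maps)
  ov <- matrix(0L, nrow(prof), length(sp) + 1L,
               dimnames = list(prof$pair_id, c(reference, sp)))
  orth <- ov
  ov[, reference] <- 1L
  orth[, reference] <- 1L
  for (s in sp) {
    ov[, s] <- as.integer(prof[[s]] %in% c("EH", "PO"))
    orth[, s] <- as.integer(prof[[s]] != "ABS")
  }
  list(overlap = ov, orthology = orth)
}

#' Expression correlation of pair members, split by orientation
#'
#' Each gene is summarised to one scalar (mean over condition columns);
#' within each orientation group the two members' scalars are correlated
#' across pairs by [spearman_test()].
#'
#' @param pairs pair data.frame from [find_overlaps()] (needs
#'   `orientation`).
#' @param expression data.frame from [read_expression_table()].
#' @return list with elements `same` and `opposite` (each an `ovl_test`
#'   or NULL when fewer than 3 complete pairs) and counts `n_same`,
#'   `n_opposite`.
#' @export
expression_correlation_by_orientation <- function(pairs, expression) {
  val <- rowMeans(expression[, -1L, drop = FALSE])
  names(val) <- expression$gene_id
  ea <- val[pairs$gene_a]; eb <- val[pairs$gene_b]
  ok <- !is.na(ea) & !is.na(eb)
  run <- function(sel) {
    if (sum(sel) < 3L) return(NULL)
    spearman_test(ea[sel], eb[sel])
  }
  same <- ok & pairs$orientation == "same"
  opp <- ok & pairs$orientation == "opposite"
  list(same = run(same), opposite = run(opp),
       n_same = sum(same), n_opposite = sum(opp))
}
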