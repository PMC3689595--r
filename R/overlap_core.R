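# Detection and classification of positionally overlapping gene pairs.
#
# Detection is strand-agnostic and requires >= 1 shared base on the same
# seq_id.  Connected components of the pairwise overlap graph of size 2
# become classified pairs; components of size >= 3 are overlapping-gene
# clusters and contribute no pairs at all.

#' Find and classify overlapping gene pairs in one genome
#'
#' Every unordered pair of genes sharing at least one base on the same
#' `seq_id` (ignoring strand) enters the overlap graph.  Connected
#' components of size two are returned as classified pairs: `EH` when one
#' span contains the other (inclusive boundaries; the container is the
#' host), otherwise `PO`.  Components with three or more members are
#' returned as clusters and are excluded from the pair list.  Identical
#' spans are classified `EH` with the lexicographically smaller `gene_id`
#' as host and flagged in the `identical_span` column.
#'
#' @param genes a [gene_table()] for a single species.
#' @return list of class `overlap_result` with elements `pairs`
#'   (data.frame: `gene_a`, `gene_b`, `category`, `host`, `embedded`,
#'   `orientation`, `overlap_len`, `identical_span`, `seq_id`, `species`)
#'   and `clusters` (data.frame: `seq_id`, `member_count`, list column
#'   `members`).
#' @export
find_overlaps <- function(genes) {
  stopifnot(inherits(genes, "gene_table"))
  if (anyDuplicated(genes$gene_id))
    abort("duplicate gene ids in input")
  n <- nrow(genes)
  species <- attr(genes, "species")
  empty_pairs <- data.frame(
    gene_a = character(0), gene_b = character(0), category = character(0),
    host = character(0), embedded = character(0), orientation = character(0),
    overlap_len = integer(0), identical_span = logical(0),
    seq_id = character(0), species = character(0),
    stringsAsFactors = FALSE)
  empty_clusters <- data.frame(seq_id = character(0),
                               member_count = integer(0))
  empty_clusters$members <- list()
  if (n < 2L)
    return(structure(list(pairs = empty_pairs, clusters = empty_clusters,
                          species = species), class = "overlap_result"))
  gr <- GenomicRanges::GRanges(genes$seq_id,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                      drop.self = TRUE,
                                      drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi))
    return(structure(list(pairs = empty_pairs, clusters = empty_clusters,
                          species = species), class = "overlap_result"))
  comp <- connected_components(n, qi, si)
  sizes <- tabulate(comp, nbins = max(comp))
  pair_edges <- which(sizes[comp[qi]] == 2L)
  pairs <- if (length(pair_edges)) {
    ia <- qi[pair_edges]; ib <- si[pair_edges]
    classify_pairs(genes, ia, ib, species)
  } else empty_pairs
  big <- which(sizes >= 3L)
  clusters <- if (length(big)) {
    rows <- lapply(big, function(cc) {
      members <- sort(genes$gene_id[comp == cc])
      data.frame(seq_id = genes$seq_id[which(comp == cc)[1L]],
                 member_count = length(members), stringsAsFactors = FALSE)
    })
    cl <- do.call(rbind, rows)
    cl$members <- lapply(big, function(cc) sort(genes$gene_id[comp == cc]))
    ord <- order(cl$seq_id, vapply(cl$members, `[`, character(1), 1L))
    cl <- cl[ord, , drop = FALSE]
    rownames(cl) <- NULL
    cl
  } else empty_clusters
  structure(list(pairs = pairs, clusters = clusters, species = species),
            class = "overlap_result")
}

# union-find over edge list
connected_components <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

classify_pairs <- function(genes, ia, ib, species) {
  # order members lexicographically for deterministic output
  swap <- genes$gene_id[ia] > genes$gene_id[ib]
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  sa <- genes$start[ia]; ea <- genes$end[ia]
  sb <- genes$start[ib]; eb <- genes$end[ib]
  a_contains_b <- sa <= sb & ea >= eb
  b_contains_a <- sb <= sa & eb >= ea
  identical_span <- a_contains_b & b_contains_a
  category <- ifelse(a_contains_b | b_contains_a, "EH", "PO")
  host <- ifelse(category == "EH",
                 ifelse(identical_span | a_contains_b,
                        genes$gene_id[ia], genes$gene_id[ib]),
                 NA_character_)
  embedded <- ifelse(category == "EH",
                     ifelse(identical_span | a_contains_b,
                            genes$gene_id[ib], genes$gene_id[ia]),
                     NA_character_)
  out <- data.frame(
    gene_a = genes$gene_id[ia], gene_b = genes$gene_id[ib],
    category = category, host = host, embedded = embedded,
    orientation = ifelse(genes$strand[ia] == genes$strand[ib],
                         "same", "opposite"),
    overlap_len = pmin(ea, eb) - pmax(sa, sb) + 1L,
    identical_span = identical_span,
    seq_id = genes$seq_id[ia], species = species,
    stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> species '%s': %d pairs (%d EH, %d PO), %d clusters\n",
              x$species %||% "unknown", nrow(x$pairs),
              sum(x$pairs$category == "EH"), sum(x$pairs$category == "PO"),
              nrow(x$clusters)))
  invisible(x)
}

#' Relative orientation of an overlapping pair
#'
#' @param pair one row of an overlap pair data.frame (or any list with
#'   `gene_a`, `gene_b`).
#' @param genes the [gene_table()] the pair came from.
#' @return "same" if the two strands are equal, else "opposite".
#' @export
classify_orientation <- function(pair, genes) {
  st <- genes$strand[match(c(pair$gene_a, pair$gene_b), genes$gene_id)]
  if (anyNA(st)) abort("pair member not found in gene table")
  if (st[1L] == st[2L]) "same" else "opposite"
}

#' Is an embedded gene fully inside one host intron?
#'
#' TRUE iff the embedded gene's whole span lies strictly inside the gap
#' between two consecutive host exons (exon bases excluded).  A single-exon
#' host has no introns and yields FALSE, never an error.
#'
#' @param pair an `EH` pair row (needs `host`, `embedded`).
#' @param genes the [gene_table()] with exon annotation for the host.
#' @return logical scalar.
#' @export
embedded_in_intron <- function(pair, genes) {
  if (!identical(pair$category, "EH"))
    abort("embedded_in_intron is defined for EH pairs only")
  hi <- match(pair$host, genes$gene_id)
  ei <- match(pair$embedded, genes$gene_id)
  if (is.na(hi) || is.na(ei)) abort("pair member not found in gene table")
  ex <- genes$exons[[hi]]
  if (nrow(ex) < 2L) return(FALSE)
  gs <- ex[-nrow(ex), 2L] + 1L   # intron starts
  ge <- ex[-1L, 1L] - 1L         # intron ends
  es <- genes$start[ei]; ee <- genes$end[ei]
  any(gs <= es & ee <= ge & gs <= ge)
}

#' Annotate EH pairs with intron embedding
#'
#' Vectorised convenience wrapper adding an `embedded_in_intron` column
#' (NA for PO pairs).
#'
#' @param pairs pair data.frame from [find_overlaps()].
#' @param genes the matching [gene_table()].
#' @return `pairs` with the extra logical column.
#' @export
annotate_intron_embedding <- function(pairs, genes) {
  flag <- rep(NA, nrow(pairs))
  for (i in which(pairs$category == "EH"))
    flag[i] <- embedded_in_intron(pairs[i, , drop = FALSE], genes)
  pairs$embedded_in_intron <- flag
  pairs
}

#' Write overlap pairs / clusters as TSV
#'
#' @param res an `overlap_result`.
#' @param pairs_path,clusters_path output files (NULL to skip one).
#' @export
write_overlap_result <- function(res, pairs_path = NULL,
                                 clusters_path = NULL) {
  if (!is.null(pairs_path)) {
    df <- res$pairs
    df <- df[, c("species", "gene_a", "gene_b", "category", "host",
                 "orientation", "overlap_len", "seq_id", "identical_span",
                 intersect("embedded_in_intron", names(df)))]
    write.table(df, pairs_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(clusters_path)) {
    cl <- data.frame(seq_id = res$clusters$seq_id,
                     member_count = res$clusters$member_count,
                     members = vapply(res$clusters$members, paste,
                                      character(1), collapse = ","))
    write.table(cl, clusters_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(res)
}
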