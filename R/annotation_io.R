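# Input/output for all external formats.  Internal coordinates are 1-based
# inclusive (GFF3 convention); BED is converted at the boundary.

# ---- gene tables -----------------------------------------------------------

#' Construct and validate a gene table
#'
#' The central annotation container: one row per gene with its genomic span,
#' strand and (merged, non-overlapping) exon structure.  Intron count is
#' always derived as `exons - 1`, never stored.
#'
#' @param df data.frame with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` and a list column `exons` of two-column integer matrices
#'   (columns `start`, `end`).  A missing `exons` column is filled with a
#'   single exon spanning the gene.
#' @param species species label attached to the table.
#' @param validate run invariant checks (default TRUE).
#' @return a `gene_table` (data.frame subclass) with a `species` attribute.
#' @export
gene_table <- function(df, species = "unknown", validate = TRUE) {
  need <- c("gene_id", "seq_id", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("gene table missing column(s): ", paste(miss, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$seq_id <- as.character(df$seq_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- as.character(df$strand)
  if (is.null(df$exons))
    df$exons <- mapply(function(s, e) cbind(start = s, end = e),
                       df$start, df$end, SIMPLIFY = FALSE)
  df$exons <- lapply(df$exons, function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m[order(m[, 1L]), , drop = FALSE]
  })
  rownames(df) <- NULL
  out <- structure(as.data.frame(df, stringsAsFactors = FALSE),
                   class = c("gene_table", "data.frame"),
                   species = species)
  if (validate) validate_gene_table(out)
  out
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("<gene_table> %d genes, species '%s'\n",
              nrow(x), attr(x, "species")))
  show <- as.data.frame(x)[, c("gene_id", "seq_id", "start", "end", "strand")]
  show$n_exons <- n_exons(x)
  print(head(show, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

validate_gene_table <- function(gt) {
  dup <- unique(gt$gene_id[duplicated(gt$gene_id)])
  if (length(dup))
    abort("duplicate gene_id: ", paste(head(dup, 5L), collapse = ", "))
  bad <- which(gt$start > gt$end)
  if (length(bad))
    abort("start > end for gene(s): ",
          paste(head(gt$gene_id[bad], 5L), collapse = ", "))
  if (!all(gt$strand %in% c("+", "-")))
    abort("strand must be '+' or '-' (\".\" is not accepted); offending: ",
          paste(head(gt$gene_id[!gt$strand %in% c("+", "-")], 5L),
                collapse = ", "))
  for (i in seq_len(nrow(gt))) {
    ex <- gt$exons[[i]]
    if (nrow(ex) == 0L)
      abort("gene ", gt$gene_id[i], ": zero exons are rejected")
    if (any(ex[, 1L] > ex[, 2L]))
      abort("gene ", gt$gene_id[i], ": exon with start > end")
    if (ex[1L, 1L] < gt$start[i] || ex[nrow(ex), 2L] > gt$end[i])
      abort("gene ", gt$gene_id[i], ": exon outside gene span")
    if (nrow(ex) > 1L && any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
      abort("gene ", gt$gene_id[i], ": exons overlap or are unsorted")
  }
  invisible(gt)
}

#' Exon and intron counts of a gene table
#'
#' @param gt a [gene_table()].
#' @return integer vector, one entry per gene.
#' @export
n_exons <- function(gt) vapply(gt$exons, nrow, integer(1))

#' @rdname n_exons
#' @export
n_introns <- function(gt) n_exons(gt) - 1L

# ---- readers ---------------------------------------------------------------

#' Read a gene table from GFF3, BED6 or TSV
#'
#' GFF3 `gene` features are paired with their `exon` descendants (walking
#' `Parent` chains through transcripts); exon intervals from multiple
#' isoforms are merged to a non-overlapping union.  BED intervals
#' (0-based, half-open) are converted to 1-based inclusive.  The TSV dialect
#' has header `gene_id, seq_id, start, end, strand, exon_starts, exon_ends`
#' with comma-separated coordinate lists.
#'
#' @param path input file.
#' @param format one of "gff3", "bed", "tsv".
#' @param species species label for the returned table.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, format = c("gff3", "bed", "tsv"),
                            species = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) abort("file not found: ", path)
  switch(format,
         gff3 = read_genes_gff3(path, species),
         bed = read_genes_bed(path, species),
         tsv = read_genes_tsv(path, species))
}

read_genes_gff3 <- function(path, species) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    ln <- which(body)[which(nf != 9L)[1L]]
    abort("GFF3 parse error at line ", ln, ": expected 9 tab-separated ",
          "fields, found ", nf[which(nf != 9L)[1L]])
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  id <- as.character(g$ID)
  parent <- vapply(seq_len(nrow(g)), function(i) {
    p <- g$Parent[[i]]
    if (length(p)) as.character(p[1L]) else NA_character_
  }, character(1))
  type <- as.character(g$type)
  is_gene <- type == "gene"
  if (!any(is_gene)) abort("no 'gene' features in ", path)
  gene_of <- setNames(rep(NA_character_, nrow(g)), id)
  # resolve each feature to its ancestral gene ID (chain depth <= 5)
  anc <- parent
  gene_of[is_gene] <- id[is_gene]
  idx <- match(anc, id)
  for (d in 1:5) {
    unresolved <- is.na(gene_of) & !is.na(idx)
    if (!any(unresolved)) break
    gene_of[unresolved] <- gene_of[idx[unresolved]]
    idx[unresolved] <- match(anc[idx[unresolved]], id)
  }
  genes <- g[is_gene, , drop = FALSE]
  gid <- id[is_gene]
  if (anyNA(gid)) abort("GFF3 gene feature without ID attribute")
  ex <- g[type == "exon", , drop = FALSE]
  ex_gene <- gene_of[match(parent[type == "exon"], names(gene_of))]
  # exon whose Parent is the gene itself
  direct <- is.na(ex_gene) & parent[type == "exon"] %in% gid
  ex_gene[direct] <- parent[type == "exon"][direct]
  exon_list <- lapply(gid, function(gg) {
    sel <- which(ex_gene == gg)
    if (!length(sel)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(ex$start[sel], ex$end[sel]))
    cbind(start = IRanges::start(ir), end = IRanges::end(ir))
  })
  none <- vapply(exon_list, is.null, logical(1))
  exon_list[none] <- mapply(function(s, e) cbind(start = s, end = e),
                            genes$start[none], genes$end[none],
                            SIMPLIFY = FALSE)
  gene_table(data.frame(gene_id = gid,
                        seq_id = as.character(genes$seqid),
                        start = genes$start, end = genes$end,
                        strand = as.character(genes$strand),
                        stringsAsFactors = FALSE) |>
               transform(exons = I(exon_list)),
             species = species)
}

read_genes_bed <- function(path, species) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("empty BED file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    abort("BED parse error at line ", which(nf < 6L)[1L],
          ": expected >= 6 fields")
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start0) || anyNA(end0))
    abort("BED parse error at line ",
          which(is.na(start0) | is.na(end0))[1L], ": non-integer coordinate")
  gene_table(data.frame(gene_id = m[, 4L], seq_id = m[, 1L],
                        start = start0 + 1L, end = end0,
                        strand = m[, 6L], stringsAsFactors = FALSE),
             species = species)
}

read_genes_tsv <- function(path, species) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "seq_id", "start", "end", "strand",
            "exon_starts", "exon_ends")
  if (!identical(intersect(need, names(df)), need))
    abort("gene TSV must have header: ", paste(need, collapse = ", "))
  parse_list <- function(s, line) {
    v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
    if (!length(v) || anyNA(v))
      abort("TSV parse error at line ", line, ": bad coordinate list '",
            s, "'")
    v
  }
  exon_list <- lapply(seq_len(nrow(df)), function(i) {
    s <- parse_list(df$exon_starts[i], i + 1L)
    e <- parse_list(df$exon_ends[i], i + 1L)
    if (length(s) != length(e))
      abort("TSV parse error at line ", i + 1L,
            ": exon_starts/exon_ends length mismatch")
    cbind(start = s, end = e)
  })
  gene_table(data.frame(gene_id = df$gene_id, seq_id = df$seq_id,
                        start = as.integer(df$start),
                        end = as.integer(df$end),
                        strand = df$strand, stringsAsFactors = FALSE) |>
               transform(exons = I(exon_list)),
             species = species)
}

#' Write a gene table
#'
#' `tsv` is lossless; `gff3` writes gene + exon features with ID/Parent
#' attributes; `bed` writes BED6 (exon structure is not representable and is
#' dropped).
#'
#' @param gt a [gene_table()].
#' @param path output file.
#' @param format "tsv", "gff3" or "bed".
#' @export
write_gene_table <- function(gt, path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(
      gene_id = gt$gene_id, seq_id = gt$seq_id, start = gt$start,
      end = gt$end, strand = gt$strand,
      exon_starts = vapply(gt$exons, function(m)
        paste(m[, 1L], collapse = ","), character(1)),
      exon_ends = vapply(gt$exons, function(m)
        paste(m[, 2L], collapse = ","), character(1)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "gff3") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (i in seq_len(nrow(gt))) {
      writeLines(sprintf("%s\tgenoverlap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         gt$seq_id[i], gt$start[i], gt$end[i],
                         gt$strand[i], gt$gene_id[i]), con)
      ex <- gt$exons[[i]]
      writeLines(sprintf(
        "%s\tgenoverlap\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        gt$seq_id[i], ex[, 1L], ex[, 2L], gt$strand[i],
        gt$gene_id[i], seq_len(nrow(ex)), gt$gene_id[i]), con)
    }
  } else {
    df <- data.frame(gt$seq_id, gt$start - 1L, gt$end, gt$gene_id, 0L,
                     gt$strand)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

# ---- ortholog maps ---------------------------------------------------------

#' Read a strictly one-to-one ortholog map
#'
#' Two-column TSV of gene identifiers (a header line `gene_a<TAB>gene_b` is
#' accepted and skipped).  Any identifier occurring more than once on either
#' side violates the one-to-one invariant and aborts with a report of the
#' offending ids.
#'
#' @param path input file.
#' @param species_a,species_b species labels for the two columns.
#' @return an `ortholog_map`: data.frame with columns `gene_a`, `gene_b` and
#'   species attributes.
#' @export
read_ortholog_map <- function(path, species_a, species_b) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty ortholog map: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    abort("ortholog map parse error at line ",
          which(lengths(fields) < 2L)[1L], ": expected two columns")
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  if (identical(tolower(a[1L]), "gene_a")) {
    a <- a[-1L]; b <- b[-1L]
  }
  if (!length(a)) abort("empty ortholog map: ", path)
  ortholog_map(data.frame(gene_a = a, gene_b = b,
                          stringsAsFactors = FALSE),
               species_a, species_b)
}

#' @rdname read_ortholog_map
#' @param df data.frame with columns `gene_a`, `gene_b`.
#' @export
ortholog_map <- function(df, species_a, species_b) {
  dup_a <- unique(df$gene_a[duplicated(df$gene_a)])
  dup_b <- unique(df$gene_b[duplicated(df$gene_b)])
  if (length(dup_a) || length(dup_b))
    abort("ortholog map is not one-to-one; duplicated ids: ",
          paste(head(c(dup_a, dup_b), 10L), collapse = ", "))
  structure(data.frame(gene_a = as.character(df$gene_a),
                       gene_b = as.character(df$gene_b),
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"),
            species_a = species_a, species_b = species_b)
}

#' Look up orthologs in a one-to-one map
#'
#' @param map an [ortholog_map()].
#' @param ids gene ids in the `from` species.
#' @param from "a" (default) or "b": which side `ids` belong to.
#' @return character vector of mapped ids, NA where absent.
#' @export
ortho_lookup <- function(map, ids, from = c("a", "b")) {
  from <- match.arg(from)
  if (from == "a") map$gene_b[match(ids, map$gene_a)]
  else map$gene_a[match(ids, map$gene_b)]
}

#' Write an ortholog map as two-column TSV
#' @param map an [ortholog_map()].
#' @param path output file.
#' @export
write_ortholog_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# ---- trees -----------------------------------------------------------------

#' Read a rooted phylogeny from newick
#'
#' Branch lengths are required unless `default_branch_length` supplies one
#' explicitly.  Polytomies (including a basal trifurcation of an unrooted
#' tree) are resolved into a rooted binary topology with zero-length
#' branches; the tree is then flagged with attribute `resolved_polytomies`.
#'
#' @param path newick file.
#' @param default_branch_length value used where lengths are missing; NULL
#'   (default) makes missing lengths an error.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, default_branch_length = NULL) {
  if (!file.exists(path)) abort("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("could not parse newick in ", path)
  if (anyDuplicated(tr$tip.label))
    abort("duplicate leaf labels: ",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                collapse = ", "))
  if (is.null(tr$edge.length)) {
    if (is.null(default_branch_length))
      abort("newick has no branch lengths; pass default_branch_length to ",
            "substitute one")
    tr$edge.length <- rep(as.numeric(default_branch_length), nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (is.null(default_branch_length))
      abort("newick has missing branch lengths")
    tr$edge.length[is.na(tr$edge.length)] <-
      as.numeric(default_branch_length)
  }
  if (any(tr$edge.length < 0)) abort("negative branch length in ", path)
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    tr <- ape::multi2di(tr, random = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
    attr(tr, "resolved_polytomies") <- TRUE
  }
  tr
}

# ---- sequences, expression, dS/dN -----------------------------------------

#' Read/write FASTA as a named character vector of upper-case sequences
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' TSV with a `gene_id` column followed by one numeric column per condition.
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    abort("expression table must have a gene_id column")
  if (ncol(df) < 2L) abort("expression table has no condition columns")
  for (j in 2:ncol(df)) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Read a per-pair dS/dN table
#'
#' Columns: `pair_id`, `species`, `gene1_dS`, `gene1_dN`, `gene2_dS`,
#' `gene2_dN`, `overlap_status` (0/1).  Rates must be non-negative; the
#' outcome strictly binary.
#'
#' @param path input file.
#' @return data.frame of class `dnds_table`.
#' @export
read_dnds_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  dnds_table(df)
}

#' @rdname read_dnds_table
#' @param df data.frame with the dS/dN columns.
#' @export
dnds_table <- function(df) {
  need <- c("pair_id", "species", "gene1_dS", "gene1_dN", "gene2_dS",
            "gene2_dN", "overlap_status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort("dS/dN table missing column(s): ", paste(miss, collapse = ", "))
  rates <- c("gene1_dS", "gene1_dN", "gene2_dS", "gene2_dN")
  for (cc in rates) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]])) || any(df[[cc]] < 0))
      abort("column ", cc, " must be finite and >= 0")
  }
  if (!all(df$overlap_status %in% c(0, 1)))
    abort("overlap_status must be 0/1")
  df$overlap_status <- as.integer(df$overlap_status)
  structure(df, class = c("dnds_table", "data.frame"))
}
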