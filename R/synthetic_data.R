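# Synthetic inputs with known ground truth.  Every generator is
# deterministic under a fixed seed, emits its truth table, and produces
# output that satisfies the gene-table invariants (validated on emission).
#
# The default world is calibrated to the biology the pipeline targets:
# roughly 10% of genes in overlapping pairs, a 0.4/0.6 split of nested vs
# partially overlapping pairs, 87% of embedded genes inside host introns,
# and 70% of pairs in opposite orientation.

#' Parameters for the toy-genome generator
#'
#' @param n_genes total genes to place (>= 2).
#' @param n_seqids number of chromosomes/supercontigs.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene length
#'   parameters (defaults give a median around 1.8 kb).
#' @param frac_overlapping fraction of genes belonging to overlapping
#'   pairs.
#' @param eh_fraction fraction of overlapping pairs that are nested (E/H)
#'   rather than partially overlapping (P/O).
#' @param frac_eh_intronic fraction of embedded genes placed wholly inside
#'   a host intron (default 0.87).
#' @param frac_opposite fraction of pairs in opposite orientation
#'   (default 0.7).
#' @param exon_rate Poisson rate for extra exons (exon count = 1 +
#'   Poisson(exon_rate)).
#' @param n_clusters number of 3-gene overlapping clusters to add
#'   (default 0).
#' @param seed integer seed.
#' @return list of class `genome_sim_params`.
#' @export
genome_sim_params <- function(n_genes = 500L, n_seqids = 3L,
                              gene_length_meanlog = 7.5,
                              gene_length_sdlog = 0.8,
                              frac_overlapping = 0.1,
                              eh_fraction = 0.4,
                              frac_eh_intronic = 0.87,
                              frac_opposite = 0.7,
                              exon_rate = 3,
                              n_clusters = 0L,
                              seed = NULL) {
  fr <- c(frac_overlapping, eh_fraction, frac_eh_intronic, frac_opposite)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (n_genes < 2L) abort("n_genes must be >= 2")
  structure(as.list(environment()), class = "genome_sim_params")
}

# exon matrix (relative coordinates 1..len) for a gene of given length
sim_exons <- function(len, n_ex, min_exon = 10L, min_intron = 30L) {
  n_ex <- max(1L, n_ex)
  while (n_ex > 1L &&
         len < n_ex * min_exon + (n_ex - 1L) * min_intron) n_ex <- n_ex - 1L
  if (n_ex == 1L) return(cbind(start = 1L, end = as.integer(len)))
  parts <- 2L * n_ex - 1L
  mins <- ifelse(seq_len(parts) %% 2L == 1L, min_exon, min_intron)
  rem <- len - sum(mins)
  w <- rexp(parts)
  add <- floor(rem * w / sum(w))
  add[parts] <- add[parts] + (rem - sum(add))
  seglen <- mins + add
  ends <- cumsum(seglen)
  starts <- c(1L, head(ends, -1L) + 1L)
  idx <- seq(1L, parts, by = 2L)
  cbind(start = as.integer(starts[idx]), end = as.integer(ends[idx]))
}

rand_len <- function(p, scale = 1) {
  max(80L, as.integer(round(rlnorm(1, p$gene_length_meanlog,
                                   p$gene_length_sdlog) * scale)))
}

rand_exn <- function(p) 1L + rpois(1L, p$exon_rate)

rand_strands <- function(opposite) {
  s1 <- sample(c("+", "-"), 1L)
  c(s1, if (opposite) setdiff(c("+", "-"), s1) else s1)
}

# block specs ---------------------------------------------------------------
# a block is a self-contained group of genes with relative coordinates;
# blocks are later laid out with gaps, so no accidental overlap can arise

spec_single <- function(id, p) {
  len <- rand_len(p)
  list(kind = "single", ids = id, lens = len,
       exons = list(sim_exons(len, rand_exn(p))),
       strands = sample(c("+", "-"), 1L))
}

spec_eh_pair <- function(id_host, id_emb, p, in_intron) {
  emb_len <- rand_len(p, scale = 0.25)
  pad <- 10L
  if (in_intron) {
    n_ex <- max(2L, rand_exn(p))
    ex_lens <- as.integer(20L + round(runif(n_ex, 0, 380)))
    in_lens <- as.integer(40L + round(runif(n_ex - 1L, 0, 360)))
    in_lens[1L] <- emb_len + 2L * pad
    seglen <- integer(2L * n_ex - 1L)
    seglen[seq(1L, by = 2L, length.out = n_ex)] <- ex_lens
    seglen[seq(2L, by = 2L, length.out = n_ex - 1L)] <- in_lens
    ends <- cumsum(seglen)
    starts <- c(1L, head(ends, -1L) + 1L)
    ex <- cbind(start = starts[seq(1L, by = 2L, length.out = n_ex)],
                end = ends[seq(1L, by = 2L, length.out = n_ex)])
    host_len <- ends[length(ends)]
    emb_start <- ex[1L, 2L] + pad + 1L
  } else {
    host_len <- max(rand_len(p), emb_len + 40L)
    ex <- sim_exons(host_len, rand_exn(p))
    emb_start <- 2L  # overlaps the first exon's bases
  }
  emb_ex <- sim_exons(emb_len, min(rand_exn(p), 2L))
  list(kind = "eh", ids = c(id_host, id_emb),
       lens = c(host_len, emb_len),
       exons = list(ex, emb_ex),
       offsets = c(1L, emb_start),
       strands = rand_strands(runif(1) < p$frac_opposite),
       in_intron = in_intron)
}

spec_po_pair <- function(id1, id2, p) {
  l1 <- rand_len(p); l2 <- rand_len(p)
  ov <- sample.int(min(l1, l2) - 1L, 1L)
  list(kind = "po", ids = c(id1, id2), lens = c(l1, l2),
       exons = list(sim_exons(l1, rand_exn(p)), sim_exons(l2, rand_exn(p))),
       offsets = c(1L, l1 - ov + 1L), ov = ov,
       strands = rand_strands(runif(1) < p$frac_opposite))
}

spec_cluster <- function(ids, p) {
  l <- vapply(seq_along(ids), function(i) rand_len(p), integer(1))
  # chain: gene i starts inside gene i-1's span (halfway), guaranteeing a
  # single connected component whatever the individual lengths are
  off <- 1L + c(0L, cumsum(head(pmax(l %/% 2L, 1L), -1L)))
  list(kind = "cluster", ids = ids, lens = l,
       exons = lapply(l, function(x) sim_exons(x, rand_exn(p))),
       offsets = off,
       strands = sample(c("+", "-"), length(ids), replace = TRUE))
}

# lay blocks out on seqids with generous gaps; returns a gene_table
layout_blocks <- function(blocks, n_seqids, species) {
  ord <- sample(seq_along(blocks))
  cursor <- setNames(as.integer(round(runif(n_seqids, 1000, 5000))),
                     paste0("ctg", seq_len(n_seqids)))
  rows <- vector("list", length(blocks) * 3L)
  nrow_used <- 0L
  for (b in blocks[ord]) {
    sq <- sample(names(cursor), 1L)
    base <- cursor[[sq]]
    offs <- b$offsets %||% rep(1L, length(b$ids))
    for (i in seq_along(b$ids)) {
      s <- base + offs[i] - 1L
      ex <- b$exons[[i]]
      nrow_used <- nrow_used + 1L
      rows[[nrow_used]] <- list(gene_id = b$ids[i], seq_id = sq,
                                start = s, end = s + b$lens[i] - 1L,
                                strand = b$strands[i],
                                exons = cbind(start = ex[, 1L] + s - 1L,
                                              end = ex[, 2L] + s - 1L))
    }
    block_end <- max(base + offs + b$lens - 1L)
    cursor[[sq]] <- block_end + as.integer(round(runif(1, 500, 3000)))
  }
  rows <- rows[seq_len(nrow_used)]
  df <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    seq_id = vapply(rows, `[[`, character(1), "seq_id"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    strand = vapply(rows, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  df$exons <- lapply(rows, `[[`, "exons")
  df <- df[order(df$seq_id, df$start, df$gene_id), , drop = FALSE]
  gene_table(df, species = species)
}

blocks_truth <- function(blocks) {
  pr <- list(); cl <- list()
  for (b in blocks) {
    if (b$kind == "eh") {
      g <- sort(b$ids)
      pr[[length(pr) + 1L]] <- data.frame(
        gene_a = g[1L], gene_b = g[2L], category = "EH",
        host = b$ids[1L], embedded = b$ids[2L],
        orientation = if (b$strands[1L] == b$strands[2L]) "same"
                      else "opposite",
        overlap_len = b$lens[2L], in_intron = b$in_intron,
        stringsAsFactors = FALSE)
    } else if (b$kind == "po") {
      g <- sort(b$ids)
      pr[[length(pr) + 1L]] <- data.frame(
        gene_a = g[1L], gene_b = g[2L], category = "PO",
        host = NA_character_, embedded = NA_character_,
        orientation = if (b$strands[1L] == b$strands[2L]) "same"
                      else "opposite",
        overlap_len = b$ov, in_intron = NA, stringsAsFactors = FALSE)
    } else if (b$kind == "cluster") {
      cl[[length(cl) + 1L]] <- data.frame(
        members = paste(sort(b$ids), collapse = ","),
        member_count = length(b$ids), stringsAsFactors = FALSE)
    }
  }
  list(pairs = if (length(pr)) do.call(rbind, pr) else
         data.frame(gene_a = character(0), gene_b = character(0),
                    category = character(0), host = character(0),
                    embedded = character(0), orientation = character(0),
                    overlap_len = integer(0), in_intron = logical(0)),
       clusters = if (length(cl)) do.call(rbind, cl) else
         data.frame(members = character(0), member_count = integer(0)))
}

#' Generate a toy annotated genome with controlled overlap structure
#'
#' Overlapping pairs and clusters are constructed explicitly (each nested
#' pair by inserting an embedded gene inside a host intron or exon span,
#' each partial overlap by staggered placement) and blocks are separated
#' by gaps, so the emitted truth table lists exactly the intended overlap
#' graph.
#'
#' @param params a [genome_sim_params()].
#' @param species species label.
#' @return list: `genes` (a [gene_table()]), `truth` (list `pairs`,
#'   `clusters`), `params`.
#' @export
generate_genome <- function(params = genome_sim_params(),
                            species = "synthetic") {
  p <- params
  with_seed(p$seed, {
    n_pair_genes <- round(p$n_genes * p$frac_overlapping / 2) * 2
    n_pairs <- n_pair_genes / 2
    n_eh <- round(n_pairs * p$eh_fraction)
    n_po <- n_pairs - n_eh
    n_cluster_genes <- p$n_clusters * 3L
    n_single <- p$n_genes - n_pair_genes - n_cluster_genes
    if (n_single < 0) abort("n_genes too small for requested pairs/clusters")
    if (n_eh > 0 && p$frac_eh_intronic > 0 && p$exon_rate == 0)
      abort("intron embedding requested but exon_rate forces single exons")
    next_id <- 0L
    nid <- function() {
      next_id <<- next_id + 1L
      pad_id("g", next_id)
    }
    blocks <- list()
    for (i in seq_len(n_eh))
      blocks[[length(blocks) + 1L]] <-
        spec_eh_pair(nid(), nid(), p, runif(1) < p$frac_eh_intronic)
    for (i in seq_len(n_po))
      blocks[[length(blocks) + 1L]] <- spec_po_pair(nid(), nid(), p)
    for (i in seq_len(p$n_clusters))
      blocks[[length(blocks) + 1L]] <-
        spec_cluster(c(nid(), nid(), nid()), p)
    for (i in seq_len(n_single))
      blocks[[length(blocks) + 1L]] <- spec_single(nid(), p)
    genes <- layout_blocks(blocks, p$n_seqids, species)
    truth <- blocks_truth(blocks)
    list(genes = genes, truth = truth, params = p, blocks = blocks)
  })
}

#' Parameters for the multi-species family generator
#'
#' @param tree rooted `phylo` species tree with branch lengths.
#' @param base_params [genome_sim_params()] for the ancestral genome.
#' @param p_rearrange per-branch baseline probability that a still
#'   overlapping pair rearranges on that branch.
#' @param birth_pairs,birth_singles young overlapping pairs / singleton
#'   genes born on each branch.
#' @param b_intron,b_ssr log-odds effects linking a pair's intron-count
#'   and SSR-content covariates (standardised) to its per-branch
#'   rearrangement probability.
#' @param seed integer seed.
#' @return list of class `family_sim_params`.
#' @export
family_sim_params <- function(tree, base_params = genome_sim_params(),
                              p_rearrange = 0.15, birth_pairs = 2L,
                              birth_singles = 3L, b_intron = 0,
                              b_ssr = 0, seed = NULL) {
  if (p_rearrange < 0 || p_rearrange > 1)
    abort("p_rearrange must lie in [0, 1]")
  structure(as.list(environment()), class = "family_sim_params")
}

#' Evolve a base genome along a species tree
#'
#' Each ancestral overlapping pair independently retains or loses its
#' overlap on every branch; the rearrangement probability is a logit-linear
#' function of the pair's intron and SSR covariates.  Young genes (pairs
#' and singletons) are born per branch and exist only in that branch's
#' descendants.  Rearrangement is realised as relocation: the two genes of
#' a rearranged pair are laid out as separate non-overlapping blocks.
#'
#' @param params a [family_sim_params()].
#' @return list: `genomes` (named list of [gene_table()]s), `maps` (named
#'   list of [ortholog_map()]s keyed "A|B" for every species pair), and
#'   `truth` (`pair_status` data.frame pair x species codes, `covariates`,
#'   `base` truth).
#' @export
generate_family <- function(params) {
  p <- params
  tree <- p$tree
  if (is.null(tree$edge.length)) abort("species tree needs branch lengths")
  with_seed(p$seed, {
    base <- generate_genome(p$base_params, species = "ancestor")
    tpairs <- base$truth$pairs
    n_anc_pairs <- nrow(tpairs)
    gt <- base$genes
    exn <- setNames(n_exons(gt), gt$gene_id)
    intron_total <- exn[tpairs$gene_a] + exn[tpairs$gene_b] - 2L
    z_int <- if (n_anc_pairs > 1 && sd(intron_total) > 0)
      as.numeric(scale(intron_total)) else rep(0, n_anc_pairs)
    z_ssr <- rnorm(n_anc_pairs)
    p_pair <- plogis(qlogis(max(min(p$p_rearrange, 1 - 1e-9), 1e-9)) +
                       p$b_intron * z_int + p$b_ssr * z_ssr)

    ntip <- length(tree$tip.label)
    edge <- tree$edge
    # preorder edge traversal
    tr <- ape::reorder.phylo(tree, "postorder")
    pre <- rev(seq_len(nrow(tr$edge)))
    root <- tr$edge[nrow(tr$edge), 1L]
    nnode <- ntip + tr$Nnode
    # per node: logical vector of pair overlap status + born genes
    status <- vector("list", nnode)
    born <- vector("list", nnode)       # list of young block specs per node
    status[[root]] <- rep(TRUE, n_anc_pairs)
    born[[root]] <- list()
    young_id <- 0L
    yid <- function() {
      young_id <<- young_id + 1L
      pad_id("y", young_id)
    }
    bp <- p$base_params
    for (e in pre) {
      par <- tr$edge[e, 1L]; chd <- tr$edge[e, 2L]
      st <- status[[par]]
      hit <- st & (runif(n_anc_pairs) < p_pair)
      status[[chd]] <- st & !hit
      newborn <- list()
      for (i in seq_len(p$birth_pairs)) {
        newborn[[length(newborn) + 1L]] <- if (runif(1) < bp$eh_fraction)
          spec_eh_pair(yid(), yid(), bp, runif(1) < bp$frac_eh_intronic)
        else spec_po_pair(yid(), yid(), bp)
      }
      for (i in seq_len(p$birth_singles))
        newborn[[length(newborn) + 1L]] <- spec_single(yid(), bp)
      born[[chd]] <- c(born[[par]], newborn)
    }

    # reuse the ancestral block structure so lengths and exon counts (and
    # therefore the intron covariate) are identical in every species
    kinds <- vapply(base$blocks, `[[`, character(1), "kind")
    anc_pair_specs <- base$blocks[kinds %in% c("eh", "po")]
    anc_other_specs <- base$blocks[!kinds %in% c("eh", "po")]
    stopifnot(length(anc_pair_specs) == n_anc_pairs)

    genomes <- list()
    pair_status <- matrix(NA, n_anc_pairs, ntip,
                          dimnames = list(
                            paste(tpairs$gene_a, tpairs$gene_b, sep = "|"),
                            tr$tip.label))
    for (t in seq_len(ntip)) {
      sp <- tr$tip.label[t]
      blocks <- list()
      for (i in seq_len(n_anc_pairs)) {
        spc <- anc_pair_specs[[i]]
        if (status[[t]][i]) {
          blocks[[length(blocks) + 1L]] <- spc
          pair_status[i, t] <- tpairs$category[i]
        } else {
          # relocation: the pair's genes become separate blocks
          for (g in seq_along(spc$ids))
            blocks[[length(blocks) + 1L]] <-
              list(kind = "single", ids = spc$ids[g], lens = spc$lens[g],
                   exons = spc$exons[g], strands = spc$strands[g])
          pair_status[i, t] <- "NOV"
        }
      }
      blocks <- c(blocks, anc_other_specs, born[[t]])
      sp_blocks <- lapply(blocks, function(b) {
        b$ids <- paste(sp, b$ids, sep = "_")
        b
      })
      genomes[[sp]] <- layout_blocks(sp_blocks, bp$n_seqids, sp)
    }

    # one-to-one maps between every ordered species pair (shared ancestry)
    maps <- list()
    tips <- tr$tip.label
    anc_of <- function(sp) sub(paste0("^", sp, "_"), "",
                               genomes[[sp]]$gene_id)
    for (a in seq_len(ntip - 1L)) for (b in (a + 1L):ntip) {
      sa <- tips[a]; sb <- tips[b]
      shared <- intersect(anc_of(sa), anc_of(sb))
      maps[[paste(sa, sb, sep = "|")]] <- ortholog_map(
        data.frame(gene_a = paste(sa, shared, sep = "_"),
                   gene_b = paste(sb, shared, sep = "_"),
                   stringsAsFactors = FALSE), sa, sb)
    }
    list(genomes = genomes, maps = maps,
         truth = list(pair_status = pair_status,
                      covariates = data.frame(
                        pair_id = rownames(pair_status),
                        intron_total = as.integer(intron_total),
                        z_intron = z_int, z_ssr = z_ssr,
                        p_rearrange = p_pair),
                      base = base$truth))
  })
}

#' Implant SSRs into a background sequence
#'
#' Inserts perfect and (with probability 0.3) imperfect tandem repeats at
#' non-overlapping positions until roughly `density` of the sequence is
#' covered.  Imperfect implants carry 1-2 isolated mismatches, never more
#' than 3 consecutive, and always end on a match.
#'
#' @param sequence background DNA string (or an integer length, in which
#'   case a uniform random background is drawn first).
#' @param density target fraction of bases covered by implants.
#' @param motifs candidate motifs (perfect primitives, 1-6 bp).
#' @param seed integer seed.
#' @return list: `sequence` (with implants), `truth` (data.frame `start`,
#'   `end`, `motif`, `n_mismatches`).
#' @export
implant_ssrs <- function(sequence, density = 0.05,
                         motifs = c("A", "AC", "AG", "AAG", "ACT",
                                    "AAAC", "ACGT", "AACGTC"),
                         seed = NULL) {
  with_seed(seed, {
    if (is.numeric(sequence))
      sequence <- paste(sample(c("A", "C", "G", "T"), sequence,
                               replace = TRUE), collapse = "")
    ch <- strsplit(toupper(sequence), "")[[1L]]
    L <- length(ch)
    target <- round(density * L)
    placed <- 0L
    occupied <- rep(FALSE, L)
    truth <- list()
    attempts <- 0L
    while (placed < target && attempts < 200L) {
      attempts <- attempts + 1L
      m <- sample(motifs, 1L)
      k <- nchar(m)
      span <- sample(max(18L, 3L * k):48L, 1L)
      s <- sample.int(max(1L, L - span - 2L), 1L)
      zone <- max(1L, s - 6L):min(L, s + span + 5L)
      if (any(occupied[zone])) next
      mm_ch <- strsplit(m, "")[[1L]]
      rep_ch <- mm_ch[((seq_len(span) - 1L) %% k) + 1L]
      n_mm <- 0L
      if (runif(1) < 0.3 && span > 2L * k + 6L) {
        n_mm <- sample(1:2, 1L)
        pos <- sample((k + 2L):(span - 2L), n_mm)
        while (n_mm == 2L && abs(diff(pos)) < 5L)
          pos <- sample((k + 2L):(span - 2L), n_mm)
        for (pp in pos) {
          alt <- setdiff(c("A", "C", "G", "T"), rep_ch[pp])
          rep_ch[pp] <- sample(alt, 1L)
        }
      }
      ch[s:(s + span - 1L)] <- rep_ch
      occupied[zone] <- TRUE
      placed <- placed + span
      truth[[length(truth) + 1L]] <- data.frame(
        start = s, end = s + span - 1L, motif = canonical_motif(m),
        n_mismatches = n_mm, stringsAsFactors = FALSE)
    }
    list(sequence = paste(ch, collapse = ""),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(start = integer(0), end = integer(0),
                      motif = character(0), n_mismatches = integer(0)))
  })
}

#' Generate expression with orientation-dependent correlation
#'
#' Same-orientation pairs draw their two latent gene levels from a
#' bivariate normal whose Pearson correlation is chosen so the implied
#' Spearman correlation equals `orientation_effect` (Gaussian copula
#' relation \eqn{r = 2\sin(\pi\rho_s/6)}); opposite-orientation pairs are
#' independent.  Condition replicates add small noise around the latent
#' level.
#'
#' @param pairs pair data.frame with `gene_a`, `gene_b`, `orientation`.
#' @param orientation_effect target Spearman correlation of
#'   same-orientation pairs (default 0.8).
#' @param n_conditions number of condition columns (>= 2).
#' @param seed integer seed.
#' @return expression data.frame (`gene_id`, `cond_1`, ...).
#' @export
generate_expression <- function(pairs, orientation_effect = 0.8,
                                n_conditions = 5L, seed = NULL) {
  if (n_conditions < 2L)
    abort("n_conditions must be >= 2: correlation undefined for a single ",
          "condition")
  if (abs(orientation_effect) > 1) abort("effect must lie in [-1, 1]")
  r <- 2 * sin(pi * orientation_effect / 6)
  with_seed(seed, {
    n <- nrow(pairs)
    a <- rnorm(n)
    eps <- rnorm(n)
    b <- ifelse(pairs$orientation == "same",
                r * a + sqrt(1 - r^2) * eps, eps)
    genes <- c(pairs$gene_a, pairs$gene_b)
    latent <- c(a, b)
    vals <- sapply(seq_len(n_conditions), function(j)
      latent + rnorm(length(latent), sd = 0.3))
    colnames(vals) <- paste0("cond_", seq_len(n_conditions))
    cbind(data.frame(gene_id = genes, stringsAsFactors = FALSE),
          as.data.frame(vals))
  })
}

#' Generate a synthetic dS/dN logit dataset
#'
#' dS values are Gamma(2, rate 1) and dN values Gamma(1.5, rate 3) per
#' gene; the overlap outcome is Bernoulli with logit-linear mean
#' `beta[1] + X beta[-1]` over (gene1_dS, gene1_dN, gene2_dS, gene2_dN).
#'
#' @param beta numeric 5-vector: intercept then the four slopes.
#' @param n number of rows.
#' @param seed integer seed.
#' @return a [dnds_table()] with attribute `beta_true`.
#' @export
generate_logit_data <- function(beta = c(-0.3, 0.4, -0.9, 0.5, -1.2),
                                n = 500L, seed = NULL) {
  if (length(beta) != 5L) abort("beta must have length 5")
  with_seed(seed, {
    X <- cbind(gene1_dS = rgamma(n, 2, rate = 1),
               gene1_dN = rgamma(n, 1.5, rate = 3),
               gene2_dS = rgamma(n, 2, rate = 1),
               gene2_dN = rgamma(n, 1.5, rate = 3))
    eta <- beta[1L] + drop(X %*% beta[-1L])
    y <- rbinom(n, 1L, plogis(eta))
    out <- dnds_table(data.frame(pair_id = pad_id("p", seq_len(n)),
                                 species = "synthetic", X,
                                 overlap_status = y,
                                 stringsAsFactors = FALSE))
    attr(out, "beta_true") <- beta
    out
  })
}
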