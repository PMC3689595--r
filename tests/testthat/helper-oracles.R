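# Independent oracles used across the suite.  These deliberately re-derive
# results by brute force / enumeration and never call the code paths they
# check.

# all-vs-all interval intersection oracle: returns the expected pairs and
# clusters exactly as find_overlaps() should report them
oracle_overlaps <- function(gt) {
  n <- nrow(gt)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (gt$seq_id[i] != gt$seq_id[j]) next
    if (min(gt$end[i], gt$end[j]) >= max(gt$start[i], gt$start[j]))
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in edges) {
      m <- min(comp[e]); M <- max(comp[e])
      if (m != M) {
        comp[comp == M] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  pairs <- list()
  clusters <- list()
  for (cc in names(sizes)) {
    idx <- which(comp == as.integer(cc))
    if (length(idx) == 2L) {
      i <- idx[1L]; j <- idx[2L]
      if (gt$gene_id[i] > gt$gene_id[j]) { t <- i; i <- j; j <- t }
      a_in_b <- gt$start[j] <= gt$start[i] && gt$end[j] >= gt$end[i]
      b_in_a <- gt$start[i] <= gt$start[j] && gt$end[i] >= gt$end[j]
      cat_ <- if (a_in_b || b_in_a) "EH" else "PO"
      host <- if (cat_ == "EH") {
        if (b_in_a && a_in_b) gt$gene_id[i]  # identical spans: lexic. smaller
        else if (b_in_a) gt$gene_id[i] else gt$gene_id[j]
      } else NA_character_
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = gt$gene_id[i], gene_b = gt$gene_id[j], category = cat_,
        host = host,
        orientation = if (gt$strand[i] == gt$strand[j]) "same"
                      else "opposite",
        overlap_len = min(gt$end[i], gt$end[j]) -
          max(gt$start[i], gt$start[j]) + 1L,
        stringsAsFactors = FALSE)
    } else if (length(idx) >= 3L) {
      clusters[[length(clusters) + 1L]] <- sort(gt$gene_id[idx])
    }
  }
  pr <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               category = character(0), host = character(0),
               orientation = character(0), overlap_len = integer(0))
  pr <- pr[order(pr$gene_a, pr$gene_b), , drop = FALSE]
  rownames(pr) <- NULL
  list(pairs = pr, clusters = clusters[order(vapply(clusters, `[`,
                                                    character(1), 1L))])
}

# vectorised variant of the brute-force oracle for larger genomes: the
# all-vs-all comparison is done with rep()/logical masks per seq_id, the
# rest (components, classification) reuses the loop oracle's logic
oracle_overlaps_fast <- function(gt) {
  n <- nrow(gt)
  ii <- integer(0); jj <- integer(0)
  for (sq in unique(gt$seq_id)) {
    idx <- which(gt$seq_id == sq)
    m <- length(idx)
    if (m < 2L) next
    a <- rep(idx, times = m)
    b <- rep(idx, each = m)
    keep <- a < b &
      pmin(gt$end[a], gt$end[b]) >= pmax(gt$start[a], gt$start[b])
    ii <- c(ii, a[keep]); jj <- c(jj, b[keep])
  }
  comp <- seq_len(n)
  if (length(ii)) repeat {
    changed <- FALSE
    for (k in seq_along(ii)) {
      m <- min(comp[ii[k]], comp[jj[k]]); M <- max(comp[ii[k]], comp[jj[k]])
      if (m != M) {
        comp[comp == M] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  pairs <- list(); clusters <- list()
  for (cc in names(sizes)[sizes >= 2L]) {
    idx <- which(comp == as.integer(cc))
    if (length(idx) == 2L) {
      i <- idx[1L]; j <- idx[2L]
      if (gt$gene_id[i] > gt$gene_id[j]) { t <- i; i <- j; j <- t }
      a_in_b <- gt$start[j] <= gt$start[i] && gt$end[j] >= gt$end[i]
      b_in_a <- gt$start[i] <= gt$start[j] && gt$end[i] >= gt$end[j]
      cat_ <- if (a_in_b || b_in_a) "EH" else "PO"
      host <- if (cat_ == "EH") {
        if (b_in_a) gt$gene_id[i] else gt$gene_id[j]
      } else NA_character_
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = gt$gene_id[i], gene_b = gt$gene_id[j], category = cat_,
        host = host,
        orientation = if (gt$strand[i] == gt$strand[j]) "same"
                      else "opposite",
        overlap_len = min(gt$end[i], gt$end[j]) -
          max(gt$start[i], gt$start[j]) + 1L,
        stringsAsFactors = FALSE)
    } else {
      clusters[[length(clusters) + 1L]] <- sort(gt$gene_id[idx])
    }
  }
  pr <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               category = character(0), host = character(0),
               orientation = character(0), overlap_len = integer(0))
  pr <- pr[order(pr$gene_a, pr$gene_b), , drop = FALSE]
  rownames(pr) <- NULL
  list(pairs = pr,
       clusters = clusters[order(vapply(clusters, `[`, character(1),
                                        1L))])
}

# exhaustive SSR oracle: enumerate every (motif length, anchor, end) window
# under the scoring rules, then apply the same resolution policy
# (score desc, start asc, motif length asc, greedy non-overlap)
oracle_ssrs <- function(seq, motif_lengths = 1:6, min_score = 15L,
                        penalty = 5L, max_mm_run = 3L) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  L <- length(ch)
  cand <- list()
  primitive <- function(m) {
    k <- length(m)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L))
      if (k %% d == 0L && all(m == m[((seq_len(k) - 1L) %% d) + 1L]))
        return(FALSE)
    TRUE
  }
  for (k in motif_lengths) {
    if (2L * k > L) next
    for (s in seq_len(L - k)) {
      motif <- ch[s:(s + k - 1L)]
      if (!primitive(motif)) next
      mm_run <- 0L
      n_mm <- 0L
      score <- k
      for (e in (s + k):L) {
        if (ch[e] == motif[((e - s) %% k) + 1L]) {
          mm_run <- 0L
          score <- score + 1L
          if (score >= min_score)
            cand[[length(cand) + 1L]] <-
              list(s = s, e = e, k = k, score = score, n_mm = n_mm,
                   motif = paste(motif, collapse = ""))
        } else {
          mm_run <- mm_run + 1L
          if (mm_run > max_mm_run) break
          n_mm <- n_mm + 1L
          score <- score - penalty
        }
      }
    }
  }
  if (!length(cand))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), n_mismatches = integer(0),
                      score = integer(0)))
  df <- do.call(rbind, lapply(cand, function(x)
    data.frame(motif = x$motif, start = x$s, end = x$e,
               n_mismatches = x$n_mm, score = x$score, k = x$k,
               stringsAsFactors = FALSE)))
  df <- df[order(-df$score, df$start, df$k, -df$end), , drop = FALSE]
  taken <- rep(FALSE, L)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    span <- df$start[i]:df$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- df[keep, c("motif", "start", "end", "n_mismatches", "score")]
  out$motif <- canonical_motif(out$motif)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# likelihood by summing over every ancestral state assignment (tiny trees)
oracle_trait_loglik <- function(tree, tip_states, Q, prior) {
  k <- nrow(Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  internal <- (ntip + 1L):(ntip + tr$Nnode)
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    Matrix::expm(Q * tr$edge.length[e]))
  root <- tr$edge[nrow(tr$edge), 1L]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + tr$Nnode)
    st[seq_len(ntip)] <- tip_states
    st[internal] <- grid[g, ]
    lik <- prior[st[root]]
    for (e in seq_len(nrow(tr$edge)))
      lik <- lik * as.matrix(P[[e]])[st[tr$edge[e, 1L]], st[tr$edge[e, 2L]]]
    total <- total + lik
  }
  log(total)
}

# naive average-linkage agglomeration under manhattan distance; returns the
# full cophenetic matrix for comparison
oracle_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m, method = "manhattan"))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  dd <- d
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); bestv <- Inf
    for (a in idx) for (b in idx) {
      if (a < b && dd[a, b] < bestv) {
        bestv <- dd[a, b]; best <- c(a, b)
      }
    }
    a <- best[1L]; b <- best[2L]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- bestv; coph[j, i] <- bestv
    }
    merged <- c(clusters[[a]], clusters[[b]])
    # average linkage: size-weighted mean of the two distances
    for (o in idx) {
      if (o == a || o == b) next
      dd[a, o] <- (length(clusters[[a]]) * dd[a, o] +
                     length(clusters[[b]]) * dd[b, o]) /
        (length(clusters[[a]]) + length(clusters[[b]]))
      dd[o, a] <- dd[a, o]
    }
    clusters[[a]] <- merged
    active[b] <- FALSE
  }
  coph
}

# deterministic random gene table (not via the package generator) used for
# order-invariance and brute-force comparisons
random_gene_table <- function(n, seed, n_seqids = 2L, span = 50000L) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(50:2000, n, replace = TRUE)
  gene_table(data.frame(
    gene_id = sprintf("r%04d", seq_len(n)),
    seq_id = paste0("c", sample.int(n_seqids, n, replace = TRUE)),
    start = start, end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE), species = "rand")
}
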