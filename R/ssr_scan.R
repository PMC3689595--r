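# Microsatellite (SSR) scanner for perfect and imperfect tandem repeats of
# 1-6 bp motifs.  Scoring: matched bases minus a fixed penalty of 5 per
# mismatch; runs containing more than 3 consecutive mismatch positions are
# never part of a hit.  Sequences containing ambiguous bases (N) yield no
# hits and are flagged.

#' Canonical rotation of a motif
#'
#' Lexicographically smallest rotation; with `revcomp = TRUE` the minimum is
#' also taken over rotations of the reverse complement (used to match
#' motifs across strands).
#'
#' @param motif character motif (ACGT).
#' @param revcomp include reverse-complement rotations.
#' @return canonical motif string.
#' @export
canonical_motif <- function(motif, revcomp = FALSE) {
  vapply(motif, function(m) {
    rots <- motif_rotations(m)
    if (revcomp) rots <- c(rots, motif_rotations(revcomp_seq(m)))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

motif_rotations <- function(m) {
  k <- nchar(m)
  ch <- strsplit(m, "")[[1L]]
  vapply(seq_len(k), function(i)
    paste(ch[c(i:k, seq_len(i - 1L))[seq_len(k)]], collapse = ""),
    character(1))
}

#' Reverse complement of a DNA string
#' @param s character string over ACGTN.
#' @return reverse complement string.
#' @export
revcomp_seq <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(s, function(x)
    paste(rev(map[strsplit(x, "")[[1L]]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# TRUE if motif is not a repetition of a shorter motif
is_primitive_motif <- function(ch) {
  k <- length(ch)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && all(ch == ch[((seq_len(k) - 1L) %% d) + 1L]))
      return(FALSE)
  }
  TRUE
}

#' Scan one sequence for perfect and imperfect SSRs
#'
#' For every motif length k and anchor position, the k-mer starting there is
#' taken as the candidate motif and extended rightwards; positions agreeing
#' with the periodic motif count +1, disagreements cost `mismatch_penalty`,
#' and extension stops before a run of more than `max_consecutive_mismatches`
#' mismatch sites.  The maximal-score end (ending on a match; ties resolved
#' to the longest) defines the candidate hit.  Candidates scoring at least
#' `min_score` are resolved greedily: highest score first, then leftmost
#' start, then shortest motif; accepted hits never overlap.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param motif_lengths motif sizes to scan (default 1:6).
#' @param min_score minimum accepted score (default 15).
#' @param mismatch_penalty per-mismatch penalty (fixed default 5).
#' @param max_consecutive_mismatches maximum allowed run of mismatch sites
#'   inside a hit (default 3).
#' @param include_penta keep 5-bp motifs (default TRUE); set FALSE to scan
#'   mono/di/tri/tetra/hexa only.
#' @param seq_id identifier recorded in the output.
#' @return data.frame of hits (`seq_id`, `motif` in canonical rotation,
#'   `start`, `end`, `n_mismatches`, `score`), sorted by start.  If the
#'   sequence contains any ambiguous base the result is empty with
#'   attribute `ambiguous = TRUE`.
#' @export
scan_ssrs <- function(sequence, motif_lengths = 1:6, min_score = 15L,
                      mismatch_penalty = 5L, max_consecutive_mismatches = 3L,
                      include_penta = TRUE, seq_id = "seq1") {
  empty <- data.frame(seq_id = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      n_mismatches = integer(0), score = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  ch <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad))
    abort("invalid characters in sequence: ", paste(bad, collapse = ", "))
  if (any(ch == "N")) {
    attr(empty, "ambiguous") <- TRUE
    return(empty)
  }
  if (!include_penta) motif_lengths <- setdiff(motif_lengths, 5L)
  L <- length(ch)
  cand <- scan_candidates(ch, motif_lengths, min_score, mismatch_penalty,
                          max_consecutive_mismatches)
  if (!nrow(cand)) return(empty)
  # resolve overlaps: best score, then leftmost, then shortest motif,
  # then longest span
  cand <- cand[order(-cand$score, cand$start, cand$k, -cand$end), ,
               drop = FALSE]
  taken <- rep(FALSE, L)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(seq_id = seq_id,
                    motif = canonical_motif(cand$motif),
                    start = cand$start, end = cand$end,
                    n_mismatches = cand$n_mismatches, score = cand$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# enumerate anchored candidates for all motif lengths: every extension end
# that terminates on a match, respects the consecutive-mismatch cap, and
# reaches min_score is a candidate (resolution later keeps the maximal ones)
scan_candidates <- function(ch, motif_lengths, min_score, penalty,
                            max_mm_run) {
  L <- length(ch)
  motif_c <- character(0); k_c <- integer(0); s_c <- integer(0)
  e_c <- integer(0); mm_c <- integer(0); sc_c <- integer(0)
  for (k in sort(motif_lengths)) {
    if (2L * k > L) next
    for (s in seq_len(L - k)) {
      motif <- ch[s:(s + k - 1L)]
      if (!is_primitive_motif(motif)) next
      ext <- extend_repeat(ch, s, motif, penalty, max_mm_run, min_score)
      if (is.null(ext)) next
      nn <- length(ext$end)
      motif_c <- c(motif_c, rep(paste(motif, collapse = ""), nn))
      k_c <- c(k_c, rep(k, nn)); s_c <- c(s_c, rep(s, nn))
      e_c <- c(e_c, ext$end); mm_c <- c(mm_c, ext$n_mismatches)
      sc_c <- c(sc_c, ext$score)
    }
  }
  data.frame(motif = motif_c, k = k_c, start = s_c, end = e_c,
             n_mismatches = mm_c, score = sc_c, stringsAsFactors = FALSE)
}

# rightward extension from anchor s with the given motif; returns every
# candidate end (ending on a match, before any run of > max_mm_run
# consecutive mismatches) whose score reaches min_score
extend_repeat <- function(ch, s, motif, penalty, max_mm_run, min_score) {
  k <- length(motif)
  L <- length(ch)
  first <- s + k
  if (first > L) return(NULL)
  idx <- first:L
  match_v <- ch[idx] == motif[((idx - s) %% k) + 1L]
  if (!any(match_v)) return(NULL)
  # truncate before the first run of > max_mm_run consecutive mismatches
  r <- rle(match_v)
  stop_at <- length(match_v)
  cum <- cumsum(r$lengths)
  too_long <- which(!r$values & r$lengths > max_mm_run)
  if (length(too_long))
    stop_at <- cum[too_long[1L]] - r$lengths[too_long[1L]]
  if (stop_at < 1L) return(NULL)
  match_v <- match_v[seq_len(stop_at)]
  score <- k + cumsum(ifelse(match_v, 1, -penalty))
  n_mm <- cumsum(!match_v)
  ok <- which(match_v & score >= min_score)  # hits must end on a match
  if (!length(ok)) return(NULL)
  list(end = first + ok - 1L, n_mismatches = n_mm[ok],
       score = as.integer(score[ok]))
}

#' Scan a set of sequences
#'
#' @param seqs named character vector (e.g. from [read_fasta()]).
#' @param ... passed to [scan_ssrs()].
#' @return list with `hits` (row-bound hit table) and `ambiguous`
#'   (character vector of flagged sequence names).
#' @export
scan_ssr_set <- function(seqs, ...) {
  flagged <- character(0)
  hits <- lapply(names(seqs), function(nm) {
    h <- scan_ssrs(seqs[[nm]], seq_id = nm, ...)
    if (isTRUE(attr(h, "ambiguous"))) flagged <<- c(flagged, nm)
    h
  })
  list(hits = do.call(rbind, hits), ambiguous = flagged)
}

#' Alignment-length-normalised SSR content of an ortholog pair
#'
#' Total bases covered by accepted hits (overlapping hits merged by
#' interval union, so nothing is double-counted) divided by the alignment
#' length of the two orthologous sequences.
#'
#' @param gene_seq_a,gene_seq_b DNA strings of the two orthologs.
#' @param alignment_len alignment length in bp (> 0); supplied by the
#'   caller (or see [align_length()] for toy data).
#' @param pair_id identifier copied into the output.
#' @param ... scanner parameters passed to [scan_ssrs()].
#' @return data.frame with two rows (`member` = "a"/"b"): `ssr_bp`,
#'   `alignment_len`, `normalized`.
#' @export
normalized_ssr_content <- function(gene_seq_a, gene_seq_b, alignment_len,
                                   pair_id = "pair1", ...) {
  if (!is_scalar_number(alignment_len) || alignment_len <= 0)
    abort("alignment_len must be a positive number")
  bp <- function(seq) {
    h <- scan_ssrs(seq, ...)
    if (!nrow(h)) return(0L)
    ir <- IRanges::reduce(IRanges::IRanges(h$start, h$end))
    sum(IRanges::width(ir))
  }
  a_bp <- bp(gene_seq_a); b_bp <- bp(gene_seq_b)
  data.frame(pair_id = pair_id, member = c("a", "b"),
             ssr_bp = c(a_bp, b_bp), alignment_len = alignment_len,
             normalized = c(a_bp, b_bp) / alignment_len,
             stringsAsFactors = FALSE)
}

#' Motifs shared by the two genes of a pair
#'
#' Motifs are canonicalised under rotation and reverse complement before
#' intersection, so e.g. AC and GT count as the same motif.
#'
#' @param hits_a,hits_b hit tables from [scan_ssrs()].
#' @return character vector of shared canonical motifs (sorted).
#' @export
shared_motifs <- function(hits_a, hits_b) {
  ca <- unique(canonical_motif(hits_a$motif, revcomp = TRUE))
  cb <- unique(canonical_motif(hits_b$motif, revcomp = TRUE))
  sort(intersect(ca, cb))
}

#' Global alignment length of two sequences (toy helper)
#'
#' Number of alignment columns of a Needleman-Wunsch global alignment.
#' Intended for synthetic tests only; real analyses should supply
#' alignment lengths computed by their own alignment pipeline.
#'
#' @param a,b DNA strings.
#' @return integer alignment length.
#' @export
align_length <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(a, b, type = "global")
  nchar(as.character(Biostrings::alignedPattern(al)))
}
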