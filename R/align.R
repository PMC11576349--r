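# Global (Needleman-Wunsch) alignment utilities.
#
# Scoring throughout: match +1, mismatch -1, gap -2 per gap position
# (linear gap). Full optimal alignments are delegated to
# Biostrings::pairwiseAlignment; the all-prefix score recurrence used by
# the chain splitter is computed here because no installed package exposes
# prefix scores.

MATCH_SCORE    <-  1
MISMATCH_SCORE <- -1
GAP_SCORE      <- -2

# Scores of global alignments of every prefix s[1..i] against the FULL
# reference g, for i = 1..n. Row-vectorized NW: the within-row dependency of
# the linear-gap recurrence F[i,j] = max(M[i,j], F[i,j-1] + gap) unrolls to a
# cummax after the substitution T[j] = F[i,j] - gap*j.
# s, g: integer code vectors (any encoding where equality means match).
nw_prefix_scores <- function(s, g) {
  n <- length(s); m <- length(g)
  prev <- GAP_SCORE * (0:m)          # row 0: aligning empty prefix to g[1..j]
  out <- numeric(n)
  jj <- seq_len(m)
  gap_ramp <- -GAP_SCORE * jj        # = +2, +4, ... under the -2 gap
  for (i in seq_len(n)) {
    sub <- ifelse(g == s[i], MATCH_SCORE, MISMATCH_SCORE)
    diag_ <- prev[jj] + sub
    up <- prev[jj + 1L] + GAP_SCORE
    M <- pmax(diag_, up)
    first <- GAP_SCORE * i
    t_ <- cummax(c(first, M + gap_ramp))[-1L]
    cur <- c(first, t_ - gap_ramp)
    out[i] <- cur[m + 1L]
    prev <- cur
  }
  out
}

# Substitution matrix over the residue alphabet for pairwiseAlignment.
fv_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      a <- AA_ALPHABET
      m <<- matrix(MISMATCH_SCORE, length(a), length(a), dimnames = list(a, a))
      diag(m) <<- MATCH_SCORE
    }
    m
  }
})

# Batch global alignment against one reference via the compiled DP.
# Returns a tibble with score and edit count (mismatches + gap positions,
# minimal among score-optimal paths).
align_to_reference <- function(queries, ref) {
  out <- .cpp_align_batch(queries, ref)
  tibble::tibble(score = out[, "score"], edits = as.integer(out[, "edits"]))
}

# Reference-path alignment through Biostrings::pairwiseAlignment; the
# independent oracle the test suite holds the compiled DP against.
align_to_reference_biostrings <- function(queries, ref) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(ref),
    type = "global",
    substitutionMatrix = fv_submat(),
    gapOpening = 0,
    gapExtension = -GAP_SCORE
  )
  # count mismatches and gap columns from the aligned strings: the nindel()
  # accessor ignores terminal gaps, which must count here
  pp <- as.character(Biostrings::alignedPattern(aln))
  ss <- as.character(Biostrings::alignedSubject(aln))
  dash <- utf8ToInt("-")
  mm <- integer(length(pp)); gp <- integer(length(pp))
  for (i in seq_along(pp)) {
    a <- utf8ToInt(pp[i]); b <- utf8ToInt(ss[i])
    isgap <- a == dash | b == dash
    gp[i] <- sum(isgap)
    mm[i] <- sum(!isgap & a != b)
  }
  tibble::tibble(
    score = Biostrings::score(aln),
    mismatches = mm,
    gaps = gp,
    edits = mm + gp
  )
}

#' Count mutations away from germline
#'
#' Each sequence is globally aligned (match +1, mismatch -1, gap -2) to
#' every germline of its chain type; the best-scoring germline is reported
#' together with the edit count (mismatches plus gap positions) of that
#' alignment. Ties go to the lexicographically first germline name.
#'
#' @param seqs Character vector of chain residue strings.
#' @param germlines Germline reference tibble (`name`, `chain`, `seq`).
#' @param chain `"VH"` or `"VL"`: which germline pool to compare against.
#' @return A tibble with one row per input: `germline` (best name) and
#'   `count` (edit distance to it under the alignment).
#' @examples
#' g <- synthetic_germlines()
#' mutation_count(g$seq[g$chain == "VH"][1], g, "VH")
#' @export
mutation_count <- function(seqs, germlines, chain = c("VH", "VL")) {
  chain <- match.arg(chain)
  pool <- germlines[germlines$chain == chain, , drop = FALSE]
  if (nrow(pool) == 0L) {
    stop("empty germline reference for chain ", chain, call. = FALSE)
  }
  pool <- pool[order(pool$name), , drop = FALSE]
  best_score <- rep(-Inf, length(seqs))
  best_name <- rep(NA_character_, length(seqs))
  best_count <- rep(NA_integer_, length(seqs))
  for (k in seq_len(nrow(pool))) {
    a <- align_to_reference(seqs, pool$seq[k])
    better <- a$score > best_score  # strict: earlier (lexicographic) name wins ties
    best_score[better] <- a$score[better]
    best_name[better] <- pool$name[k]
    best_count[better] <- a$edits[better]
  }
  tibble::tibble(germline = best_name, count = as.integer(best_count))
}

# Pairwise sequence distance: Hamming when lengths are equal, otherwise
# alignment edit count (mismatches + gap positions).
seq_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  } else {
    align_to_reference(a, b)$edits
  }
}

#' Nearest-neighbour Hamming novelty
#'
#' For each query chain, the distance to its closest sequence in a reference
#' set. Equal-length pairs use plain Hamming distance; unequal-length pairs
#' use the mismatch-plus-gap count of the +1/-1/-2 global alignment. When a
#' query is literally present in the reference set (identity-aware: same
#' `exclude_self` index), that self-match is skipped.
#'
#' @param query Character vector of chain sequences.
#' @param reference Character vector of chain sequences.
#' @param exclude_self If `TRUE` (default) a query at reference index `i`
#'   with identical string AND the two sets being the same object is not
#'   matched to itself; concretely, when `identical(query, reference)` the
#'   diagonal is excluded.
#' @return A list: `distances` (per-query minima) and `mean`.
#' @export
nn_hamming <- function(query, reference, exclude_self = TRUE) {
  if (length(query) == 0L || length(reference) == 0L) {
    stop("query and reference sets must be non-empty", call. = FALSE)
  }
  same <- exclude_self && identical(query, reference)
  if (same && length(query) < 2L) {
    stop("need at least two sequences to exclude self-matches", call. = FALSE)
  }
  dm <- distance_matrix(query, reference)
  if (same) diag(dm) <- Inf
  d <- apply(dm, 1L, min)
  list(distances = d, mean = mean(d))
}

# Full query x reference distance matrix, grouped by length for speed:
# equal-length blocks are vectorized Hamming; cross-length blocks go through
# pairwiseAlignment once per (query length-group, reference sequence).
distance_matrix <- function(query, reference) {
  nq <- length(query); nr <- length(reference)
  dm <- matrix(NA_real_, nq, nr)
  qlen <- nchar(query); rlen <- nchar(reference)
  qcodes <- lapply(query, utf8ToInt)
  rcodes <- lapply(reference, utf8ToInt)
  for (L in unique(qlen)) {
    qi <- which(qlen == L)
    ri <- which(rlen == L)
    if (length(ri) > 0L) {
      Q <- do.call(rbind, qcodes[qi])          # |qi| x L
      R <- do.call(rbind, rcodes[ri])          # |ri| x L
      acc <- matrix(0L, length(qi), length(ri))
      for (p in seq_len(L)) acc <- acc + outer(Q[, p], R[, p], "!=")
      dm[qi, ri] <- acc
    }
    ri2 <- which(rlen != L)
    for (j in ri2) {
      dm[qi, j] <- align_to_reference(query[qi], reference[j])$edits
    }
  }
  dm
}
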