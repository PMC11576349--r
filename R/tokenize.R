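#' Token streams
#'
#' A token stream is the model-facing form of a (paired or single-chain)
#' antibody sequence: integer residue tokens wrapped in a start sentinel
#' (`"1"`) and an end sentinel (`"2"`), with an explicit direction. A
#' `forward` stream reads `1, <heavy residues>, <light residues>, 2`; the
#' `reverse` stream is the forward stream with its token order fully
#' reversed (so it begins with `"2"`). Training in both directions is what
#' lets a heavy chain be completed from a light chain and vice versa.
#'
#' @param tokens Integer token ids.
#' @param direction `"forward"` or `"reverse"`.
#' @return An `fv_stream`: list with elements `tokens` and `direction`.
#' @export
fv_stream <- function(tokens, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  structure(list(tokens = as.integer(tokens), direction = direction),
            class = "fv_stream")
}

#' @export
print.fv_stream <- function(x, ...) {
  cat("<fv_stream ", x$direction, "> length ", length(x$tokens), "\n", sep = "")
  invisible(x)
}

#' Encode a paired VH/VL sequence as a token stream
#'
#' The light chain is concatenated to the heavy chain and the result is
#' wrapped in one start/end sentinel pair (a single wrap around the whole
#' concatenation; no per-chain separator token is used).
#'
#' @param heavy,light Character scalars: VH and VL residue strings.
#' @param direction `"forward"` or `"reverse"`.
#' @param vocab An [fv_vocabulary()].
#' @param max_positions Maximum stream length the consuming model accepts;
#'   combined residue length must be at most `max_positions - 2`.
#' @return An [fv_stream()].
#' @examples
#' v <- fv_vocabulary()
#' s <- encode_pair("EVQ", "DIQ", "forward", v)
#' decode_stream(s, v)
#' @export
encode_pair <- function(heavy, light, direction = c("forward", "reverse"),
                        vocab = fv_vocabulary(), max_positions = Inf) {
  direction <- match.arg(direction)
  validate_chain(heavy, "VH", max_x_fraction = 1)
  validate_chain(light, "VL", max_x_fraction = 1)
  res <- c(residue_ids(heavy, vocab), residue_ids(light, vocab))
  if (length(res) > max_positions - 2L) {
    stop("combined chain length ", length(res),
         " exceeds max_positions - 2 (", max_positions - 2L, ")", call. = FALSE)
  }
  fwd <- c(vocab_bos(vocab), res, vocab_eos(vocab))
  if (direction == "forward") fv_stream(fwd, "forward")
  else fv_stream(rev(fwd), "reverse")
}

#' Encode a single chain as a token stream
#'
#' Used for the unpaired pretraining stage: a lone VH or VL is wrapped in
#' the same sentinels as a pair.
#'
#' @inheritParams encode_pair
#' @param seq Residue string.
#' @return An [fv_stream()].
#' @export
encode_chain <- function(seq, direction = c("forward", "reverse"),
                         vocab = fv_vocabulary(), max_positions = Inf) {
  direction <- match.arg(direction)
  validate_chain(seq, "VH", max_x_fraction = 1)
  res <- residue_ids(seq, vocab)
  if (length(res) > max_positions - 2L) {
    stop("chain length exceeds max_positions - 2", call. = FALSE)
  }
  fwd <- c(vocab_bos(vocab), res, vocab_eos(vocab))
  if (direction == "forward") fv_stream(fwd, "forward")
  else fv_stream(rev(fwd), "reverse")
}

#' Reverse a token stream
#'
#' Involution: reversing twice returns the original stream.
#'
#' @param stream An [fv_stream()].
#' @return The stream with token order reversed and direction flipped.
#' @export
reverse_stream <- function(stream) {
  stopifnot(inherits(stream, "fv_stream"))
  fv_stream(rev(stream$tokens),
            if (stream$direction == "forward") "reverse" else "forward")
}

#' Decode a token stream back to a residue string
#'
#' Reverse streams are un-reversed first, so the result is always the
#' forward-orientation concatenated residue string with sentinels stripped.
#'
#' @param stream An [fv_stream()].
#' @param vocab The [fv_vocabulary()] used to encode it.
#' @return Character scalar: concatenated heavy+light (or single-chain)
#'   residues in forward orientation.
#' @export
decode_stream <- function(stream, vocab = fv_vocabulary()) {
  stopifnot(inherits(stream, "fv_stream"))
  toks <- stream$tokens
  if (stream$direction == "reverse") toks <- rev(toks)
  n <- length(toks)
  if (n < 2L || toks[1] != vocab_bos(vocab) || toks[n] != vocab_eos(vocab)) {
    stop("malformed stream: sentinels missing or misplaced", call. = FALSE)
  }
  interior <- toks[-c(1L, n)]
  if (!all(interior %in% attr(vocab, "residue_ids"))) {
    stop("malformed stream: non-residue token in interior", call. = FALSE)
  }
  paste(vocab_tokens(vocab, interior), collapse = "")
}

#' Split a concatenated heavy+light string at the chain boundary
#'
#' Germline-anchored boundary recovery: for every candidate split index the
#' prefix is scored against the best-matching VH germline and the suffix
#' against the best-matching VL germline by global alignment (match +1,
#' mismatch -1, gap -2), and the split maximizing the combined score wins
#' (lowest index on ties). This replaces numbering-tool-based chain
#' identification and is deterministic.
#'
#' @param concatenated Character scalar: heavy followed by light residues.
#' @param germlines Germline reference tibble as from [synthetic_germlines()]
#'   (columns `name`, `chain`, `seq` at minimum), with at least one VH and
#'   one VL entry.
#' @param score_floor Minimum combined alignment score accepted; below it the
#'   string is declared unsplittable. The default 0 rejects random strings
#'   (unrelated sequences align with negative expected score under the
#'   +1/-1/-2 scheme) while accepting heavily mutated antibody sequences.
#' @param window Optional integer margin: candidate splits are restricted to
#'   within `window` of the germline VH length range (a speed device; set to
#'   `Inf` to scan every index).
#' @return A list with `heavy`, `light`, `boundary` (length of the heavy
#'   prefix), and `score`.
#' @export
split_pair <- function(concatenated, germlines, score_floor = 0, window = 25L) {
  stopifnot(is.character(concatenated), length(concatenated) == 1L)
  gh <- germlines[germlines$chain == "VH", , drop = FALSE]
  gl <- germlines[germlines$chain == "VL", , drop = FALSE]
  if (nrow(gh) < 1L || nrow(gl) < 1L) {
    stop("germline reference must contain at least one VH and one VL",
         call. = FALSE)
  }
  n <- nchar(concatenated)
  if (n < 2L) stop("sequence too short to split", call. = FALSE)
  s <- utf8ToInt(concatenated)
  # prefix_scores[i]: best score of s[1..i] vs any full VH germline
  pref <- rep(-Inf, n)
  for (g in gh$seq) pref <- pmax(pref, nw_prefix_scores(s, utf8ToInt(g)))
  # suffix scores via reversed strings
  suf <- rep(-Inf, n)
  s_rev <- rev(s)
  for (g in gl$seq) {
    suf <- pmax(suf, rev(nw_prefix_scores(s_rev, rev(utf8ToInt(g)))))
  }
  # combined score for boundary i (heavy = s[1..i], light = s[(i+1)..n])
  cand <- seq_len(n - 1L)
  if (is.finite(window)) {
    lens <- nchar(gh$seq)
    lo <- max(1L, min(lens) - as.integer(window))
    hi <- min(n - 1L, max(lens) + as.integer(window))
    if (lo <= hi) cand <- lo:hi
  }
  comb <- pref[cand] + suf[cand + 1L]
  best <- which.max(comb)  # first index on ties
  score <- comb[best]
  if (!is.finite(score) || score < score_floor) {
    stop("unsplittable: best combined germline alignment score ",
         signif(score, 4), " is below the floor ", score_floor, call. = FALSE)
  }
  boundary <- cand[best]
  list(
    heavy = substr(concatenated, 1L, boundary),
    light = substr(concatenated, boundary + 1L, n),
    boundary = boundary,
    score = score
  )
}
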