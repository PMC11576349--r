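#' Amino-acid residue alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order, plus the
#' ambiguity code `X`.
#'
#' @format Character vectors.
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname alphabet
#' @export
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Build a residue-level vocabulary
#'
#' The vocabulary is a bijection between tokens and integer ids. It always
#' contains, in fixed order: a padding token (`"."`), the start sentinel
#' (`"1"`), the end sentinel (`"2"`), the 20 canonical amino acids, and the
#' ambiguity code `"X"`. If `vocab_size` exceeds the 24 core tokens, the
#' remainder is filled with reserved unused tokens so that the tokenizer's
#' size and the model's embedding size decouple cleanly.
#'
#' @param vocab_size Total number of tokens (default 26: 24 core + 2 reserved).
#' @return An object of class `fv_vocab`: a named integer vector mapping
#'   token to id, with attributes `pad_id`, `bos_id` (start sentinel `"1"`),
#'   `eos_id` (end sentinel `"2"`), and `residue_ids`.
#' @examples
#' v <- fv_vocabulary()
#' v[["A"]]
#' @export
fv_vocabulary <- function(vocab_size = 26L) {
  core <- c(".", "1", "2", AA_ALPHABET)
  if (vocab_size < length(core)) {
    stop("vocab_size must be at least ", length(core), call. = FALSE)
  }
  n_res <- vocab_size - length(core)
  reserved <- if (n_res > 0) sprintf("<r%d>", seq_len(n_res)) else character()
  tokens <- c(core, reserved)
  ids <- stats::setNames(seq_along(tokens), tokens)
  structure(
    ids,
    pad_id = 1L,
    bos_id = 2L,
    eos_id = 3L,
    residue_ids = unname(ids[AA_ALPHABET]),
    class = "fv_vocab"
  )
}

#' @export
print.fv_vocab <- function(x, ...) {
  cat("<fv_vocab> ", length(x), " tokens: ",
      paste(utils::head(names(x), 8), collapse = " "), " ...\n", sep = "")
  invisible(x)
}

vocab_pad <- function(vocab) attr(vocab, "pad_id")
vocab_bos <- function(vocab) attr(vocab, "bos_id")
vocab_eos <- function(vocab) attr(vocab, "eos_id")

# id -> token lookup
vocab_tokens <- function(vocab, ids) names(vocab)[ids]

# residues string -> integer ids; errors on anything outside the alphabet
residue_ids <- function(seq, vocab) {
  chars <- strsplit(seq, "")[[1]]
  ids <- unname(vocab[chars])
  bad <- is.na(ids) | !(ids %in% attr(vocab, "residue_ids"))
  if (any(bad)) {
    stop("invalid residue(s) outside the amino-acid alphabet: ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  ids
}

#' Validate a chain sequence
#'
#' Checks that a sequence is a non-empty string over the allowed amino-acid
#' alphabet (20 canonical residues plus optional `X`).
#'
#' @param seq Character scalar of one-letter residues.
#' @param chain_type `"VH"` or `"VL"`.
#' @param max_x_fraction Maximum tolerated fraction of `X` residues
#'   (default 0: any `X` rejected). Corpus filtering uses this same rule.
#' @return Invisibly, `seq`; errors otherwise.
#' @export
validate_chain <- function(seq, chain_type = c("VH", "VL"), max_x_fraction = 0) {
  chain_type <- match.arg(chain_type)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("chain sequence must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    stop("invalid residue(s) in ", chain_type, " chain: ",
         paste(unique(chars[bad]), collapse = ", "), call. = FALSE)
  }
  if (mean(chars == "X") > max_x_fraction) {
    stop(chain_type, " chain exceeds the allowed 'X' fraction (",
         max_x_fraction, ")", call. = FALSE)
  }
  invisible(seq)
}
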