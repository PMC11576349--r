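#' Corpus filtering with pluggable predicates
#'
#' Training-corpus hygiene is dataset-specific (the redundancy and
#' sequencing-error rules used for public repertoire databases live in
#' supplementary protocols and vary between releases), so the filter is a
#' composition of named predicates rather than a fixed rule. Each
#' predicate receives the corpus tibble and returns a logical vector;
#' rows failing any predicate are dropped, with per-predicate counts
#' attached.
#'
#' @param corpus Tibble with `heavy` and `light` columns (or `seq` for an
#'   unpaired corpus).
#' @param predicates Named list of `function(corpus) -> logical`.
#'   Defaults: `valid_residues` (chains parse over the amino-acid
#'   alphabet), `max_x_fraction` (at most `x_fraction` of residues are
#'   `X`), and `max_length` (combined residue length fits
#'   `max_positions - 2`).
#' @param x_fraction Maximum tolerated `X` fraction per chain (default 0).
#' @param max_positions Model position budget for the length predicate.
#' @return The filtered corpus; attribute `n_dropped` holds the named
#'   per-predicate drop counts.
#' @export
filter_corpus <- function(corpus,
                          predicates = default_corpus_predicates(
                            x_fraction, max_positions),
                          x_fraction = 0, max_positions = 1024L) {
  keep <- rep(TRUE, nrow(corpus))
  dropped <- integer(0)
  for (nm in names(predicates)) {
    ok <- predicates[[nm]](corpus)
    dropped[nm] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- corpus[keep, , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}

#' @rdname filter_corpus
#' @export
default_corpus_predicates <- function(x_fraction = 0, max_positions = 1024L) {
  chains_of <- function(corpus) {
    if (!is.null(corpus[["heavy"]])) list(corpus$heavy, corpus$light)
    else list(corpus$seq)
  }
  ok_chain <- function(s) {
    !is.na(s) & nzchar(s) &
      !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), s)
  }
  x_frac <- function(s) {
    vapply(strsplit(s, ""), function(ch) mean(ch == "X"), numeric(1))
  }
  list(
    valid_residues = function(corpus) {
      Reduce(`&`, lapply(chains_of(corpus), ok_chain))
    },
    max_x_fraction = function(corpus) {
      Reduce(`&`, lapply(chains_of(corpus), function(s) {
        ok <- rep(FALSE, length(s))
        valid <- ok_chain(s)
        ok[valid] <- x_frac(s[valid]) <= x_fraction
        ok
      }))
    },
    max_length = function(corpus) {
      len <- Reduce(`+`, lapply(chains_of(corpus), function(s)
        ifelse(is.na(s), Inf, nchar(s))))
      len <= max_positions - 2L
    }
  )
}
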