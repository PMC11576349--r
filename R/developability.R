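#' Total CDR length of annotated pairs
#'
#' Sum of the six CDR interval lengths (three per chain) of each pair.
#' Annotations are 0-based half-open intervals on each chain's residue
#' string, as produced by [sample_repertoire()] or [annotate_cdrs()].
#'
#' @param pairs Tibble with `heavy`, `light` and the twelve annotation
#'   columns `vh_cdr{1,2,3}_{start,end}`, `vl_cdr{1,2,3}_{start,end}`.
#' @return Integer vector of total CDR lengths.
#' @export
total_cdr_length <- function(pairs) {
  cols <- as.vector(outer(c("vh", "vl"), 1:3,
                          function(c, i) paste0(c, "_cdr", i)))
  tot <- rep(0L, nrow(pairs))
  for (cc in cols) {
    s <- pairs[[paste0(cc, "_start")]]
    e <- pairs[[paste0(cc, "_end")]]
    if (is.null(s) || is.null(e)) {
      stop("missing annotation columns for ", cc, call. = FALSE)
    }
    len <- nchar(if (startsWith(cc, "vh")) pairs$heavy else pairs$light)
    if (any(s < 0 | e < s | e > len)) {
      stop("annotation error: ", cc, " interval out of sequence bounds",
           call. = FALSE)
    }
    tot <- tot + (e - s)
  }
  as.integer(tot)
}

#' Flag a total CDR length
#'
#' Green if within `green_range` (inclusive); amber if within
#' `amber_margin` outside it; red beyond. The published risk bands for
#' this metric are not part of this package: the thresholds are pure
#' configuration.
#'
#' @param length Integer total CDR length(s).
#' @param green_range `c(lo, hi)` inclusive green band.
#' @param amber_margin Residues beyond the green band still flagged amber.
#' @return Character vector: `"green"`, `"amber"` or `"red"`.
#' @export
flag_total_cdr_length <- function(length, green_range = c(40L, 60L),
                                  amber_margin = 3L) {
  if (length(green_range) != 2L || green_range[1] > green_range[2]) {
    stop("green_range must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  lo <- green_range[1]; hi <- green_range[2]
  dplyr::case_when(
    length >= lo & length <= hi ~ "green",
    length >= lo - amber_margin & length <= hi + amber_margin ~ "amber",
    TRUE ~ "red"
  )
}

#' Transfer germline CDR annotations onto observed chains
#'
#' Anchor heuristic for the synthetic germline families: each chain is
#' aligned to its best-matching germline and the germline's CDR intervals
#' are mapped through the alignment onto the chain's own coordinates
#' (0-based half-open). Numbering-tool annotations for real data are
#' user-supplied instead.
#'
#' @param pairs Tibble with `heavy` and `light` columns.
#' @param germlines Germline reference tibble with CDR columns.
#' @return `pairs` with the twelve `vh_cdr*`/`vl_cdr*` annotation columns
#'   added (plus `vh_germline`/`vl_germline` best-match names).
#' @export
annotate_cdrs <- function(pairs, germlines) {
  for (chain in c("VH", "VL")) {
    pre <- tolower(chain)
    seqs <- if (chain == "VH") pairs$heavy else pairs$light
    best <- mutation_count(seqs, germlines, chain)$germline
    starts <- matrix(NA_integer_, length(seqs), 3)
    ends <- matrix(NA_integer_, length(seqs), 3)
    for (gname in unique(best)) {
      gi <- germlines[germlines$name == gname, ]
      sel <- which(best == gname)
      for (j in sel) {
        map <- .cpp_align_map(seqs[j], gi$seq)
        for (k in 1:3) {
          s0 <- gi[[paste0("cdr", k, "_start")]]
          e0 <- gi[[paste0("cdr", k, "_end")]]
          starts[j, k] <- map$start[s0 + 1L]
          ends[j, k] <- map$end[e0]
        }
      }
    }
    for (k in 1:3) {
      pairs[[paste0(pre, "_cdr", k, "_start")]] <- starts[, k]
      pairs[[paste0(pre, "_cdr", k, "_end")]] <- ends[, k]
    }
    pairs[[paste0(pre, "_germline")]] <- best
  }
  pairs
}

# Map subject (germline) residue indices to pattern (query) coordinates
# through an alignment. Returns, for each subject residue i (1-based):
#  start[i] = 0-based query offset where the region starting at subject i
#             begins; end[i] = 0-based query offset just past the region
#             ending at subject i.
alignment_position_map <- function(pp, ss) {
  a <- utf8ToInt(pp); b <- utf8ToInt(ss)
  dash <- utf8ToInt("-")
  qpos <- cumsum(a != dash)          # query residues consumed through col j
  scols <- which(b != dash)          # alignment column of each subject residue
  m <- length(scols)
  start <- integer(m); end <- integer(m)
  for (i in seq_len(m)) {
    j <- scols[i]
    start[i] <- qpos[j] - (a[j] != dash)   # 0-based: residues strictly before
    end[i] <- qpos[j]
  }
  list(start = start, end = end)
}

#' Filter a corpus to developable antibodies
#'
#' Default policy: keep items whose four structure-based developability
#' flags (PSH, PPC, PNC, SFvCSP) are all green, ignoring the sequence-based
#' CDR-length flag. Items without a flag record are dropped and counted.
#' Split labels are preserved, so held-out sets stay held out across the
#' finetuning stages. Idempotent and order-preserving.
#'
#' @param corpus Tibble with an `id` column (and any other columns, which
#'   are preserved).
#' @param flags Tibble `id`, `psh`, `ppc`, `pnc`, `sfvcsp` with values in
#'   green/amber/red, as from [sample_flags()] or [read_flags_csv()].
#' @param policy Predicate `function(flag_row) -> logical`; the default
#'   requires all four structure-based flags green.
#' @return The filtered corpus, with attribute `n_missing_flags`.
#' @export
filter_developable <- function(corpus, flags,
                               policy = all_green_policy) {
  m <- match(corpus$id, flags$id)
  missing <- is.na(m)
  keep <- rep(FALSE, nrow(corpus))
  if (any(!missing)) {
    fr <- flags[m[!missing], , drop = FALSE]
    keep[!missing] <- vapply(seq_len(nrow(fr)),
                             function(i) isTRUE(policy(fr[i, ])), logical(1))
  }
  out <- corpus[keep, , drop = FALSE]
  attr(out, "n_missing_flags") <- sum(missing)
  out
}

#' @rdname filter_developable
#' @param flag_row One row of the flags tibble.
#' @export
all_green_policy <- function(flag_row) {
  all(unlist(flag_row[c("psh", "ppc", "pnc", "sfvcsp")]) == "green")
}

#' Developability-biasing finetune stage
#'
#' Finetunes a paired-stage model on a developable subset with all
#' parameters trainable, exactly the mechanics of [finetune()], recording
#' `stage = "developable"` in the checkpoint metadata. The architecture
#' and tokenizer are never altered. For sampling from the resulting model
#' a slightly higher temperature (1.25) is the published default, to
#' maintain diversity.
#'
#' @param model A paired-stage `fv_model`.
#' @param dev_corpus The developable corpus (for example the output of
#'   [filter_developable()]).
#' @param config An [train_config()]; the published stage used 2 epochs at
#'   learning rate 1e-5.
#' @param quiet Suppress progress messages.
#' @return The finetuned `fv_model`.
#' @export
finetune_developable <- function(model, dev_corpus,
                                 config = train_config(peak_lr = 1e-5,
                                                       epochs = 2L,
                                                       batch_size = 256L,
                                                       grad_accum_steps = 1L),
                                 quiet = FALSE) {
  finetune(model, dev_corpus, config, stage = "developable", quiet = quiet)
}
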