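# Readers and writers for the package's plain-text formats:
#  - paired FASTA dialect: two records per antibody, ids "<name>_VH" and
#    "<name>_VL"
#  - paired CSV dialect: header id,heavy,light
#  - fitness CSV: id,heavy,light,fitness
#  - flags CSV: id,psh,ppc,pnc,sfvcsp
#  - YAML run configs

#' Read and write paired sequences
#'
#' `read_paired_sequences()` auto-dispatches on extension (`.fasta`/`.fa`
#' vs `.csv`). The FASTA dialect stores each antibody as two records named
#' `<id>_VH` and `<id>_VL`; a chain whose partner record is missing is a
#' pairing error and the offending ids are reported.
#'
#' @param path File path.
#' @param format `"fasta"`, `"csv"`, or `"auto"`.
#' @return Tibble: `id`, `heavy`, `light` (file order of first appearance).
#' @export
read_paired_sequences <- function(path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("id", "heavy", "light") %in% names(df))) {
      stop("paired CSV must have header id,heavy,light", call. = FALSE)
    }
    df <- tibble::as_tibble(df[, c("id", "heavy", "light")])
  } else {
    aa <- Biostrings::readAAStringSet(path)
    nm <- names(aa)
    chain <- sub("^.*_(V[HL])$", "\\1", nm)
    id <- sub("_(V[HL])$", "", nm)
    if (any(!chain %in% c("VH", "VL"))) {
      stop("FASTA record ids must end in _VH or _VL; offenders: ",
           paste(utils::head(nm[!chain %in% c("VH", "VL")], 5), collapse = ", "),
           call. = FALSE)
    }
    hv <- stats::setNames(as.character(aa[chain == "VH"]), id[chain == "VH"])
    lt <- stats::setNames(as.character(aa[chain == "VL"]), id[chain == "VL"])
    orphans <- c(setdiff(names(hv), names(lt)), setdiff(names(lt), names(hv)))
    if (length(orphans) > 0) {
      stop("pairing error: unmatched chain record(s) for id(s): ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
    ids <- unique(id)
    df <- tibble::tibble(id = ids, heavy = unname(hv[ids]),
                         light = unname(lt[ids]))
  }
  purrr::walk2(df$heavy, seq_len(nrow(df)), function(s, i) {
    tryCatch(validate_chain(s, "VH", max_x_fraction = 1),
             error = function(e) stop("row ", i, " (", df$id[i], "): ",
                                      conditionMessage(e), call. = FALSE))
  })
  purrr::walk2(df$light, seq_len(nrow(df)), function(s, i) {
    tryCatch(validate_chain(s, "VL", max_x_fraction = 1),
             error = function(e) stop("row ", i, " (", df$id[i], "): ",
                                      conditionMessage(e), call. = FALSE))
  })
  df
}

#' @rdname read_paired_sequences
#' @param pairs Tibble with `id`, `heavy`, `light` (an `id` is generated
#'   if absent).
#' @export
write_paired_sequences <- function(pairs, path, format = c("auto", "fasta", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "fasta"
  }
  if (is.null(pairs[["id"]])) {
    pairs$id <- sprintf("seq%05d", seq_len(nrow(pairs)))
  }
  if (format == "csv") {
    readr::write_csv(pairs[, c("id", "heavy", "light")], path)
  } else {
    seqs <- as.vector(rbind(pairs$heavy, pairs$light))
    names(seqs) <- as.vector(rbind(paste0(pairs$id, "_VH"),
                                   paste0(pairs$id, "_VL")))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  }
  invisible(path)
}

#' Read a fitness dataset CSV
#'
#' Expected header: `id,heavy,light,fitness` (a `label` column is kept if
#' present).
#'
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_fitness_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "heavy", "light", "fitness")
  if (!all(need %in% names(df))) {
    stop("fitness CSV must have header id,heavy,light,fitness", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a developability flags CSV
#'
#' Expected header: `id,psh,ppc,pnc,sfvcsp` with values in
#' green/amber/red. These structure-based annotations are computed by
#' external tools; this package never computes them.
#'
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_flags_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "psh", "ppc", "pnc", "sfvcsp")
  if (!all(need %in% names(df))) {
    stop("flags CSV must have header id,psh,ppc,pnc,sfvcsp", call. = FALSE)
  }
  bad <- !unlist(df[, need[-1]]) %in% c("green", "amber", "red")
  if (any(bad)) stop("flag values must be green/amber/red", call. = FALSE)
  tibble::as_tibble(df)
}

#' Read and write germline reference FASTA
#'
#' Record ids must end in `_VH` or `_VL` to mark the chain type (CDR
#' annotation columns are not representable in FASTA; use
#' [annotate_cdrs()]-style columns via CSV if needed).
#'
#' @param path File path.
#' @return Tibble `name`, `chain`, `seq`.
#' @export
read_germline_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- names(aa)
  chain <- sub("^.*_(V[HL])$", "\\1", nm)
  if (any(!chain %in% c("VH", "VL"))) {
    stop("germline FASTA ids must end in _VH or _VL", call. = FALSE)
  }
  tibble::tibble(name = sub("_(V[HL])$", "", nm), chain = chain,
                 seq = as.character(aa))
}
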