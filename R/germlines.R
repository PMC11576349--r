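# Synthetic germline pools.
#
# Four VH and four VL "families" of invented Fv-like sequences with a
# plausible framework/CDR layout (FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4). They
# are loosely styled after human V-gene consensus frameworks but are
# fixtures, NOT biological references; real IMGT germline sets are
# user-supplied files. CDR3 lengths differ deliberately across families so
# that family usage shifts are visible in total-CDR-length distributions.

vh_parts <- list(
  SynVH1 = list(
    fr1 = "EVQLVESGGGLVQPGGSLRLSCAAS", cdr1 = "GFTFSSYA",
    fr2 = "MSWVRQAPGKGLEWVSA", cdr2 = "ISGSGGST",
    fr3 = "YYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAK", cdr3 = "DRGYSSGWYDYFDY",
    fr4 = "WGQGTLVTVSS"),
  SynVH2 = list(
    fr1 = "QVQLVQSGAEVKKPGASVKVSCKAS", cdr1 = "GYTFTGYY",
    fr2 = "MHWVRQAPGQGLEWMGW", cdr2 = "INPNSGGT",
    fr3 = "NYAQKFQGRVTMTRDTSISTAYMELSRLRSDDTAVYYCAR", cdr3 = "EGLGYFDW",
    fr4 = "WGQGTTVTVSS"),
  SynVH3 = list(
    fr1 = "QVQLQESGPGLVKPSETLSLTCTVS", cdr1 = "GGSISSYY",
    fr2 = "WSWIRQPPGKGLEWIGY", cdr2 = "IYYSGST",
    fr3 = "NYNPSLKSRVTISVDTSKNQFSLKLSSVTAADTAVYYCAR", cdr3 = "HGDYVWGSYRY",
    fr4 = "WGQGTLVTVSS"),
  SynVH4 = list(
    fr1 = "EVQLVETGGGLIQPGGSLRLSCAAS", cdr1 = "GFTVSSNY",
    fr2 = "MSWVRQAPGKGLEWVSV", cdr2 = "IYSGGST",
    fr3 = "YYADSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCAR", cdr3 = "DLSPYSSSWYGGFGLDV",
    fr4 = "WGQGTLVTVSS")
)

vl_parts <- list(
  SynVL1 = list(
    fr1 = "DIQMTQSPSSLSASVGDRVTITC", cdr1 = "QSISSY",
    fr2 = "LNWYQQKPGKAPKLLIY", cdr2 = "AASSLQS",
    fr3 = "GVPSRFSGSGSGTDFTLTISSLQPEDFATYYC", cdr3 = "QQSYSTPLT",
    fr4 = "FGQGTKVEIK"),
  SynVL2 = list(
    fr1 = "EIVLTQSPGTLSLSPGERATLSC", cdr1 = "QSVSSSY",
    fr2 = "LAWYQQKPGQAPRLLIY", cdr2 = "GASSRAT",
    fr3 = "GIPDRFSGSGSGTDFTLTISRLEPEDFAVYYC", cdr3 = "QQYGSSPWT",
    fr4 = "FGQGTKVEIK"),
  SynVL3 = list(
    fr1 = "QSVLTQPPSVSGAPGQRVTISC", cdr1 = "SSNIGAGYD",
    fr2 = "VHWYQQLPGTAPKLLIY", cdr2 = "GNSNRPS",
    fr3 = "GVPDRFSGSKSGTSASLAITGLQAEDEADYYC", cdr3 = "QSYDSSLSGSV",
    fr4 = "FGGGTKLTVL"),
  SynVL4 = list(
    fr1 = "SYELTQPPSVSVSPGQTASITC", cdr1 = "SGDKLGDKY",
    fr2 = "ACWYQQKPGQSPVLVIY", cdr2 = "QDSKRPS",
    fr3 = "GIPERFSGSNSGNTATLTISGTQAMDEADYYC", cdr3 = "QAWDSSTYV",
    fr4 = "FGGGTKLTVL")
)

assemble_germline <- function(name, chain, parts) {
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  tibble::tibble(
    name = name, chain = chain,
    seq = paste(unlist(parts), collapse = ""),
    cdr1_start = starts[["cdr1"]], cdr1_end = ends[["cdr1"]],
    cdr2_start = starts[["cdr2"]], cdr2_end = ends[["cdr2"]],
    cdr3_start = starts[["cdr3"]], cdr3_end = ends[["cdr3"]]
  )
}

#' Synthetic germline reference set
#'
#' Four VH and four VL invented germline families (~110-125 residues each)
#' with framework/CDR layout and 0-based half-open CDR interval
#' annotations. These are synthetic fixtures for simulation and testing,
#' not biological V genes; supply your own reference (same columns) for
#' real data.
#'
#' @return Tibble: `name`, `chain` (`"VH"`/`"VL"`), `seq`, and
#'   `cdr{1,2,3}_{start,end}` columns.
#' @examples
#' synthetic_germlines()
#' @export
synthetic_germlines <- function() {
  dplyr::bind_rows(c(
    unname(purrr::imap(vh_parts, function(p, nm) assemble_germline(nm, "VH", p))),
    unname(purrr::imap(vl_parts, function(p, nm) assemble_germline(nm, "VL", p)))
  ))
}
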