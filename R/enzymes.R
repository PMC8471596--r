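#' Restriction enzyme specifications
#'
#' Built-in table of the enzymes used in the part-engineering workflow: the
#' type-IIS enzymes of the modular cloning (MoClo) standard, which cut
#' outside their non-palindromic recognition sites leaving 4-nt overhangs
#' (BsaI GGTCTC N1/N5; BpiI, an isoschizomer of BbsI, GAAGAC N2/N6), and the
#' ordinary enzymes used to linearise plasmids before electroporation (ScaI
#' AGTACT and EcoRV GATATC, both blunt; NcoI CCATGG, 4-nt 5' overhang).
#'
#' `cut_offset_top`/`cut_offset_bottom` give the cut position in bases
#' downstream of the recognition sequence's 3' end on the top/bottom strand
#' for type-IIS enzymes, and the within-site cut position (bases after the
#' recognition start) for palindromic enzymes (`type_iis = FALSE`).
#'
#' @param names Optional subset of enzyme names to return.
#' @return Data frame `name`, `recognition`, `cut_offset_top`,
#'   `cut_offset_bottom`, `overhang_len`, `type_iis`.
#' @export
enzyme_table <- function(names = NULL) {
  tab <- data.frame(
    name = c("BsaI", "BpiI", "ScaI", "NcoI", "EcoRV"),
    recognition = c("GGTCTC", "GAAGAC", "AGTACT", "CCATGG", "GATATC"),
    cut_offset_top = c(1L, 2L, 3L, 1L, 3L),
    cut_offset_bottom = c(5L, 6L, 3L, 5L, 3L),
    overhang_len = c(4L, 4L, 0L, 4L, 0L),
    type_iis = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(tab)
  missing <- setdiff(names, tab$name)
  if (length(missing) > 0) stop("unknown enzyme(s): ", paste(missing, collapse = ", "))
  tab[match(names, tab$name), , drop = FALSE]
}

#' The MoClo domestication enzymes (BsaI + BpiI)
#' @return Enzyme table rows for BsaI and BpiI.
#' @export
moclo_enzymes <- function() enzyme_table(c("BsaI", "BpiI"))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(sequence, what = "sequence") {
  s <- toupper(chartr("u", "t", chartr("U", "T", sequence)))
  if (grepl("[^ACGT]", s)) {
    stop(what, " contains non-ACGT characters (ambiguity codes are not supported)")
  }
  s
}
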