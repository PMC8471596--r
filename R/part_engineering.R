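#' Scan a sequence for all (overlapping) motif occurrences
#'
#' The polyadenylation signal of *C. reinhardtii* is the transcript-level
#' UGUAA motif, so scanning is sense-strand only: the caller supplies the
#' strand-oriented sequence (RNA `U` is mapped to `T` on load) and all
#' overlapping occurrences are returned.
#'
#' @param sequence DNA (or RNA) string.
#' @param motif Motif to search for, default `"TGTAA"` (DNA form of UGUAA).
#' @return Integer vector of 1-based start positions, ascending.
#' @examples
#' scan_motif("TGTAATGTAA")  # 1, 6
#' @export
scan_motif <- function(sequence, motif = "TGTAA") {
  if (nchar(motif) == 0) stop("motif must be non-empty")
  s <- check_dna(sequence)
  motif <- check_dna(motif, "motif")
  if (nchar(s) < nchar(motif)) return(integer(0))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(s))
  sort(Biostrings::start(hits))
}

#' Trim a terminator part to end a fixed tail after the poly(A) motif
#'
#' Returns the prefix of `sequence` ending `tail` bp after the end of the
#' last motif occurrence that still leaves room for the full tail (the rule
#' used to shorten the photosystem-I-subunit terminator part: keep the UGUAA
#' motif plus a further 33 bp). If no occurrence leaves `tail` bp, the last
#' occurrence is used, the available shorter tail is kept and a warning is
#' issued.
#'
#' @param sequence DNA string containing the motif at least once.
#' @param motif Motif, default `"TGTAA"`.
#' @param tail Bases to retain after the motif end (default 33).
#' @return The trimmed sequence (character).
#' @export
trim_to_motif <- function(sequence, motif = "TGTAA", tail = 33) {
  stopifnot(tail >= 0)
  s <- check_dna(sequence)
  hits <- scan_motif(s, motif)
  if (length(hits) == 0) stop("motif ", motif, " not found in sequence")
  ends <- hits + nchar(motif) - 1
  ok <- ends[ends + tail <= nchar(s)]
  if (length(ok) > 0) {
    substr(s, 1, max(ok) + tail)
  } else {
    warning(sprintf("no motif occurrence leaves a %d-bp tail; keeping %d bp after the last motif",
                    tail, nchar(s) - max(ends)))
    s
  }
}

#' Find restriction sites on both strands
#'
#' Minus-strand sites are reported at their plus-strand coordinates via the
#' reverse-complemented recognition sequence; palindromic recognition sites
#' are reported once, on the plus strand.
#'
#' @param sequence DNA string.
#' @param enzymes Enzyme table rows (default [moclo_enzymes()]).
#' @return Data frame `enzyme`, `position` (1-based start of the recognition
#'   match on the plus strand), `strand`, sorted by position.
#' @examples
#' find_sites("AAGGTCTCAA")  # BsaI at 3, + strand
#' find_sites("TTGAGACCTT")  # BsaI at 3, - strand
#' @export
find_sites <- function(sequence, enzymes = moclo_enzymes()) {
  s <- check_dna(sequence)
  subject <- Biostrings::DNAString(s)
  rows <- lapply(seq_len(nrow(enzymes)), function(i) {
    rec <- enzymes$recognition[i]
    plus <- if (nchar(s) >= nchar(rec)) {
      Biostrings::start(Biostrings::matchPattern(rec, subject))
    } else integer(0)
    rc <- revcomp(rec)
    minus <- if (rc != rec && nchar(s) >= nchar(rc)) {
      Biostrings::start(Biostrings::matchPattern(rc, subject))
    } else integer(0)
    data.frame(
      enzyme = rep(enzymes$name[i], length(plus) + length(minus)),
      position = c(plus, minus),
      strand = c(rep("+", length(plus)), rep("-", length(minus))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a TerminatorPart
#'
#' A candidate terminator: the strand-oriented (sense) sequence of a gene's
#' 3' UTR, with its size class, poly(A)-motif positions, expression rank and
#' domestication state.
#'
#' @param name Part name.
#' @param sequence Sense-strand DNA sequence.
#' @param source_gene Gene id the part derives from.
#' @param rank Expression rank of the source gene, or `NA`.
#' @param motif Poly(A) motif used for annotation (default `"TGTAA"`).
#' @return A `TerminatorPart` (list with `name`, `source_gene`, `sequence`,
#'   `length`, `size_class`, `motif_hits`, `rank`, `domesticated`,
#'   `mutations`).
#' @export
terminator_part <- function(name, sequence, source_gene = NA_character_,
                            rank = NA_integer_, motif = "TGTAA") {
  s <- check_dna(sequence)
  structure(
    list(name = name, source_gene = source_gene, sequence = s,
         length = nchar(s),
         size_class = as.character(classify_length(nchar(s))),
         motif_hits = scan_motif(s, motif),
         motif = motif,
         rank = rank,
         domesticated = FALSE,
         mutations = data.frame(position = integer(), from = character(),
                                to = character(), stringsAsFactors = FALSE)),
    class = "TerminatorPart"
  )
}

#' @export
print.TerminatorPart <- function(x, ...) {
  cat(sprintf("TerminatorPart %s (%s): %d bp, class %s, %d %s motif(s), rank %s%s\n",
              x$name, x$source_gene, x$length, x$size_class,
              length(x$motif_hits), x$motif,
              ifelse(is.na(x$rank), "NA", x$rank),
              if (x$domesticated) sprintf(", domesticated (%d edit(s))",
                                          nrow(x$mutations)) else ""))
  invisible(x)
}

# ordered substitution candidates: transversions first (the bigger chemical
# change is less likely to recreate a related site), then the transition
substitution_candidates <- function(base) {
  switch(base,
         A = c("C", "T", "G"),
         G = c("C", "T", "A"),
         C = c("A", "G", "T"),
         T = c("A", "G", "C"),
         stop("invalid base ", base))
}

#' Remove type-IIS recognition sites from a part (domestication)
#'
#' Repeatedly scans the part for recognition sites of the given enzymes on
#' both strands and removes each with a single substitution inside the
#' recognition footprint: the leftmost position not covered by a protected
#' interval, preferring a transversion there. An edit is only accepted if it
#' destroys the site without creating a new site of any listed enzyme. By
#' default the part's poly(A)-motif occurrences are protected.
#'
#' @param part A `TerminatorPart`.
#' @param enzymes Enzyme table rows (default [moclo_enzymes()]).
#' @param protected Data frame of 1-based inclusive intervals `start`, `end`
#'   that must not be edited. Default: every motif occurrence of the part.
#' @return The domesticated `TerminatorPart` with `domesticated = TRUE` and
#'   its `mutations` log filled in. A part with no sites is returned with an
#'   empty log (idempotent).
#' @export
domesticate <- function(part, enzymes = moclo_enzymes(), protected = NULL) {
  stopifnot(inherits(part, "TerminatorPart"))
  if (is.null(protected)) {
    protected <- data.frame(start = part$motif_hits,
                            end = part$motif_hits + nchar(part$motif) - 1)
  }
  is_protected <- function(pos) {
    nrow(protected) > 0 && any(pos >= protected$start & pos <= protected$end)
  }
  site_key <- function(sites) {
    if (nrow(sites) == 0) character(0)
    else paste(sites$enzyme, sites$position, sites$strand)
  }

  seq_chars <- strsplit(part$sequence, "")[[1]]
  mutations <- part$mutations
  for (iter in seq_len(1000)) {
    sites <- find_sites(paste(seq_chars, collapse = ""), enzymes)
    if (nrow(sites) == 0) break
    site <- sites[1, ]
    rec_len <- nchar(enzymes$recognition[match(site$enzyme, enzymes$name)])
    footprint <- site$position:(site$position + rec_len - 1)
    old_keys <- site_key(sites)
    fixed <- FALSE
    for (pos in footprint) {
      if (is_protected(pos)) next
      for (b in substitution_candidates(seq_chars[pos])) {
        trial <- seq_chars
        trial[pos] <- b
        new_sites <- find_sites(paste(trial, collapse = ""), enzymes)
        new_keys <- site_key(new_sites)
        destroyed <- !(paste(site$enzyme, site$position, site$strand) %in% new_keys)
        no_new <- all(new_keys %in% old_keys)
        if (destroyed && no_new) {
          mutations <- rbind(mutations, data.frame(
            position = pos, from = seq_chars[pos], to = b,
            stringsAsFactors = FALSE))
          seq_chars <- trial
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) {
      stop(sprintf("no legal single-substitution edit for %s site at position %d (%s strand); site may be fully protected",
                   site$enzyme, site$position, site$strand))
    }
  }
  part$sequence <- paste(seq_chars, collapse = "")
  part$motif_hits <- scan_motif(part$sequence, part$motif)
  part$mutations <- mutations
  part$domesticated <- TRUE
  part
}

#' Construct an AssemblyPart for Golden Gate simulation
#'
#' A part's sequence begins with its 4-nt upstream fusion site (overhang)
#' and ends with its 4-nt downstream fusion site; consecutive parts in a
#' valid assembly share identical overhangs at each junction.
#'
#' @param sequence DNA string of length >= 8.
#' @param role One of `promoter`, `utr5`, `intron`, `cds`, `terminator`,
#'   `backbone`.
#' @param upstream_overhang,downstream_overhang Optional 4-nt overrides;
#'   default: the first/last 4 nt of `sequence` (which they must equal).
#' @return An `AssemblyPart` list.
#' @export
assembly_part <- function(sequence, role,
                          upstream_overhang = NULL, downstream_overhang = NULL) {
  role <- match.arg(role, c("promoter", "utr5", "intron", "cds",
                            "terminator", "backbone"))
  s <- check_dna(sequence)
  if (nchar(s) < 8) stop("assembly parts need >= 8 bp (two 4-nt overhangs)")
  up <- if (is.null(upstream_overhang)) substr(s, 1, 4) else check_dna(upstream_overhang)
  dn <- if (is.null(downstream_overhang)) substr(s, nchar(s) - 3, nchar(s)) else check_dna(downstream_overhang)
  if (nchar(up) != 4 || nchar(dn) != 4) stop("overhangs must be 4 nt")
  if (substr(s, 1, 4) != up || substr(s, nchar(s) - 3, nchar(s)) != dn) {
    stop("sequence must begin/end with its declared overhangs")
  }
  structure(list(sequence = s, role = role,
                 upstream_overhang = up, downstream_overhang = dn),
            class = "AssemblyPart")
}

#' Simulate a one-pot Golden Gate assembly into a circular plasmid
#'
#' Checks the fusion-site chain (each consecutive pair of parts shares an
#' overhang; the last part closes onto the backbone and the backbone back
#' onto the first part) and that no overhang is reused at two junctions,
#' which would make the one-pot ligation ambiguous. Each shared overhang is
#' counted once in the circular product.
#'
#' @param parts List of `AssemblyPart`s in assembly order.
#' @param backbone An `AssemblyPart` with role `backbone`.
#' @return An `AssemblyProduct`: list with the circular `sequence` (written
#'   starting at the first part's upstream overhang), `junction_starts`
#'   (1-based start of each junction overhang on the circle, one per part
#'   plus the backbone) and the input parts; supports [digest_assembly()].
#' @export
simulate_assembly <- function(parts, backbone) {
  stopifnot(length(parts) >= 1,
            all(vapply(parts, inherits, logical(1), "AssemblyPart")),
            inherits(backbone, "AssemblyPart"))
  all_parts <- c(parts, list(backbone))
  n <- length(all_parts)
  for (i in seq_len(n)) {
    a <- all_parts[[i]]
    b <- all_parts[[if (i == n) 1 else i + 1]]
    if (a$downstream_overhang != b$upstream_overhang) {
      stop(sprintf("overhang mismatch at junction %s->%s: %s vs %s",
                   a$role, b$role, a$downstream_overhang, b$upstream_overhang))
    }
  }
  junction_overhangs <- vapply(all_parts, `[[`, character(1), "downstream_overhang")
  dup <- junction_overhangs[duplicated(junction_overhangs)]
  if (length(dup) > 0) {
    stop("overhang used at more than one junction (ambiguous assembly): ",
         paste(unique(dup), collapse = ", "))
  }
  starts <- integer(n)
  seqs <- character(n)
  pos <- 1L
  for (i in seq_len(n)) {
    # part i's upstream overhang is already on the growing strand (it is the
    # previous part's downstream overhang), 4 bp before the appended body
    starts[i] <- if (i == 1) 1L else pos - 4L
    body <- if (i == 1) all_parts[[i]]$sequence
            else substr(all_parts[[i]]$sequence, 5, nchar(all_parts[[i]]$sequence))
    seqs[i] <- body
    pos <- pos + nchar(body)
  }
  linear <- paste(seqs, collapse = "")
  # the backbone's downstream overhang equals the first part's upstream
  # overhang, already present at position 1: drop the duplicate
  circ <- substr(linear, 1, nchar(linear) - 4)
  structure(list(sequence = circ, parts = all_parts,
                 junction_starts = starts, overhang_len = 4L),
            class = "AssemblyProduct")
}

#' Recover part sequences from an assembly by cutting at the junctions
#'
#' The inverse of [simulate_assembly()]: slices the circular product at the
#' recorded fusion sites, returning each input part's full sequence
#' (including both overhangs).
#'
#' @param product An `AssemblyProduct`.
#' @return Character vector of part sequences, in assembly order (parts then
#'   backbone).
#' @export
digest_assembly <- function(product) {
  stopifnot(inherits(product, "AssemblyProduct"))
  s <- product$sequence
  L <- nchar(s)
  n <- length(product$parts)
  starts <- product$junction_starts
  vapply(seq_len(n), function(i) {
    from <- starts[i]
    to <- (if (i == n) starts[1] else starts[i + 1]) + product$overhang_len - 1L
    if (to <= L && from <= to) {
      substr(s, from, to)
    } else {
      paste0(substr(s, from, L), substr(s, 1, ((to - 1L) %% L) + 1L))
    }
  }, character(1))
}

#' Locate the linearization cut and its flank on a circular plasmid
#'
#' Scans the circular plasmid (both strands, wrap-around included) for the
#' enzyme's recognition site. If the enzyme cuts exactly once and outside
#' the expression cassette, the flank is the shorter circular distance (bp
#' strictly between) from the cut to the nearest cassette boundary — the
#' stretch of vector DNA left protecting that cassette end after
#' linearization.
#'
#' @param plasmid Circular DNA string.
#' @param enzyme One row of [enzyme_table()] (or its name).
#' @param cassette Length-2 integer vector `c(start, end)`, 1-based
#'   inclusive on the plasmid.
#' @return List `is_unique`, `n_sites`, `cut_position` (1-based position of
#'   the first base after the top-strand cut; `NA` unless unique),
#'   `in_cassette`, `flank_bp` (`NA` unless unique and outside).
#' @export
linearization_flank <- function(plasmid, enzyme, cassette) {
  if (is.character(enzyme) && length(enzyme) == 1) {
    enzyme <- enzyme_table(enzyme)
  }
  stopifnot(length(cassette) == 2, cassette[1] >= 1, cassette[2] >= cassette[1])
  s <- check_dna(plasmid)
  L <- nchar(s)
  if (cassette[2] > L) stop("cassette interval exceeds plasmid length")
  rec <- enzyme$recognition
  k <- nchar(rec)
  # wrap k-1 bases so sites spanning the origin are seen once
  ext <- paste0(s, substr(s, 1, k - 1))
  hits <- find_sites(ext, enzyme)
  hits <- hits[hits$position <= L, , drop = FALSE]
  n_sites <- nrow(hits)
  if (n_sites == 0) stop("enzyme ", enzyme$name, " has no site on the plasmid")
  if (n_sites > 1) {
    return(list(is_unique = FALSE, n_sites = n_sites, cut_position = NA,
                in_cassette = NA, flank_bp = NA))
  }
  cut0 <- if (!enzyme$type_iis) {
    hits$position - 1L + enzyme$cut_offset_top
  } else if (hits$strand == "+") {
    hits$position - 1L + k + enzyme$cut_offset_top
  } else {
    # recognition on the bottom strand: the top-strand cut lies upstream of
    # the site by the enzyme's bottom-strand offset
    hits$position - 1L - enzyme$cut_offset_bottom
  }
  cut <- (cut0 %% L) + 1L  # first base after the top-strand cut
  inside <- cut > cassette[1] && cut <= cassette[2]
  if (inside) {
    return(list(is_unique = TRUE, n_sites = 1L, cut_position = cut,
                in_cassette = TRUE, flank_bp = NA))
  }
  gap <- function(a, b) (b - a - 1) %% L  # bases strictly between a and b on the circle
  flank <- min(gap(cassette[2], cut), gap(cut, cassette[1]))
  list(is_unique = TRUE, n_sites = 1L, cut_position = cut,
       in_cassette = FALSE, flank_bp = flank)
}

#' Select terminator-part candidates from gene models, genome and ranks
#'
#' Applies the screen's selection rules: the source gene must pass the
#' expression-rank filter (default: among the 350 most expressed, plus
#' explicit exceptions), its annotated 3' UTR must not exceed `max_len`
#' (default 1000 bp, to keep parts compatible with modular cloning), and the
#' extracted, strand-oriented 3' UTR sequence must carry at least one
#' poly(A) motif. Minus-strand genes are reverse-complemented so every part
#' reads in the sense direction.
#'
#' @param models A `GeneModelSet`.
#' @param genome A named `DNAStringSet` (or path to a FASTA file) covering
#'   all model chromosomes.
#' @param ranks A `RankTable`, or `NULL` to skip the rank filter.
#' @param max_rank,exceptions Passed to [rank_filter()] when `ranks` is
#'   supplied.
#' @param max_len Maximum 3' UTR length in bp.
#' @param motif Required poly(A) motif (default `"TGTAA"`).
#' @param extend_3prime Extra genomic bases to append past the annotated UTR
#'   end (in the sense direction); default 0.
#' @return List of `TerminatorPart`s, ordered by gene id (input-order
#'   invariant).
#' @export
select_candidates <- function(models, genome, ranks = NULL,
                              max_rank = 350, exceptions = character(),
                              max_len = 1000, motif = "TGTAA",
                              extend_3prime = 0) {
  stopifnot(inherits(models, "GeneModelSet"))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  g <- models$genes[models$genes$has_utr3, , drop = FALSE]
  if (nrow(g) == 0) return(list())
  missing_chrom <- setdiff(unique(g$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    stop("chromosome(s) missing from FASTA: ", paste(missing_chrom, collapse = ", "))
  }
  if (!is.null(ranks)) {
    keep <- rank_filter(ranks, max_rank, exceptions)
    g <- g[g$gene_id %in% keep, , drop = FALSE]
  }
  g <- g[g$utr3_length <= max_len, , drop = FALSE]
  g <- g[order(g$gene_id), , drop = FALSE]
  parts <- list()
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    seq <- extract_utr3_sequence(models, genome, gid, extend_3prime)
    if (length(scan_motif(seq, motif)) == 0) next
    rk <- if (is.null(ranks)) NA_integer_ else {
      m <- match(gid, ranks$gene_id)
      if (is.na(m)) NA_integer_ else ranks$rank[m]
    }
    parts[[gid]] <- terminator_part(name = paste0("t", gid), sequence = seq,
                                    source_gene = gid, rank = rk, motif = motif)
  }
  unname(parts[order(names(parts))])
}

# sense-oriented 3' UTR sequence of one gene; intervals concatenated in
# genomic order then reverse-complemented for minus-strand genes
extract_utr3_sequence <- function(models, genome, gene_id, extend_3prime = 0) {
  f <- models$features
  u <- f[f$gene_id == gene_id & f$kind == "utr3", , drop = FALSE]
  if (nrow(u) == 0) stop("gene ", gene_id, " has no annotated 3' UTR")
  u <- u[order(u$start), , drop = FALSE]
  strand <- u$strand[1]
  chrom_seq <- genome[[u$chrom[1]]]
  if (extend_3prime > 0) {
    if (strand == "+") {
      u$end[nrow(u)] <- min(u$end[nrow(u)] + extend_3prime, length(chrom_seq))
    } else {
      u$start[1] <- max(u$start[1] - extend_3prime, 1)
    }
  }
  pieces <- vapply(seq_len(nrow(u)), function(i) {
    as.character(Biostrings::subseq(chrom_seq, u$start[i], u$end[i]))
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

#' Export terminator parts to FASTA
#' @param parts List of `TerminatorPart`s.
#' @param path Output FASTA path.
#' @export
write_parts_fasta <- function(parts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(parts, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(parts, `[[`, character(1), "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Tabulate a list of terminator parts
#' @param parts List of `TerminatorPart`s.
#' @return Data frame `name`, `source_gene`, `length`, `size_class`,
#'   `rank`, `n_motifs`, `domesticated`, `n_mutations`.
#' @export
parts_table <- function(parts) {
  if (length(parts) == 0) {
    return(data.frame(name = character(), source_gene = character(),
                      length = integer(), size_class = character(),
                      rank = integer(), n_motifs = integer(),
                      domesticated = logical(), n_mutations = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    name = vapply(parts, `[[`, character(1), "name"),
    source_gene = vapply(parts, `[[`, character(1), "source_gene"),
    length = vapply(parts, `[[`, numeric(1), "length"),
    size_class = vapply(parts, `[[`, character(1), "size_class"),
    rank = vapply(parts, function(p) as.integer(p$rank), integer(1)),
    n_motifs = vapply(parts, function(p) length(p$motif_hits), integer(1)),
    domesticated = vapply(parts, `[[`, logical(1), "domesticated"),
    n_mutations = vapply(parts, function(p) nrow(p$mutations), integer(1)),
    stringsAsFactors = FALSE
  )
}
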