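# XPPX stall-motif scanning over amino-acid sequences.

# 20 standard residues plus 'X' for an unknown residue. 'X' may occupy the
# flanking slots of an XPPX window but never counts as proline.
AA_ALPHABET_STR <- "ACDEFGHIKLMNPQRSTVWYX"

#' Validate a protein sequence against the allowed amino-acid alphabet
#'
#' @param sequence Uppercase amino-acid string.
#' @param id Protein identifier, used in error messages.
#' @return Invisibly, the sequence.
#' @keywords internal
check_sequence <- function(sequence, id = "<unnamed>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) < 1L) {
    stop("protein '", id, "': sequence must be a non-empty string",
         call. = FALSE)
  }
  bad <- regexpr(sprintf("[^%s]", AA_ALPHABET_STR), sequence)
  if (bad != -1L) {
    stop("protein '", id, "': invalid residue '",
         substr(sequence, bad, bad), "' at position ", as.integer(bad),
         call. = FALSE)
  }
  invisible(sequence)
}

empty_hits <- function() {
  data.frame(protein_id = character(), position = integer(),
             motif = character(), kind = character(),
             stringsAsFactors = FALSE)
}

#' Scan one protein for XPPX diproline motifs
#'
#' An XPPX motif is any in-bounds window of four residues whose middle two
#' residues are both proline. Elongation factor P (EF-P) relieves ribosome
#' stalling at such diproline sites, so proteins carrying the motif are the
#' candidate substrates for EF-P-dependent translational control.
#'
#' Overlapping windows are all reported, so a polyproline tract of n >= 3
#' prolines yields one hit per window. A proline pair at the absolute N- or
#' C-terminus has no flanking residue inside the sequence and is not
#' reported: the pattern requires four in-bounds residues. `position` is the
#' 1-based index of the window's first residue (the leading X), which
#' matches the convention of quoting a four-letter motif starting at a
#' stated codon (e.g. the RpoB motif EPPT at codon 244).
#'
#' @param sequence Uppercase amino-acid string (20 standard letters plus X).
#' @param id Protein identifier copied into the result.
#' @return A data frame with columns `protein_id`, `position` (1-based,
#'   ascending), `motif` (the 4-letter window), and `kind` (`"xppx"`).
#' @examples
#' scan_xppx("APPV")            # one hit at position 1
#' scan_xppx("APPPA")           # overlapping hits at positions 1 and 2
#' scan_xppx("MAAAA")           # no proline pair: zero rows
#' @export
scan_xppx <- function(sequence, id = "protein") {
  check_sequence(sequence, id)
  m <- gregexpr("(?=.PP.)", sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(empty_hits())
  }
  pos <- as.integer(m)
  data.frame(protein_id = rep(id, length(pos)),
             position = pos,
             motif = substring(sequence, pos, pos + 3L),
             kind = rep("xppx", length(pos)),
             stringsAsFactors = FALSE)
}

#' Scan one protein for non-canonical stall triplets
#'
#' Besides diproline XPPX sites, EF-P also relieves stalling at some
#' single-proline triplets (IPI, KPG, and DPG in *B. subtilis*). This scan
#' reports every occurrence of any supplied triplet. Occurrences may
#' overlap; each is reported. The `motif` column holds the matched
#' three-letter triplet unpadded; `kind` distinguishes these hits from
#' four-letter XPPX windows.
#'
#' @param sequence Uppercase amino-acid string.
#' @param id Protein identifier copied into the result.
#' @param triplets Character vector of 3-letter uppercase triplets. An empty
#'   set returns zero rows.
#' @return A data frame with columns `protein_id`, `position` (1-based index
#'   of the triplet's first residue, ascending), `motif`, and `kind`
#'   (`"noncanonical"`).
#' @examples
#' scan_noncanonical("MIPIK", triplets = "IPI")
#' scan_noncanonical("DPGDPG", triplets = "DPG")
#' @export
scan_noncanonical <- function(sequence, id = "protein",
                              triplets = c("IPI", "KPG", "DPG")) {
  check_sequence(sequence, id)
  triplets <- unique(as.character(triplets))
  if (length(triplets) == 0L) {
    return(empty_hits())
  }
  ok <- grepl("^[A-Z]{3}$", triplets)
  if (!all(ok)) {
    stop("triplets must be 3 uppercase letters; offending: ",
         paste(triplets[!ok], collapse = ", "), call. = FALSE)
  }
  pos <- integer(0)
  mot <- character(0)
  for (tp in triplets) {
    m <- gregexpr(sprintf("(?=%s)", tp), sequence, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      pos <- c(pos, as.integer(m))
      mot <- c(mot, rep(tp, length(m)))
    }
  }
  if (length(pos) == 0L) {
    return(empty_hits())
  }
  o <- order(pos, mot)
  data.frame(protein_id = rep(id, length(pos)),
             position = pos[o],
             motif = mot[o],
             kind = rep("noncanonical", length(pos)),
             stringsAsFactors = FALSE)
}

#' Scan a whole proteome and flag XPPX-bearing proteins
#'
#' @param proteome A data frame with columns `id` and `sequence` (and
#'   optionally `gene`), e.g. from [read_proteome_fasta()] or
#'   [generate_proteome()]. Identifiers must be unique.
#' @return A list of class `motif_table` with elements:
#'   \describe{
#'     \item{flags}{data frame `protein_id`, `has_xppx`, `n_hits`, one row
#'       per protein in input order.}
#'     \item{hits}{data frame of all XPPX hits (see [scan_xppx()]).}
#'   }
#' A protein "has the motif" iff it has at least one XPPX hit.
#' @export
proteome_motif_table <- function(proteome) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  dup <- duplicated(proteome$id)
  if (any(dup)) {
    stop("duplicate protein ids: ",
         paste(unique(proteome$id[dup]), collapse = ", "), call. = FALSE)
  }
  hits <- lapply(seq_len(nrow(proteome)), function(i) {
    scan_xppx(proteome$sequence[i], proteome$id[i])
  })
  n_hits <- vapply(hits, nrow, integer(1))
  hits <- do.call(rbind, c(list(empty_hits()), hits))
  rownames(hits) <- NULL
  structure(list(
    flags = data.frame(protein_id = proteome$id,
                       has_xppx = n_hits > 0L,
                       n_hits = n_hits,
                       stringsAsFactors = FALSE),
    hits = hits
  ), class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat("motif_table:", nrow(x$flags), "proteins,",
      sum(x$flags$has_xppx), "with >=1 XPPX motif,",
      nrow(x$hits), "hits total\n")
  invisible(x)
}

#' Read a proteome from a multi-FASTA of amino-acid sequences
#'
#' The header token up to the first whitespace is the protein id; a
#' `gene=<name>` key anywhere in the description is parsed as the gene name,
#' which otherwise defaults to the id. Sequences are uppercased.
#'
#' @param path Path to an (uncompressed or gzipped) amino-acid FASTA file.
#' @return Data frame with columns `id`, `gene`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  gene <- ifelse(grepl("gene=(\\S+)", headers),
                 sub(".*gene=(\\S+).*", "\\1", headers),
                 ids)
  out <- data.frame(id = ids, gene = gene,
                    sequence = toupper(as.character(aa)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  for (i in seq_len(nrow(out))) check_sequence(out$sequence[i], out$id[i])
  if (anyDuplicated(out$id)) {
    stop("duplicate protein ids in ", path, call. = FALSE)
  }
  out
}

#' Write motif hits as TSV
#'
#' Columns: protein_id, position (1-based index of the motif's first
#' residue), motif, kind.
#'
#' @param hits A hits data frame, or a `motif_table` (its `hits` element is
#'   written).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motif_table <- function(hits, path) {
  if (inherits(hits, "motif_table")) hits <- hits$hits
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
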