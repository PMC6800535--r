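# In-silico tryptic digestion with conjugation-blocked lysines. Trypsin
# cleaves C-terminal to K and R (not before proline); a lysine carrying a
# drug-linker is no longer a substrate, so conjugation merges the flanking
# peptides and changes the peptide map.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Protein sequence
#'
#' @param id Sequence identifier.
#' @param residues One-letter amino-acid string (20 standard letters).
#' @return A `protein_sequence` object.
#' @export
protein_sequence <- function(id, residues) {
  residues <- toupper(gsub("[[:space:]]", "", residues))
  ch <- strsplit(residues, "")[[1L]]
  bad <- which(!ch %in% AA_LETTERS)
  if (length(bad))
    stop_arg("non-standard residue \"%s\" at position %d in %s",
             ch[bad[1L]], bad[1L], id)
  structure(list(id = as.character(id), residues = residues),
            class = "protein_sequence")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return List of [protein_sequence()] objects.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    protein_sequence(names(set)[i], as.character(set[[i]])))
  setNames(out, vapply(out, `[[`, "", "id"))
}

#' Tryptic digest with blocked lysines
#'
#' Cleaves C-terminal to every K and R except when the next residue is
#' proline, and except at blocked (conjugated) lysine positions. Zero
#' missed cleavages. Positions are 1-based indices into the residue string.
#'
#' @param seq A [protein_sequence()] (or a bare residue string).
#' @param blocked_positions Integer vector of 1-based positions of
#'   conjugated lysines; each must index a K.
#' @return A `digest_result` data frame with columns `start`, `end`,
#'   `sequence` and `blocked_sites` (list column of blocked positions each
#'   peptide contains), plus attribute `parent` (the input string).
#' @export
#' @examples
#' tryptic_digest(protein_sequence("x", "AAKAARAA"))$sequence
#' # "AAK" "AAR" "AA"
#' tryptic_digest(protein_sequence("x", "AAKAARAA"), 3)$sequence
#' # "AAKAAR" "AA"
tryptic_digest <- function(seq, blocked_positions = integer()) {
  if (is.character(seq)) seq <- protein_sequence("seq", seq)
  stopifnot(inherits(seq, "protein_sequence"))
  ch <- strsplit(seq$residues, "")[[1L]]
  n <- length(ch)
  blocked_positions <- as.integer(blocked_positions)
  if (length(blocked_positions)) {
    if (any(blocked_positions < 1L | blocked_positions > n))
      stop_arg("blocked position %d outside sequence 1..%d",
               blocked_positions[which(blocked_positions < 1L |
                                         blocked_positions > n)][1L], n)
    not_k <- blocked_positions[ch[blocked_positions] != "K"]
    if (length(not_k))
      stop_arg("blocked position %d is \"%s\", not a lysine",
               not_k[1L], ch[not_k[1L]])
  }
  is_site <- (ch == "R" | (ch == "K" & !seq_len(n) %in% blocked_positions)) &
    c(ch[-1L] != "P", FALSE)   # last residue never a cleavage site
  cut_after <- which(is_site)
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  keep <- starts <= ends       # guards a terminal K/R producing no tail
  starts <- starts[keep]; ends <- ends[keep]
  peptides <- substring(seq$residues, starts, ends)
  blocked_in <- lapply(seq_along(starts), function(i)
    blocked_positions[blocked_positions >= starts[i] &
                        blocked_positions <= ends[i]])
  structure(data.frame(start = starts, end = ends, sequence = peptides,
                       blocked_sites = I(blocked_in)),
            parent = seq$residues, parent_id = seq$id,
            class = c("digest_result", "data.frame"))
}

#' Compare two digests of the same protein
#'
#' Lists the peptides present in exactly one digest (as (start, end,
#' sequence) intervals) and, for each peptide gained in the modified
#' digest, the blocked sites that explain the merge.
#'
#' @param unmodified Digest of the unconjugated protein.
#' @param modified Digest of the conjugated protein (blocked lysines).
#' @return A `map_difference` list with data frames `lost` (peptides only
#'   in the unmodified map) and `gained` (only in the modified map, with a
#'   `blocked_sites` column), and `n_differences`.
#' @export
compare_maps <- function(unmodified, modified) {
  stopifnot(inherits(unmodified, "digest_result"),
            inherits(modified, "digest_result"))
  if (nchar(attr(unmodified, "parent")) != nchar(attr(modified, "parent")))
    stop_arg("digests come from parents of different lengths (%d vs %d)",
             nchar(attr(unmodified, "parent")),
             nchar(attr(modified, "parent")))
  key <- function(d) paste(d$start, d$end, d$sequence)
  lost <- unmodified[!key(unmodified) %in% key(modified), , drop = FALSE]
  gained <- modified[!key(modified) %in% key(unmodified), , drop = FALSE]
  rownames(lost) <- rownames(gained) <- NULL
  structure(list(lost = as.data.frame(lost)[c("start", "end", "sequence")],
                 gained = as.data.frame(gained),
                 n_differences = nrow(lost) + nrow(gained)),
            class = "map_difference")
}

#' @export
print.map_difference <- function(x, ...) {
  if (x$n_differences == 0L) {
    cat("<map_difference> maps identical\n")
  } else {
    cat(sprintf("<map_difference> %d peptides lost, %d gained\n",
                nrow(x$lost), nrow(x$gained)))
    for (i in seq_len(nrow(x$gained)))
      cat(sprintf("  + %s (%d-%d; blocked at %s)\n",
                  x$gained$sequence[i], x$gained$start[i], x$gained$end[i],
                  paste(x$gained$blocked_sites[[i]], collapse = ",")))
  }
  invisible(x)
}

#' Write a digest as a peptide table CSV
#'
#' @param digest A `digest_result`.
#' @param path Output CSV (columns start, end, sequence, blocked_sites).
#' @return `path`, invisibly.
#' @export
write_digest_csv <- function(digest, path) {
  df <- data.frame(start = digest$start, end = digest$end,
                   sequence = digest$sequence,
                   blocked_sites = vapply(digest$blocked_sites,
                                          paste, "", collapse = ";"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
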