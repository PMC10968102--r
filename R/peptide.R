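#' Construct an annotated peptide sequence
#'
#' A `peptide_sequence` holds an ordered vector of one-letter residue codes plus
#' the chemical annotations needed by the descriptor calculators: terminal
#' modifications, disulfide connectivity and uniform 15N labelling.
#'
#' @param residues character scalar (e.g. `"SPRVC..."`) or character vector of
#'   one-letter codes; only the 20 canonical residues are allowed.
#' @param id text label for the peptide.
#' @param c_terminal_amide logical; `TRUE` when the C-terminus is amidated.
#' @param n_terminal_free_amine logical; `FALSE` for e.g. acylated N-termini.
#' @param disulfide_pairs list of integer pairs (1-based residue indices); every
#'   index must point at a Cys and each Cys may appear in at most one pair.
#' @param label_n15 logical; `TRUE` when all nitrogens are 15N.
#' @param min_length minimum accepted length (default 2). Exposed so that unit
#'   tests can construct single-residue fragments.
#' @return an object of class `peptide_sequence`.
#' @examples
#' capitellacin <- peptide_sequence("SPRVCIRVCRNGVCYRRCWG", id = "capitellacin",
#'                                  disulfide_pairs = list(c(5, 18), c(9, 14)))
#' @export
peptide_sequence <- function(residues, id = "peptide",
                             c_terminal_amide = FALSE,
                             n_terminal_free_amine = TRUE,
                             disulfide_pairs = list(),
                             label_n15 = FALSE,
                             min_length = 2L) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  bad <- which(!(residues %in% .AA_LETTERS))
  if (length(bad) > 0L)
    stop(sprintf("record '%s': non-canonical residue '%s' at position %d",
                 id, residues[bad[1]], bad[1]), call. = FALSE)
  if (length(residues) < min_length)
    stop(sprintf("record '%s': sequence length %d < %d", id,
                 length(residues), min_length), call. = FALSE)
  disulfide_pairs <- lapply(disulfide_pairs, function(p) {
    p <- as.integer(p)
    if (length(p) != 2L || anyNA(p) || p[1] == p[2])
      stop(sprintf("record '%s': malformed disulfide pair", id), call. = FALSE)
    sort(p)
  })
  all_idx <- unlist(disulfide_pairs)
  if (length(all_idx) > 0L) {
    if (any(all_idx < 1L | all_idx > length(residues)))
      stop(sprintf("record '%s': disulfide index out of range", id), call. = FALSE)
    if (any(residues[all_idx] != "C"))
      stop(sprintf("record '%s': disulfide pair references a non-Cys residue", id),
           call. = FALSE)
    if (anyDuplicated(all_idx))
      stop(sprintf("record '%s': a Cys participates in more than one disulfide", id),
           call. = FALSE)
  }
  structure(list(id = id, residues = residues,
                 c_terminal_amide = isTRUE(c_terminal_amide),
                 n_terminal_free_amine = isTRUE(n_terminal_free_amine),
                 disulfide_pairs = disulfide_pairs,
                 label_n15 = isTRUE(label_n15)),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %s (%d aa)\n", x$id, length(x$residues)))
  cat(" ", paste(x$residues, collapse = ""), "\n")
  if (length(x$disulfide_pairs) > 0L)
    cat("  disulfides:",
        paste(vapply(x$disulfide_pairs, function(p) paste(p, collapse = "-"),
                     character(1)), collapse = ", "), "\n")
  if (x$c_terminal_amide) cat("  C-terminal amide\n")
  if (!x$n_terminal_free_amine) cat("  blocked N-terminus\n")
  if (x$label_n15) cat("  uniformly 15N labelled\n")
  invisible(x)
}

#' Read annotated peptide sequences from a FASTA file
#'
#' Standard FASTA, parsed with [Biostrings::readAAStringSet()]. Annotations are
#' encoded as `key=value` tokens after the record id in the header, e.g.
#' `>capitellacin ss=5-18,9-14 amide=0 n15=1 source=...`:
#' \describe{
#'   \item{`ss`}{comma-separated disulfide pairs `i-j` (1-based)}
#'   \item{`amide`}{1 for a C-terminal amide (default 0)}
#'   \item{`nfree`}{0 for a blocked N-terminus (default 1, free amine)}
#'   \item{`n15`}{1 for uniform 15N labelling (default 0)}
#' }
#' Unknown tokens are ignored, so headers may carry provenance notes.
#'
#' @param path path to a FASTA file.
#' @return a named list of [peptide_sequence] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    tokens <- strsplit(trimws(header), "\\s+")[[1]]
    id <- tokens[1]
    ann <- list(amide = FALSE, nfree = TRUE, n15 = FALSE, ss = list())
    for (tok in tokens[-1]) {
      if (!grepl("=", tok, fixed = TRUE)) next
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      key <- kv[1]; val <- kv[2]
      if (key == "amide") ann$amide <- identical(val, "1")
      else if (key == "nfree") ann$nfree <- !identical(val, "0")
      else if (key == "n15") ann$n15 <- identical(val, "1")
      else if (key == "ss") {
        pairs <- strsplit(val, ",", fixed = TRUE)[[1]]
        ann$ss <- lapply(pairs, function(p) {
          ij <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
          if (length(ij) != 2L || anyNA(ij))
            stop(sprintf("record '%s': malformed ss token '%s'", id, p),
                 call. = FALSE)
          ij
        })
      }
    }
    out[[i]] <- peptide_sequence(as.character(set[[i]]), id = id,
                                 c_terminal_amide = ann$amide,
                                 n_terminal_free_amine = ann$nfree,
                                 disulfide_pairs = ann$ss,
                                 label_n15 = ann$n15)
  }
  names(out) <- vapply(out, function(s) s$id, character(1))
  out
}
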