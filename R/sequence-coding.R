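# Conjoint-triad (CT) coding of protein sequences.
#
# The 20 canonical amino acids are grouped into seven classes by dipole and
# side-chain volume; a window of width three slides along the class-recoded
# sequence and every ordered class triad is counted, giving a fixed
# 343-dimensional descriptor per protein.

# Seven-class amino-acid alphabet. "Trp" sits in class 4 with His/Asn/Gln.
CT_CLASS <- c(
  A = 1L, G = 1L, V = 1L,
  I = 2L, L = 2L, F = 2L, P = 2L,
  Y = 3L, M = 3L, T = 3L, S = 3L,
  H = 4L, N = 4L, Q = 4L, W = 4L,
  R = 5L, K = 5L,
  D = 6L, E = 6L,
  C = 7L
)

#' Map a single amino-acid letter to its conjoint-triad class
#'
#' Classes: C1 = \{A,G,V\}, C2 = \{I,L,F,P\}, C3 = \{Y,M,T,S\},
#' C4 = \{H,N,Q,W\}, C5 = \{R,K\}, C6 = \{D,E\}, C7 = \{C\}.
#'
#' @param aa a single upper-case amino-acid letter.
#' @return integer class label in 1..7.
#' @examples
#' classify_residue("R") # 5
#' classify_residue("C") # 7
#' @export
classify_residue <- function(aa) {
  cls <- CT_CLASS[aa]
  if (anyNA(cls)) {
    bad <- aa[is.na(cls)][1L]
    stop("invalid residue '", bad, "': not one of the 20 canonical amino acids",
         call. = FALSE)
  }
  unname(cls)
}

#' Encode a protein sequence as a conjoint-triad count vector
#'
#' Slides a window of size three along the class-recoded sequence and counts
#' every ordered triad (c1, c2, c3), c in 1..7. The triad maps to flat
#' (0-based) index (c1-1)*49 + (c2-1)*7 + (c3-1); vectors are stored 1-based
#' in R, so R index = flat index + 1. For a sequence of length L over
#' canonical residues the counts sum to L - 2.
#'
#' @param sequence amino-acid string (upper case; canonical residues only).
#' @param id optional identifier used in error messages.
#' @return integer vector of length 343 with attribute `source_length`.
#' @examples
#' v <- encode_ct("AGV") # one count at flat index 0
#' sum(v)                # 1
#' @export
encode_ct <- function(sequence, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  cls <- unname(CT_CLASS[chars])
  if (anyNA(cls)) {
    pos <- which(is.na(cls))[1L]
    stop("invalid residue '", chars[pos], "' at position ", pos,
         if (!is.null(id)) paste0(" in sequence '", id, "'") else "",
         call. = FALSE)
  }
  counts <- integer(343)
  if (L >= 3L) {
    idx <- (cls[1:(L - 2)] - 1L) * 49L +
      (cls[2:(L - 1)] - 1L) * 7L +
      (cls[3:L] - 1L) + 1L
    tab <- tabulate(idx, nbins = 343L)
    counts <- as.integer(tab)
  } else {
    warning("sequence", if (!is.null(id)) paste0(" '", id, "'") else "",
            " shorter than 3 residues; returning all-zero CT vector",
            call. = FALSE)
  }
  attr(counts, "source_length") <- L
  counts
}

#' Build the N x 343 conjoint-triad feature matrix
#'
#' Row i is the CT vector of record i, in input order (the same order the
#' adjacency matrix uses). The default keeps raw triad counts, which is what
#' the CT descriptor lists and what trains the encoder most stably under
#' degree-normalized propagation; `normalize = TRUE` divides each row by its
#' sum to give triad frequencies instead (all-zero rows stay zero).
#'
#' @param records a protein record data frame (see [read_fasta()]).
#' @param normalize divide each row by its sum?
#' @return numeric matrix, rownames = protein ids.
#' @export
build_feature_matrix <- function(records, normalize = FALSE) {
  stopifnot(nrow(records) > 0L)
  if (anyDuplicated(records$id)) {
    stop("duplicate protein id: ",
         records$id[anyDuplicated(records$id)], call. = FALSE)
  }
  X <- matrix(0, nrow(records), 343L,
              dimnames = list(records$id, NULL))
  for (i in seq_len(nrow(records))) {
    X[i, ] <- tryCatch(
      encode_ct(records$sequence[i], id = records$id[i]),
      error = function(e) stop("record '", records$id[i], "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  if (normalize) {
    rs <- rowSums(X)
    nz <- rs > 0
    X[nz, ] <- X[nz, , drop = FALSE] / rs[nz]
  }
  X
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the id; sequences
#' are upper-cased. Ids must be unique.
#'
#' @param path FASTA file path.
#' @return a data frame with columns `id`, `sequence` and empty annotation
#'   columns `species` (NA), `localizations` (list of character vectors),
#'   `is_fragment` (NA); one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no sequences", call. = FALSE)
    return(protein_records(character(), character()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein id in FASTA: ", ids[anyDuplicated(ids)],
         call. = FALSE)
  }
  protein_records(ids, toupper(as.character(set)))
}

#' Construct a protein record table
#'
#' @param id character ids (unique, non-empty).
#' @param sequence amino-acid strings.
#' @param species optional species tag per record.
#' @param localizations optional list of character vectors of
#'   subcellular-localization terms.
#' @param is_fragment optional logical fragment flag.
#' @return data frame with one row per protein.
#' @export
protein_records <- function(id, sequence, species = NA_character_,
                            localizations = NULL, is_fragment = NA) {
  stopifnot(length(id) == length(sequence))
  if (length(id) && any(!nzchar(id))) stop("empty protein id", call. = FALSE)
  if (is.null(localizations)) {
    localizations <- rep(list(character()), length(id))
  }
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    species = species, is_fragment = is_fragment,
                    stringsAsFactors = FALSE)
  out$localizations <- localizations
  out
}

#' Write protein records to a FASTA file
#' @param records protein record data frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Export a feature matrix as TSV (id + 343 columns)
#' @param X feature matrix from [build_feature_matrix()].
#' @param path output path.
#' @export
write_feature_tsv <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  colnames(df) <- c("id", paste0("ct", seq_len(ncol(X)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
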