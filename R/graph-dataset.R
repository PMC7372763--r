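# Signed interaction graph construction: negative-candidate filtering,
# cross-compartment negative sampling, the signed adjacency matrix with its
# high-confidence mask, stratified splits and coverage sparsification.

AMBIGUOUS_LOC_TERMS <- c("potential", "probable", "probably", "maybe",
                         "by similarity")

#' Filter proteins eligible for negative-pair construction
#'
#' Applies the five selection criteria used to build high-confidence
#' negative pairs from localization annotation. A record is kept only if:
#' its species tag equals `species` (skipped when `species` is NULL); none
#' of its localization terms contains an ambiguous qualifier ("potential",
#' "probable", "probably", "maybe", "by similarity"); it has exactly one
#' localization term; it is not flagged as a fragment and has at least 50
#' residues; its sequence contains no nonstandard residue such as U or X.
#' Records lacking localization annotation are dropped from this pool (they
#' remain usable as graph nodes).
#'
#' @param records protein record data frame.
#' @param species required species tag, or NULL to skip the species check.
#' @param verbose log per-criterion rejection counts?
#' @return the retained subset of `records`.
#' @export
filter_negative_candidates <- function(records, species = NULL,
                                       verbose = FALSE) {
  n <- nrow(records)
  keep <- rep(TRUE, n)
  rej <- c(species = 0L, ambiguous = 0L, multi_location = 0L,
           fragment_or_short = 0L, nonstandard_residue = 0L)

  if (!is.null(species)) {
    ok <- !is.na(records$species) & records$species == species
    rej["species"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  locs <- records$localizations
  ambiguous <- vapply(locs, function(l) {
    any(vapply(AMBIGUOUS_LOC_TERMS,
               function(term) any(grepl(term, tolower(l), fixed = TRUE)),
               logical(1)))
  }, logical(1))
  rej["ambiguous"] <- sum(keep & ambiguous)
  keep <- keep & !ambiguous

  single <- lengths(locs) == 1L
  rej["multi_location"] <- sum(keep & !single)
  keep <- keep & single

  frag <- !is.na(records$is_fragment) & records$is_fragment
  short <- nchar(records$sequence) < 50L
  rej["fragment_or_short"] <- sum(keep & (frag | short))
  keep <- keep & !frag & !short

  nonstd <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", records$sequence)
  rej["nonstandard_residue"] <- sum(keep & nonstd)
  keep <- keep & !nonstd

  if (verbose) {
    message("negative-candidate filter rejections: ",
            paste(names(rej), rej, sep = "=", collapse = ", "))
  }
  records[keep, , drop = FALSE]
}

#' Construct an edge list
#' @param id_a,id_b protein id vectors (undirected pairs).
#' @param label "positive" or "high_negative" per pair.
#' @return edge-list data frame.
#' @export
edge_list <- function(id_a = character(), id_b = character(),
                      label = character()) {
  stopifnot(length(id_a) == length(id_b), length(id_a) == length(label))
  if (length(label)) stopifnot(all(label %in% c("positive", "high_negative")))
  if (any(id_a == id_b)) stop("self-pair in edge list", call. = FALSE)
  out <- data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                    label = as.character(label), stringsAsFactors = FALSE)
  key <- pair_key(out$id_a, out$id_b)
  if (anyDuplicated(key)) {
    d <- anyDuplicated(key)
    stop("duplicate unordered pair: (", out$id_a[d], ", ", out$id_b[d], ")",
         call. = FALSE)
  }
  out
}

# Canonical unordered-pair key.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Sample high-confidence negative pairs across compartments
#'
#' Pairs proteins whose (single) subcellular-localization labels differ,
#' excluding observed positive pairs, uniformly at random without
#' replacement.
#'
#' @param records filtered protein records (single localization each).
#' @param n_pairs number of negative pairs requested.
#' @param positives edge list of positive pairs to exclude.
#' @param seed RNG seed.
#' @return edge list with label "high_negative".
#' @export
generate_negative_pairs <- function(records, n_pairs, positives = NULL,
                                    seed = 1L) {
  stopifnot(n_pairs >= 1L)
  loc <- vapply(records$localizations, function(l) {
    if (length(l) != 1L) NA_character_ else l
  }, character(1))
  usable <- !is.na(loc)
  ids <- records$id[usable]
  loc <- loc[usable]
  n <- length(ids)
  if (n < 2L) stop("need at least 2 annotated proteins", call. = FALSE)
  # enumerate all cross-location unordered pairs
  idx <- which(outer(loc, loc, "!=") & upper.tri(matrix(0, n, n)),
               arr.ind = TRUE)
  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  if (!is.null(positives) && nrow(positives)) {
    drop <- pair_key(a, b) %in% pair_key(positives$id_a, positives$id_b)
    a <- a[!drop]
    b <- b[!drop]
  }
  if (length(a) < n_pairs) {
    stop("only ", length(a), " valid negative pairs exist; ", n_pairs,
         " requested", call. = FALSE)
  }
  set.seed(seed)
  pick <- sample.int(length(a), n_pairs)
  edge_list(a[pick], b[pick], rep("high_negative", n_pairs))
}

#' Build the signed adjacency matrix with its high-confidence mask
#'
#' Off-diagonal entries: +1 for observed interactions, -1 for
#' high-confidence negatives, 0 for uncertain pairs; the diagonal is +1
#' (self-loops added by the identity matrix). The confidence mask marks the
#' off-diagonal cells whose label is known (entries of the high-confidence
#' set over which the reconstruction loss is computed).
#'
#' @param ids ordered protein ids (defines node order).
#' @param edges edge list; every id must occur in `ids`.
#' @return object of class `signed_adjacency` with elements `matrix`
#'   (N x N), `mask` (N x N logical) and `node_index` (ids).
#' @export
build_signed_adjacency <- function(ids, edges) {
  n <- length(ids)
  stopifnot(!anyDuplicated(ids))
  A <- diag(1, n)
  mask <- matrix(FALSE, n, n)
  dimnames(A) <- dimnames(mask) <- list(ids, ids)
  if (nrow(edges)) {
    i <- match(edges$id_a, ids)
    j <- match(edges$id_b, ids)
    if (anyNA(i) || anyNA(j)) {
      bad <- c(edges$id_a[is.na(i)], edges$id_b[is.na(j)])[1L]
      stop("edge references unknown protein id: ", bad, call. = FALSE)
    }
    val <- ifelse(edges$label == "positive", 1, -1)
    # conflicting duplicate labels are a hard error (edge_list already
    # rejects duplicates; this guards merged lists)
    key <- pair_key(edges$id_a, edges$id_b)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      pr <- strsplit(dup, "\r", fixed = TRUE)[[1]]
      stop("conflicting labels for pair (", pr[1], ", ", pr[2], ")",
           call. = FALSE)
    }
    A[cbind(i, j)] <- val
    A[cbind(j, i)] <- val
    mask[cbind(i, j)] <- TRUE
    mask[cbind(j, i)] <- TRUE
  }
  structure(list(matrix = A, mask = mask, node_index = ids),
            class = "signed_adjacency")
}

#' @export
print.signed_adjacency <- function(x, ...) {
  off <- x$matrix
  diag(off) <- 0
  cat("signed adjacency:", length(x$node_index), "nodes,",
      sum(off == 1) / 2, "positive edges,",
      sum(off == -1) / 2, "high-confidence negative edges\n")
  invisible(x)
}

#' Hide a set of edges from a signed adjacency matrix
#'
#' Zeroes the matrix entries and the confidence mask for the given pairs.
#' Used to keep held-out test pairs out of the encoder's view so link
#' prediction is evaluated without information leak.
#'
#' @param adj `signed_adjacency`.
#' @param edges edge list of pairs to hide.
#' @return modified `signed_adjacency`.
#' @export
mask_edges <- function(adj, edges) {
  if (!nrow(edges)) return(adj)
  i <- match(edges$id_a, adj$node_index)
  j <- match(edges$id_b, adj$node_index)
  stopifnot(!anyNA(i), !anyNA(j))
  adj$matrix[cbind(i, j)] <- 0
  adj$matrix[cbind(j, i)] <- 0
  adj$mask[cbind(i, j)] <- FALSE
  adj$mask[cbind(j, i)] <- FALSE
  adj
}

#' Stratified train/test splits with cross-validation folds
#'
#' Splits labeled pairs into train and test preserving the
#' positive:negative ratio, then partitions the training pairs into
#' stratified folds. Repeated `n_repeats` times with independent derived
#' seeds.
#'
#' @param edges edge list containing both labels.
#' @param test_fraction held-out proportion (default 0.2).
#' @param n_repeats number of independent splits (default 5).
#' @param n_folds folds within each training set (default 5).
#' @param seed master seed.
#' @return list of splits; each has `train`, `test` (edge lists),
#'   `fold` (fold index per training pair) and `seed`.
#' @export
split_edges <- function(edges, test_fraction = 0.2, n_repeats = 5L,
                        n_folds = 5L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  labs <- unique(edges$label)
  if (length(labs) < 2L) stop("both labels required to stratify", call. = FALSE)
  lapply(seq_len(n_repeats), function(r) {
    sseed <- derive_seed(seed, r)
    set.seed(sseed)
    test_idx <- unlist(lapply(split(seq_len(nrow(edges)), edges$label),
                              function(ix) {
      k <- round(length(ix) * test_fraction)
      if (k < 1L || length(ix) - k < n_folds) {
        stop("too few edges to stratify", call. = FALSE)
      }
      sample(ix, k)
    }), use.names = FALSE)
    train <- edges[-test_idx, , drop = FALSE]
    test <- edges[test_idx, , drop = FALSE]
    fold <- integer(nrow(train))
    for (ix in split(seq_len(nrow(train)), train$label)) {
      fold[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
    }
    list(train = train, test = test, fold = fold, seed = sseed)
  })
}

#' Sparsify an edge list by per-protein coverage
#'
#' For each protein, independently for its positive and its high-negative
#' incident edges, retains ceiling(coverage * degree) of them (at least one
#' when the degree is nonzero), chosen uniformly at random. An edge kept in
#' either endpoint's draw is kept.
#'
#' @param edges edge list.
#' @param coverage proportion in (0, 1].
#' @param seed RNG seed.
#' @return the retained edge list.
#' @export
coverage_sample <- function(edges, coverage, seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1)
  if (coverage == 1 || !nrow(edges)) return(edges)
  set.seed(seed)
  keep <- rep(FALSE, nrow(edges))
  prots <- unique(c(edges$id_a, edges$id_b))
  for (p in prots) {
    inc <- which(edges$id_a == p | edges$id_b == p)
    for (lab in c("positive", "high_negative")) {
      ix <- inc[edges$label[inc] == lab]
      if (!length(ix)) next
      k <- max(1L, ceiling(coverage * length(ix)))
      keep[ix[sample.int(length(ix), k)]] <- TRUE
    }
  }
  edges[keep, , drop = FALSE]
}

#' Read / write edge-list TSV (`id_a  id_b  label`, label 1 or -1)
#' @param path TSV path.
#' @return edge list data frame.
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id_a", "id_b", "label"))
  if (identical(tolower(df$id_a[1]), "id_a")) df <- df[-1L, , drop = FALSE]
  lab <- ifelse(as.integer(df$label) == 1L, "positive", "high_negative")
  edge_list(df$id_a, df$id_b, lab)
}

#' @rdname read_edge_tsv
#' @param edges edge list to write.
#' @export
write_edge_tsv <- function(edges, path) {
  out <- data.frame(id_a = edges$id_a, id_b = edges$id_b,
                    label = ifelse(edges$label == "positive", 1L, -1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write annotation TSV
#' (`id  species  localizations(semicolon-separated)  fragment(0/1)`)
#' @param path TSV path.
#' @return data frame with id, species, localizations (list), is_fragment.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "species", "loc", "frag"))
  data.frame(id = df$id, species = df$species,
             is_fragment = df$frag == 1L,
             localizations = I(strsplit(df$loc, ";", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' @rdname read_annotation_tsv
#' @param records protein records with annotation columns.
#' @export
write_annotation_tsv <- function(records, path) {
  out <- data.frame(
    id = records$id,
    species = ifelse(is.na(records$species), "", records$species),
    loc = vapply(records$localizations, paste, character(1), collapse = ";"),
    frag = as.integer(!is.na(records$is_fragment) & records$is_fragment)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach annotations from an annotation table to protein records
#' @param records protein records (e.g. from [read_fasta()]).
#' @param ann annotation data frame from [read_annotation_tsv()].
#' @return records with species / localizations / is_fragment filled in.
#' @export
annotate_records <- function(records, ann) {
  m <- match(records$id, ann$id)
  hit <- !is.na(m)
  records$species[hit] <- ann$species[m[hit]]
  records$is_fragment[hit] <- ann$is_fragment[m[hit]]
  locs <- records$localizations
  locs[hit] <- ann$localizations[m[hit]]
  records$localizations <- locs
  records
}
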