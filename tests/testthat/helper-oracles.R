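# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# Seven-class lookup re-stated independently of the package's table.
oracle_class <- function(aa) {
  groups <- list(`1` = c("A", "G", "V"), `2` = c("I", "L", "F", "P"),
                 `3` = c("Y", "M", "T", "S"), `4` = c("H", "N", "Q", "W"),
                 `5` = c("R", "K"), `6` = c("D", "E"), `7` = "C")
  for (g in names(groups)) if (aa %in% groups[[g]]) return(as.integer(g))
  stop("not canonical: ", aa)
}

# Explicit window-by-window triad count.
oracle_ct <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  counts <- integer(343)
  if (length(chars) >= 3) {
    for (i in 1:(length(chars) - 2)) {
      cls <- vapply(chars[i:(i + 2)], oracle_class, integer(1))
      idx <- (cls[1] - 1) * 49 + (cls[2] - 1) * 7 + (cls[3] - 1) + 1
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

random_protein <- function(len) {
  paste(sample(c("A","G","V","I","L","F","P","Y","M","T","S","H","N","Q",
                 "W","R","K","D","E","C"), len, replace = TRUE),
        collapse = "")
}

# Dense triple-product GCN oracle.
oracle_gcn <- function(X, P, W, act = "relu") {
  out <- P %*% (X %*% W)
  if (act == "relu") out[out < 0] <- 0
  out
}

# A small labeled graph + features for encoder tests.
tiny_graph <- function(seed = 1, n = 8, f = 5) {
  set.seed(seed)
  ids <- sprintf("t%02d", 1:n)
  pairs <- t(combn(n, 2))
  lab <- sample(c("positive", "high_negative", "none"), nrow(pairs),
                replace = TRUE, prob = c(0.3, 0.2, 0.5))
  keep <- lab != "none"
  edges <- edge_list(ids[pairs[keep, 1]], ids[pairs[keep, 2]], lab[keep])
  list(ids = ids, edges = edges,
       adj = build_signed_adjacency(ids, edges),
       X = matrix(runif(n * f), n, f))
}

# A small synthetic dataset reused by several slow-ish tests.
small_dataset <- function(seed = 5, n = 120) {
  generate_dataset(synthetic_spec(n_proteins = n, seed = seed))
}
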