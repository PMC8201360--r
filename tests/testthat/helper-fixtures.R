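# Shared fixtures and independent oracles used across the suite.

random_peptide <- function(id, len, alphabet = aa_alphabet()) {
  peptide(id, paste(sample(alphabet, len, replace = TRUE), collapse = ""))
}

random_peptides <- function(n, len_range = c(5L, 30L)) {
  lapply(seq_len(n), function(i)
    random_peptide(paste0("rp", i), sample(seq(len_range[1], len_range[2]), 1L)))
}

# small abundance table: 3 peptides, 2 species, 2 replicates
tiny_abundance <- function() {
  mat <- rbind(p1 = c(1, 2, 3, 4),
               p2 = c(0, 0, 5, 6),
               p3 = c(7, 8, 0, 0))
  abundance_table(mat,
                  species = c("spA", "spA", "spB", "spB"),
                  replicate = c("1", "2", "1", "2"))
}

# brute-force pair-count oracle for dipeptide composition
oracle_dipeptide <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  aa <- aa_alphabet()
  out <- numeric(400)
  names(out) <- paste0("dp_", as.vector(t(outer(aa, aa, paste0))))
  for (i in seq_len(length(chars) - 1L)) {
    key <- paste0("dp_", chars[i], chars[i + 1L])
    out[key] <- out[key] + 1
  }
  out / (length(chars) - 1L)
}

# brute-force kNN oracle with the documented tie rules
oracle_knn <- function(train_Z, labels, query_Z, k) {
  apply(query_Z, 1L, function(q) {
    d <- sqrt(colSums((t(train_Z) - q)^2))
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(k)]
    frac <- mean(labels[nn] == 1L)
    if (frac > 0.5) return(1L)
    if (frac < 0.5) return(0L)
    at_min <- labels[nn][d[nn] == d[nn[1L]]]
    if (any(at_min == 1L) && any(at_min == 0L)) 1L else at_min[1L]
  })
}

# exhaustive minimum k-modes cost over all 2-partitions of the rows
oracle_kmodes2_cost <- function(X) {
  n <- nrow(X)
  best <- Inf
  cluster_cost <- function(rows) {
    if (length(rows) == 0L) return(Inf)
    sub <- X[rows, , drop = FALSE]
    # on a tied column either mode value gives the same mismatch count,
    # so the >= 0.5 tie-break is cost-optimal
    mode <- as.integer(colMeans(sub) >= 0.5)
    sum(sub != matrix(mode, length(rows), ncol(X), byrow = TRUE))
  }
  for (mask in 1:(2^n - 2)) {
    rows1 <- which(as.logical(intToBits(mask)[1:n]))
    rows2 <- setdiff(1:n, rows1)
    best <- min(best, cluster_cost(rows1) + cluster_cost(rows2))
  }
  best
}
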