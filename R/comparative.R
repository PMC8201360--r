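# Cross-species comparative peptidomics: presence calling, mean centering,
# ANOVA screening, core/variable partition, hierarchical and k-modes
# clustering, and correspondence analysis of pattern x species tables.

#' Call peptide presence per species
#'
#' A peptide is present in a species when the maximum intensity over that
#' species' replicates exceeds the threshold (strictly).  The default
#' threshold of 0 means any detected signal counts.
#'
#' @param a An [abundance_table()].
#' @param threshold Intensity cutoff; presence requires `max > threshold`.
#' @return An object of class `presence_matrix`: binary `presence` matrix
#'   (peptides x species), the `threshold` used, and the source table.
#' @export
call_presence <- function(a, threshold = 0) {
  species <- unique(a$species)
  pres <- vapply(species, function(s) {
    cols <- which(a$species == s)
    apply(a$intensity[, cols, drop = FALSE], 1L, max) > threshold
  }, logical(nrow(a$intensity)))
  pres <- matrix(as.integer(pres), nrow = nrow(a$intensity),
                 dimnames = list(rownames(a$intensity), species))
  structure(list(presence = pres, threshold = threshold, source = a),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix: %d peptides x %d species; %d present cells>\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Mean-center intensities per sample column
#'
#' Normalizes each sample column by subtracting the column mean computed
#' over detected peptides (intensity > 0); undetected cells stay 0.  After
#' centering, every column's mean over its detected peptides is 0.
#' Centering is idempotent.  Columns with no detected peptide are left
#' unchanged with a warning.
#'
#' @param a An [abundance_table()] or a previously centered table.
#' @return A `centered_table`: same shape as the input, with `detected`
#'   logical matrix recording which cells held signal.
#' @export
mean_center <- function(a) {
  mat <- a$intensity
  detected <- if (inherits(a, "centered_table")) a$detected else mat > 0
  for (j in seq_len(ncol(mat))) {
    det <- detected[, j]
    if (!any(det)) {
      warning("column ", colnames(mat)[j], " has no detected peptide; left unchanged")
      next
    }
    mat[det, j] <- mat[det, j] - mean(mat[det, j])
  }
  structure(list(intensity = mat, species = a$species,
                 replicate = a$replicate, detected = detected),
            class = "centered_table")
}

#' One-way ANOVA screen across species
#'
#' For each peptide, tests equality of mean intensity across species groups
#' (replicates as within-group observations) with a standard one-way ANOVA.
#' Species with fewer than 2 replicates are dropped; peptides for which
#' fewer than 2 usable groups remain are skipped with a warning.
#'
#' @param a An [abundance_table()] or `centered_table`.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with columns `peptide_id`, `f_statistic`, `p_value`,
#'   `significant`.
#' @export
anova_screen <- function(a, alpha = 0.05) {
  mat <- a$intensity
  species <- a$species
  reps_per_species <- table(species)
  usable <- names(reps_per_species)[reps_per_species >= 2L]
  if (length(usable) < length(unique(species)))
    warning("species with < 2 replicates dropped from ANOVA: ",
            paste(setdiff(unique(species), usable), collapse = ", "))
  if (length(usable) < 2L)
    stop("ANOVA needs at least 2 species with >= 2 replicates")
  keep <- species %in% usable
  g <- factor(species[keep])
  sub <- mat[, keep, drop = FALSE]
  n <- ncol(sub)
  k <- nlevels(g)
  group_means <- t(apply(sub, 1L, function(y) tapply(y, g, mean)))
  grand <- rowMeans(sub)
  ng <- as.vector(table(g))  # counts in level order
  ss_between <- rowSums(sweep(group_means, 2L, ng, function(m, w) w * m^2)) -
    n * grand^2
  ss_total <- rowSums(sub^2) - n * grand^2
  ss_within <- ss_total - ss_between
  df1 <- k - 1L
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  # degenerate rows: no within-group variance
  zero_within <- ss_within <= 1e-12 * pmax(ss_total, 1)
  f[zero_within & ss_between > 1e-12] <- Inf
  p[zero_within & ss_between > 1e-12] <- 0
  f[zero_within & ss_between <= 1e-12] <- NaN
  p[zero_within & ss_between <= 1e-12] <- NA_real_
  data.frame(peptide_id = rownames(mat),
             f_statistic = f, p_value = p,
             significant = !is.na(p) & p < alpha,
             row.names = NULL)
}

#' Partition peptides into core and variable sets
#'
#' Core peptides are present in every species; variable peptides are the
#' remaining detected peptides (present in at least one but not all
#' species).  Peptides absent everywhere are reported separately and belong
#' to neither set.
#'
#' @param m A [call_presence()] result or a binary peptides x species
#'   matrix with dimnames.
#' @return List with `core` and `variable` peptide id vectors, `undetected`
#'   ids, `species_count` (named, per peptide) and `histogram` of peptides
#'   by number of species.
#' @export
partition_core_variable <- function(m) {
  pres <- if (inherits(m, "presence_matrix")) m$presence else as.matrix(m)
  if (ncol(pres) < 1L) stop("at least one species is required")
  n_species <- ncol(pres)
  counts <- rowSums(pres > 0)
  core <- rownames(pres)[counts == n_species]
  variable <- rownames(pres)[counts > 0 & counts < n_species]
  undetected <- rownames(pres)[counts == 0]
  list(core = core, variable = variable, undetected = undetected,
       species_count = stats::setNames(as.integer(counts), rownames(pres)),
       histogram = stats::setNames(
         as.integer(table(factor(counts, levels = 0:n_species))),
         0:n_species))
}

#' Average replicate intensities per species
#'
#' @param a An [abundance_table()] or `centered_table`.
#' @return Numeric matrix, peptides x species (mean over replicates).
#' @export
average_by_species <- function(a) {
  species <- unique(a$species)
  out <- vapply(species, function(s) {
    rowMeans(a$intensity[, a$species == s, drop = FALSE])
  }, numeric(nrow(a$intensity)))
  rownames(out) <- rownames(a$intensity)
  out
}

#' Hierarchical clustering of peptides or profiles
#'
#' Agglomerative clustering via [stats::hclust()] on either Euclidean
#' distance or binary (Jaccard-complement) distance, the latter suited to
#' presence/absence profiles.
#'
#' @param x A [call_presence()] result, or a numeric matrix (rows are
#'   clustered).
#' @param linkage `"complete"` (default) or `"average"`.
#' @param distance `"euclidean"` (default) or `"binary"`.
#' @return An object of class `hclust`.
#' @export
hcluster <- function(x, linkage = c("complete", "average"),
                     distance = c("euclidean", "binary")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  mat <- if (inherits(x, "presence_matrix")) x$presence else as.matrix(x)
  if (nrow(mat) < 2L) stop("clustering needs at least 2 rows")
  stats::hclust(stats::dist(mat, method = distance), method = linkage)
}

# simple-matching dissimilarity between each row of X and each mode row
.smd <- function(X, modes) {
  # returns nrow(X) x nrow(modes) matrix of mismatch counts
  vapply(seq_len(nrow(modes)), function(j) {
    rowSums(X != matrix(modes[j, ], nrow(X), ncol(X), byrow = TRUE))
  }, numeric(nrow(X)))
}

#' k-modes clustering of binary presence profiles
#'
#' Huang-style k-modes for categorical data: rows are assigned to the mode
#' with the smallest simple-matching dissimilarity (number of differing
#' positions); each cluster's mode is then recomputed as the column-wise
#' majority value, iterating until no assignment changes.  Modes are
#' initialized from k distinct rows sampled at random; the best of
#' `n_restarts` runs by total cost is returned.  An empty cluster during
#' iteration is re-seeded from the point farthest from its current mode.
#' Ties are deterministic: assignment ties go to the lowest-index mode,
#' column majority ties to 1.
#'
#' @param m Binary matrix (rows = variable peptides, columns = species)
#'   with rownames, or a [call_presence()] result restricted upstream.
#' @param k Number of patterns; must not exceed the number of distinct
#'   rows.
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Iteration cap per restart.
#' @return An object of class `pattern_assignment`: `n_patterns`,
#'   `assignment` (named pattern id per row), `modes` (k x species binary
#'   matrix) and `cost` (total simple-matching dissimilarity).
#' @export
kmodes <- function(m, k, seed = 1L, n_restarts = 10L, max_iter = 100L) {
  X <- if (inherits(m, "presence_matrix")) m$presence else as.matrix(m)
  storage.mode(X) <- "integer"
  n <- nrow(X)
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stop("k (", k, ") exceeds the number of distinct rows (", n_distinct, ")")
  old_seed <- .save_seed()
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # initialize from k distinct rows
    dup <- duplicated(X)
    init <- sample(which(!dup), k)
    modes <- X[init, , drop = FALSE]
    assign_prev <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      d <- .smd(X, modes)
      assign_cur <- max.col(-d, ties.method = "first")
      # re-seed empty clusters from the farthest point
      for (cl in seq_len(k)) {
        if (!any(assign_cur == cl)) {
          far <- which.max(d[cbind(seq_len(n), assign_cur)])
          modes[cl, ] <- X[far, ]
          assign_cur[far] <- cl
        }
      }
      for (cl in seq_len(k)) {
        members <- X[assign_cur == cl, , drop = FALSE]
        modes[cl, ] <- as.integer(colMeans(members) >= 0.5)
      }
      if (identical(assign_cur, assign_prev)) break
      assign_prev <- assign_cur
    }
    d <- .smd(X, modes)
    assign_cur <- max.col(-d, ties.method = "first")
    cost <- sum(d[cbind(seq_len(n), assign_cur)])
    if (is.null(best) || cost < best$cost)
      best <- list(assignment = assign_cur, modes = modes, cost = cost)
  }
  .restore_seed(old_seed)
  rownames(best$modes) <- paste0("pattern_", seq_len(k))
  colnames(best$modes) <- colnames(X)
  structure(list(n_patterns = k,
                 assignment = stats::setNames(best$assignment, rownames(X)),
                 modes = best$modes,
                 cost = best$cost),
            class = "pattern_assignment")
}

#' @export
print.pattern_assignment <- function(x, ...) {
  cat(sprintf("<pattern_assignment: %d patterns over %d peptides; cost %d>\n",
              x$n_patterns, length(x$assignment), x$cost))
  invisible(x)
}

#' Pattern-by-species contingency table
#'
#' Counts, for each discovered pattern and species, the peptides assigned
#' to the pattern that are present in the species (the quantity shown as a
#' balloon plot in comparative mucus peptidomics).
#'
#' @param pa A [kmodes()] `pattern_assignment` covering all rows of `m`.
#' @param m A [call_presence()] result or binary matrix over the same
#'   peptides.
#' @return Integer matrix, patterns x species.
#' @export
pattern_contingency <- function(pa, m) {
  pres <- if (inherits(m, "presence_matrix")) m$presence else as.matrix(m)
  ids <- names(pa$assignment)
  if (!all(ids %in% rownames(pres)))
    stop("assignment contains peptides missing from the presence matrix")
  pres <- pres[ids, , drop = FALSE]
  out <- t(vapply(seq_len(pa$n_patterns), function(g) {
    colSums(pres[pa$assignment == g, , drop = FALSE])
  }, numeric(ncol(pres))))
  storage.mode(out) <- "integer"
  dimnames(out) <- list(paste0("pattern_", seq_len(pa$n_patterns)),
                        colnames(pres))
  out
}

#' Correspondence analysis of a contingency table
#'
#' Classical CA: with correspondence matrix P = N/n, row masses r and
#' column masses c, the standardized residuals
#' S = Dr^(-1/2) (P - r c') Dc^(-1/2) are decomposed by SVD; principal
#' inertias are the squared singular values, principal coordinates are the
#' mass-rescaled singular vectors, and the square cosine of a point on a
#' dimension is its squared coordinate over its squared chi-square distance
#' to the centroid.  Total inertia equals the table's chi-square statistic
#' divided by its grand total.
#'
#' @param n Contingency table (non-negative matrix).  All-zero rows or
#'   columns are dropped with a warning.
#' @return An object of class `ca_result`: `inertias`, `explained`
#'   (percentages summing to 100), `row_coords`, `col_coords`, `row_cos2`,
#'   `col_cos2`, `total_inertia`.
#' @export
correspondence_analysis <- function(n) {
  N <- as.matrix(n)
  if (any(N < 0)) stop("contingency table must be non-negative")
  if (sum(N) <= 0) stop("contingency table has zero grand total")
  zr <- rowSums(N) == 0; zc <- colSums(N) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ",
            sum(zc), " all-zero column(s)")
    N <- N[!zr, !zc, drop = FALSE]
  }
  if (nrow(N) < 2L || ncol(N) < 2L)
    stop("correspondence analysis needs at least a 2x2 table")
  P <- N / sum(N)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  ndim <- min(nrow(N), ncol(N)) - 1L
  sigma <- sv$d[seq_len(ndim)]
  inertias <- sigma^2
  total <- sum(inertias)
  row_coords <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(ndim), drop = FALSE] %*%
    diag(sigma, ndim)
  col_coords <- diag(1 / sqrt(cc)) %*% sv$v[, seq_len(ndim), drop = FALSE] %*%
    diag(sigma, ndim)
  dims <- paste0("dim_", seq_len(ndim))
  dimnames(row_coords) <- list(rownames(N), dims)
  dimnames(col_coords) <- list(colnames(N), dims)
  cos2 <- function(coords) {
    d2 <- rowSums(coords^2)
    out <- coords^2 / ifelse(d2 > 0, d2, NA_real_)
    out
  }
  structure(list(inertias = stats::setNames(inertias, dims),
                 explained = stats::setNames(100 * inertias / total, dims),
                 row_coords = row_coords, col_coords = col_coords,
                 row_cos2 = cos2(row_coords), col_cos2 = cos2(col_coords),
                 total_inertia = total),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result: %d dimensions; total inertia %.4f>\n",
              length(x$inertias), x$total_inertia))
  expl <- cumsum(x$explained)
  cat(sprintf("  first two dimensions explain %.2f%% of the variation\n",
              expl[min(2L, length(expl))]))
  invisible(x)
}

#' Filter proteins by peptide support
#'
#' Keeps proteins identified by at least `min_peptides` distinct peptides,
#' then drops duplicated accessions.
#'
#' @param mapping Data frame with columns `peptide_id` and `accession`.
#' @param min_peptides Minimum number of distinct supporting peptides.
#' @return Character vector of retained accessions (unique).
#' @export
filter_proteins_by_peptides <- function(mapping, min_peptides = 2L) {
  if (!all(c("peptide_id", "accession") %in% names(mapping)))
    stop("mapping needs columns 'peptide_id' and 'accession'")
  support <- tapply(mapping$peptide_id, mapping$accession,
                    function(p) length(unique(p)))
  sort(names(support)[support >= min_peptides])
}

#' Flag high-abundance peptides
#'
#' Descriptive report of peptides whose relative abundance reaches a
#' threshold.  Relative abundance is the mean-centered intensity shifted by
#' the grand mean of all detected intensities, so the table average sits at
#' the grand mean and unusually intense peptides stand out.
#'
#' @param a An [abundance_table()].
#' @param threshold Relative-abundance cutoff (default 20).
#' @return List with `peptides` (ids whose maximum relative abundance is
#'   >= threshold), `relative` (the relative-abundance matrix) and
#'   `grand_mean`.
#' @export
high_abundance_peptides <- function(a, threshold = 20) {
  centered <- mean_center(a)
  grand <- mean(a$intensity[a$intensity > 0])
  rel <- centered$intensity
  rel[centered$detected] <- rel[centered$detected] + grand
  peak <- apply(rel, 1L, max)
  list(peptides = rownames(rel)[peak >= threshold],
       relative = rel, grand_mean = grand)
}
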