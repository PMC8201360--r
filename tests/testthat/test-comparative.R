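test_that("presence is the replicate maximum above threshold", {
  a <- tiny_abundance()
  m <- call_presence(a)
  expect_equal(m$presence["p1", ], c(spA = 1L, spB = 1L))
  expect_equal(m$presence["p2", ], c(spA = 0L, spB = 1L))
  expect_equal(m$presence["p3", ], c(spA = 1L, spB = 0L))

  # agrees with a brute-force max scan on random tables
  set.seed(13)
  for (i in 1:5) {
    mat <- matrix(rexp(40) * rbinom(40, 1, 0.6), 10,
                  dimnames = list(paste0("p", 1:10), NULL))
    a2 <- abundance_table(mat, species = rep(c("s1", "s2"), each = 2),
                          replicate = rep(c("r1", "r2"), 2))
    m2 <- call_presence(a2)
    for (s in c("s1", "s2")) {
      cols <- which(a2$species == s)
      expect_equal(unname(m2$presence[, s]),
                   as.integer(apply(mat[, cols], 1, max) > 0))
    }
  }
})

test_that("mean centering zeroes each column's detected mean and is idempotent", {
  mat <- cbind(`s1|1` = c(1, 2, 3), `s1|2` = c(4, 0, 8))
  rownames(mat) <- paste0("p", 1:3)
  a <- abundance_table(mat, species = c("s1", "s1"), replicate = c("1", "2"))
  cen <- mean_center(a)
  expect_equal(unname(cen$intensity[, 1]), c(-1, 0, 1))
  expect_equal(mean(cen$intensity[cen$detected[, 2], 2]), 0, tolerance = 1e-9)
  # undetected stays zero; centering twice = centering once
  expect_equal(cen$intensity["p2", 2], 0)
  cen2 <- mean_center(cen)
  expect_equal(cen2$intensity, cen$intensity, tolerance = 1e-12)

  empty_col <- abundance_table(
    cbind(`s1|1` = c(1, 2), `s1|2` = c(0, 0)) |>
      `rownames<-`(c("p1", "p2")),
    species = c("s1", "s1"), replicate = c("1", "2"))
  expect_warning(mean_center(empty_col), "no detected")
})

test_that("the ANOVA screen matches stats::anova and flags correctly", {
  set.seed(23)
  n_rep <- 3L
  species <- rep(c("s1", "s2", "s3"), each = n_rep)
  mat <- matrix(rnorm(10 * 9, mean = 5), 10,
                dimnames = list(paste0("p", 1:10), NULL))
  mat[1, ] <- 5 + c(0, 0, 0, 3, 3, 3, -3, -3, -3) + rnorm(9, sd = 0.1)
  a <- abundance_table(abs(mat), species = species,
                       replicate = rep(as.character(1:n_rep), 3))
  res <- anova_screen(a)
  # independent oracle: per-peptide lm/anova F and p
  for (i in c(1L, 4L, 7L)) {
    fit <- anova(lm(a$intensity[i, ] ~ factor(species)))
    expect_equal(res$f_statistic[i], fit[["F value"]][1], tolerance = 1e-9)
    expect_equal(res$p_value[i], fit[["Pr(>F)"]][1], tolerance = 1e-9)
  }
  expect_true(res$significant[1])

  # two groups: F equals the square of the pooled-variance t statistic
  a2 <- abundance_table(a$intensity[, 1:6], species = species[1:6],
                        replicate = a$replicate[1:6])
  res2 <- anova_screen(a2)
  tt <- t.test(a2$intensity[3, 1:3], a2$intensity[3, 4:6], var.equal = TRUE)
  expect_equal(res2$f_statistic[3], unname(tt$statistic)^2, tolerance = 1e-9)

  # identical group means with within-variance: tiny F, not significant
  flat <- matrix(rep(c(4, 5, 6), 3), 1, dimnames = list("p1", NULL))
  a3 <- abundance_table(flat, species = species,
                        replicate = a$replicate)
  res3 <- anova_screen(a3)
  expect_equal(res3$f_statistic[1], 0, tolerance = 1e-9)
  expect_false(res3$significant[1])
})

test_that("core/variable partition is exhaustive, disjoint and order-invariant", {
  pres <- rbind(p1 = c(1L, 1L), p2 = c(1L, 0L), p3 = c(0L, 1L))
  colnames(pres) <- c("sA", "sB")
  part <- partition_core_variable(pres)
  expect_equal(part$core, "p1")
  expect_setequal(part$variable, c("p2", "p3"))
  expect_length(intersect(part$core, part$variable), 0L)
  expect_setequal(c(part$core, part$variable), rownames(pres))

  # order invariance and idempotence
  part2 <- partition_core_variable(pres[c(3, 1, 2), ])
  expect_setequal(part2$core, part$core)
  expect_setequal(part2$variable, part$variable)
  expect_equal(partition_core_variable(pres), part)

  # histogram partitions all peptides including undetected
  pres2 <- rbind(pres, p4 = c(0L, 0L))
  part3 <- partition_core_variable(pres2)
  expect_equal(part3$undetected, "p4")
  expect_equal(sum(part3$histogram), 4L)
})

test_that("hierarchical clustering merges identical rows at height zero", {
  m <- rbind(a = c(0, 0, 1), b = c(0, 0, 1), c = c(5, 5, 5), d = c(9, 9, 0))
  hc <- hcluster(m)
  expect_s3_class(hc, "hclust")
  expect_equal(min(hc$height), 0)
  expect_true(all(diff(hc$height) >= 0))  # complete linkage is monotone
  # first merge joins the identical pair
  first <- hc$merge[1, ]
  expect_setequal(-first, c(1, 2))
  # 4-point oracle: nearest pair under Euclidean distance merges first
  d <- as.matrix(dist(m))
  diag(d) <- Inf
  expect_equal(min(d), hc$height[1])
})

test_that("simple-matching k-modes recovers grouped identical rows at cost 0", {
  X <- rbind(matrix(rep(c(1L, 0L, 1L, 0L), 4), 4, byrow = TRUE),
             matrix(rep(c(0L, 1L, 0L, 1L), 3), 3, byrow = TRUE))
  rownames(X) <- paste0("p", 1:7)
  pa <- kmodes(X, k = 2L, seed = 1L)
  expect_equal(pa$cost, 0)
  expect_setequal(split(names(pa$assignment), pa$assignment) |> lengths(),
                  c(4L, 3L))
  expect_setequal(apply(pa$modes, 1, paste, collapse = ""),
                  c("1010", "0101"))

  # same seed reproduces the assignment
  pa2 <- kmodes(X, k = 2L, seed = 1L)
  expect_identical(pa$assignment, pa2$assignment)

  expect_error(kmodes(X, k = 3L), "distinct rows")
})

test_that("k-modes attains the exhaustive-partition minimum at k = 2", {
  set.seed(37)
  X <- matrix(rbinom(8 * 7, 1L, 0.5), 8, 7,
              dimnames = list(paste0("p", 1:8), paste0("s", 1:7)))
  pa <- kmodes(X, k = 2L, seed = 4L, n_restarts = 10L)
  expect_equal(pa$cost, oracle_kmodes2_cost(X))
})

test_that("k-modes iteration never increases the cost", {
  set.seed(53)
  X <- matrix(rbinom(20 * 5, 1L, 0.4), 20, 5,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:5)))
  for (seed in 1:5) {
    # with identical seeding, longer iteration can only lower the cost
    early <- kmodes(X, k = 3L, seed = seed, n_restarts = 1L, max_iter = 1L)
    full <- kmodes(X, k = 3L, seed = seed, n_restarts = 1L)
    expect_lte(full$cost, early$cost)
    # reported cost is the recount of assignment mismatches
    d <- bioactpep:::.smd(X, full$modes)
    expect_equal(full$cost, sum(d[cbind(1:20, full$assignment)]))
  }
})

test_that("the pattern contingency table is an exact recount", {
  set.seed(61)
  pres <- matrix(rbinom(12 * 4, 1L, 0.6), 12, 4,
                 dimnames = list(paste0("p", 1:12), paste0("s", 1:4)))
  pres[pres[, 1] + pres[, 2] + pres[, 3] + pres[, 4] == 0, 1] <- 1L
  pa <- kmodes(pres, k = 3L, seed = 2L)
  ct <- pattern_contingency(pa, pres)
  for (g in 1:3) for (s in 1:4) {
    expect_equal(ct[g, s],
                 sum(pres[names(pa$assignment)[pa$assignment == g], s]))
  }
  expect_true(all(ct >= 0))

  # one pattern, one species, 3 present peptides -> cell = 3
  one <- matrix(1L, 3, 2, dimnames = list(paste0("p", 1:3), c("sA", "sB")))
  pa1 <- structure(list(n_patterns = 1L,
                        assignment = setNames(rep(1L, 3), rownames(one)),
                        modes = matrix(1L, 1, 2), cost = 0),
                   class = "pattern_assignment")
  expect_equal(unname(pattern_contingency(pa1, one)[1, "sA"]), 3L)
})

test_that("correspondence analysis satisfies the classical identities", {
  set.seed(71)
  for (i in 1:5) {
    N <- matrix(rpois(12, 8) + 1, 4, 3)
    dimnames(N) <- list(paste0("r", 1:4), paste0("c", 1:3))
    ca <- correspondence_analysis(N)
    # total inertia = chi-square / n
    chi <- suppressWarnings(chisq.test(N)$statistic)
    expect_equal(ca$total_inertia, unname(chi) / sum(N), tolerance = 1e-9)
    # inertias match an independent eigendecomposition of S'S
    P <- N / sum(N); r <- rowSums(P); cc <- colSums(P)
    S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
    ev <- sort(eigen(t(S) %*% S, symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(unname(ca$inertias), ev[1:2], tolerance = 1e-9)
    # explained percentages sum to 100; inertias non-increasing
    expect_equal(sum(ca$explained), 100, tolerance = 1e-9)
    expect_true(all(diff(ca$inertias) <= 1e-12))
    # cos2 per point sums to 1 over all dimensions
    expect_equal(unname(rowSums(ca$row_cos2)), rep(1, 4), tolerance = 1e-9)
    expect_equal(unname(rowSums(ca$col_cos2)), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("CA handles rank-1 and degenerate tables as specified", {
  # 2x2: exactly one nontrivial dimension explaining 100%
  N <- matrix(c(10, 2, 3, 9), 2, dimnames = list(c("r1", "r2"),
                                                 c("c1", "c2")))
  ca <- correspondence_analysis(N)
  expect_length(ca$inertias, 1L)
  expect_equal(unname(ca$explained), 100, tolerance = 1e-9)

  # independent table (outer product) has ~zero total inertia
  ind <- outer(c(2, 3, 5), c(1, 4, 7))
  dimnames(ind) <- list(paste0("r", 1:3), paste0("c", 1:3))
  expect_lt(correspondence_analysis(ind)$total_inertia, 1e-12)

  # all-zero rows are dropped with a warning; 1-column tables error
  Nz <- rbind(N, r3 = c(0, 0))
  expect_warning(correspondence_analysis(Nz), "all-zero")
  expect_error(suppressWarnings(
    correspondence_analysis(matrix(c(1, 2), 2, 1))), "2x2")
})

test_that("protein filtering needs two distinct supporting peptides", {
  mapping <- data.frame(
    peptide_id = c("p1", "p2", "p1", "p1", "p3", "p4"),
    accession = c("A", "A", "A", "B", "C", "C"))
  expect_equal(filter_proteins_by_peptides(mapping), c("A", "C"))
  expect_equal(filter_proteins_by_peptides(mapping, min_peptides = 1L),
               c("A", "B", "C"))
})

test_that("species averaging and high-abundance flags are coherent", {
  a <- tiny_abundance()
  avg <- average_by_species(a)
  expect_equal(avg["p1", "spA"], 1.5)
  expect_equal(avg["p2", "spB"], 5.5)
  flag <- high_abundance_peptides(a, threshold = 20)
  expect_true(all(flag$peptides %in% rownames(a$intensity)))
  expect_equal(flag$grand_mean, mean(a$intensity[a$intensity > 0]))
})
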