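# Synthetic peptide sets and presence/abundance matrices with planted
# ground truth, so classifiers and the comparative pipeline can be
# exercised end to end without external data.

#' Generate a labeled peptide set with controllable class separability
#'
#' Negative-class residues are drawn uniformly over the 20 canonical amino
#' acids.  Positive-class residues are drawn from a mixture placing
#' probability mass `effect` uniformly on the enriched residue set and the
#' remaining `1 - effect` uniformly over all 20 residues.  The signal is
#' thus compositional, mapping directly onto the dipeptide feature space
#' the classifiers consume.  At `effect = 0` the two classes are
#' indistinguishable; at `effect = 1` positives use only enriched residues.
#'
#' @param n_per_class Number of peptides in each class.
#' @param length_range Integer `c(min, max)` peptide lengths; min >= 2.
#' @param effect Class separability in `[0, 1]`.
#' @param enriched_residues Residues over-represented in positives.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param property_name Label attached to the generated set.
#' @return A [labeled_peptide_set()] with `2 * n_per_class` peptides
#'   (positives first, labels 1 then 0).
#' @export
gen_labeled_peptides <- function(n_per_class, length_range = c(8L, 30L),
                                 effect = 0.8,
                                 enriched_residues = c("K", "R", "W", "L"),
                                 seed = 1L,
                                 property_name = "synthetic") {
  stopifnot(length_range[1L] >= 2L, effect >= 0, effect <= 1,
            all(enriched_residues %in% aa_alphabet()))
  old_seed <- .save_seed()
  set.seed(seed)
  draw_seq <- function(len, positive) {
    if (positive) {
      from_enriched <- stats::runif(len) < effect
      chars <- character(len)
      chars[from_enriched] <- sample(enriched_residues,
                                     sum(from_enriched), replace = TRUE)
      chars[!from_enriched] <- sample(aa_alphabet(),
                                      sum(!from_enriched), replace = TRUE)
    } else {
      chars <- sample(aa_alphabet(), len, replace = TRUE)
    }
    paste(chars, collapse = "")
  }
  lens <- sample(seq(length_range[1L], length_range[2L]),
                 2L * n_per_class, replace = TRUE)
  pos <- lapply(seq_len(n_per_class), function(i)
    peptide(paste0("pos_", i), draw_seq(lens[i], TRUE)))
  neg <- lapply(seq_len(n_per_class), function(i)
    peptide(paste0("neg_", i), draw_seq(lens[n_per_class + i], FALSE)))
  .restore_seed(old_seed)
  labeled_peptide_set(property_name, c(pos, neg),
                      c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

#' Generate a peptide abundance matrix with planted core/variable structure
#'
#' Core peptides are present in all species; each variable peptide carries
#' one of `n_patterns` distinct planted binary species profiles (never
#' all-present or all-absent).  Where a peptide is present, each
#' replicate's intensity is drawn log-normally with `sdlog = noise_sd`
#' around a common median; absent cells are 0.  Presence is noise-free by
#' construction, so the planted core/variable labels are always exactly
#' recoverable from the generated table.
#'
#' @param n_species Number of species (>= 2).
#' @param n_core Number of core peptides.
#' @param n_variable Number of variable peptides.
#' @param n_patterns Number of planted patterns; at most
#'   `2^n_species - 2`.
#' @param replicates Replicates per species (default 3).
#' @param noise_sd Log-scale intensity spread; 0 makes all present
#'   intensities equal.
#' @param median_intensity Median of present intensities (default 10).
#' @param seed Integer seed.
#' @return List with `abundance` (an [abundance_table()]) and `truth`
#'   (planted `core` ids, `variable` ids, `pattern` assignment per variable
#'   peptide, and the `profiles` matrix of the planted patterns).
#' @export
gen_presence_matrix <- function(n_species, n_core, n_variable, n_patterns,
                                replicates = 3L, noise_sd = 0.5,
                                median_intensity = 10, seed = 1L) {
  stopifnot(n_species >= 2L, n_core >= 0L, n_variable >= 0L,
            n_patterns >= 1L, n_patterns <= 2^n_species - 2,
            n_variable == 0L || n_variable >= n_patterns,
            replicates >= 1L, noise_sd >= 0)
  old_seed <- .save_seed()
  set.seed(seed)
  species <- paste0("sp", seq_len(n_species))
  # planted pattern profiles: distinct, excluding all-absent and all-present
  codes <- sample(seq_len(2^n_species - 2L), n_patterns)
  profiles <- t(vapply(codes, function(code)
    as.integer(intToBits(code)[seq_len(n_species)]), integer(n_species)))
  dimnames(profiles) <- list(paste0("pattern_", seq_len(n_patterns)), species)
  # every pattern gets at least one peptide; the rest are assigned at random
  pattern_of <- integer(0)
  if (n_variable > 0L) {
    pattern_of <- c(seq_len(n_patterns),
                    sample(seq_len(n_patterns), n_variable - n_patterns,
                           replace = TRUE))
    pattern_of <- sample(pattern_of)
  }
  ids <- c(if (n_core > 0L) paste0("core_", seq_len(n_core)),
           if (n_variable > 0L) paste0("var_", seq_len(n_variable)))
  presence <- rbind(
    matrix(1L, n_core, n_species),
    if (n_variable > 0L) profiles[pattern_of, , drop = FALSE])
  dimnames(presence) <- list(ids, species)
  n_pep <- n_core + n_variable
  intensity <- matrix(0, n_pep, n_species * replicates)
  colnames(intensity) <- paste(rep(species, each = replicates),
                               rep(seq_len(replicates), n_species),
                               sep = "|")
  rownames(intensity) <- ids
  for (s in seq_len(n_species)) {
    present <- presence[, s] == 1L
    cols <- (s - 1L) * replicates + seq_len(replicates)
    intensity[present, cols] <- stats::rlnorm(sum(present) * replicates,
                                              meanlog = log(median_intensity),
                                              sdlog = noise_sd)
  }
  .restore_seed(old_seed)
  tab <- abundance_table(intensity,
                         species = rep(species, each = replicates),
                         replicate = rep(as.character(seq_len(replicates)),
                                         n_species))
  truth <- list(core = if (n_core > 0L) paste0("core_", seq_len(n_core)) else character(0),
                variable = if (n_variable > 0L) paste0("var_", seq_len(n_variable)) else character(0),
                pattern = if (n_variable > 0L)
                  stats::setNames(pattern_of, paste0("var_", seq_len(n_variable)))
                  else integer(0),
                profiles = profiles)
  list(abundance = tab, truth = truth)
}
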