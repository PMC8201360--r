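# The 407-element physicochemical feature vector: 7 scalar descriptors plus
# the 400 ordered dipeptide relative frequencies.

# Kyte-Doolittle hydropathy values per residue.
.kd_scale <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
               L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
               S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Average (isotope-abundance weighted) residue masses in Daltons.
.avg_residue_mass <- c(A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                       C = 103.1388, E = 129.1155, Q = 128.1307, G =  57.0519,
                       H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                       M = 131.1926, F = 147.1766, P =  97.1167, S =  87.0782,
                       T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

.water_mass <- 18.0153

# Residues counted as hydrophobic for the hydrophobic-fraction descriptor.
.hydrophobic_set <- c("A", "V", "L", "I", "M", "F", "W", "C")

.residue_chars <- function(p) strsplit(p$sequence, "", fixed = TRUE)[[1L]]

#' Feature names of the 407-element descriptor
#'
#' Fixed, bit-stable ordering: `mass_da`, `length`, `gravy`, `n_positive`,
#' `n_negative`, `net_charge`, `frac_hydrophobic`, then the 400 dipeptide
#' frequencies `dp_AA` ... `dp_YY` in lexicographic order.
#'
#' @return Character vector of length 407.
#' @export
feature_names <- function() {
  aa <- aa_alphabet()
  pairs <- as.vector(t(outer(aa, aa, paste0)))
  c("mass_da", "length", "gravy", "n_positive", "n_negative",
    "net_charge", "frac_hydrophobic", paste0("dp_", pairs))
}

#' Dipeptide composition
#'
#' Relative frequency of each of the 400 ordered adjacent residue pairs,
#' counted with an overlapping window: the entry for pair XY is
#' (number of adjacent XY occurrences) / (length - 1).  Entries sum to 1 for
#' any peptide of length >= 2.
#'
#' @param p A [peptide()].
#' @return Named numeric vector of length 400 (`dp_AA` ... `dp_YY`).
#' @export
#' @examples
#' dp <- dipeptide_composition(peptide("p", "ACAC"))
#' dp[c("dp_AC", "dp_CA")]
dipeptide_composition <- function(p) {
  chars <- .residue_chars(p)
  n <- length(chars)
  if (n < 2L) stop("dipeptide composition requires length >= 2")
  aa <- aa_alphabet()
  pair_names <- paste0("dp_", as.vector(t(outer(aa, aa, paste0))))
  counts <- stats::setNames(numeric(400L), pair_names)
  obs <- table(paste0("dp_", chars[-n], chars[-1L]))
  counts[names(obs)] <- as.numeric(obs)
  counts / (n - 1L)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean per-residue Kyte-Doolittle hydropathy value of the peptide.
#'
#' @param p A [peptide()].
#' @return A single numeric hydropathy score.
#' @export
#' @examples
#' gravy(peptide("p", "AILV"))  # 3.575
gravy <- function(p) {
  mean(.kd_scale[.residue_chars(p)])
}

#' Charged-residue counts
#'
#' Counts of positively charged (K, R, H) and negatively charged (D, E)
#' residues, and their difference.  Termini are not counted; this is a
#' residue count, not a pH-dependent charge model.
#'
#' @param p A [peptide()].
#' @return Named numeric vector `c(n_positive, n_negative, net_charge)`.
#' @export
#' @examples
#' charge_counts(peptide("p", "KRHDE"))  # 3, 2, 1
charge_counts <- function(p) {
  chars <- .residue_chars(p)
  np <- sum(chars %in% c("K", "R", "H"))
  nn <- sum(chars %in% c("D", "E"))
  c(n_positive = np, n_negative = nn, net_charge = np - nn)
}

#' Molecular mass
#'
#' Average molecular mass in Daltons: sum of average residue masses plus one
#' water.  Average (not monoisotopic) masses are used; the value is a
#' physicochemical descriptor, not intended for spectrum matching.
#'
#' @param p A [peptide()].
#' @return Mass in Daltons.
#' @export
molecular_mass <- function(p) {
  sum(.avg_residue_mass[.residue_chars(p)]) + .water_mass
}

#' Compute the 407-element feature vector of a peptide
#'
#' Deterministic physicochemical descriptor used by all property
#' classifiers: molecular mass (Da), length (residues), GRAVY hydropathy,
#' positive/negative residue counts, net charge, hydrophobic-residue
#' fraction (A, V, L, I, M, F, W, C), and the 400 ordered dipeptide relative
#' frequencies.
#'
#' @param p A [peptide()].
#' @return Named numeric vector of length 407, ordered as [feature_names()].
#' @export
#' @examples
#' fv <- featurize(peptide("p1", "ACDK"))
#' length(fv)  # 407
featurize <- function(p) {
  chars <- .residue_chars(p)
  cc <- charge_counts(p)
  scalars <- c(mass_da = molecular_mass(p),
               length = length(chars),
               gravy = gravy(p),
               cc,
               frac_hydrophobic = mean(chars %in% .hydrophobic_set))
  out <- c(scalars, dipeptide_composition(p))
  names(out) <- feature_names()
  out
}

#' Feature matrix for a list of peptides
#'
#' @param peptides List of [peptide()] objects.
#' @return Numeric matrix, one row per peptide (rownames = ids), 407 named
#'   columns in the fixed [feature_names()] order.
#' @export
featurize_set <- function(peptides) {
  mat <- t(vapply(peptides, featurize, numeric(407L)))
  rownames(mat) <- vapply(peptides, `[[`, "", "id")
  mat
}

#' Write a feature table to TSV
#'
#' One row per peptide: `peptide_id` plus the 407 named feature columns in
#' fixed order.
#'
#' @param features Matrix from [featurize_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  tab <- data.frame(peptide_id = rownames(features), features,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
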