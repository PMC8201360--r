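# Consensus voting across the kNN and RF predictors and multi-functional
# peptide summaries.

.default_all_properties <- c(
  "antibacterial", "antibiofilm", "anticancer", "antifungal",
  "antihypertensive", "antioxidant", "antiparasitic", "anti-inflammatory",
  "antiprotease", "antiviral", "cell-communicating", "cell-penetrating",
  "chemotactic", "drug-delivering", "haemolytic", "insecticide",
  "quorum-sensing", "spermicide", "surface-immobilized", "toxic",
  "tumor-homing", "wound-healing")

.default_knn_supported <- c(
  "antibacterial", "antibiofilm", "anticancer", "antifungal",
  "antihypertensive", "antiparasitic", "anti-inflammatory", "antiviral",
  "cell-communicating", "cell-penetrating", "drug-delivering",
  "quorum-sensing", "toxic", "tumor-homing")

.default_rf_supported <- c(
  "antibacterial", "antihypertensive", "antiparasitic",
  "anti-inflammatory", "antiviral", "cell-communicating",
  "cell-penetrating", "drug-delivering", "quorum-sensing", "toxic",
  "tumor-homing")

#' Bioactive-property registry
#'
#' Holds the category vocabulary and the subsets of properties each
#' classifier method supports reliably.  The consensus set is the sorted
#' intersection of the kNN- and RF-supported labels; with the default
#' registry it has 11 members.
#'
#' @param all_properties Full category vocabulary.
#' @param knn_supported Labels with a usable kNN classifier (default 14).
#' @param rf_supported Labels with a usable RF classifier (default 11).
#' @return An object of class `property_registry` with the three label sets
#'   plus `consensus_set`.
#' @export
#' @examples
#' length(property_registry()$consensus_set)  # 11
property_registry <- function(all_properties = .default_all_properties,
                              knn_supported = .default_knn_supported,
                              rf_supported = .default_rf_supported) {
  bad <- setdiff(c(knn_supported, rf_supported), all_properties)
  if (length(bad) > 0L)
    stop("unknown property label(s): ", paste(unique(bad), collapse = ", "))
  structure(list(all_properties = all_properties,
                 knn_supported = knn_supported,
                 rf_supported = rf_supported,
                 consensus_set = consensus_properties(knn_supported,
                                                      rf_supported,
                                                      all_properties)),
            class = "property_registry")
}

#' @export
print.property_registry <- function(x, ...) {
  cat(sprintf("<property_registry: %d categories; kNN %d, RF %d, consensus %d>\n",
              length(x$all_properties), length(x$knn_supported),
              length(x$rf_supported), length(x$consensus_set)))
  invisible(x)
}

#' Read a property registry from YAML
#'
#' The YAML file lists `all_properties`, `knn_supported` and `rf_supported`.
#'
#' @param path YAML file path.
#' @return A [property_registry()].
#' @export
read_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  property_registry(all_properties = cfg$all_properties,
                    knn_supported = cfg$knn_supported,
                    rf_supported = cfg$rf_supported)
}

#' Properties supported by both classifier methods
#'
#' Exact set intersection of the two supported-label sets, sorted
#' lexicographically.  Commutative and idempotent.
#'
#' @param knn_supported Labels supported by the kNN method.
#' @param rf_supported Labels supported by the RF method.
#' @param vocabulary Allowed label vocabulary; unknown labels are an error.
#' @return Sorted character vector of shared labels.
#' @export
consensus_properties <- function(knn_supported, rf_supported,
                                 vocabulary = .default_all_properties) {
  bad <- setdiff(c(knn_supported, rf_supported), vocabulary)
  if (length(bad) > 0L)
    stop("unknown property label(s): ", paste(unique(bad), collapse = ", "))
  sort(intersect(knn_supported, rf_supported))
}

#' Combine per-method calls into consensus assignments
#'
#' A peptide-property assignment is a consensus positive exactly when both
#' the kNN and the RF classifier call it positive and the property is in
#' the registry's consensus set.
#'
#' @param knn Binary matrix of kNN calls, peptides x properties, with
#'   dimnames.
#' @param rf Binary matrix of RF calls sharing `knn`'s dimnames.
#' @param registry A [property_registry()].
#' @return An object of class `prediction_table` with binary matrices
#'   `knn_call`, `rf_call`, `consensus_call` and the registry.
#' @export
consensus_calls <- function(knn, rf, registry = property_registry()) {
  knn <- as.matrix(knn); rf <- as.matrix(rf)
  if (is.null(rownames(knn)) || is.null(colnames(knn)))
    stop("call matrices need peptide rownames and property colnames")
  if (!identical(dimnames(knn), dimnames(rf)))
    stop("kNN and RF call tables must share peptide and property indices")
  bad <- setdiff(colnames(knn), registry$all_properties)
  if (length(bad) > 0L)
    stop("unknown property label(s): ", paste(bad, collapse = ", "))
  gate <- matrix(rep(colnames(knn) %in% registry$consensus_set,
                     each = nrow(knn)), nrow = nrow(knn))
  cons <- (knn == 1L) & (rf == 1L) & gate
  storage.mode(cons) <- "integer"
  dimnames(cons) <- dimnames(knn)
  structure(list(knn_call = knn, rf_call = rf, consensus_call = cons,
                 registry = registry),
            class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat(sprintf("<prediction_table: %d peptides x %d properties; %d consensus positives>\n",
              nrow(x$knn_call), ncol(x$knn_call), sum(x$consensus_call)))
  invisible(x)
}

#' Summarize multi-functional peptides
#'
#' Counts peptides carrying at least `min_properties` positive calls, under
#' either the any-method reading (positive by kNN or RF) or consensus-only
#' calls, and returns the per-peptide property-count histogram.
#'
#' @param t A `prediction_table` from [consensus_calls()].
#' @param min_properties Minimum number of positive properties (>= 1).
#' @param use `"any-method"` (default) or `"consensus"`.
#' @return List with `count`, `percentage` (of all peptides, rounded to one
#'   decimal) and `histogram` (named vector over per-peptide property
#'   counts 0, 1, 2, ...).
#' @export
multifunctionality_summary <- function(t, min_properties = 5L,
                                       use = c("any-method", "consensus")) {
  use <- match.arg(use)
  if (min_properties < 1L) stop("min_properties must be >= 1")
  calls <- if (use == "consensus") t$consensus_call
           else (t$knn_call == 1L) | (t$rf_call == 1L)
  per_pep <- rowSums(calls)
  count <- sum(per_pep >= min_properties)
  total <- length(per_pep)
  hist <- table(factor(per_pep, levels = 0:max(per_pep)))
  list(count = count,
       percentage = round(100 * count / total, 1L),
       histogram = stats::setNames(as.integer(hist), names(hist)))
}

#' Write consensus calls to TSV
#'
#' Long-format table: one row per (peptide, property) with the three binary
#' calls.
#'
#' @param t A `prediction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(t, path) {
  long <- expand.grid(peptide_id = rownames(t$knn_call),
                      property = colnames(t$knn_call),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$knn_call <- as.vector(t$knn_call)
  long$rf_call <- as.vector(t$rf_call)
  long$consensus_call <- as.vector(t$consensus_call)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
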