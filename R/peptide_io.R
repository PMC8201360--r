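# Reading, writing and validation of peptide sequences, labeled training
# sets and per-species replicate abundance tables.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, sorted alphabetically.  All
#' peptide validation and the dipeptide feature space are defined over this
#' alphabet; ambiguity codes (B, Z, X) and non-canonical residues (U, O) are
#' rejected.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a validated peptide
#'
#' A peptide is an identifier plus a sequence over the 20 canonical residues.
#' Sequences must have at least two residues so that the dipeptide
#' composition is defined.
#'
#' @param id Character identifier.
#' @param sequence Amino-acid sequence (one-letter codes, upper case).
#' @return An object of class `peptide` (a list with `id` and `sequence`).
#' @export
#' @examples
#' peptide("p1", "ACDK")
peptide <- function(id, sequence) {
  validate_sequence(sequence, id = id)
  structure(list(id = as.character(id), sequence = sequence),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide %s: %s (%d aa)>\n", x$id, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Validate a peptide sequence
#'
#' Checks that a sequence is non-degenerate (length >= 2) and uses only the
#' canonical 20-letter alphabet.
#'
#' @param sequence Candidate sequence.
#' @param id Identifier used in error messages.
#' @return The sequence, invisibly, if valid; otherwise an error is thrown
#'   naming the offending peptide and character.
#' @export
validate_sequence <- function(sequence, id = "<unnamed>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("peptide '", id, "': sequence must be a single character string")
  if (nchar(sequence) < 2L)
    stop("peptide '", id, "': sequence must have at least 2 residues")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad) > 0L)
    stop("peptide '", id, "': illegal residue character(s): ",
         paste(bad, collapse = ", "))
  invisible(sequence)
}

#' Read peptides from FASTA or TSV
#'
#' FASTA files are read with [Biostrings::readAAStringSet()]; tabular files
#' must contain columns `peptide_id` and `sequence`.  Duplicate sequences are
#' retained (identity is the id).  Every sequence is validated against the
#' canonical alphabet.
#'
#' @param path Input file path.
#' @param format `"fasta"` or `"tsv"`.  Defaults to a guess from the file
#'   extension (`.fa`, `.fasta`, `.faa` read as FASTA, anything else as TSV).
#' @return A list of [peptide()] objects in file order.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "faa")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    if (file.size(path) == 0L) {
      warning("empty peptide file: ", path)
      return(list())
    }
    seqs <- Biostrings::readAAStringSet(path)
    ids <- names(seqs)
    ids[is.na(ids) | ids == ""] <- paste0("peptide_", which(is.na(ids) | ids == ""))
    seqs <- as.character(seqs)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) {
      warning("empty peptide file: ", path)
      return(list())
    }
    if (!all(c("peptide_id", "sequence") %in% names(tab)))
      stop("TSV peptide file must have columns 'peptide_id' and 'sequence': ",
           path)
    ids <- as.character(tab$peptide_id)
    seqs <- as.character(tab$sequence)
  }
  mapply(peptide, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write peptides to FASTA
#'
#' @param peptides List of [peptide()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  lines <- unlist(lapply(peptides, function(p) c(paste0(">", p$id), p$sequence)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled peptide set
#'
#' Reads a TSV with columns `peptide_id`, `sequence`, `label` (0 = negative,
#' 1 = positive) into a labeled set for one bioactive-property category.
#'
#' @param path Input TSV path.
#' @param property_name Name of the bioactive property the labels refer to.
#' @return A `labeled_peptide_set`: list with `property_name`, `peptides`
#'   (list of [peptide()]) and `labels` (integer 0/1 vector).
#' @export
read_labeled_set <- function(path, property_name = "unspecified") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "sequence", "label")
  if (!all(need %in% names(tab)))
    stop("labeled set must have columns ", paste(need, collapse = ", "))
  peps <- mapply(peptide, tab$peptide_id, tab$sequence,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  labeled_peptide_set(property_name, peps, as.integer(tab$label))
}

#' Construct a labeled peptide set
#'
#' @param property_name Property category name.
#' @param peptides List of [peptide()] objects.
#' @param labels Binary vector (0 = negative, 1 = positive), aligned 1:1
#'   with `peptides`.
#' @return An object of class `labeled_peptide_set`.
#' @export
labeled_peptide_set <- function(property_name, peptides, labels) {
  labels <- as.integer(labels)
  if (length(peptides) != length(labels))
    stop("labels must align 1:1 with peptides")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  structure(list(property_name = property_name,
                 peptides = peptides,
                 labels = labels),
            class = "labeled_peptide_set")
}

#' @export
print.labeled_peptide_set <- function(x, ...) {
  cat(sprintf("<labeled_peptide_set '%s': %d peptides (%d positive, %d negative)>\n",
              x$property_name, length(x$peptides),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Write a labeled peptide set to TSV
#'
#' @param s A `labeled_peptide_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_set <- function(s, path) {
  tab <- data.frame(peptide_id = vapply(s$peptides, `[[`, "", "id"),
                    sequence = vapply(s$peptides, `[[`, "", "sequence"),
                    label = s$labels)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an abundance table
#'
#' Holds non-negative peptide ion intensities per (peptide, species,
#' replicate).  Columns are sample columns named `<species>|<replicate>`;
#' every sample column shares the same peptide index.  A zero intensity means
#' "not detected".
#'
#' @param intensity Numeric matrix, peptides in rows (rownames = peptide
#'   ids), sample columns.
#' @param species Character vector of species labels, one per column.
#' @param replicate Character vector of replicate labels, one per column.
#' @return An object of class `abundance_table` with elements `intensity`,
#'   `species`, `replicate`.
#' @export
abundance_table <- function(intensity, species, replicate) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)))
    stop("intensity matrix must have peptide ids as rownames")
  if (length(species) != ncol(intensity) || length(replicate) != ncol(intensity))
    stop("species and replicate labels must match the number of columns")
  if (anyNA(intensity)) stop("intensities must not be NA (use 0 for missing)")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  key <- paste(species, replicate, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (species, replicate) column: ", key[duplicated(key)][1L])
  colnames(intensity) <- key
  structure(list(intensity = intensity,
                 species = as.character(species),
                 replicate = as.character(replicate)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table: %d peptides x %d samples (%d species)>\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$species))))
  invisible(x)
}

#' Read a per-species replicate abundance table
#'
#' Expects a TSV/CSV with a `peptide_id` column followed by sample columns
#' named `<species>|<replicate>`.  Blank or missing cells are read as 0
#' ("not detected"); negative intensities are rejected.
#'
#' @param path Input path.  Comma- or tab-separated is detected from the
#'   extension (`.csv` reads as CSV).
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!"peptide_id" %in% names(tab))
    stop("abundance table must have a 'peptide_id' column: ", path)
  samp <- setdiff(names(tab), "peptide_id")
  if (length(samp) == 0L) stop("abundance table has no sample columns")
  parts <- strsplit(samp, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("sample columns must be named '<species>|<replicate>'")
  mat <- as.matrix(tab[, samp, drop = FALSE])
  storage.mode(mat) <- "double"
  mat[is.na(mat)] <- 0
  if (any(mat < 0)) stop("negative intensity in ", path)
  rownames(mat) <- as.character(tab$peptide_id)
  abundance_table(mat,
                  species = vapply(parts, `[[`, "", 1L),
                  replicate = vapply(parts, `[[`, "", 2L))
}

#' Write an abundance table
#'
#' Inverse of [read_abundance()]: the written file round-trips all
#' intensities exactly.
#'
#' @param a An [abundance_table()].
#' @param path Output path (`.csv` writes comma-separated).
#' @return `path`, invisibly.
#' @export
write_abundance <- function(a, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- data.frame(peptide_id = rownames(a$intensity),
                    a$intensity, check.names = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
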