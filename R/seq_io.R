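#' Construct a labeled alignment
#'
#' A labeled alignment holds equal-length gapped sequences with species
#' labels, stored internally as a character matrix (members x columns), plus
#' a logical column mask. Masked-out columns (mask `FALSE`) are excluded from
#' diagnostic-site detection and distance computation; by convention the 5.8S
#' gene columns are masked out via [mask_58s()].
#'
#' @param residues Character vector of equal-length sequence strings over
#'   `A,C,G,T,U`, IUPAC ambiguity codes, `N` and the gap `-`
#'   (case-insensitive; stored upper-case).
#' @param accession Character vector of unique accession identifiers.
#' @param species Character vector of species labels.
#' @param geography Optional character vector of collection locations.
#' @param mask Optional logical vector, one per column; default all `TRUE`.
#' @return An object of class `labeled_alignment`.
#' @export
labeled_alignment <- function(residues, accession, species,
                              geography = NULL, mask = NULL) {
  residues <- toupper(residues)
  stopifnot(length(residues) == length(accession),
            length(residues) == length(species))
  if (length(residues) == 0L) stop("empty alignment")
  if (anyDuplicated(accession))
    stop("duplicate accession: ",
         accession[duplicated(accession)][1L])
  w <- nchar(residues)
  if (length(unique(w)) != 1L)
    stop("sequences have unequal lengths; not an alignment")
  seq <- do.call(rbind, strsplit(residues, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(seq)), .ALPHABET)
  if (length(bad) > 0L)
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  rownames(seq) <- accession
  if (is.null(mask)) mask <- rep(TRUE, ncol(seq))
  stopifnot(length(mask) == ncol(seq), is.logical(mask))
  structure(list(accession = accession, species = species,
                 geography = geography %||% rep(NA_character_,
                                                length(accession)),
                 seq = seq, mask = mask),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat(sprintf("labeled_alignment: %d sequences x %d columns (%d masked out), %d species\n",
              nrow(x$seq), ncol(x$seq), sum(!x$mask),
              length(unique(x$species))))
  invisible(x)
}

#' Number of alignment columns
#' @param x A `labeled_alignment`.
#' @return Integer count of columns.
#' @export
alignment_columns <- function(x) ncol(x$seq)

# Subset an alignment's columns (used by the bootstrap); the mask is carried
# along, so resampled alignments stay consistent.
subset_columns <- function(x, cols) {
  x$seq <- x$seq[, cols, drop = FALSE]
  x$mask <- x$mask[cols]
  x
}

#' Read labeled sequences from a FASTA file
#'
#' Headers follow the machine-safe dialect `accession|species|geography`
#' (geography optional); the delimiter is configurable. If all sequences
#' have equal length the result is a [labeled_alignment()] with an all-true
#' mask; otherwise a plain list of sequences is returned with attribute
#' `aligned = FALSE`.
#'
#' @param path FASTA file (gap character `-` allowed).
#' @param delim Header field delimiter (default `"|"`).
#' @return A `labeled_alignment`, or (for ragged input) a list with elements
#'   `accession`, `species`, `geography`, `residues` of class
#'   `labeled_sequences` carrying `attr(, "aligned") == FALSE`.
#' @export
read_labeled_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  parts <- strsplit(headers, delim, fixed = TRUE)
  accession <- vapply(parts, `[`, "", 1L)
  species <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else
    NA_character_, "")
  geography <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else
    NA_character_, "")
  if (anyDuplicated(accession))
    stop("duplicate accession in FASTA: ",
         accession[duplicated(accession)][1L])
  if (anyNA(species))
    stop("FASTA header lacks a species field under delimiter '", delim, "'")
  residues <- toupper(as.character(set))
  if (length(unique(nchar(residues))) == 1L) {
    labeled_alignment(residues, accession, species, geography)
  } else {
    structure(list(accession = accession, species = species,
                   geography = geography, residues = residues),
              class = "labeled_sequences", aligned = FALSE)
  }
}

#' Write labeled sequences to FASTA
#'
#' Inverse of [read_labeled_fasta()] for the canonical dialect: one header
#' line `>accession|species[|geography]` and one sequence line per record, so
#' read-write-read round-trips are byte-exact.
#'
#' @param x A `labeled_alignment` or `labeled_sequences` object.
#' @param path Output file path.
#' @param delim Header field delimiter.
#' @return `path`, invisibly.
#' @export
write_labeled_fasta <- function(x, path, delim = "|") {
  residues <- if (inherits(x, "labeled_alignment"))
    apply(x$seq, 1L, paste, collapse = "") else x$residues
  geo <- x$geography
  header <- ifelse(is.na(geo) | geo == "",
                   paste(x$accession, x$species, sep = delim),
                   paste(x$accession, x$species, geo, sep = delim))
  lines <- as.vector(rbind(paste0(">", header), residues))
  writeLines(lines, path)
  invisible(path)
}

#' ITS1 / 5.8S / ITS2 annotation intervals
#'
#' Intervals are 1-based inclusive over the (ungapped) coordinates of one
#' sequence, ordered and non-overlapping: ITS1 before 5.8S before ITS2.
#'
#' @param its1,r58s,its2 Length-2 integer vectors `c(start, end)`.
#' @return An object of class `its_annotation`.
#' @export
its_annotation <- function(its1, r58s, its2) {
  iv <- list(its1 = as.integer(its1), r58s = as.integer(r58s),
             its2 = as.integer(its2))
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || anyNA(v) || v[1L] > v[2L] || v[1L] < 1L)
      stop("invalid or empty interval for ", nm)
  }
  if (!(iv$its1[2L] < iv$r58s[1L] && iv$r58s[2L] < iv$its2[1L]))
    stop("annotation intervals must be ordered ITS1 < 5.8S < ITS2 and disjoint")
  structure(iv, class = "its_annotation")
}

#' @export
print.its_annotation <- function(x, ...) {
  cat(sprintf("ITS1 %d-%d | 5.8S %d-%d | ITS2 %d-%d\n",
              x$its1[1L], x$its1[2L], x$r58s[1L], x$r58s[2L],
              x$its2[1L], x$its2[2L]))
  invisible(x)
}

#' Read or write annotation configuration as JSON
#'
#' The JSON maps an accession (or the key `"columns"` for alignment-column
#' coordinates) to `{its1: [s, e], r58s: [s, e], its2: [s, e]}` with 1-based
#' inclusive bounds.
#'
#' @param path JSON file path.
#' @return For `read_annotation_json`, a named list of `its_annotation`
#'   objects.
#' @export
read_annotation_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(a) its_annotation(a$its1, a$r58s, a$its2))
}

#' @rdname read_annotation_json
#' @param annotations Named list of `its_annotation` objects.
#' @export
write_annotation_json <- function(annotations, path) {
  jsonlite::write_json(lapply(annotations, unclass), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
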