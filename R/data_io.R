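# Input/output conventions shared by the whole pipeline.
#
# FASTA headers carry specimen metadata as "specimenID|speciesLabel|areaLabel".
# All tabular artifacts are comma-delimited with a header row; decimal ".".

#' Construct a sequence set
#'
#' A `sequence_set` bundles COI specimen records: specimen id, species
#' label, sampling-area label and the nucleotide sequence. IUPAC
#' ambiguity codes other than `N` are mapped to `N`; sequences are
#' uppercased. `N` and `-` are treated as missing sites by
#' [p_distance()].
#'
#' @param specimen_id character vector of unique specimen identifiers.
#' @param species_label character vector of species (or morphospecies)
#'   labels, one per specimen.
#' @param area_label character vector of sampling-area labels.
#' @param sequence character vector of nucleotide sequences.
#' @return An object of class `sequence_set`: a data frame with columns
#'   `specimen_id`, `species_label`, `area_label`, `sequence`, plus
#'   `areas` and `species` attributes holding the ordered label sets.
#' @export
sequence_set <- function(specimen_id, species_label, area_label, sequence) {
  n <- length(specimen_id)
  .assert(length(species_label) == n && length(area_label) == n &&
            length(sequence) == n, "all fields must have equal length")
  .assert(!anyDuplicated(specimen_id), "duplicate specimen_id in sequence set")
  sequence <- toupper(sequence)
  .assert(all(nchar(sequence) > 0), "empty sequence in sequence set")
  # map non-{A,C,G,T,N,-} IUPAC codes to N
  sequence <- gsub("[^ACGTN-]", "N", sequence)
  out <- data.frame(
    specimen_id = as.character(specimen_id),
    species_label = as.character(species_label),
    area_label = as.character(area_label),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  attr(out, "areas") <- unique(out$area_label)
  attr(out, "species") <- unique(out$species_label)
  class(out) <- c("sequence_set", "data.frame")
  out
}

#' Read specimen sequences from FASTA
#'
#' Headers must have three pipe-separated fields,
#' `specimenID|speciesLabel|areaLabel`. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad)) {
    stop("malformed FASTA header (need 'id|species|area'): ",
         headers[bad[1]], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  message(sprintf("read_fasta: %d records, %d species, %d areas",
                  length(seqs), length(unique(m[, 2])), length(unique(m[, 3]))))
  sequence_set(m[, 1], m[, 2], m[, 3], as.character(seqs))
}

#' Write a sequence set to FASTA
#'
#' Inverse of [read_fasta()]; headers are rebuilt as `id|species|area`.
#'
#' @param seqs a [sequence_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs$sequence)
  names(x) <- paste(seqs$specimen_id, seqs$species_label, seqs$area_label,
                    sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct an incidence matrix
#'
#' Binary islands x species presence-absence matrix, the substrate of all
#' community analyses. Rows are islands, columns species.
#'
#' @param cells numeric/integer matrix of 0/1 values.
#' @param islands,species optional row/column labels (default taken from
#'   dimnames).
#' @return An `incidence_matrix`: an integer matrix with unique dimnames.
#' @export
incidence_matrix <- function(cells, islands = rownames(cells),
                             species = colnames(cells)) {
  cells <- as.matrix(cells)
  if (is.null(islands)) {
    islands <- if (nrow(cells)) paste0("island_", seq_len(nrow(cells))) else character(0)
  }
  if (is.null(species)) {
    species <- if (ncol(cells)) paste0("sp_", seq_len(ncol(cells))) else character(0)
  }
  .assert(!anyDuplicated(islands) && !anyDuplicated(species),
          "duplicate island or species labels")
  bad <- which(!(cells %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(cells))
    stop(sprintf("non-binary cell at row %d ('%s'), column %d ('%s'): %s",
                 rc[1], islands[rc[1]], rc[2], species[rc[2]],
                 cells[bad[1]]), call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  dimnames(cells) <- list(as.character(islands), as.character(species))
  class(cells) <- c("incidence_matrix", class(matrix()))
  cells
}

#' Read an incidence matrix from CSV
#'
#' First column = island labels, remaining columns = species; values 0/1.
#' File order of rows and columns is preserved.
#'
#' @param path path to a CSV file.
#' @return An [incidence_matrix()].
#' @export
read_incidence <- function(path) {
  .assert(file.exists(path), paste0("incidence file not found: ", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "incidence table needs an island column plus species columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) & !is.na(m))
    rc <- if (length(bad)) arrayInd(bad[1], dim(m)) else c(NA, NA)
    stop(sprintf("non-numeric incidence cell at row %s, column '%s'",
                 rc[1], colnames(m)[rc[2]]), call. = FALSE)
  }
  incidence_matrix(m, islands = as.character(df[[1]]), species = colnames(m))
}

#' Write an incidence matrix to CSV
#'
#' @param m an [incidence_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(m, path) {
  df <- data.frame(island = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.covariate_cols <- c("MT", "AP", "IA", "EL", "IS", "SR", "PC", "richness")

#' Construct an island covariate table
#'
#' Validates the predictor table used by the richness models: mean annual
#' temperature `MT` (degrees C), annual precipitation `AP` (mm), island
#' area `IA` (km^2, > 0), maximum elevation `EL` (m), isolation `IS` (km,
#' >= 0, distance to the faunistic source), source richness `SR` (species
#' count, >= 1), Pleistocene connection `PC` (0/1 factor) and observed
#' `richness` (species count, >= 0).
#'
#' @param df data frame with one row per island; must contain a first
#'   label column `island` plus the columns above.
#' @return A validated `covariate_table` (data frame).
#' @export
covariate_table <- function(df) {
  .assert("island" %in% names(df), "missing 'island' label column")
  missing_cols <- setdiff(.covariate_cols, names(df))
  if (length(missing_cols)) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  .assert(!anyDuplicated(df$island), "duplicate island labels")
  num <- .covariate_cols
  for (cl in num) {
    .assert(is.numeric(df[[cl]]), paste0("column ", cl, " must be numeric (PC as 0/1)"))
  }
  .assert(all(df$IA > 0), "island area IA must be > 0")
  .assert(all(df$IS >= 0), "isolation IS must be >= 0")
  .assert(all(df$SR >= 1), "source richness SR must be >= 1")
  .assert(all(df$richness >= 0), "richness must be >= 0")
  .assert(all(df$PC %in% c(0, 1)), "PC must be coded 0/1")
  df$PC <- as.integer(df$PC)
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Read island covariates from CSV
#'
#' @param path path to a CSV with columns `island`, `MT`, `AP`, `IA`,
#'   `EL`, `IS`, `SR`, `PC`, `richness`.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  .assert(file.exists(path), paste0("covariate file not found: ", path))
  covariate_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a covariate table to CSV
#'
#' @param cov a [covariate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  write.csv(as.data.frame(cov), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Reads each provided path with the matching reader and reports record
#' counts; stops at the first invalid input.
#'
#' @param fasta,incidence,covariates optional paths; `NULL` entries are
#'   skipped.
#' @return Named list of the parsed objects, invisibly.
#' @export
validate_inputs <- function(fasta = NULL, incidence = NULL, covariates = NULL) {
  out <- list()
  if (!is.null(fasta)) out$sequences <- read_fasta(fasta)
  if (!is.null(incidence)) out$incidence <- read_incidence(incidence)
  if (!is.null(covariates)) out$covariates <- read_covariates(covariates)
  invisible(out)
}
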