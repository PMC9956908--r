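#' Build a karyotype table
#'
#' A karyotype is a tibble with one row per chromosome: its name, length in
#' bp, sex class (`autosome`, `Z` or `W`) and the species label. Most
#' Lepidoptera have a ZW system (females ZW, males ZZ); male-only
#' assemblies carry no W entry.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Numeric vector of chromosome lengths in bp (positive).
#' @param sex_class Character vector of sex classes; recycled `"autosome"`
#'   by default. At most one `Z` and one `W` entry are allowed.
#' @param species Single species label.
#' @return A karyotype tibble.
#' @export
karyotype <- function(chrom, length, sex_class = "autosome", species = "species") {
  k <- tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    sex_class = rep_len(as.character(sex_class), length(chrom)),
    species = species
  )
  validate_karyotype(k)
  k
}

validate_karyotype <- function(k) {
  if (anyDuplicated(k$chrom)) {
    abort(paste0(
      "duplicate chromosome name: ",
      k$chrom[duplicated(k$chrom)][1L]
    ))
  }
  if (any(k$length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  if (!all(k$sex_class %in% c("autosome", "Z", "W"))) {
    abort("sex_class must be one of 'autosome', 'Z', 'W'")
  }
  if (sum(k$sex_class == "Z") > 1L) abort("at most one Z chromosome allowed")
  if (sum(k$sex_class == "W") > 1L) abort("at most one W chromosome allowed")
  invisible(k)
}

#' Load a karyotype from a FASTA-index-style table
#'
#' Reads a chromosome length table in the FASTA-index dialect (chromosome
#' name and length in the first two tab-separated columns; any further
#' columns are ignored) and attaches sex-class labels.
#'
#' @param index_path Path to the index file.
#' @param sex_labels Named character vector mapping chromosome names to
#'   `"Z"` or `"W"`; unnamed chromosomes default to `"autosome"`.
#' @param species Species label for the karyotype.
#' @return A karyotype tibble (see [karyotype()]).
#' @export
load_karyotype <- function(index_path, sex_labels = character(), species = "species") {
  if (!file.exists(index_path)) {
    abort(paste0("index file not found: ", index_path))
  }
  lines <- readLines(index_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    abort("index file lines must have at least two tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(len)) abort("non-numeric chromosome length in index file")
  sex <- rep("autosome", length(chrom))
  hit <- match(chrom, names(sex_labels))
  sex[!is.na(hit)] <- unname(sex_labels[hit[!is.na(hit)]])
  karyotype(chrom, len, sex, species = species)
}

#' Write a karyotype as a FASTA-index-style table
#'
#' @param k A karyotype tibble.
#' @param path Output path; two tab-separated columns (name, length).
#' @return `path`, invisibly.
#' @export
write_fai <- function(k, path) {
  writeLines(
    paste(k$chrom, format(k$length, scientific = FALSE, trim = TRUE), sep = "\t"),
    path
  )
  invisible(path)
}
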