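#' Write a synthetic dataset to plain-text fixtures
#'
#' Emits the dataset as TSV/BED files that round-trip losslessly through
#' [read_dataset()]: `sites.tsv` (1-based positions), `chip_counts.tsv`
#' (per-read ChIP observations), `bisulfite_obs.tsv`,
#' `expression_counts.tsv`, `population_genotypes.tsv`,
#' `known_polymorphisms.tsv`, `truth.tsv`, and the annotation tracks
#' `imprinted.bed` / `deletions.bed` (0-based half-open, converted from the
#' package's 1-based inclusive internal intervals).
#'
#' @param dataset An `ashm_dataset` from [simulate_dataset()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(dataset, directory) {
  stopifnot(inherits(dataset, "ashm_dataset"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L) {
    stop("I/O error: cannot write to directory: ", directory, call. = FALSE)
  }
  p <- function(f) file.path(directory, f)
  w <- function(x, f) fwrite(x, p(f), sep = "\t", na = "NA", quote = FALSE)
  w(dataset$sites, "sites.tsv")
  w(dataset$chip_reads, "chip_counts.tsv")
  w(dataset$bis_obs, "bisulfite_obs.tsv")
  w(dataset$expression, "expression_counts.tsv")
  w(dataset$population, "population_genotypes.tsv")
  w(dataset$known_polymorphisms, "known_polymorphisms.tsv")
  w(dataset$truth, "truth.tsv")
  write_bed(dataset$annotations[track == "imprinted"], p("imprinted.bed"))
  write_bed(dataset$annotations[track == "deletion_syndrome"],
            p("deletions.bed"))
  invisible(c("sites.tsv", "chip_counts.tsv", "bisulfite_obs.tsv",
              "expression_counts.tsv", "population_genotypes.tsv",
              "known_polymorphisms.tsv", "truth.tsv", "imprinted.bed",
              "deletions.bed"))
}

#' Read a fixture directory back into an `ashm_dataset`-shaped list
#'
#' Inverse of [write_fixtures()] (the `config` element is not serialised and
#' comes back `NULL`).
#'
#' @param directory Directory holding the fixture files.
#' @return List with the same table elements as [simulate_dataset()].
#' @export
read_dataset <- function(directory) {
  p <- function(f) file.path(directory, f)
  need <- c("sites.tsv", "chip_counts.tsv", "bisulfite_obs.tsv",
            "expression_counts.tsv", "truth.tsv")
  missing <- need[!file.exists(p(need))]
  if (length(missing)) {
    stop("I/O error: missing input file(s) in ", directory, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  opt <- function(f, reader = read_tsv) {
    if (file.exists(p(f))) reader(p(f)) else NULL
  }
  ann <- rbind(
    if (file.exists(p("imprinted.bed")))
      read_bed(p("imprinted.bed"), track = "imprinted"),
    if (file.exists(p("deletions.bed")))
      read_bed(p("deletions.bed"), track = "deletion_syndrome")
  )
  sites <- read_tsv(p("sites.tsv"))
  setkey(sites, site_id)
  truth <- read_tsv(p("truth.tsv"))
  structure(list(
    sites = sites,
    chip_reads = read_tsv(p("chip_counts.tsv")),
    bis_obs = read_tsv(p("bisulfite_obs.tsv")),
    expression = read_tsv(p("expression_counts.tsv")),
    annotations = ann,
    population = opt("population_genotypes.tsv"),
    known_polymorphisms = opt("known_polymorphisms.tsv"),
    truth = truth,
    config = NULL
  ), class = "ashm_dataset")
}

#' Read a TSV, skipping `#` comment headers
#'
#' @param path File path.
#' @return A `data.table`.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fread(text = lines, sep = "\t")
}

#' Write a TSV with an optional `#` comment header
#'
#' @param x Table to write.
#' @param path File path.
#' @param header Character vector of comment lines (written with a leading
#'   `"# "`).
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path, header = NULL) {
  if (length(header)) {
    writeLines(paste0("# ", header), path)
    fwrite(x, path, sep = "\t", na = "NA", quote = FALSE, append = TRUE,
           col.names = TRUE)
  } else {
    fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Read a BED annotation track
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (a record `start=999, end=2000` becomes the
#' 1-based interval 1000--2000).
#'
#' @param path BED file (3 or more columns; 4th column taken as the label).
#' @param track Track name to attach (`imprinted`, `deletion_syndrome`, or
#'   any custom label).
#' @return `data.table` with columns `chrom`, `start`, `end`, `label`,
#'   `track`.
#' @export
read_bed <- function(path, track = "custom") {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  bed <- fread(path, sep = "\t", header = FALSE)
  if (ncol(bed) < 3L) {
    stop("I/O error: BED file needs >= 3 columns: ", path, call. = FALSE)
  }
  out <- data.table(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    label = if (ncol(bed) >= 4L) as.character(bed[[4]])
            else paste0("region_", seq_len(nrow(bed))),
    track = track
  )
  if (any(out$start > out$end)) {
    stop("I/O error: malformed BED interval (start >= end) in ", path,
         call. = FALSE)
  }
  out
}

#' Write an annotation track as BED
#'
#' Converts the package's 1-based inclusive intervals to 0-based half-open
#' BED records.
#'
#' @param regions Annotation table with `chrom`, `start`, `end`, `label`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  bed <- data.table(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, name = regions$label)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
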