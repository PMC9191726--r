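#' Read a BED3-BED6 file into a GRanges
#'
#' Coordinates are 0-based half-open on disk and kept half-open internally
#' (`GRanges` end = BED end - 1). Track/browser/comment lines are skipped.
#' Name, score and strand columns are carried through when present; the
#' score column carries the (scaled) signal.
#'
#' @param path BED file.
#' @return `GRanges` with optional `name` and `score` metadata.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | lines == ""
  body <- lines[!skip]
  if (length(body) == 0) stop("no records in ", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("parse error at line ", which(!skip)[which(nf < 3)[1]],
                        ": fewer than 3 fields")
  tab <- do.call(rbind, lapply(fields, function(f) f[1:min(6, max(nf))]))
  start <- suppressWarnings(as.numeric(tab[, 2]))
  end <- suppressWarnings(as.numeric(tab[, 3]))
  bad <- is.na(start) | is.na(end) | start >= end | !grepl("^[A-Za-z0-9_.]+$", tab[, 1])
  if (any(bad)) stop("parse error at line ", which(!skip)[which(bad)[1]],
                     ": invalid interval")
  gr <- GenomicRanges::GRanges(tab[, 1], IRanges::IRanges(start, end - 1),
                               strand = if (ncol(tab) >= 6)
                                 ifelse(tab[, 6] %in% c("+", "-"), tab[, 6], "*")
                               else "*")
  if (ncol(tab) >= 4) gr$name <- tab[, 4]
  if (ncol(tab) >= 5) gr$score <- suppressWarnings(as.numeric(tab[, 5]))
  gr
}

#' Write a GRanges as BED6
#'
#' Inverse of [read_bed()]: 0-based half-open coordinates, name and score
#' from the metadata columns (`.` and 0 defaults), strand `.` when
#' unstranded. `read_bed()` then `write_bed()` round-trips byte-identically.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @export
write_bed <- function(gr, path) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 format(GenomicRanges::start(gr), scientific = FALSE, trim = TRUE),
                 format(GenomicRanges::end(gr) + 1, scientific = FALSE, trim = TRUE),
                 name,
                 format(score, scientific = FALSE, trim = TRUE),
                 strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Convert peaks with signal to a BED-writable GRanges
#'
#' Score is the normalized signal scaled by 1000 and clamped to
#' `[0, 1000]` (integer), the BED score convention.
#'
#' @param peaks `GRanges` with `peak_id` and a `signal` column.
#' @param signal numeric per-peak signal (defaults to `peaks$signal`).
#' @return `GRanges` with `name` and `score` ready for [write_bed()].
#' @export
peaks_to_bed <- function(peaks, signal = peaks$signal) {
  out <- GenomicRanges::granges(peaks)
  out$name <- if (!is.null(peaks$peak_id)) peaks$peak_id else
    sprintf("peak%03d", seq_along(peaks))
  out$score <- as.integer(pmin(1000, pmax(0, round(signal * 1000))))
  out
}

#' Write a sparse matrix as MatrixMarket with sidecar tables
#'
#' Writes `matrix.mtx`, `barcodes.tsv` (columns) and `features.tsv` (rows)
#' into `dir`.
#'
#' @param mat matrix (rows = features, columns = barcodes).
#' @param dir output directory (created if missing).
#' @export
write_mtx <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!inherits(mat, "sparseMatrix")) mat <- Matrix::Matrix(mat, sparse = TRUE)
  Matrix::writeMM(methods::as(mat, "generalMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket directory written by [write_mtx()]
#'
#' @param dir directory with `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#' @return a sparse `CsparseMatrix` with dimnames restored.
#' @export
read_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  if (nrow(m) != length(features) || ncol(m) != length(barcodes))
    stop("dimension mismatch between matrix.mtx and sidecar files")
  dimnames(m) <- list(features, barcodes)
  methods::as(m, "CsparseMatrix")  # from a Matrix class, always registered
}

#' Write / read a foci table as CSV
#'
#' Plain CSV with columns `cell_id`, `dose`, `time_min`, `foci`.
#'
#' @param table foci data.frame.
#' @param path CSV path.
#' @export
write_foci <- function(table, path) {
  stopifnot(all(c("cell_id", "dose", "time_min", "foci") %in% names(table)))
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname write_foci
#' @export
read_foci <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("cell_id", "dose", "time_min", "foci") %in% names(tab)))
  if (any(tab$foci < 0)) stop("negative foci count")
  tab
}

#' Write run provenance
#'
#' Records the configuration, seed and package/R versions as JSON next to
#' a run's outputs so any result table can be regenerated.
#'
#' @param dir output directory.
#' @param cfg the [sim_config()] (or any list) used.
#' @param seed master seed of the run.
#' @export
write_provenance <- function(dir, cfg, seed) {
  prov <- list(
    package = "sehet",
    package_version = as.character(utils::packageVersion("sehet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = unclass(cfg))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "provenance.json"))
}
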