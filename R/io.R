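# Schema-checked readers and writers. TSV is canonical (CSV accepted),
# header required, '.' decimal, UTF-8; lengths um, areas um^2,
# densities per mm^2, with units embedded in column names.

.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

.writeDelim <- function(df, path) {
  # doubles serialized at 17 significant digits so numeric round-trips
  # are exact
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) {
      v <- formatC(out[[j]], digits = 17, format = "g")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.requireColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
}

.checkNumeric <- function(df, cols, path, min = NULL, strict = FALSE) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop("schema error in ", path, ": non-numeric value in column '",
           cl, "' at data row ", if (is.na(bad)) "?" else bad)
    }
    if (!is.null(min)) {
      bad <- which(!is.na(v) & (if (strict) v <= min else v < min))
      if (length(bad))
        stop("schema error in ", path, ": column '", cl, "' must be ",
             if (strict) "> " else ">= ", min, " (data row ", bad[1], ")")
    }
  }
}

#' Read and validate a section-record table
#'
#' Expects the schema written by [writeSections()] (TSV or CSV): columns
#' `animal_id`, `region`, `section`, `width_um`, `thickness_um`,
#' `cone_count`, `onl_rows`, `nucleus_diameter_um`, `os_length_um`,
#' `rpe_height_um`, `phagosome_count`, `rpe_cell_count`. Numeric ranges
#' are checked and violations reported with row and column; duplicated
#' `(animal_id, region, section)` keys are an error.
#'
#' @param path file path.
#' @return validated data.frame of section records.
#' @export
readSections <- function(path) {
  df <- .readDelim(path)
  .requireColumns(df, c("animal_id", "region", "section", "width_um",
                        "thickness_um", "cone_count", "onl_rows",
                        "nucleus_diameter_um", "os_length_um",
                        "rpe_height_um", "phagosome_count",
                        "rpe_cell_count"), path)
  .checkNumeric(df, c("width_um", "thickness_um", "nucleus_diameter_um"),
                path, min = 0, strict = TRUE)
  .checkNumeric(df, c("cone_count", "onl_rows", "os_length_um",
                      "rpe_height_um", "phagosome_count",
                      "rpe_cell_count"), path, min = 0)
  key <- paste(df$animal_id, df$region, df$section, sep = "\r")
  if (anyDuplicated(key))
    stop("schema error in ", path, ": duplicated (animal_id, region, ",
         "section) key at data row ", which(duplicated(key))[1])
  df
}

#' @describeIn readSections write the table (TSV, UTF-8).
#' @param sections section-record data.frame.
#' @export
writeSections <- function(sections, path) .writeDelim(sections, path)

#' Read and write RPE trace tables
#'
#' Long format, one nucleus per row: `animal_id`, `region`, `section`,
#' `segment_length_um`, `position_um` (a wide format with a
#' comma-separated `positions_um` column is also accepted on read).
#'
#' @param path file path.
#' @return `readTraces()`: list of [RPETrace-class] objects.
#' @export
readTraces <- function(path) {
  df <- .readDelim(path)
  .requireColumns(df, c("animal_id", "region", "segment_length_um"), path)
  if (!"section" %in% names(df)) df$section <- 1L
  long <- "position_um" %in% names(df)
  if (!long && !"positions_um" %in% names(df))
    stop("schema error in ", path,
         ": need column position_um (long) or positions_um (wide)")
  .checkNumeric(df, "segment_length_um", path, min = 0, strict = TRUE)
  key <- paste(df$animal_id, df$region, df$section, sep = "\r")
  traces <- lapply(split(df, factor(key, levels = unique(key))),
    function(d) {
      pos <- if (long) sort(d$position_um)
             else as.numeric(strsplit(d$positions_um[1], ",")[[1]])
      rpeTrace(pos, segmentLength = d$segment_length_um[1],
               animalId = d$animal_id[1], region = d$region[1])
    })
  unname(traces)
}

#' @describeIn readTraces write a list of traces in long format.
#' @param traces list of [RPETrace-class] objects.
#' @export
writeTraces <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    p <- positions(tr)
    if (!length(p)) return(NULL)
    data.frame(animal_id = animalId(tr), region = region(tr),
               section = i, segment_length_um = segmentLength(tr),
               position_um = p, stringsAsFactors = FALSE)
  })
  .writeDelim(do.call(rbind, rows), path)
}

#' Read and write protein matrices
#'
#' Matrix file: first column the protein id, remaining columns samples,
#' header row, empty cell = missing. Groups file: columns `sample_id`,
#' `group`.
#'
#' @param path,groupsPath file paths.
#' @param scale `"raw"` or `"log2"`, the scale the file is on.
#' @return `readProteinMatrix()`: a [ProteinQuant-class].
#' @export
readProteinMatrix <- function(path, groupsPath, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- .readDelim(path)
  if (ncol(df) < 3L)
    stop("schema error in ", path, ": need protein id plus >= 2 samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("schema error in ", path, ": duplicated protein id '",
         ids[duplicated(ids)][1], "'")
  m <- as.matrix(df[-1])
  if (!is.numeric(m))
    stop("schema error in ", path, ": non-numeric intensities")
  rownames(m) <- ids
  g <- .readDelim(groupsPath)
  .requireColumns(g, c("sample_id", "group"), groupsPath)
  missingSamples <- setdiff(colnames(m), g$sample_id)
  if (length(missingSamples))
    stop("schema error in ", groupsPath, ": no group for sample(s) ",
         paste(missingSamples, collapse = ", "))
  groups <- stats::setNames(as.character(g$group), g$sample_id)[colnames(m)]
  proteinQuant(m, groups = groups, scale = scale)
}

#' @describeIn readProteinMatrix write the matrix and its group mapping.
#' @param x a [ProteinQuant-class].
#' @export
writeProteinMatrix <- function(x, path, groupsPath) {
  a <- SummarizedExperiment::assay(x, "intensity")
  df <- data.frame(protein_id = rownames(a), a, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeDelim(df, path)
  .writeDelim(data.frame(sample_id = colnames(a),
                         group = as.character(sampleGroups(x)),
                         stringsAsFactors = FALSE), groupsPath)
  invisible(path)
}
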