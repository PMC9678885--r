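#' Read a peak file (BED or ENCODE narrowPeak)
#'
#' BED input may have 3 columns (`chrom start end`; peak ids are generated)
#' or 6 (`chrom start end name score strand`; the score column is read as
#' signal). narrowPeak is BED6+4: column 7 is read as signal and column 10
#' as the summit offset from start, with `-1` meaning absent.
#'
#' @param path input file.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param set_id label for the returned set (default: file base name).
#' @return a [peak_set()].
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"), set_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(set_id)) set_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(peak_set(character(0), integer(0), integer(0), set_id = set_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  need <- if (format == "narrowPeak") 10L else c(3L, 6L)
  bad <- which(!(ncol %in% need))
  if (length(bad)) {
    stop("line ", bad[1], " of ", path, " has ", ncol[bad[1]],
         " columns; expected ", paste(need, collapse = " or "))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1], " of ", path)
  }
  if (format == "narrowPeak") {
    off <- as.integer(m[, 10])
    peak_set(m[, 1], start, end, peak_id = m[, 4],
             signal = as.numeric(m[, 7]),
             summit_offset = ifelse(off < 0L, NA_integer_, off),
             set_id = set_id)
  } else if (ncol[1] >= 6L) {
    peak_set(m[, 1], start, end, peak_id = m[, 4],
             signal = as.numeric(m[, 5]), set_id = set_id)
  } else {
    peak_set(m[, 1], start, end, set_id = set_id)
  }
}

fmt_num <- function(x, digits = 4) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  sub("^-0\\.0+$", "0.0000", out)
}

#' Write a peak set as BED6 or narrowPeak
#'
#' Writers and readers round-trip: a written file read back with
#' [read_peaks()] reproduces the coordinates, ids, signal (4 decimals) and
#' summit offsets exactly. BED6 stores the signal in the score column;
#' narrowPeak stores it in column 7 (signalValue) with `-1` placeholders for
#' p/q columns and the summit offset in column 10 (`-1` when absent).
#'
#' @param peaks a [peak_set()].
#' @param path output file.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  validate_peak_set(peaks)
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                     peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                     fmt_num(peaks$signal))
  } else {
    off <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                     peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                     fmt_num(peaks$signal), off)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-model TSV
#'
#' Expects a header line and columns `gene_id`, `chrom`, `strand`,
#' `body_start`, `body_end` (0-based half-open).
#'
#' @param path input file.
#' @return a [gene_model()] table.
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "body_start", "body_end")
  if (!all(need %in% names(df))) {
    stop("gene model file must have columns: ", paste(need, collapse = ", "))
  }
  gene_model(df$gene_id, df$chrom, df$strand, df$body_start, df$body_end)
}

#' @rdname read_gene_models
#' @param genes a [gene_model()] table.
#' @export
write_gene_models <- function(genes, path) {
  write_tsv(genes[, c("gene_id", "chrom", "strand", "body_start", "body_end")],
            path)
}

#' Write / read a TSV with exact numeric round-trip
#'
#' Numeric columns are serialised with 17 significant digits so that reading
#' the file back reproduces each double bit-exactly, and rewriting the read
#' table reproduces the file byte-exactly.
#'
#' @param df a data frame.
#' @param path output file.
#' @param comments optional character vector written as leading `#` lines.
#' @return `path` invisibly (`write_tsv`); a data.frame (`read_tsv`).
#' @export
write_tsv <- function(df, path, comments = NULL) {
  cols <- lapply(df, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(names(df), collapse = "\t"),
    body
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: set name, description, then one member per field.
#'
#' @param path file path.
#' @return named list of character vectors (the `description` attribute holds
#'   the second column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) stop("GMT line ", short[1], " has fewer than 2 fields")
  sets <- lapply(fields, function(f) if (length(f) > 2L) f[-(1:2)] else
    character(0))
  names(sets) <- vapply(fields, `[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (second GMT column).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a header and at least `gene_id`, `log2fc`, `pvalue`; `padj` is
#' optional. Extra columns (e.g. a test statistic) are kept.
#'
#' @param path input TSV.
#' @return data.frame, one row per gene.
#' @export
read_de_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "log2fc", "pvalue")
  if (!all(need %in% names(df))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("DE table has duplicate gene_ids")
  df
}

#' Read / write wide CyTOF event tables
#'
#' One row per event; marker columns hold raw ion counts, metadata columns
#' are prefixed `meta_`. Numeric columns round-trip bit-exactly.
#'
#' @param events data.frame of events.
#' @param path CSV file path.
#' @return `path` invisibly (`write_events`); a data.frame (`read_events`).
#' @export
write_events <- function(events, path) {
  cols <- lapply(events, function(x) {
    if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  })
  body <- do.call(paste, c(cols, sep = ","))
  writeLines(c(paste(names(events), collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Split an event table into marker matrix and metadata
#'
#' @param events data.frame from [read_events()] or [sim_cytof()].
#' @return list with `markers` (numeric matrix) and `meta` (data.frame of
#'   the `meta_`-prefixed columns, prefix stripped).
#' @export
split_events <- function(events) {
  is_meta <- grepl("^meta_", names(events))
  meta <- events[, is_meta, drop = FALSE]
  names(meta) <- sub("^meta_", "", names(meta))
  list(markers = as.matrix(events[, !is_meta, drop = FALSE]), meta = meta)
}
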