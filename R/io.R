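#' Write a spectral map to TSV
#'
#' The on-disk dialect mirrors goniometry source-data tables: `#`-prefixed
#' `key=value` metadata lines, a header row `wavelength_nm` followed by the
#' detection angles in degrees, then one row per wavelength. Angles are in
#' degrees, wavelengths in nm, decimal separator `.`, UTF-8.
#'
#' @param map A [spectral_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_map <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  meta <- map$metadata
  meta$normalized <- map$normalized
  header_lines <- sprintf("# %s=%s", names(meta),
                          vapply(meta, function(v) format(v, digits = 15),
                                 character(1)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(c("wavelength_nm", format(map$angle_deg, trim = TRUE,
                                             digits = 15)),
                   collapse = "\t"), con)
  body <- cbind(map$wavelength_nm, map$reflectance)
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_meta_value <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  if (x %in% c("TRUE", "FALSE")) return(as.logical(x))
  if (x == "NA") return(NA)
  x
}

#' Read a spectral map from TSV
#'
#' Inverse of [write_spectral_map()]. Malformed files (ragged rows,
#' non-numeric cells, duplicated or unsorted grid values) fail with an
#' error naming the offending line; nothing is silently coerced.
#'
#' @param path Path to a spectral-map TSV.
#' @return A [spectral_map()] with metadata restored.
#' @export
read_spectral_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- startsWith(lines, "#")
  meta_lines <- lines[is_meta]
  body_idx <- which(!is_meta)
  if (length(body_idx) < 2) stop_parse("%s: no data rows found", path)

  metadata <- list()
  for (ml in meta_lines) {
    kv <- stringr::str_match(ml, "^#\\s*([^=]+)=(.*)$")
    if (!is.na(kv[1, 1])) {
      metadata[[stringr::str_trim(kv[1, 2])]] <-
        parse_meta_value(stringr::str_trim(kv[1, 3]))
    }
  }
  normalized <- isTRUE(metadata$normalized)
  metadata$normalized <- NULL

  header_line_no <- body_idx[1]
  header <- strsplit(lines[header_line_no], "\t", fixed = TRUE)[[1]]
  if (header[1] != "wavelength_nm") {
    stop_parse("%s line %d: header must start with 'wavelength_nm'",
               path, header_line_no)
  }
  angles <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(angles))) {
    stop_parse("%s line %d: non-numeric angle in header", path, header_line_no)
  }
  if (anyDuplicated(angles)) {
    stop_parse("%s line %d: duplicated angle column", path, header_line_no)
  }
  if (is.unsorted(angles, strictly = TRUE)) {
    stop_parse("%s line %d: angle grid not strictly increasing",
               path, header_line_no)
  }

  data_line_nos <- body_idx[-1]
  rows <- lapply(seq_along(data_line_nos), function(i) {
    ln <- data_line_nos[i]
    cells <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(header)) {
      stop_parse("%s line %d: expected %d columns, found %d",
                 path, ln, length(header), length(cells))
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals))) {
      stop_parse("%s line %d: non-numeric cell", path, ln)
    }
    vals
  })
  body <- do.call(rbind, rows)
  wl <- body[, 1]
  if (is.unsorted(wl, strictly = TRUE)) {
    stop_parse("%s: wavelength grid not strictly increasing", path)
  }
  spectral_map(wl, angles, body[, -1, drop = FALSE],
               metadata = metadata, normalized = normalized)
}

#' Read gene loci from GFF3 or TSV
#'
#' GFF3 files are read through `rtracklayer` (gene-level features; the
#' `Name` attribute supplies the gene symbol, falling back to `ID` and then
#' to a coordinate-derived label). TSV files need columns `contig`, `start`,
#' `end`, `name` and optionally `strand`. Coordinates are 1-based inclusive
#' in both encodings.
#'
#' @param path Path to a `.gff`/`.gff3` or `.tsv` file.
#' @param feature_type GFF3 feature types to keep (default `"gene"`; `NULL`
#'   keeps all).
#' @return A tibble of loci: `contig`, `start`, `end`, `strand`, `name`.
#' @export
read_loci <- function(path, feature_type = "gene") {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop_input("reading GFF3 requires the rtracklayer package")
    }
    gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
    if (!is.null(feature_type) && "type" %in% names(gr)) {
      keep <- as.character(gr$type) %in% feature_type
      if (any(keep)) gr <- gr[keep, , drop = FALSE]
    }
    nm <- function(col) {
      if (col %in% names(gr)) as.character(gr[[col]]) else rep(NA_character_, nrow(gr))
    }
    loci <- tibble::tibble(
      contig = as.character(gr$seqnames),
      start = as.integer(gr$start),
      end = as.integer(gr$end),
      strand = as.character(gr$strand)
    )
    loci$name <- dplyr::coalesce(
      nm("Name"), nm("ID"),
      sprintf("%s:%d-%d", loci$contig, loci$start, loci$end)
    )
  } else {
    loci <- readr::read_tsv(path, show_col_types = FALSE,
                            comment = "#", progress = FALSE)
    need <- c("contig", "start", "end", "name")
    missing <- setdiff(need, names(loci))
    if (length(missing)) {
      stop_parse("%s: missing columns %s", path,
                 paste(missing, collapse = ", "))
    }
    if (!"strand" %in% names(loci)) loci$strand <- "*"
    loci$start <- as.integer(loci$start)
    loci$end <- as.integer(loci$end)
    loci <- loci[c("contig", "start", "end", "strand", "name")]
  }
  if (any(loci$start > loci$end)) {
    bad <- which(loci$start > loci$end)[1]
    stop_parse("%s: locus %s has start > end", path, loci$name[bad])
  }
  check_loci(loci)
  tibble::as_tibble(loci)
}

#' Write and read a presence/absence matrix CSV
#'
#' The CSV carries a `genome` column, a `class` column (SC / non-SC) and
#' one 0/1 column per gene, matching the layout of comparative-genomics
#' source-data tables.
#'
#' @param matrix Presence/absence tibble (see [gene_prevalence()]).
#' @param path File path.
#' @return `write_presence_matrix()` returns `path` invisibly;
#'   `read_presence_matrix()` returns the tibble.
#' @export
write_presence_matrix <- function(matrix, path) {
  check_pa_matrix(matrix, setdiff(names(matrix), c("genome", "class")))
  readr::write_csv(matrix, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_pa_matrix(m, setdiff(names(m), c("genome", "class")))
  m
}

#' Write and read a long-format abundance table TSV
#'
#' Columns `accession`, `group`, `replicate`, `abundance`; `NA` marks a
#' protein not detected in that replicate (distinct from zero).
#'
#' @param abundance Long abundance tibble (see [proteome_de()]).
#' @param path File path.
#' @return `write_abundance_table()` returns `path` invisibly;
#'   `read_abundance_table()` returns the tibble.
#' @export
write_abundance_table <- function(abundance, path) {
  readr::write_tsv(abundance, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  ab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          accession = readr::col_character(),
                          group = readr::col_character(),
                          replicate = readr::col_integer(),
                          abundance = readr::col_double()
                        ))
  need <- c("accession", "group", "replicate", "abundance")
  missing <- setdiff(need, names(ab))
  if (length(missing)) {
    stop_parse("%s: missing columns %s", path, paste(missing, collapse = ", "))
  }
  ab
}
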