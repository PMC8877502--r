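#' Read a peptide-spectrum-match (PSM) table
#'
#' Reads a tab-separated table of identified peptide observations and applies
#' the identification-quality filters used throughout the pipeline: an
#' expectation-value cut-off (`log_e` strictly below `log_e_max`), a limit on
#' missed tryptic cleavages, and an accepted precursor charge range. Rows
#' failing any filter are dropped and the rejected count is reported with a
#' message.
#'
#' The expected columns are `protein_id`, `peptide`, `charge`, `parent_mz`,
#' `retention_time`, `fragment_intensity_sum`, `sample_id`, `log_e` and
#' `missed_cleavages`. Lines starting with `#` are comments. The
#' `fragment_intensity_sum` column holds the summed MS/MS fragment-ion
#' intensity of the spectrum, the quantity later rolled up into protein
#' total ion counts (TIC).
#'
#' @param path Path to a tab-separated PSM file.
#' @param log_e_max Identification expectation score cut-off (log10 of the
#'   e-value); records are kept when `log_e < log_e_max`. Default -1.5.
#' @param max_missed_cleavages Maximum permitted missed tryptic cleavages
#'   (inclusive). Default 1.
#' @param charges Accepted precursor charge states. Default `2:4`.
#'
#' @return A tibble of accepted PSM records with attribute `n_rejected`
#'   (number of input rows removed by the filters).
#' @seealso [rollup_tic()] to aggregate PSMs into an expression matrix.
#' @export
read_psm_table <- function(path, log_e_max = -1.5, max_missed_cleavages = 1,
                           charges = 2:4) {
  if (!file.exists(path)) stop_format(paste0("PSM file not found: ", path))
  required <- c("protein_id", "peptide", "charge", "parent_mz",
                "retention_time", "fragment_intensity_sum", "sample_id",
                "log_e", "missed_cleavages")
  hdr_line <- readLines(path, warn = FALSE)
  hdr_line <- hdr_line[!grepl("^\\s*#", hdr_line) & nzchar(hdr_line)][1]
  if (is.na(hdr_line)) stop_format(paste0("PSM file has no header: ", path))
  header <- strsplit(hdr_line, "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop_format(paste0("PSM table is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  raw <- readr::read_tsv(
    path,
    comment = "#",
    col_types = readr::cols(
      protein_id = readr::col_character(),
      peptide = readr::col_character(),
      charge = readr::col_integer(),
      parent_mz = readr::col_double(),
      retention_time = readr::col_double(),
      fragment_intensity_sum = readr::col_double(),
      sample_id = readr::col_character(),
      log_e = readr::col_double(),
      missed_cleavages = readr::col_integer(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    bad <- probs[probs$col %in% match(required, names(raw)) |
                   probs$col %in% required, , drop = FALSE]
    if (nrow(bad) == 0) bad <- probs
    stop_format(paste0(
      "non-numeric or malformed value in PSM table at line ",
      bad$row[1] + 1L, " (column ", bad$col[1], ")"
    ))
  }
  if (any(raw$fragment_intensity_sum < 0, na.rm = TRUE)) {
    stop_format("fragment_intensity_sum must be non-negative")
  }
  keep <- raw$log_e < log_e_max &
    raw$missed_cleavages <= max_missed_cleavages &
    raw$charge %in% charges
  keep[is.na(keep)] <- FALSE
  out <- raw[keep, , drop = FALSE]
  n_rejected <- nrow(raw) - nrow(out)
  if (n_rejected > 0) {
    inform(paste0("read_psm_table: rejected ", n_rejected, " of ", nrow(raw),
                  " records failing identification filters"))
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. Recognised keys are `TITLE`,
#' `PEPMASS`, `CHARGE` and `RTINSECONDS`; unknown keys are ignored.
#' Retention times are converted from seconds to minutes. The per-spectrum
#' sum of fragment-ion intensities is returned as a derived column so
#' spectra can be joined to PSM assignments.
#'
#' @param path Path to an MGF file.
#' @return A tibble with one row per spectrum: `spectrum` (index), `title`,
#'   `charge`, `parent_mz`, `retention_time` (minutes), `n_fragments`,
#'   `fragment_intensity_sum`, and list-columns `fragment_mz` and
#'   `fragment_intensity`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop_format(paste0("MGF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    return(tibble(
      spectrum = integer(), title = character(), charge = integer(),
      parent_mz = double(), retention_time = double(),
      n_fragments = integer(), fragment_intensity_sum = double(),
      fragment_mz = list(), fragment_intensity = list()
    ))
  }
  # byte offset of the start of each line, for error reporting
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  records <- vector("list", length(begins))
  used_end <- 0L
  for (b in seq_along(begins)) {
    i <- begins[b]
    j <- ends[ends > i]
    j <- j[j > used_end]
    if (length(j) == 0) {
      stop_format(paste0("unterminated BEGIN IONS block starting at byte ",
                         offsets[i]))
    }
    j <- j[1]
    used_end <- j
    block <- lines[(i + 1L):(j - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    peaks <- block[!is_kv & nzchar(trimws(block))]
    if (!"PEPMASS" %in% keys) {
      warn(paste0("MGF spectrum at byte ", offsets[i],
                  " has no PEPMASS; skipped"))
      records[b] <- list(NULL)
      next
    }
    pepmass <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                                   "\\s+")[[1]][1])
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", trimws(vals[match("CHARGE", keys)])))
    } else {
      NA_integer_
    }
    rt_min <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[match("RTINSECONDS", keys)]) / 60
    } else {
      NA_real_
    }
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else NA_character_
    frag <- do.call(rbind, lapply(strsplit(trimws(peaks), "\\s+"), function(x) {
      as.numeric(x[1:2])
    }))
    mz <- if (is.null(frag)) double() else frag[, 1]
    inten <- if (is.null(frag)) double() else frag[, 2]
    if (any(inten < 0, na.rm = TRUE)) {
      stop_format(paste0("negative fragment intensity in spectrum at byte ",
                         offsets[i]))
    }
    records[[b]] <- tibble(
      title = title, charge = charge, parent_mz = pepmass,
      retention_time = rt_min, n_fragments = length(mz),
      fragment_intensity_sum = sum(inten),
      fragment_mz = list(mz), fragment_intensity = list(inten)
    )
  }
  records <- records[!vapply(records, is.null, logical(1))]
  out <- bind_rows(records)
  if (nrow(out) == 0) {
    return(tibble(
      spectrum = integer(), title = character(), charge = integer(),
      parent_mz = double(), retention_time = double(),
      n_fragments = integer(), fragment_intensity_sum = double(),
      fragment_mz = list(), fragment_intensity = list()
    ))
  }
  dplyr::bind_cols(tibble(spectrum = seq_len(nrow(out))), out)
}

#' Write spectra to a Mascot Generic Format (MGF) file
#'
#' Inverse of [read_mgf()] for the dialect this package reads: one
#' `BEGIN IONS` block per row, with `TITLE`, `PEPMASS`, `CHARGE` and
#' `RTINSECONDS` (minutes converted back to seconds) followed by
#' `m/z intensity` peak lines.
#'
#' @param spectra Tibble as returned by [read_mgf()] (the `spectrum` and
#'   derived columns are optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap_chr(
    list(
      spectra$title %||% rep(NA_character_, nrow(spectra)),
      spectra$charge, spectra$parent_mz, spectra$retention_time,
      spectra$fragment_mz, spectra$fragment_intensity
    ),
    function(title, charge, pepmass, rt, mz, inten) {
      hdr <- c(
        "BEGIN IONS",
        if (!is.na(title)) paste0("TITLE=", title),
        paste0("PEPMASS=", format(pepmass, digits = 15)),
        if (!is.na(charge)) paste0("CHARGE=", charge, "+"),
        if (!is.na(rt)) paste0("RTINSECONDS=", format(rt * 60, digits = 15))
      )
      peaks <- paste(format(mz, digits = 15, trim = TRUE),
                     format(inten, digits = 15, trim = TRUE))
      paste(c(hdr, peaks, "END IONS"), collapse = "\n")
    }
  )
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Construct a gene set
#'
#' A gene set is a named collection of unique accession strings (for
#' example NCU gene identifiers), used for compartment annotation, overlap
#' analysis against stress signatures, and enrichment testing. Accessions
#' are compared as exact, case-sensitive strings.
#'
#' @param name Non-empty set name.
#' @param ids Character vector of accessions; duplicates are collapsed.
#' @param source Free-text provenance (file path, citation, ...).
#' @return An object of class `gene_set` with elements `name`, `ids`,
#'   `source`.
#' @export
gene_set <- function(name, ids, source = "") {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop_config("gene_set name must be a non-empty string")
  }
  ids <- unique(as.character(ids))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  structure(list(name = name, ids = ids, source = source),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$ids), " accessions\n", sep = "")
  shown <- head(x$ids, 6)
  cat("  ", paste(shown, collapse = ", "),
      if (length(x$ids) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

as_gene_set <- function(x, name = "set") {
  if (inherits(x, "gene_set")) return(x)
  gene_set(name, x)
}

# Coerce a (possibly named) list of gene sets / character vectors.
as_gene_set_list <- function(xs) {
  nms <- names(xs) %||% rep("", length(xs))
  purrr::map2(xs, seq_along(xs), function(x, i) {
    if (inherits(x, "gene_set")) return(x)
    as_gene_set(x, if (nzchar(nms[i])) nms[i] else paste0("set", i))
  })
}

#' Read a gene set from a plain-text or TSV file
#'
#' Accepts either one accession per line, or a tab-separated file in which
#' case the first column (or the column named by `column`) is taken.
#' Duplicates are collapsed; ordering is irrelevant; case is preserved.
#' An empty file is an error: an empty set must be constructed explicitly
#' with [gene_set()].
#'
#' @param path File path.
#' @param name Set name; defaults to the file name without extension.
#' @param column Optional column name to read from a headered TSV file.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL, column = NULL) {
  if (!file.exists(path)) stop_format(paste0("gene set file not found: ", path))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  if (!is.null(column)) {
    tab <- readr::read_tsv(path, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
    if (!column %in% names(tab)) {
      stop_format(paste0("column '", column, "' not found in ", path))
    }
    ids <- as.character(tab[[column]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    # drop a header line if the first field is not accession-like data
    ids <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
    ids <- trimws(ids)
  }
  ids <- ids[!is.na(ids) & nzchar(ids)]
  if (length(ids) == 0) {
    stop_format(paste0("gene set file is empty: ", path,
                       " (construct an empty set explicitly with gene_set())"))
  }
  gene_set(name, ids, source = path)
}

#' Write a result table to TSV with a provenance header
#'
#' Writes any result tibble as tab-separated values preceded by `#` comment
#' lines recording the package version, a hash of the table contents, and
#' any caller-supplied provenance fields (input digests, configuration
#' hashes). Numeric columns are written with full round-trip precision, and
#' the output contains no timestamps so repeated runs are byte-identical.
#'
#' @param table A data frame (list-columns are dropped with a message).
#' @param path Output path.
#' @param provenance Optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(table, path, provenance = NULL) {
  if (is.null(table)) stop_config("write_results: table must not be NULL")
  table <- as_tibble(table)
  is_list_col <- vapply(table, is.list, logical(1))
  if (any(is_list_col)) {
    inform(paste0("write_results: dropping list column(s): ",
                  paste(names(table)[is_list_col], collapse = ", ")))
    table <- table[, !is_list_col, drop = FALSE]
  }
  hdr <- c(
    paste0("# ticdiff ", as.character(packageVersion("ticdiff"))),
    paste0("# table_hash: ", config_hash(table)),
    if (!is.null(provenance)) paste0("# ", names(provenance), ": ", provenance)
  )
  body <- readr::format_tsv(table)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, sub("\n$", "", body)), con = con, sep = "\n")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a TSV file with `#` comment headers.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
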