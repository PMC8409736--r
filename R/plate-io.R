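#' Construct a plate of growth curves
#'
#' The basic container for a plate-reader assay: a shared, strictly
#' increasing time axis (hours) and one row of optical-density readings per
#' well. Gaps (missing readings) are not allowed.
#'
#' @param od numeric matrix, wells in rows, time points in columns.
#' @param time time vector in hours, strictly increasing, one per column.
#' @param wells well labels, one per row (e.g. `"A1"`..`"H12"`).
#' @param plate_id plate identifier.
#' @return object of class `"growth_plate"`.
#' @export
growth_plate <- function(od, time, wells, plate_id = "plate") {
  od <- as.matrix(od)
  storage.mode(od) <- "double"
  if (length(time) != ncol(od))
    stop("time length (", length(time), ") must equal od columns (", ncol(od), ")")
  if (length(wells) != nrow(od))
    stop("wells length must equal od rows")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (anyDuplicated(wells)) stop("duplicate well labels: ",
                                 paste(unique(wells[duplicated(wells)]), collapse = ", "))
  if (anyNA(od)) {
    bad <- which(is.na(od), arr.ind = TRUE)[1L, ]
    stop("missing reading at well ", wells[bad[1L]], ", time point ", bad[2L])
  }
  rownames(od) <- wells
  structure(list(plate_id = plate_id, wells = as.character(wells),
                 time = as.numeric(time), od = od),
            class = "growth_plate")
}

#' @export
print.growth_plate <- function(x, ...) {
  cat(sprintf("growth_plate '%s': %d wells x %d time points (%.2f-%.2f h)\n",
              x$plate_id, length(x$wells), length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Read a plate-reader text file
#'
#' Accepts tab- or comma-delimited matrices with either wells in rows and
#' time points in columns, or the transpose; the axis whose labels match
#' the 96-well pattern `A1`--`H12` is taken as the well axis. A time
#' header/column is optional: when absent, times are generated as
#' `0, interval, 2*interval, ...` from `config$interval_seconds` and
#' converted to hours. Explicit numeric time values larger than 100 are
#' interpreted as seconds and divided by 3600 unless
#' `config$time_units` says otherwise.
#'
#' @param path path to the delimited text file.
#' @param config a [growth_config()] list (uses `interval_seconds`,
#'   `time_units`).
#' @param plate_id plate identifier; defaults to the file name without
#'   extension.
#' @return a [growth_plate()].
#' @export
read_plate <- function(path, config = growth_config(),
                       plate_id = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("plate file has fewer than two rows: ", path)
  delim <- if (lengths(gregexpr("\t", lines[1L], fixed = TRUE))[1L] >=
               lengths(gregexpr(",", lines[1L], fixed = TRUE))[1L]) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  nc <- lengths(cells)
  if (length(unique(nc)) != 1L)
    stop("ragged rows in ", path, ": row ", which(nc != nc[1L])[1L],
         " has ", nc[nc != nc[1L]][1L], " fields, expected ", nc[1L])
  M <- trimws(do.call(rbind, cells))

  row_wells <- is_well_label(M[-1L, 1L])
  col_wells <- is_well_label(M[1L, -1L])
  if (all(is_well_label(M[, 1L]))) {
    # rows are wells, no header row
    parse_plate(wells = M[, 1L], values = M[, -1L, drop = FALSE],
                times = NULL, config = config, plate_id = plate_id)
  } else if (all(row_wells)) {
    # rows are wells, header row may carry times
    hdr <- M[1L, -1L]
    times <- suppressWarnings(as.numeric(hdr))
    parse_plate(wells = M[-1L, 1L], values = M[-1L, -1L, drop = FALSE],
                times = if (!anyNA(times)) times, config = config,
                plate_id = plate_id)
  } else if (all(is_well_label(M[1L, ]))) {
    # columns are wells, no time column
    parse_plate(wells = M[1L, ], values = t(M[-1L, , drop = FALSE]),
                times = NULL, config = config, plate_id = plate_id)
  } else if (all(col_wells)) {
    # columns are wells, first column may carry times
    tc <- suppressWarnings(as.numeric(M[-1L, 1L]))
    parse_plate(wells = M[1L, -1L], values = t(M[-1L, -1L, drop = FALSE]),
                times = if (!anyNA(tc)) tc, config = config,
                plate_id = plate_id)
  } else {
    stop("could not locate a well-label axis (A1-H12) in ", path)
  }
}

parse_plate <- function(wells, values, times, config, plate_id) {
  num <- suppressWarnings(matrix(as.numeric(values), nrow = nrow(values)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("unparseable value '", values[bad[1L], bad[2L]], "' at well ",
         wells[bad[1L]], ", time point ", bad[2L])
  }
  if (is.null(times)) {
    times <- (seq_len(ncol(num)) - 1L) * config$interval_seconds / 3600
  } else {
    units <- config$time_units %||% "auto"
    if (units == "seconds" || (units == "auto" && max(times) > 100))
      times <- times / 3600
  }
  growth_plate(num, times, wells, plate_id = plate_id)
}

#' Read well/plate metadata mapping tables
#'
#' Each mapping file is a delimited table with a header containing at least
#' `well_id` (or `well`); an optional master table keyed by `plate_id`
#' broadcasts values to all wells of a plate, with well-level values taking
#' precedence. Unknown columns are preserved as extra covariates. Missing
#' fields default to `group = "all"`, `is_blank = FALSE`,
#' `is_control = FALSE`.
#'
#' @param mapping_paths character vector of mapping file paths (may be
#'   empty).
#' @param master_path optional master metadata table path.
#' @param plate_ids plate id to assume for mapping files lacking a
#'   `plate_id` column (recycled along `mapping_paths`).
#' @return data.frame of per-well metadata.
#' @export
read_well_map <- function(mapping_paths, master_path = NULL,
                          plate_ids = tools::file_path_sans_ext(basename(mapping_paths))) {
  maps <- list()
  for (i in seq_along(mapping_paths)) {
    m <- read_delim_auto(mapping_paths[i])
    names(m)[names(m) == "well"] <- "well_id"
    if (!"well_id" %in% names(m))
      stop("mapping file lacks a well_id column: ", mapping_paths[i])
    if (!"plate_id" %in% names(m)) m$plate_id <- plate_ids[i]
    maps[[i]] <- m
  }
  meta <- if (length(maps)) do.call(rbind_fill, maps) else
    data.frame(plate_id = character(0), well_id = character(0))

  key <- paste(meta$plate_id, meta$well_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    rows <- meta[key %in% dup, , drop = FALSE]
    if (nrow(unique(rows)) != length(unique(key[key %in% dup])))
      stop("conflicting duplicate metadata rows for: ",
           paste(unique(dup), collapse = ", "))
    meta <- meta[!duplicated(key), , drop = FALSE]
  }

  if (!is.null(master_path)) {
    master <- read_delim_auto(master_path)
    if (!"plate_id" %in% names(master))
      stop("master table lacks a plate_id column: ", master_path)
    for (p in master$plate_id) {
      mrow <- master[master$plate_id == p, setdiff(names(master), "plate_id"),
                     drop = FALSE]
      sel <- meta$plate_id == p
      if (!any(sel)) next
      for (col in names(mrow)) {
        if (!col %in% names(meta)) meta[[col]] <- NA
        fill <- is.na(meta[[col]]) | (is.character(meta[[col]]) & meta[[col]] == "")
        meta[[col]][sel & fill] <- mrow[[col]][1L]
      }
    }
  }

  for (col in c("substrate", "strain", "group")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
    meta[[col]] <- as.character(meta[[col]])
  }
  meta$group[is.na(meta$group) | meta$group == ""] <- "all"
  for (col in c("is_blank", "is_control")) {
    meta[[col]] <- if (col %in% names(meta)) parse_flag(meta[[col]]) else FALSE
  }
  if (any(meta$is_blank & meta$is_control))
    stop("a well cannot be both blank and a group control")
  rownames(meta) <- NULL
  meta
}

read_delim_auto <- function(path) {
  l1 <- readLines(path, n = 1L)
  sep <- if (lengths(gregexpr("\t", l1, fixed = TRUE))[1L] >=
             lengths(gregexpr(",", l1, fixed = TRUE))[1L]) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

parse_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("1", "true", "t", "yes", "y")
}

#' Biolog PM1 plate layout from a file name
#'
#' Recognizes Biolog phenotype-microarray PM1 plates from a token in the
#' file name (e.g. `"CD2015_PM1-1.txt"`) and returns the packaged
#' well-to-carbon-substrate map; well A1 is the no-substrate minimal-medium
#' control and is flagged `is_control`. Returns `NULL` for file names
#' without a recognized token. Other PM plate types are supplied by user
#' mapping files.
#'
#' @param filename file name or path.
#' @return data.frame with `well_id`, `substrate`, `is_control`, or `NULL`.
#' @export
biolog_layout <- function(filename) {
  if (!grepl("PM0?1([^0-9]|$)", basename(filename))) return(NULL)
  data.frame(well_id = well_labels_96(),
             substrate = pm1_substrates,
             is_control = c(TRUE, rep(FALSE, 95L)),
             stringsAsFactors = FALSE)
}

# Biolog PM1 carbon-source layout, row-major A1..H12; A1 is the
# negative (minimal medium) control.
pm1_substrates <- c(
  "Negative Control", "L-Arabinose", "N-Acetyl-D-Glucosamine",
  "D-Saccharic Acid", "Succinic Acid", "D-Galactose", "L-Aspartic Acid",
  "L-Proline", "D-Alanine", "D-Trehalose", "D-Mannose", "Dulcitol",
  "D-Serine", "D-Sorbitol", "Glycerol", "L-Fucose", "D-Glucuronic Acid",
  "D-Gluconic Acid", "D,L-alpha-Glycerol Phosphate", "D-Xylose",
  "L-Lactic Acid", "Formic Acid", "D-Mannitol", "L-Glutamic Acid",
  "D-Glucose-6-Phosphate", "D-Galactonic Acid gamma-Lactone",
  "D,L-Malic Acid", "D-Ribose", "Tween 20", "L-Rhamnose", "D-Fructose",
  "Acetic Acid", "alpha-D-Glucose", "Maltose", "D-Melibiose", "Thymidine",
  "L-Asparagine", "D-Aspartic Acid", "D-Glucosaminic Acid",
  "1,2-Propanediol", "Tween 40", "alpha-Keto-Glutaric Acid",
  "alpha-Keto-Butyric Acid", "alpha-Methyl-D-Galactoside", "alpha-D-Lactose",
  "Lactulose", "Sucrose", "Uridine", "L-Glutamine", "m-Tartaric Acid",
  "D-Glucose-1-Phosphate", "D-Fructose-6-Phosphate", "Tween 80",
  "alpha-Hydroxy-Glutaric Acid gamma-Lactone", "alpha-Hydroxy-Butyric Acid",
  "beta-Methyl-D-Glucoside", "Adonitol", "Maltotriose", "2-Deoxy-Adenosine",
  "Adenosine", "Glycyl-L-Aspartic Acid", "Citric Acid", "myo-Inositol",
  "D-Threonine", "Fumaric Acid", "Bromo-Succinic Acid", "Propionic Acid",
  "Mucic Acid", "Glycolic Acid", "Glyoxylic Acid", "D-Cellobiose",
  "Inosine", "Glycyl-L-Glutamic Acid", "Tricarballylic Acid", "L-Serine",
  "L-Threonine", "L-Alanine", "L-Alanyl-Glycine", "Acetoacetic Acid",
  "N-Acetyl-beta-D-Mannosamine", "Mono-Methyl Succinate", "Methyl Pyruvate",
  "D-Malic Acid", "L-Malic Acid", "Glycyl-L-Proline",
  "p-Hydroxy-Phenylacetic Acid", "m-Hydroxy-Phenylacetic Acid", "Tyramine",
  "D-Psicose", "L-Lyxose", "Glucuronamide", "Pyruvic Acid",
  "L-Galactonic Acid gamma-Lactone", "D-Galacturonic Acid",
  "Phenylethylamine", "2-Aminoethanol")

#' Write parameter and prediction tables
#'
#' Writes two tab-delimited tables to a directory: a parameter table
#' (`<prefix>_summary.txt`, one row per well or pooled condition) and a
#' prediction table (`<prefix>_fitted.txt`, with time, predicted mean, band
#' bounds and derivative mean). Ordering is deterministic: wells/conditions
#' row-major in their given order, time ascending. Numeric fields are
#' written with 15 significant digits so a re-read preserves at least 6.
#'
#' @param results list with data.frames `params` and `predictions` (either
#'   may be omitted).
#' @param out_dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the paths written.
#' @export
write_growth_tables <- function(results, out_dir, prefix = "gpgrowth") {
  if (length(results) == 0L || (is.null(results$params) && is.null(results$predictions)))
    stop("results must contain a 'params' and/or a 'predictions' data.frame")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  wt <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) signif(x, 15))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    path
  }
  if (!is.null(results$params))
    paths <- c(paths, wt(results$params,
                         file.path(out_dir, paste0(prefix, "_summary.txt"))))
  if (!is.null(results$predictions))
    paths <- c(paths, wt(results$predictions,
                         file.path(out_dir, paste0(prefix, "_fitted.txt"))))
  invisible(paths)
}
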