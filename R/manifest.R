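# Dataset manifests: a data.frame with one row per cytology image plus a
# provenance note, written/read as plain CSV. Columns follow a fixed schema so
# manifests round-trip across labs; unknown stains and species collapse to
# "other" with a logged warning rather than failing the load.

MANIFEST_COLUMNS <- c(
  "image_path", "subject_id", "species", "strain", "stain", "magnification",
  "lab", "collected_at_days", "stage", "leukocyte_frac", "cornified_frac",
  "nucleated_frac", "total_cells", "exclude", "width", "height"
)

KNOWN_SPECIES <- c("mouse", "rat")
KNOWN_STAINS <- c("HE", "Shorr", "Giemsa", "CresylViolet", "CrystalViolet")
KNOWN_MAGNIFICATIONS <- c("10x", "20x")

#' Construct a dataset manifest
#'
#' A manifest is a `data.frame` (class `estrous_manifest`) with one row per
#' image and a fixed column schema; missing optional columns are filled with
#' `NA`. `image_path` values must be unique.
#'
#' @param records A `data.frame` with at least an `image_path` column; the
#'   remaining schema columns (`subject_id`, `species`, `strain`, `stain`,
#'   `magnification`, `lab`, `collected_at_days`, `stage`, `leukocyte_frac`,
#'   `cornified_frac`, `nucleated_frac`, `total_cells`, `exclude`, `width`,
#'   `height`) are optional.
#' @param provenance Free-text note on where the records came from.
#' @return An `estrous_manifest`.
#' @export
as_manifest <- function(records, provenance = "") {
  if (!is.data.frame(records)) stopf("records must be a data.frame")
  if (!"image_path" %in% names(records)) {
    stopf("manifest schema error: missing required column 'image_path'")
  }
  m <- records
  for (col in MANIFEST_COLUMNS) {
    if (!col %in% names(m)) {
      m[[col]] <- if (col %in% c("collected_at_days", "leukocyte_frac",
                                 "cornified_frac", "nucleated_frac",
                                 "width", "height")) NA_real_
                  else if (col == "total_cells") NA_integer_
                  else if (col == "exclude") FALSE
                  else NA_character_
    }
  }
  extra <- setdiff(names(m), MANIFEST_COLUMNS)
  m <- m[, c(MANIFEST_COLUMNS, extra), drop = FALSE]
  if (anyDuplicated(m$image_path)) stopf("manifest image_path values must be unique")
  if (!all(is.na(m$stage))) m$stage <- normalize_stage(m$stage)
  m$exclude <- isTRUE_vec(m$exclude)
  bad_dim <- !is.na(m$width) & !is.na(m$height) & (m$width < 1 | m$height < 1)
  if (any(bad_dim)) stopf("manifest rows with width/height < 1: %s",
                          paste(which(bad_dim), collapse = ", "))
  map_other <- function(x, known, what) {
    x <- as.character(x)
    # case-insensitive match onto the canonical spelling
    idx <- match(tolower(x), tolower(known))
    out <- ifelse(is.na(x), NA_character_, ifelse(is.na(idx), "other", known[idx]))
    unknown <- !is.na(x) & is.na(idx) & tolower(x) != "other"
    if (any(unknown)) {
      ec_log("load_manifest: unknown %s value(s) %s mapped to 'other'", what,
             paste(unique(x[unknown]), collapse = ", "))
    }
    out
  }
  m$species <- map_other(m$species, KNOWN_SPECIES, "species")
  m$stain <- map_other(m$stain, KNOWN_STAINS, "stain")
  m$magnification <- map_other(m$magnification, KNOWN_MAGNIFICATIONS, "magnification")
  rownames(m) <- NULL
  structure(m, provenance = provenance,
            class = c("estrous_manifest", "data.frame"))
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' @export
print.estrous_manifest <- function(x, ...) {
  cat(sprintf("<estrous_manifest> %d image record(s)\n", nrow(x)))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("provenance:", attr(x, "provenance"), "\n")
  }
  st <- table(factor(x$stage, levels = c(canonical_stages(), transition_stages())))
  st <- st[st > 0]
  if (length(st)) cat("stages:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  print(utils::head(as.data.frame(x)[, c("image_path", "subject_id", "stain", "stage")], 5))
  invisible(x)
}

#' Read a dataset manifest from CSV
#'
#' The CSV must carry a header row including `image_path`; all other schema
#' columns are optional. Stage labels are normalised through the alias table
#' (`"E"` becomes `"estrus"`, etc.); unknown stains/species/magnifications map
#' to `"other"` with a logged warning. When `width`/`height` are absent and
#' the image file is a readable PNG, dimensions are filled from the file
#' header.
#'
#' @param path Path to a manifest CSV.
#' @param read_dimensions Logical; probe PNG files for missing dimensions.
#' @return An `estrous_manifest`.
#' @export
load_manifest <- function(path, read_dimensions = TRUE) {
  if (!file.exists(path)) stopf("manifest file not found: %s", path)
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stopf("failed to parse manifest %s: %s", path, conditionMessage(e))
  )
  if (!"image_path" %in% names(df)) {
    stopf("manifest schema error: missing required column 'image_path' in %s", path)
  }
  bad <- which(is.na(df$image_path) | !nzchar(trimws(df$image_path)))
  if (length(bad)) {
    stopf("manifest %s: unparseable row(s) at line(s) %s (empty image_path)",
          path, paste(bad + 1L, collapse = ", "))
  }
  m <- as_manifest(df, provenance = sprintf("loaded from %s", path))
  if (read_dimensions) {
    need <- which(is.na(m$width) | is.na(m$height))
    for (i in need) {
      p <- m$image_path[i]
      if (file.exists(p) && grepl("\\.png$", p, ignore.case = TRUE)) {
        dims <- tryCatch(dim(png::readPNG(p)), error = function(e) NULL)
        if (!is.null(dims)) {
          m$height[i] <- dims[1]
          m$width[i] <- dims[2]
        }
      }
    }
  }
  m
}

#' Write a dataset manifest to CSV
#'
#' Inverse of [load_manifest()]: `load_manifest(write_manifest(m))` reproduces
#' `m` field for field.
#'
#' @param m An `estrous_manifest`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the curation exclusion filters
#'
#' Mirrors the bank-curation rules: images smaller than `min_pixels` on either
#' side, images with fewer than `min_cells` counted cells (only when a total
#' cell count is recorded), and images manually marked `exclude = TRUE` are
#' removed. Records lacking dimensions or counts are retained. The filter is
#' idempotent. Every exclusion is logged with its rule and collected in the
#' `exclusions` attribute of the result.
#'
#' @param m An `estrous_manifest`.
#' @param min_pixels Minimum width and height in pixels (default 300).
#' @param min_cells Minimum total cell count (default 10), applied only to
#'   records carrying `total_cells`.
#' @return The filtered `estrous_manifest`, with an `exclusions` attribute
#'   (data.frame of `image_path`, `reason`).
#' @export
apply_exclusion_filters <- function(m, min_pixels = 300, min_cells = 10) {
  if (min_pixels < 1) stopf("min_pixels must be >= 1")
  if (min_cells < 0) stopf("min_cells must be >= 0")
  reasons <- character(nrow(m))
  too_small <- !is.na(m$width) & !is.na(m$height) &
    (pmin(m$width, m$height) < min_pixels)
  reasons[too_small] <- sprintf("min(width,height) < %d pixels", min_pixels)
  few_cells <- !is.na(m$total_cells) & m$total_cells < min_cells
  reasons[few_cells & !too_small] <- sprintf("n < %d cells", min_cells)
  manual <- m$exclude & !too_small & !few_cells
  reasons[manual] <- "manual exclude flag"
  drop <- too_small | few_cells | m$exclude
  for (i in which(drop)) {
    ec_log("exclusion: %s (%s)", m$image_path[i], reasons[i])
  }
  out <- m[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, provenance = attr(m, "provenance"),
                   class = class(m))
  attr(out, "exclusions") <- data.frame(
    image_path = m$image_path[drop],
    reason = reasons[drop],
    stringsAsFactors = FALSE
  )
  out
}

#' Serialize classification results to JSON
#'
#' Writes one JSON object per image with the predicted stage, the per-stage
#' probability vector, the Confidence Index, the post-hoc flags and (when
#' available) the fitted cycle phase. Values round-trip losslessly through
#' [read_results()].
#'
#' @param results A list of classification results as produced by
#'   [classification_result()] / [resolve_prediction()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  if (length(results) == 0) stopf("results must be non-empty")
  if (inherits(results, "estrous_result")) results <- list(results)
  payload <- lapply(results, function(r) {
    stopifnot(inherits(r, "estrous_result"))
    unclass(r)
  })
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot write results to %s: %s", path, conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), con)
  invisible(path)
}

#' Read classification results from JSON
#'
#' @param path JSON file written by [write_results()].
#' @return A list of `estrous_result` objects.
#' @export
read_results <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    r$probabilities <- unlist(r$probabilities)
    structure(r, class = "estrous_result")
  })
}
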