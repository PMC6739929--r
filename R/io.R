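#' Read a cohort manifest
#'
#' Reads and validates the cohort CSV with header
#' `sample_id,image,mask,er,pr,her2,subtype`. Receptor strings are normalized
#' case-insensitively to `pos`/`neg`/`unknown`; `subtype` to one of
#' `LuminalA`, `LuminalB`, `HER2E`, `TN`, `unknown`. Relative image/mask
#' paths are resolved against the manifest's directory. Every row must carry
#' either a full receptor triplet or a subtype.
#'
#' @param path Path to the manifest CSV.
#' @param check_files Verify that referenced image/mask files exist
#'   (default `TRUE`).
#' @return A `cohort_manifest` data frame.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "image", "mask", "er", "pr", "her2", "subtype")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id in manifest: ", paste(unique(dup), collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  df$image <- resolve(df$image)
  df$mask <- resolve(df$mask)
  for (col in c("er", "pr", "her2")) {
    df[[col]] <- normalize_status(df[[col]], col)
  }
  df$subtype <- normalize_subtype(df$subtype)
  no_label <- df$subtype == "unknown" &
    (df$er == "unknown" | df$pr == "unknown" | df$her2 == "unknown")
  if (any(no_label)) {
    stop("manifest rows without receptor triplet or subtype: ",
         paste(df$sample_id[no_label], collapse = ", "))
  }
  if (check_files) {
    for (i in seq_len(nrow(df))) {
      for (col in c("image", "mask")) {
        if (!file.exists(df[[col]][i])) {
          stop(sprintf("row '%s': %s file not found: %s",
                       df$sample_id[i], col, df[[col]][i]))
        }
      }
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

normalize_status <- function(x, what) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- "unknown"
  x[x %in% c("pos", "positive", "+", "1", "true")] <- "pos"
  x[x %in% c("neg", "negative", "-", "0", "false")] <- "neg"
  x[x %in% c("", "na", "unknown", "nan")] <- "unknown"
  bad <- !x %in% c("pos", "neg", "unknown")
  if (any(bad)) {
    stop(sprintf("unrecognized %s status: %s", what,
                 paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

normalize_subtype <- function(x) {
  x <- trimws(as.character(x))
  key <- tolower(gsub("[^[:alnum:]]", "", x))
  key[is.na(key)] <- "unknown"
  map <- c(luminala = "LuminalA", luma = "LuminalA",
           luminalb = "LuminalB", lumb = "LuminalB",
           her2e = "HER2E", her2enriched = "HER2E",
           tn = "TN", triplenegative = "TN",
           unknown = "unknown", na = "unknown")
  key[key == ""] <- "unknown"
  out <- unname(map[key])
  out[is.na(out)] <- x[is.na(out)]   # pass through custom class names
  out
}

#' Read a lesion image/mask pair
#'
#' Loads a grayscale image (TIFF or PNG, 8- or 16-bit) and its binary mask
#' (any nonzero pixel is foreground). Both must have identical pixel
#' dimensions and the mask must contain at least 16 pixels (small-lesion
#' floor that keeps matrix statistics meaningful).
#'
#' @param image_path,mask_path File paths.
#' @return List with `image` (integer matrix) and `mask` (logical matrix).
#' @export
read_lesion <- function(image_path, mask_path) {
  img <- read_gray(image_path)
  msk <- read_gray(mask_path) > 0
  if (!all(dim(img) == dim(msk))) {
    stop(sprintf("mask dimensions (%s) do not match image (%s) for %s",
                 paste(dim(msk), collapse = "x"),
                 paste(dim(img), collapse = "x"), image_path))
  }
  if (sum(msk) < 16) {
    stop(sprintf("mask %s has %d foreground pixels; at least 16 required",
                 mask_path, sum(msk)))
  }
  list(image = img, mask = msk)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  # readers scale to [0,1]; restore 16-bit integer intensities
  matrix(as.integer(round(arr * 65535)), nrow(arr), ncol(arr))
}

# 16-bit grayscale TIFF writer (values 0..65535)
write_image16 <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image / 65535, 0), 1), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# 8-bit PNG mask writer, foreground = 255
write_mask <- function(mask, path) {
  png::writePNG(matrix(ifelse(mask, 1, 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write / read a radiomic feature table
#'
#' Feature tables are CSVs with a `sample_id` column followed by the 352
#' registry features in canonical order; the round trip is lossless to at
#' least 12 significant digits. Writing refuses non-finite values; reading
#' rejects unknown feature columns.
#'
#' @param table Data frame as returned by [extract_cohort()].
#' @param path CSV path.
#' @return `read_feature_table` returns the feature table;
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot("sample_id" %in% names(table))
  feat <- setdiff(names(table), "sample_id")
  unknown <- setdiff(feat, feature_registry())
  if (length(unknown) > 0) {
    stop("unknown feature column(s): ", paste(unknown[1:min(3, length(unknown))],
                                              collapse = ", "))
  }
  vals <- as.matrix(table[feat])
  if (!all(is.finite(vals))) {
    stop("feature table contains non-finite values; refusing to write")
  }
  ord <- intersect(feature_registry(), feat)
  out <- table[c("sample_id", ord)]
  # fixed 15-significant-digit formatting for deterministic, lossless output
  for (col in ord) out[[col]] <- sprintf("%.15g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("feature table lacks sample_id column")
  feat <- setdiff(names(df), "sample_id")
  unknown <- setdiff(feat, feature_registry())
  if (length(unknown) > 0) {
    stop("unknown feature column(s): ", paste(unknown[1:min(3, length(unknown))],
                                              collapse = ", "))
  }
  for (col in feat) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Write / read a frozen feature set
#'
#' Feature sets (selected feature names with criterion scores and the
#' sample-size-derived subset size) are stored as JSON so external-validation
#' runs can reuse exactly the features selected on a training cohort.
#'
#' @param selection A `selection_result` from [select_features()].
#' @param path JSON path.
#' @export
write_featureset <- function(selection, path) {
  stopifnot(inherits(selection, "selection_result"))
  jsonlite::write_json(
    list(criterion = selection$criterion, k = selection$k,
         pair = selection$pair, features = selection$ranked$feature,
         scores = selection$ranked$score),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_featureset
#' @export
read_featureset <- function(path) {
  if (!file.exists(path)) stop("feature set not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(criterion = js$criterion, k = as.integer(js$k),
                 pair = js$pair,
                 ranked = data.frame(feature = js$features,
                                     score = as.numeric(js$scores),
                                     stringsAsFactors = FALSE)),
            class = "selection_result")
}
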