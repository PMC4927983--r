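#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG, TIFF or PGM image as a numeric matrix of
#' intensities in \[0, 1\]. RGB(A) input is converted to luminance
#' (Rec. 709 weights, alpha ignored).
#'
#' @param path Path to a `.png`, `.tif(f)` or `.pgm` file.
#' @return A numeric matrix (rows x cols) with values in \[0, 1\].
#' @seealso [write_gray_image()], [read_mask()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot decode PNG: ", path,
                                             call. = FALSE)),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("cannot decode TIFF: ", path,
                                             call. = FALSE)),
    pgm  = read_pgm(path),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L)
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img[, , 1]
  }
  if (!is.matrix(img) || nrow(img) == 0L || ncol(img) == 0L)
    stop("zero-sized or malformed image: ", path, call. = FALSE)
  clamp01(img)
}

#' Write a grayscale image
#'
#' Writes a \[0, 1\] intensity matrix as an 8-bit PNG, TIFF or plain-text PGM
#' (P2) file, quantizing to 256 levels.
#'
#' @param img Numeric matrix with values in \[0, 1\].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  img <- clamp01(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    pgm  = write_pgm(img, path),
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  invisible(path)
}

# plain (P2) and raw (P5) 8-bit PGM support; no installed R package reads PGM
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5"))
    stop("cannot decode PGM (bad magic '", magic, "'): ", path, call. = FALSE)
  tokens <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "")
        stop("truncated PGM header: ", path, call. = FALSE)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (ch == "\n" || ch == "") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("zero-sized image: ", path, call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE,
                 comment.char = "#")
  }
  if (length(vals) < n) stop("truncated PGM data: ", path, call. = FALSE)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path) {
  q <- round(clamp01(img) * 255)
  lines <- c("P2", paste(ncol(img), nrow(img)), "255",
             apply(q, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write binary lesion masks
#'
#' Masks are stored on disk as 8-bit grayscale images with 0 = background and
#' 255 = lesion; in memory they are logical matrices.
#'
#' @param path Image path (`.png`, `.tif(f)` or `.pgm`).
#' @return `read_mask()` returns a logical matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) read_gray_image(path) > 0.5

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  write_gray_image(mask * 1.0, path)
}

#' Write a morphological feature table to CSV
#'
#' @param rows Either a tibble/data.frame with columns `id`, `label` and one
#'   column per feature, or a list of lists each holding `id`, `label` and
#'   `features` (a named numeric vector). All rows must share the same feature
#'   names in the same order.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  tbl <- as_feature_table(rows)
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(tbl)
}

as_feature_table <- function(rows) {
  if (is.data.frame(rows)) {
    if (nrow(rows) == 0L) stop("empty feature table", call. = FALSE)
    stopifnot(all(c("id", "label") %in% names(rows)))
    return(as_tibble(rows))
  }
  if (!is.list(rows) || length(rows) == 0L)
    stop("empty feature table", call. = FALSE)
  nm <- names(rows[[1]]$features)
  for (r in rows) {
    if (!identical(names(r$features), nm))
      stop("feature names differ between rows", call. = FALSE)
  }
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble(id = r$id, label = r$label, !!!as.list(r$features))
  }))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_tibble(utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE))
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end pipeline and validates
#' them. Window sizes must be odd (symmetric neighbourhoods); the train
#' fraction defaults to the conventional 70/30 split.
#'
#' @param preprocess_window Odd integer, Wiener filter window (px).
#' @param median_window Odd integer, median filter window (px).
#' @param segmenter_name One of `"active_contour"`, `"region_growing"`,
#'   `"fuzzy_cmeans"`, `"kmeans"`, `"som"`.
#' @param mlp_hidden Positive integer, hidden-layer size of the classifier.
#' @param mlp_learning_rate Learning rate in (0, 1).
#' @param train_fraction Fraction of cases assigned to training, in (0, 1).
#' @param rng_seed Integer seed governing all stochastic steps.
#' @return A `bus_config` list.
#' @export
pipeline_config <- function(preprocess_window = 5L, median_window = 3L,
                            segmenter_name = "som", mlp_hidden = 2L,
                            mlp_learning_rate = 0.5, train_fraction = 0.7,
                            rng_seed = 1L) {
  stopifnot_odd_window(preprocess_window, "preprocess_window")
  stopifnot_odd_window(median_window, "median_window")
  segmenter_name <- match.arg(segmenter_name,
    c("som", "active_contour", "region_growing", "fuzzy_cmeans", "kmeans"))
  if (mlp_hidden < 1L) stop("mlp_hidden must be >= 1", call. = FALSE)
  if (mlp_learning_rate <= 0 || mlp_learning_rate >= 1)
    stop("mlp_learning_rate must be in (0, 1)", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  structure(list(
    preprocess_window = as.integer(preprocess_window),
    median_window = as.integer(median_window),
    segmenter_name = segmenter_name,
    mlp_hidden = as.integer(mlp_hidden),
    mlp_learning_rate = mlp_learning_rate,
    train_fraction = train_fraction,
    rng_seed = as.integer(rng_seed)
  ), class = "bus_config")
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Keys match the arguments of [pipeline_config()]; unknown keys
#' are an error. Values given on the command line should override these.
#'
#' @param path Path to the configuration file.
#' @return A validated `bus_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (is.na(num)) val else num
  }
  unknown <- setdiff(names(args), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, args)
}
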