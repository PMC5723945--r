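# Image readers/writers. Everything is mapped to a plain numeric matrix on
# the 0--255 intensity scale; plain-text matrices are passed through as-is
# so they round-trip bit-exactly.

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

luminance <- function(arr) {
  if (length(dim(arr)) == 3) {
    warning("multi-channel image converted to luminance average", call. = FALSE)
    arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  }
  arr
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  tokens <- integer(0)
  if (magic == "P2") {
    txt <- readLines(con, warn = FALSE)
    txt <- sub("#.*", "", txt)
    tokens <- as.numeric(unlist(strsplit(paste(txt, collapse = " "), "[[:space:]]+")))
    tokens <- tokens[!is.na(tokens)]
    hdr <- tokens[1:3]; vals <- tokens[-(1:3)]
  } else {
    # read header tokens byte-wise (width height maxval), then raster
    tok <- character(0)
    while (length(tok) < 3) {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (ch == "#") repeat {
        ch <- readChar(con, 1, useBytes = TRUE); if (ch %in% c("\n", "\r")) break
      }
      if (grepl("[[:space:]]", ch)) next
      word <- ch
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (grepl("[[:space:]]", ch) || ch == "") break
        word <- paste0(word, ch)
      }
      tok <- c(tok, word)
    }
    hdr <- as.numeric(tok)
    nbytes <- if (hdr[3] > 255) 2L else 1L
    vals <- readBin(con, "integer", n = hdr[1] * hdr[2], size = nbytes,
                    signed = FALSE, endian = "big")
  }
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval * 255
}

#' Read a grey-scale image
#'
#' Supports PNG, TIFF, PGM (plain `P2` and raw `P5`) and whitespace-
#' delimited text matrices, selected by file extension. PNG/TIFF/PGM
#' intensities are mapped to the 0--255 scale (a 16-bit TIFF maximum maps to
#' 255); text matrices are read verbatim. Multi-channel inputs are averaged
#' to a single luminance channel with a warning.
#'
#' @param path path to an existing file.
#' @return numeric matrix of non-negative intensities.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- file_ext(path)
  img <- switch(ext,
    png = luminance(png::readPNG(path)) * 255,
    tif = , tiff = luminance(tiff::readTIFF(path)) * 255,
    pgm = read_pgm(path),
    {
      m <- tryCatch(as.matrix(read.table(path)),
                    error = function(e) stop("cannot parse text matrix: ", path,
                                             call. = FALSE))
      storage.mode(m) <- "double"
      dimnames(m) <- NULL
      m
    })
  if (length(img) == 0) stop("empty image: ", path, call. = FALSE)
  if (any(img < 0)) {
    warning("negative intensities in ", basename(path), " clamped to 0",
            call. = FALSE)
    img <- pmax(img, 0)
  }
  assert_image(img, nonneg = TRUE)
}

#' Write a grey-scale image or matrix
#'
#' `.png` and `.pgm` (plain `P2`) writers expect intensities in `[0, 255]`
#' and clamp before writing; `.txt` writes the matrix in full precision
#' (`%.17g`) so values round-trip bit-exactly through [read_image()].
#'
#' @param image numeric matrix.
#' @param path output path; the extension picks the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  ext <- file_ext(path)
  if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  } else if (ext == "pgm") {
    v <- round(pmin(pmax(image, 0), 255))
    lines <- apply(v, 1, paste, collapse = " ")
    writeLines(c("P2", paste(ncol(image), nrow(image)), "255", lines), path)
  } else {
    lines <- apply(image, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write segmentation outputs to a directory
#'
#' Writes the binary mask (PNG, 0/255), and optionally the estimated bias
#' field (full-precision text matrix), the bias-corrected image (PNG,
#' clamped to 0--255), the energy trace (tab-delimited, one row per
#' recorded energy including the initial one) and a key-value echo of the
#' run parameters. A `manifest.txt` lists every file written.
#'
#' @param result an `"lgdf_segmentation"` object from [segment()].
#' @param dir output directory (created if missing).
#' @param save_bias,save_corrected,save_trace toggles for optional outputs.
#' @param extra named list of additional key-value settings to echo into
#'   `params.txt` (e.g. input path, seed).
#' @return character vector of the written file paths (the manifest), invisibly.
#' @export
write_outputs <- function(result, dir, save_bias = TRUE, save_corrected = TRUE,
                          save_trace = TRUE, extra = list()) {
  stopifnot(inherits(result, "lgdf_segmentation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)

  mask_path <- file.path(dir, "mask.png")
  write_image(ifelse(result$mask, 255, 0), mask_path); add(mask_path)
  if (save_bias) {
    p <- file.path(dir, "bias.txt"); write_image(result$bias, p); add(p)
  }
  if (save_corrected) {
    p <- file.path(dir, "corrected.png"); write_image(result$corrected, p); add(p)
  }
  if (save_trace) {
    p <- file.path(dir, "energy_trace.tsv")
    writeLines(c("iteration\tenergy",
                 sprintf("%d\t%.17g", seq_along(result$energy_trace) - 1L,
                         result$energy_trace)), p)
    add(p)
  }
  pp <- file.path(dir, "params.txt")
  kv <- result$params[!vapply(result$params, is.null, logical(1))]
  kv <- c(kv, list(iterations_run = result$iterations_run,
                   converged = result$converged), extra)
  writeLines(sprintf("%s=%s", names(kv), vapply(kv, function(v)
    paste(format(v), collapse = ","), character(1))), pp)
  add(pp)
  manifest <- file.path(dir, "manifest.txt")
  writeLines(written, manifest)
  invisible(c(written, manifest))
}
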