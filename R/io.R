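ARCHIVE_FORMAT_VERSION <- "1.0"

#' Read a single-plane microscopy image
#'
#' Reads a TIFF (8/16-bit, via \pkg{tiff}, returning the raw integer sample
#' values) or PNG (via \pkg{png}, returning intensities scaled to
#' `[0, 1]`) as a numeric matrix. Multi-channel images are reduced to their
#' first channel; multi-page TIFFs to their first page.
#'
#' @param path image file path, extension `.tif`, `.tiff` or `.png`.
#' @return numeric matrix (rows x cols).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
      if (is.list(x)) x[[1]] else x
    },
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (expected TIFF or PNG)"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Read a spot-coordinate label table
#'
#' Parses a per-image CSV of spot positions into the internal (row, col)
#' convention. Two dialects are supported: `"plain"` — a header of either
#' `r,c` (row, col directly) or `x,y` (x = column, y = row, as written by
#' [write_coords_csv()]); and `"trackmate"` — a TrackMate "All Spots
#' statistics" export with `POSITION_X`/`POSITION_Y` columns, mapped as
#' `POSITION_Y` to row and `POSITION_X` to col. TrackMate positions are taken
#' as pixel units with no half-pixel offset; use `shift` to add a constant
#' to both axes if your export uses a different pixel-centre convention.
#'
#' @param path CSV file path.
#' @param dialect `"plain"` or `"trackmate"`.
#' @param shift constant added to both coordinates after parsing.
#' @return n x 2 numeric matrix of (row, col) coordinates; possibly 0-row.
#' @export
read_label_table <- function(path, dialect = c("plain", "trackmate"), shift = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  get_num <- function(col) {
    v <- df[[col]]
    if (is.character(v)) {
      out <- suppressWarnings(as.numeric(v))
      if (anyNA(out) && !anyNA(v))
        stop("non-numeric entries in column '", col, "' of ", path)
      v <- out
    }
    if (anyNA(v)) stop("missing or non-numeric entries in column '", col,
                       "' of ", path)
    as.numeric(v)
  }
  if (dialect == "plain") {
    if (all(c("r", "c") %in% names(df))) {
      m <- cbind(get_num("r"), get_num("c"))
    } else if (all(c("x", "y") %in% names(df))) {
      m <- cbind(get_num("y"), get_num("x"))
    } else {
      stop("plain label table needs columns 'r,c' or 'x,y': ", path)
    }
  } else {
    need <- c("POSITION_X", "POSITION_Y")
    if (!all(need %in% names(df)))
      stop("trackmate label table needs columns POSITION_X and POSITION_Y: ",
           path)
    m <- cbind(get_num("POSITION_Y"), get_num("POSITION_X"))
  }
  as_coord_matrix(m + shift)
}

#' Write spot coordinates as CSV
#'
#' Writes the conventional `x,y` CSV (x = column coordinate, y = row
#' coordinate) at full float precision, one row per spot.
#'
#' @param coords n x 2 matrix of (row, col) coordinates.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_coords_csv <- function(coords, path) {
  coords <- as_coord_matrix(coords)
  lines <- c("x,y", sprintf("%.17g,%.17g", coords[, 2], coords[, 1]))
  writeLines(lines, path)
  invisible(path)
}

# Shared archive assembly: shuffles image/label pairs, partitions them with
# floor-rounded valid/test sizes (remainder to train), optionally within
# strata, and packs each split into an H x W x N array plus label list.
build_archive <- function(images, labels, split_fractions, seed,
                          source = "create_dataset", strata = NULL) {
  n <- length(images)
  if (length(labels) != n) stop("image and label counts differ")
  if (length(split_fractions) != 3 || any(split_fractions <= 0) ||
      abs(sum(split_fractions) - 1) > 1e-8)
    stop("'split_fractions' must be three positive fractions summing to 1")
  shp <- dim(images[[1]])
  for (i in seq_len(n)) {
    if (!identical(dim(images[[i]]), shp))
      stop("all images in an archive must share one shape")
    ci <- as_coord_matrix(labels[[i]])
    if (nrow(ci) > 0 && (any(ci[, 1] < 0) || any(ci[, 1] >= shp[1]) ||
                         any(ci[, 2] < 0) || any(ci[, 2] >= shp[2])))
      stop("coordinate outside image bounds in image ", i)
    labels[[i]] <- ci
  }
  groups <- if (is.null(strata)) list(seq_len(n)) else split(seq_len(n), strata)
  tr <- va <- te <- integer(0)
  for (g in groups) {
    perm <- g[sample.int(length(g))]
    nv <- floor(split_fractions[2] * length(g))
    nt <- floor(split_fractions[3] * length(g))
    va <- c(va, perm[seq_len(nv)])
    te <- c(te, perm[nv + seq_len(nt)])
    tr <- c(tr, perm[setdiff(seq_along(perm), seq_len(nv + nt))])
  }
  if (length(va) == 0 || length(te) == 0 || length(tr) == 0)
    stop("too few images for the requested split fractions")
  pack <- function(idx) {
    x <- array(0, dim = c(shp[1], shp[2], length(idx)))
    for (k in seq_along(idx)) x[, , k] <- images[[idx[k]]]
    list(x = x, y = labels[idx])
  }
  ptr <- pack(tr); pva <- pack(va); pte <- pack(te)
  structure(list(
    x_train = ptr$x, y_train = ptr$y,
    x_valid = pva$x, y_valid = pva$y,
    x_test = pte$x, y_test = pte$y,
    metadata = list(format_version = ARCHIVE_FORMAT_VERSION, source = source,
                    split_seed = seed, split_fractions = split_fractions,
                    image_shape = shp, n_images = n)),
    class = "spot_archive")
}

#' Build a partitioned dataset archive from image and label files
#'
#' Pairs image files with label CSVs by file stem, reads them, validates that
#' every coordinate lies inside its image, shuffles the pairs with `seed` and
#' partitions them into train/valid/test splits. Valid and test sizes are
#' floored; the remainder goes to train, so the training split is never
#' starved. When a per-image stratum value is supplied (e.g. an SNR bin) the
#' split is performed within each stratum, mirroring SNR-balanced dataset
#' construction.
#'
#' @param image_paths character vector of TIFF/PNG files.
#' @param label_paths character vector of CSV files; stems must match
#'   `image_paths` one-to-one.
#' @param split_fractions length-3 positive fractions (train, valid, test)
#'   summing to 1.
#' @param seed integer shuffle seed.
#' @param dialect label dialect passed to [read_label_table()].
#' @param shift coordinate shift passed to [read_label_table()].
#' @param strata optional per-image stratification values (in `image_paths`
#'   order).
#' @return an object of class `spot_archive`: arrays `x_train`, `x_valid`,
#'   `x_test` (H x W x N), label lists `y_train`, `y_valid`, `y_test` and a
#'   `metadata` record.
#' @seealso [simulate_spot_dataset()], [save_archive()], [load_archive()]
#' @export
create_dataset <- function(image_paths, label_paths,
                           split_fractions = c(0.7, 0.15, 0.15), seed = 1,
                           dialect = "plain", shift = 0, strata = NULL) {
  if (length(image_paths) != length(label_paths))
    stop("equal numbers of image and label files required")
  stem <- function(p) tools::file_path_sans_ext(basename(p))
  im_stems <- stem(image_paths)
  lb_stems <- stem(label_paths)
  ord <- match(im_stems, lb_stems)
  if (anyNA(ord) || anyDuplicated(im_stems) || anyDuplicated(lb_stems))
    stop("image and label files must pair one-to-one by stem name; unpaired: ",
         paste(im_stems[is.na(ord)], collapse = ", "))
  label_paths <- label_paths[ord]
  images <- lapply(image_paths, read_image)
  labels <- lapply(label_paths, read_label_table, dialect = dialect,
                   shift = shift)
  for (i in seq_along(images)) {
    shp <- dim(images[[i]])
    ci <- labels[[i]]
    if (nrow(ci) > 0 && (any(ci[, 1] < 0) || any(ci[, 1] >= shp[1]) ||
                         any(ci[, 2] < 0) || any(ci[, 2] >= shp[2])))
      stop("coordinate outside image bounds in ", label_paths[i])
  }
  with_seed(seed, build_archive(images, labels, split_fractions, seed,
                                source = "create_dataset", strata = strata))
}

#' @export
print.spot_archive <- function(x, ...) {
  shp <- x$metadata$image_shape
  cat(sprintf("spot dataset archive (format %s): %dx%d px images\n",
              x$metadata$format_version, shp[1], shp[2]))
  cat(sprintf("  train %d, valid %d, test %d images\n",
              dim(x$x_train)[3], dim(x$x_valid)[3], dim(x$x_test)[3]))
  invisible(x)
}

#' Save / load a dataset archive
#'
#' The archive is persisted as a single RDS file (a named-array container
#' with a metadata record). Loading is loss-free: images are restored
#' bit-exactly and coordinates at full float precision. The format version
#' recorded in the metadata is checked on load.
#'
#' @param archive a `spot_archive`.
#' @param path file path.
#' @return `load_archive` returns the `spot_archive`; `save_archive` returns
#'   `path` invisibly.
#' @export
save_archive <- function(archive, path) {
  stopifnot(inherits(archive, "spot_archive"))
  saveRDS(archive, path, version = 3)
  invisible(path)
}

#' @rdname save_archive
#' @export
load_archive <- function(path) {
  if (!file.exists(path)) stop("archive not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not a readable archive file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (!inherits(obj, "spot_archive") || is.null(obj$metadata$format_version))
    stop("file is not a spot dataset archive: ", path)
  if (!identical(obj$metadata$format_version, ARCHIVE_FORMAT_VERSION))
    stop(sprintf("archive format version mismatch: file has %s, expected %s",
                 obj$metadata$format_version, ARCHIVE_FORMAT_VERSION))
  obj
}
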