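#' Read a greyscale shell micrograph
#'
#' Reads a PNG or TIFF micrograph into an integer intensity matrix in
#' \[0, 255\], row-major with origin at the top-left (rows = image rows).
#' Colour images are converted to greyscale by channel averaging.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param scale_tag free-text magnification tag stored as an attribute
#'   (default `"25x"`, the imaging protocol's magnification).
#' @return An integer matrix of class `"shell_image"`, intensities 0-255.
#' @export
read_shell_image <- function(path, scale_tag = "25x") {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 3) raw <- apply(raw[, , 1:min(3, dim(raw)[3])], c(1, 2), mean)
  shell_image(round(raw * 255), scale_tag = scale_tag)
}

#' Construct a shell image from an intensity matrix
#'
#' @param pixels numeric matrix of greyscale intensities in \[0, 255\].
#' @param scale_tag free-text magnification tag.
#' @return An integer matrix of class `"shell_image"`.
#' @export
shell_image <- function(pixels, scale_tag = "25x") {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  structure(matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels)),
            scale_tag = scale_tag, class = c("shell_image", "matrix", "array"))
}

# 8-connected component labelling by vectorised min-label propagation.
# Adequate for micrograph-sized rasters; returns an integer label matrix
# (0 = background) with labels renumbered 1..n_components.
.label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  cur <- matrix(Inf, nr, nc)
  cur[fg] <- lab[fg]
  repeat {
    nxt <- cur
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
      nxt <- pmin(nxt, shift(cur, d[1], d[2]))
    nxt[!fg] <- Inf
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  lab[] <- 0L
  lab[fg] <- as.integer(match(cur[fg], sort(unique(cur[fg]))))
  lab
}

# Even-odd membership of raster pixels (centres at (row, col)) in a list of
# polygons, each a two-column matrix of (row, col) vertices.
.in_polygons <- function(nr, nc, polygons) {
  inside <- matrix(FALSE, nr, nc)
  if (!length(polygons)) return(inside)
  pts <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  for (poly in polygons) {
    poly <- as.matrix(poly)
    if (ncol(poly) != 2 || nrow(poly) < 3)
      stop("each excluded region must be a polygon of >= 3 (row, col) vertices",
           call. = FALSE)
    inside[mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)] <- TRUE
  }
  inside
}

#' Segment the shell from a white-background micrograph
#'
#' Thresholds the image (shell = pixels darker than `background_cutoff`),
#' keeps the largest 8-connected component, and removes any excluded
#' regions (apertures, holes) given as polygons. This reproduces, in batch
#' form, the manual threshold-and-crop scoring protocol.
#'
#' @param image a [shell_image()].
#' @param background_cutoff intensity below which a pixel counts as shell.
#'   Default 250: the protocol's background is 255 but a small margin
#'   absorbs vignetting. `"otsu"` selects the cutoff by Otsu's method.
#' @param excluded_regions list of polygons (two-column `(row, col)` vertex
#'   matrices) to exclude from the mask, e.g. apertures and holes.
#' @return A logical matrix of class `"shell_mask"` (TRUE = shell pixel)
#'   with the exclusion polygons kept in attribute `excluded_regions`.
#' @examples
#' img <- shell_image(matrix(c(rep(120, 4), rep(255, 12)), 4, 4))
#' sum(segment_shell(img))
#' @export
segment_shell <- function(image, background_cutoff = 250,
                          excluded_regions = list()) {
  stopifnot(inherits(image, "shell_image"))
  px <- unclass(image)
  if (identical(background_cutoff, "otsu")) background_cutoff <- .otsu(px)
  fg <- px < background_cutoff
  fg[.in_polygons(nrow(px), ncol(px), excluded_regions)] <- FALSE
  if (!any(fg)) stop("no shell detected", call. = FALSE)
  lab <- .label_components(fg)
  counts <- tabulate(lab[lab > 0L])
  keep <- lab == which.max(counts)
  structure(keep, excluded_regions = excluded_regions,
            class = c("shell_mask", "matrix", "array"))
}

# Otsu threshold on a 0-255 histogram (maximises between-class variance).
.otsu <- function(px) {
  h <- tabulate(as.integer(px) + 1L, nbins = 256)
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * w - mu)^2 / (w * (1 - w))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) - 1L + 0.5
}

#' Shell transparency score
#'
#' Mean greyscale intensity over the shell pixels divided by 255, on a scale
#' of 0 (black, fully altered) to 1 (white, fully transparent/pristine).
#'
#' @param image a [shell_image()].
#' @param mask a [segment_shell()] mask; if `NULL`, one is computed with
#'   default settings.
#' @return A single number in \[0, 1\].
#' @examples
#' img <- shell_image(matrix(c(rep(178, 6), rep(255, 10)), 4, 4))
#' transparency_score(img)  # 178/255 = 0.698
#' @export
transparency_score <- function(image, mask = NULL) {
  stopifnot(inherits(image, "shell_image"))
  if (is.null(mask)) mask <- segment_shell(image)
  stopifnot(inherits(mask, "shell_mask"))
  if (!identical(dim(mask), dim(image)))
    stop("mask and image dimensions differ", call. = FALSE)
  if (!any(mask)) stop("empty shell mask", call. = FALSE)
  mean(unclass(image)[mask]) / 255
}

#' Score a batch of shell micrographs
#'
#' @param paths character vector of image file paths.
#' @param background_cutoff passed to [segment_shell()].
#' @param exclusions optional named list (by image basename) of
#'   excluded-region polygon lists.
#' @return A data.frame with columns `image_id`, `n_shell_pixels`,
#'   `transparency`.
#' @export
score_shell_images <- function(paths, background_cutoff = 250,
                               exclusions = list()) {
  rows <- lapply(paths, function(p) {
    id <- basename(p)
    img <- read_shell_image(p)
    excl <- if (!is.null(exclusions[[id]])) exclusions[[id]] else list()
    m <- segment_shell(img, background_cutoff, excl)
    data.frame(image_id = id, n_shell_pixels = sum(m),
               transparency = transparency_score(img, m))
  })
  do.call(rbind, rows)
}
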