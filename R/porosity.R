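#' Binary cross-section
#'
#' Container for a two-valued bone cross-section raster. Internally the
#' section is a logical matrix with `TRUE` = bone matrix and `FALSE` =
#' void (vascular space or exterior background); which grey level maps to
#' bone is decided at I/O time (see [read_section()]).
#'
#' @param bone Logical matrix, `TRUE` where there is bone.
#' @param pixel_size Optional length of a pixel side (reporting only).
#' @return An object of class `"binary_section"`.
#' @export
binary_section <- function(bone, pixel_size = NULL) {
  stopifnot(is.matrix(bone), is.logical(bone))
  if (anyNA(bone)) stop("bone mask contains NA")
  structure(list(bone = bone, pixel_size = pixel_size),
            class = "binary_section")
}

#' @export
print.binary_section <- function(x, ...) {
  cat("Binary section ", nrow(x$bone), "x", ncol(x$bone),
      " (", sum(x$bone), " bone px, ", sum(!x$bone), " void px)\n", sep = "")
  invisible(x)
}

#' Threshold a greyscale raster into a binary section
#'
#' Dark-bone convention: pixels with intensity at or below `threshold`
#' become bone, brighter pixels become void. The canonical pipeline input
#' is an already two-valued image; this is a convenience for greyscale
#' sources.
#'
#' @param gray Numeric matrix of intensities.
#' @param threshold Intensity cut; should lie within the image's range.
#' @return A `"binary_section"`.
#' @export
binarize <- function(gray, threshold) {
  stopifnot(is.matrix(gray), is.numeric(gray), length(threshold) == 1)
  rng <- range(gray)
  if (rng[1] == rng[2])
    warning("constant image; all pixels fall on one side of the threshold")
  else if (threshold < rng[1] || threshold > rng[2])
    warning("threshold outside the intensity range [", rng[1], ", ",
            rng[2], "]")
  binary_section(gray <= threshold)
}

#' Read a section image
#'
#' Reads a single-channel PNG or TIFF. By default white (high intensity)
#' is void and black is bone, matching segmented histological sections
#' where the bone matrix is rendered black; set `void_high = FALSE` for
#' the opposite polarity. Multi-channel images use the first channel.
#'
#' @param path Image path, `.png`, `.tif` or `.tiff`.
#' @param void_high If `TRUE` (default), intensity > 0.5 is void.
#' @param pixel_size Optional pixel size forwarded to the section.
#' @return A `"binary_section"`.
#' @export
read_section <- function(path, void_high = TRUE, pixel_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  bone <- if (void_high) img <= 0.5 else img > 0.5
  binary_section(bone, pixel_size = pixel_size)
}

#' Write a section image
#'
#' @param section A `"binary_section"`.
#' @param path Output path, `.png`, `.tif` or `.tiff`.
#' @param void_high If `TRUE` (default), void is written white (1), bone
#'   black (0).
#' @return `path`, invisibly.
#' @export
write_section <- function(section, path, void_high = TRUE) {
  stopifnot(inherits(section, "binary_section"))
  img <- ifelse(section$bone, if (void_high) 0 else 1,
                if (void_high) 1 else 0)
  img <- matrix(as.numeric(img), nrow(section$bone))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

# Surface elevation profile facing a side. Returns positions along the
# ornament axis, elevations (-Inf where no bone), and the (row, col) of the
# surface pixel at each position.
.surface_profile <- function(bone, side) {
  nr <- nrow(bone); nc <- ncol(bone)
  if (side %in% c("top", "bottom")) {
    pos <- seq_len(nc)
    elev <- rep(-Inf, nc); srow <- rep(NA_integer_, nc)
    for (j in pos) {
      rows <- which(bone[, j])
      if (length(rows)) {
        i <- if (side == "top") min(rows) else max(rows)
        srow[j] <- i
        elev[j] <- if (side == "top") nr - i + 1 else i
      }
    }
    list(pos = pos, elev = elev, row = srow, col = pos)
  } else {
    pos <- seq_len(nr)
    elev <- rep(-Inf, nr); scol <- rep(NA_integer_, nr)
    for (i in pos) {
      cols <- which(bone[i, ])
      if (length(cols)) {
        j <- if (side == "left") min(cols) else max(cols)
        scol[i] <- j
        elev[i] <- if (side == "left") nc - j + 1 else j
      }
    }
    list(pos = pos, elev = elev, row = pos, col = scol)
  }
}

# Local maxima of a 1-D profile with topographic prominence and minimum
# separation. Plateaus collapse to their midpoint (ties toward the lower
# index). A side with no samples (peak at the profile border) contributes
# the peak's own height, i.e. a border plateau spanning everything has
# prominence zero, while a peak flanked by -Inf (no-bone columns) has
# infinite prominence.
.find_peaks <- function(h, min_prominence, min_separation) {
  n <- length(h)
  if (!n) return(integer(0))
  r <- rle(h)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  cand <- integer(0); prom <- numeric(0)
  for (m in seq_len(k)) {
    v <- r$values[m]
    if (!is.finite(v)) next
    left_v  <- if (m > 1) r$values[m - 1] else -Inf
    right_v <- if (m < k) r$values[m + 1] else -Inf
    if (v <= left_v || v <= right_v) next
    pmid <- (starts[m] + ends[m]) %/% 2
    # left base: min until a strictly higher sample or the border
    lb <- v
    i <- starts[m] - 1
    while (i >= 1) {
      if (h[i] > v) break
      lb <- min(lb, h[i]); i <- i - 1
    }
    rb <- v
    i <- ends[m] + 1
    while (i <= n) {
      if (h[i] > v) break
      rb <- min(rb, h[i]); i <- i + 1
    }
    cand <- c(cand, pmid)
    prom <- c(prom, v - max(lb, rb))
  }
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))
  ord <- order(-prom, cand)
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(cand[i] - accepted) >= min_separation))
      accepted <- c(accepted, cand[i])
  }
  sort(accepted)
}

#' Detect ornamentation crest apices
#'
#' Scans the bone boundary facing one side of the section and returns the
#' apices (local maxima of the surface elevation profile) of the
#' ornamentation crests, ordered along the ornament axis. Flat crest
#' plateaus contribute their midpoint (ties round toward the lower index).
#' A minimum topographic prominence and a minimum separation suppress
#' pixel noise.
#'
#' @param section A `"binary_section"`.
#' @param side Which boundary carries the ornament: `"top"`, `"bottom"`,
#'   `"left"` or `"right"`.
#' @param min_prominence Minimum apex prominence in pixels (default 3).
#' @param min_separation Minimum spacing between apices along the axis in
#'   pixels (default 5).
#' @return A data.frame with columns `row`, `col` (apex pixel) and `pos`
#'   (position along the ornament axis), ordered by `pos`; zero rows when
#'   nothing passes the filters.
#' @export
detect_crest_apices <- function(section, side = c("top", "bottom", "left", "right"),
                                min_prominence = 3, min_separation = 5) {
  stopifnot(inherits(section, "binary_section"))
  side <- match.arg(side)
  if (!any(section$bone)) stop("section has no bone pixels")
  prof <- .surface_profile(section$bone, side)
  pk <- .find_peaks(prof$elev, min_prominence, min_separation)
  data.frame(row = prof$row[pk], col = prof$col[pk], pos = pk)
}

# 8-connected digital straight segment between two pixels, both endpoints
# included (integer DDA with half-up rounding).
.digital_segment <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0))
  if (n == 0) return(cbind(row = r0, col = c0))
  t <- 0:n
  cbind(row = floor(r0 + t * (r1 - r0) / n + 0.5),
        col = floor(c0 + t * (c1 - c0) / n + 0.5))
}

#' Bridge ornamentation crests
#'
#' Joins consecutive crest apices with one-pixel-wide digital straight
#' segments of bone, so that the pits between crests become enclosed void
#' and count as vascular space. Connecting consecutive apices along the
#' ornament axis realises the shortest total bridging length over
#' order-preserving pairings ("most parsimonious"). Optionally the
#' outermost apices are also connected to the bone surface at the lateral
#' ends of the section (`connect_edges`), embedding marginal pits.
#'
#' @param section A `"binary_section"`.
#' @param apices Apex data.frame from [detect_crest_apices()] (columns
#'   `row`, `col`, ordered along the axis).
#' @param side Side the apices face (used only when `connect_edges = TRUE`).
#' @param connect_edges Also bridge the outermost apices to the first/last
#'   bone surface point along the axis (default `FALSE`).
#' @return The bridged `"binary_section"`, with attributes `bridged`
#'   (logical: were any segments drawn) and `bridge_length` (void pixels
#'   converted to bone). With fewer than two apices the input is returned
#'   unchanged with `bridged = FALSE`.
#' @export
bridge_crests <- function(section, apices,
                          side = c("top", "bottom", "left", "right"),
                          connect_edges = FALSE) {
  stopifnot(inherits(section, "binary_section"))
  side <- match.arg(side)
  if (is.null(apices) || nrow(apices) < 2) {
    attr(section, "bridged") <- FALSE
    attr(section, "bridge_length") <- 0L
    return(section)
  }
  bone <- section$bone
  segs <- list()
  for (m in seq_len(nrow(apices) - 1)) {
    segs[[m]] <- .digital_segment(apices$row[m], apices$col[m],
                                  apices$row[m + 1], apices$col[m + 1])
  }
  if (connect_edges) {
    prof <- .surface_profile(bone, side)
    fin <- which(is.finite(prof$elev))
    lo <- fin[1]; hi <- fin[length(fin)]
    segs <- c(segs,
              list(.digital_segment(apices$row[1], apices$col[1],
                                    prof$row[lo], prof$col[lo]),
                   .digital_segment(apices$row[nrow(apices)],
                                    apices$col[nrow(apices)],
                                    prof$row[hi], prof$col[hi])))
  }
  pts <- unique(do.call(rbind, segs))
  converted <- sum(!bone[pts])
  bone[pts] <- TRUE
  out <- binary_section(bone, pixel_size = section$pixel_size)
  attr(out, "bridged") <- TRUE
  attr(out, "bridge_length") <- as.integer(converted)
  out
}

# Void pixels 4-connected to the raster border (exterior background).
# Iterative vectorised propagation; bone is implicitly 8-connected through
# the complementary 4-connectivity of void.
.exterior_void <- function(bone) {
  void <- !bone
  nr <- nrow(void); nc <- ncol(void)
  ext <- matrix(FALSE, nr, nc)
  ext[1, ] <- void[1, ]; ext[nr, ] <- void[nr, ]
  ext[, 1] <- ext[, 1] | void[, 1]; ext[, nc] <- ext[, nc] | void[, nc]
  frow <- matrix(FALSE, 1, nc); fcol <- matrix(FALSE, nr, 1)
  repeat {
    grown <- ext |
      rbind(ext[-1, , drop = FALSE], frow) |
      rbind(frow, ext[-nr, , drop = FALSE]) |
      cbind(ext[, -1, drop = FALSE], fcol) |
      cbind(fcol, ext[, -nc, drop = FALSE])
    grown <- grown & void
    if (identical(grown, ext)) break
    ext <- grown
  }
  ext
}

#' Measure the vascular area fraction of a section
#'
#' The porosity of a cross-section is the area of enclosed void (cavities
#' not connected to the exterior background) over the total sectional area
#' (enclosed void plus bone). Exterior background — void 4-connected to
#' the raster border after any bridging — is excluded. With
#' `bridge = TRUE`, crest apices are detected on `side` and bridged first
#' so ornamentation pits count as vascular space.
#'
#' @param section A `"binary_section"`.
#' @param bridge Bridge ornamentation crests before measuring.
#' @param side Side carrying the ornament (see [detect_crest_apices()]).
#' @param min_prominence,min_separation Apex filters, forwarded.
#' @param connect_edges Forwarded to [bridge_crests()].
#' @return An object of class `"porosity_result"`: list with
#'   `vascular_area`, `bone_area`, `total_area` (pixel counts), `porosity`
#'   (fraction), `bridged`, `bridge_length`.
#' @export
measure_vascular_area <- function(section, bridge = FALSE,
                                  side = c("top", "bottom", "left", "right"),
                                  min_prominence = 3, min_separation = 5,
                                  connect_edges = FALSE) {
  stopifnot(inherits(section, "binary_section"))
  side <- match.arg(side)
  bridged <- FALSE; bridge_length <- 0L
  if (bridge) {
    apices <- detect_crest_apices(section, side,
                                  min_prominence = min_prominence,
                                  min_separation = min_separation)
    section <- bridge_crests(section, apices, side,
                             connect_edges = connect_edges)
    bridged <- attr(section, "bridged")
    bridge_length <- attr(section, "bridge_length")
  }
  bone <- section$bone
  bone_area <- sum(bone)
  if (bone_area == 0) stop("zero total area: section has no bone pixels")
  enclosed <- !bone & !.exterior_void(bone)
  vascular <- sum(enclosed)
  total <- vascular + bone_area
  structure(list(vascular_area = as.integer(vascular),
                 bone_area = as.integer(bone_area),
                 total_area = as.integer(total),
                 porosity = vascular / total,
                 bridged = bridged,
                 bridge_length = as.integer(bridge_length)),
            class = "porosity_result")
}

#' @export
print.porosity_result <- function(x, ...) {
  cat("Vascular area fraction: ", signif(x$porosity, 4),
      "  (", x$vascular_area, " / ", x$total_area, " px",
      if (x$bridged) paste0("; bridged, +", x$bridge_length, " px"),
      ")\n", sep = "")
  invisible(x)
}

#' Batch porosity measurement
#'
#' Measures every PNG/TIFF section in a directory and returns one row per
#' image.
#'
#' @param dir Directory of section images.
#' @param ... Forwarded to [measure_vascular_area()].
#' @inheritParams read_section
#' @return data.frame with columns `file`, `porosity`, `vascular_area`,
#'   `total_area`, `bridged`, `bridge_length`.
#' @export
measure_directory <- function(dir, void_high = TRUE, ...) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  res <- lapply(files, function(f) {
    r <- measure_vascular_area(read_section(f, void_high = void_high), ...)
    data.frame(file = basename(f), porosity = r$porosity,
               vascular_area = r$vascular_area, total_area = r$total_area,
               bridged = r$bridged, bridge_length = r$bridge_length)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
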