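#' Convert an RGB image to HSI (hue, saturation, intensity)
#'
#' Classical arccos formulation: `I = (R+G+B)/3`, `S = 1 - min(R,G,B)/I`,
#' `H = acos(0.5*((R-G)+(R-B)) / sqrt((R-G)^2 + (R-B)*(G-B)))` in degrees,
#' with `H <- 360 - H` when `B > G`. Achromatic pixels (R = G = B, including
#' black) get `H = 0`, `S = 0` and a `chromatic` flag of `FALSE`.
#'
#' @param image A numeric array `height x width x 3` with channel values in
#'   \[0, 1\] (values in 0..255 are rescaled).
#'
#' @return An object of class `hsi_image`: list of matrices `hue` (degrees
#'   in \[0, 360)), `saturation`, `intensity` (both in \[0, 1\]) and logical
#'   `chromatic`.
#' @export
rgb_to_hsi <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop("image must be an array height x width x 3 (RGB)", call. = FALSE)
  }
  if (max(image) > 1) image <- image / 255
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  chromatic <- den > .Machine$double.eps
  h <- matrix(0, nrow(r), ncol(r))
  ratio <- pmin(pmax(num[chromatic] / den[chromatic], -1), 1)
  hc <- acos(ratio) * 180 / pi
  hc <- ifelse(b[chromatic] > g[chromatic], 360 - hc, hc)
  h[chromatic] <- hc %% 360
  s[!chromatic] <- 0
  structure(list(hue = h, saturation = s, intensity = i,
                 chromatic = chromatic),
            class = "hsi_image")
}

# Inverse HSI -> RGB (classical sector formulation); used by the fiber
# simulator to paint pixels with an exact target hue.
hsi_to_rgb <- function(h, s, i) {
  h <- h %% 360
  s <- rep_len(s, length(h))
  i <- rep_len(i, length(h))
  r <- g <- b <- numeric(length(h))
  sec1 <- h < 120
  sec2 <- h >= 120 & h < 240
  sec3 <- h >= 240
  deg <- pi / 180
  f <- function(hh) (1 + s * cos(hh * deg) / cos((60 - hh) * deg))
  b[sec1] <- (i * (1 - s))[sec1]
  r[sec1] <- (i * f(h))[sec1]
  g[sec1] <- (3 * i)[sec1] - r[sec1] - b[sec1]
  h2 <- h - 120
  r[sec2] <- (i * (1 - s))[sec2]
  g[sec2] <- (i * f(h2))[sec2]
  b[sec2] <- (3 * i)[sec2] - r[sec2] - g[sec2]
  h3 <- h - 240
  g[sec3] <- (i * (1 - s))[sec3]
  b[sec3] <- (i * f(h3))[sec3]
  r[sec3] <- (3 * i)[sec3] - g[sec3] - b[sec3]
  cbind(r = pmin(pmax(r, 0), 1), g = pmin(pmax(g, 0), 1),
        b = pmin(pmax(b, 0), 1))
}

#' Define a reference color for collagen scoring
#'
#' A reference is an HSI target with tolerances: pixels score 1 at the
#' reference hue and fall off linearly to 0 at `hue_tol` degrees away;
#' pixels below `sat_min` saturation, outside `int_range` intensity, or
#' achromatic score 0 regardless of hue. Type I collagen fibers appear
#' red/yellow under polarized light, type III fibers green.
#'
#' @param name One of `"red"`, `"yellow"`, `"green"`.
#' @param hue_center Reference hue in degrees.
#' @param hue_tol Hue tolerance in degrees (> 0).
#' @param sat_min Minimum saturation (< 1).
#' @param int_range Admissible intensity interval inside \[0, 1\].
#' @param falloff Score falloff with hue distance; only `"linear"`.
#'
#' @return An object of class `reference_color`.
#' @export
reference_color <- function(name, hue_center, hue_tol, sat_min = 0.2,
                            int_range = c(0.05, 0.95), falloff = "linear") {
  name <- match.arg(name, c("red", "yellow", "green"))
  falloff <- match.arg(falloff, "linear")
  stopifnot(hue_tol > 0, sat_min >= 0, sat_min < 1,
            length(int_range) == 2L, int_range[1] < int_range[2],
            int_range[1] >= 0, int_range[2] <= 1)
  structure(list(name = name, hue_center = as.numeric(hue_center) %% 360,
                 hue_tol = as.numeric(hue_tol), sat_min = sat_min,
                 int_range = as.numeric(int_range), falloff = falloff),
            class = "reference_color")
}

#' Default reference colors for Picro-Sirius red scoring
#'
#' Red at hue 0 (tol 20), yellow at hue 50 (tol 20), green at hue 120
#' (tol 30); saturation >= 0.2 and intensity in \[0.05, 0.95\]. These are
#' engineering defaults for the scorer, overridable per study.
#'
#' @return Named list of three [reference_color()] objects.
#' @export
default_reference_colors <- function() {
  list(red = reference_color("red", 0, 20),
       yellow = reference_color("yellow", 50, 20),
       green = reference_color("green", 120, 30))
}

#' Per-pixel closeness scores against one reference color
#'
#' Score = `max(0, 1 - d/hue_tol)` where `d` is the circular hue distance to
#' the reference hue; forced to 0 for pixels failing the saturation or
#' intensity gates or lacking chroma. Shades close to the reference score
#' high, distant shades low, anything else zero.
#'
#' @param hsi An `hsi_image` (or an RGB array, converted on the fly).
#' @param ref A [reference_color()].
#'
#' @return A matrix of scores in \[0, 1\], same shape as the image.
#' @export
pixel_scores <- function(hsi, ref) {
  if (!inherits(hsi, "hsi_image")) hsi <- rgb_to_hsi(hsi)
  stopifnot(inherits(ref, "reference_color"))
  d <- abs(hsi$hue - ref$hue_center)
  d <- pmin(d, 360 - d)
  score <- 1 - d / ref$hue_tol
  score[score < 0] <- 0
  score[!hsi$chromatic] <- 0
  score[hsi$saturation < ref$sat_min] <- 0
  score[hsi$intensity < ref$int_range[1] | hsi$intensity > ref$int_range[2]] <- 0
  score
}

#' Quantify collagen classes in a stained image
#'
#' Scores every pixel against the red, yellow and green references, assigns
#' each pixel exclusively to the class with the highest positive score (ties
#' broken by the priority red > yellow > green, preventing double counting),
#' and aggregates per class: `score_sum` (sum of winning scores), `area_px`
#' (pixels with positive score), `pct_score` (100 * score_sum / total pixel
#' count). Type I collagen = red + yellow, type III = green;
#' `total_collagen_pct` is the sum of the three class percentages.
#'
#' @param image An RGB array or `hsi_image`.
#' @param refs Named list of three distinct [reference_color()] objects.
#'
#' @return An object of class `collagen_scores`: list with a tibble
#'   `scores` (class, score_sum, area_px, pct_score), `total_collagen_pct`
#'   and `n_pixels`.
#' @export
quantify_collagen <- function(image, refs = default_reference_colors()) {
  hsi <- if (inherits(image, "hsi_image")) image else rgb_to_hsi(image)
  nms <- vapply(refs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("reference colors must have distinct class names", call. = FALSE)
  }
  # canonical priority order for tie-breaking
  priority <- intersect(c("red", "yellow", "green"), nms)
  refs <- refs[match(priority, nms)]
  n_px <- length(hsi$hue)
  score_mat <- vapply(refs, function(r) as.vector(pixel_scores(hsi, r)),
                      numeric(n_px))
  best <- max.col(score_mat, ties.method = "first")
  best_score <- score_mat[cbind(seq_len(n_px), best)]
  assigned <- best_score > 0
  rows <- lapply(seq_along(priority), function(j) {
    sel <- assigned & best == j
    ssum <- sum(score_mat[sel, j])
    tibble::tibble(class = priority[j], score_sum = ssum,
                   area_px = sum(sel), pct_score = 100 * ssum / n_px)
  })
  scores <- dplyr::bind_rows(rows)
  structure(list(scores = scores,
                 total_collagen_pct = sum(scores$pct_score),
                 n_pixels = n_px),
            class = "collagen_scores")
}

#' @export
print.collagen_scores <- function(x, ...) {
  cat(sprintf("<collagen_scores> %d pixels, total collagen %.2f%%\n",
              x$n_pixels, x$total_collagen_pct))
  print(x$scores)
  invisible(x)
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path Image file; format chosen by extension.
#' @return Numeric array `height x width x 3` in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)",
         call. = FALSE)
  )
  if (length(dim(img)) == 2L) stop("grayscale image; RGB required", call. = FALSE)
  img[, , 1:3, drop = FALSE]
}

#' Write an 8-bit RGB image (PNG or TIFF)
#'
#' @param image Numeric array `height x width x 3` in \[0, 1\].
#' @param path Output file; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

qualitative_indicator_cols <- c("thick", "thin", "papillary", "mid", "deep",
                                "horizontal", "vertical")

#' Read qualitative fiber-scoring records
#'
#' Reads the presence/absence records a pathologist produces for each
#' section: fiber color (Yellow/Red/Green), thick/thin, dermal layer
#' (papillary/mid/deep) and orientation (horizontal/vertical), each coded
#' `+` (present) or `-`/`_` (absent). These records carry no computation;
#' they are validated for joint reporting alongside the quantitative
#' image scores.
#'
#' @param path CSV with columns `fiber_color`, `thick`, `thin`, `papillary`,
#'   `mid`, `deep`, `horizontal`, `vertical` (plus optional `group`, `day`).
#'
#' @return A tibble with `fiber_color` as character and logical indicator
#'   columns.
#' @examples
#' f <- system.file("extdata", "example_qualitative_scores.csv",
#'                  package = "collafluor")
#' read_qualitative_scores(f)
#' @export
read_qualitative_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, warn = FALSE)) <= 1L) {
    return(tibble::tibble(fiber_color = character(0)))
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!"fiber_color" %in% names(tbl)) {
    stop("qualitative score file needs a 'fiber_color' column", call. = FALSE)
  }
  colors <- c(yellow = "Yellow", red = "Red", green = "Green")
  key <- tolower(trimws(tbl$fiber_color))
  bad <- setdiff(unique(key), names(colors))
  if (length(bad)) {
    stop("unknown fiber color value(s): ", paste(bad, collapse = ", "),
         " (expected Yellow, Red or Green)", call. = FALSE)
  }
  tbl$fiber_color <- unname(colors[key])
  for (col in intersect(qualitative_indicator_cols, names(tbl))) {
    v <- trimws(tbl[[col]])
    ok_present <- v == "+"
    ok_absent <- v %in% c("-", "_", "") | is.na(v)
    if (any(!ok_present & !ok_absent)) {
      stop("unknown category value in column '", col, "': ",
           paste(unique(v[!ok_present & !ok_absent]), collapse = ", "),
           call. = FALSE)
    }
    tbl[[col]] <- ok_present
  }
  if ("day" %in% names(tbl)) tbl$day <- as.integer(tbl$day)
  tibble::as_tibble(tbl)
}
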