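# Plain-text file formats: curves as 3-column '.dat' files with '#' headers
# (the de facto SAXS dialect), difference matrices as delimited tables with
# a delay header row, ground truth as a key/value + matrix-block sidecar,
# detector images as float TIFF with a YAML geometry sidecar. Everything is
# diff-able text except the TIFF payload.

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write and read 1D scattering curves
#'
#' Three whitespace-delimited numeric columns (q in inverse Angstrom,
#' intensity, sigma) preceded by `# key: value` header lines carrying the
#' exposure metadata (chamber, laser state, delay, exposure index). A
#' write/read round trip preserves values to better than 1e-12 relative and
#' all metadata keys.
#'
#' @param curve An [scattering_curve()].
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns the
#'   curve.
#' @export
write_curve <- function(curve, path) {
  m <- curve_meta(curve)
  ch <- m$chamber %||% c(NA, NA)
  hdr <- c(
    "# sxl scattering curve",
    sprintf("# chamber_row: %s", ch[1L]),
    sprintf("# chamber_col: %s", ch[2L]),
    sprintf("# laser_state: %s", m$laser_state %||% NA),
    sprintf("# delay: %s", fmt_num(m$delay %||% NA_real_)),
    sprintf("# exposure_index: %s", m$exposure_index %||% NA),
    "# columns: q intensity sigma"
  )
  body <- paste(fmt_num(curve$q), fmt_num(curve$intensity), fmt_num(curve$sigma))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  body_lineno <- which(!is_hdr)
  meta <- list()
  for (h in hdr) {
    mm <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1L]]
    if (length(mm) == 3L) meta[[mm[2L]]] <- mm[3L]
  }
  body <- body[nzchar(trimws(body))]
  vals <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(vals, function(v) {
    length(v) != 3L || anyNA(suppressWarnings(as.numeric(v)))
  }, logical(1L)))
  if (length(bad) > 0L) {
    stop_sxl(sprintf("malformed curve row at line %d of %s: '%s'",
                     body_lineno[bad[1L]], path, body[bad[1L]]),
             "sxl_parse_error")
  }
  num <- matrix(as.numeric(unlist(vals)), ncol = 3L, byrow = TRUE)
  as_num <- function(x) if (is.null(x) || x == "NA") NA_real_ else as.numeric(x)
  ch <- c(as_num(meta$chamber_row), as_num(meta$chamber_col))
  scattering_curve(
    num[, 1L], num[, 2L], num[, 3L],
    chamber = if (all(is.na(ch))) NULL else ch,
    laser_state = if (is.null(meta$laser_state) || meta$laser_state == "NA") NA_character_ else meta$laser_state,
    delay = as_num(meta$delay),
    exposure_index = as_num(meta$exposure_index)
  )
}

#' Write and read difference matrices
#'
#' Delimited text: `#` metadata lines (kept/rejected counts), then a header
#' row `q <delay1> <delay2> ...` (delays in seconds) and one row per q
#' value — the layout of a time-delay contour table. Sigma columns are
#' stored in a parallel block introduced by `# sigma`.
#'
#' @param dm An [difference_matrix()].
#' @param path File path.
#' @return `write_difference_matrix` returns `path` invisibly;
#'   `read_difference_matrix` returns the matrix object.
#' @export
write_difference_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "sxl_diffmat"))
  hdr <- c(
    "# sxl difference matrix",
    sprintf("# n_kept: %s", paste(dm$n_kept %||% "", collapse = " ")),
    sprintf("# n_rejected: %s", paste(dm$n_rejected %||% "", collapse = " "))
  )
  head_row <- paste(c("q", fmt_num(dm$delays)), collapse = " ")
  body <- apply(cbind(dm$q, dm$delta), 1L, function(r) paste(fmt_num(r), collapse = " "))
  sig <- apply(cbind(dm$q, dm$sigma), 1L, function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(hdr, head_row, body, "# sigma", head_row, sig), path)
  invisible(path)
}

#' @rdname write_difference_matrix
#' @export
read_difference_matrix <- function(path) {
  lines <- readLines(path)
  meta <- list()
  for (h in lines[startsWith(lines, "#")]) {
    mm <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", h))[[1L]]
    if (length(mm) == 3L) meta[[mm[2L]]] <- mm[3L]
  }
  sig_at <- which(trimws(lines) == "# sigma")
  parse_block <- function(block) {
    block <- block[!startsWith(block, "#")]
    block <- block[nzchar(trimws(block))]
    head <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    if (head[1L] != "q") stop_sxl(sprintf("bad header row in %s", path), "sxl_parse_error")
    delays <- as.numeric(head[-1L])
    num <- t(vapply(
      strsplit(trimws(block[-1L]), "\\s+"),
      function(v) as.numeric(v), numeric(length(head))
    ))
    list(q = num[, 1L], delays = delays, mat = num[, -1L, drop = FALSE])
  }
  main <- parse_block(lines[seq_len(if (length(sig_at)) sig_at - 1L else length(lines))])
  sigma <- NULL
  if (length(sig_at)) {
    sg <- parse_block(lines[seq.int(sig_at + 1L, length(lines))])
    sigma <- sg$mat
  }
  parse_counts <- function(x) {
    if (is.null(x) || !nzchar(trimws(x))) return(NULL)
    as.integer(strsplit(trimws(x), "\\s+")[[1L]])
  }
  difference_matrix(
    main$q, main$delays, main$mat, sigma,
    n_kept = parse_counts(meta$n_kept), n_rejected = parse_counts(meta$n_rejected)
  )
}

#' Write and read a simulated dataset directory
#'
#' `write_dataset` writes one curve file per exposure under `dir/curves/`,
#' the exposure table as TSV, and the ground-truth record as a structured
#' sidecar `truth.txt` — deliberately a separate file from anything the
#' reduction chain reads, so recovery tests never touch the truth through
#' the data path. Identical datasets (same configuration and seed) produce
#' byte-identical directories.
#'
#' @param dataset An `sxl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   reconstructed `sxl_dataset` (without layout/plan objects).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sxl_dataset"))
  cdir <- file.path(dir, "curves")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset$exposures))) {
    write_curve(dataset_curve(dataset, i), file.path(cdir, sprintf("exp%05d.dat", i)))
  }
  utils::write.table(
    dataset$exposures, file.path(dir, "exposures.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  write_truth(dataset$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(file.path(dir, "curves"), pattern = "\\.dat$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_sxl(sprintf("no curve files under %s/curves.", dir), "sxl_io_error")
  }
  curves <- purrr::map(files, read_curve)
  q <- curves[[1L]]$q
  exposures <- utils::read.table(file.path(dir, "exposures.tsv"),
                                 header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.txt")
  structure(
    list(
      q = q,
      exposures = as_tibble(exposures),
      intensity = vapply(curves, function(cv) cv$intensity, numeric(length(q))),
      sigma = vapply(curves, function(cv) cv$sigma, numeric(length(q))),
      scheme = if (all(exposures$laser_state %in% c("on", "off")) &&
                   any(duplicated(exposures$pair_id))) "dual" else "single",
      truth = if (file.exists(truth_path)) read_truth(truth_path) else NULL
    ),
    class = "sxl_dataset"
  )
}

# Ground-truth sidecar: '<key>: values' scalar/vector lines plus named
# matrix blocks introduced by '[name]' with one row per line.
write_truth <- function(truth, path) {
  lines <- c("# sxl ground truth")
  scalars <- c("species", "rates", "tau", "phi", "delays", "norm_constant", "seed")
  for (key in scalars) {
    val <- truth[[key]]
    if (is.null(val)) next
    lines <- c(lines, sprintf(
      "%s: %s", key,
      paste(if (is.numeric(val)) fmt_num(val) else as.character(val), collapse = " ")
    ))
  }
  for (key in c("sads_raw", "sads_norm", "populations", "ground")) {
    val <- truth[[key]]
    if (is.null(val)) next
    val <- as.matrix(val)
    lines <- c(lines, sprintf("[%s]", key),
               apply(val, 1L, function(r) paste(fmt_num(r), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  truth <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^\\[", ln)) {
      name <- sub("^\\[(.*)\\]$", "\\1", trimws(ln))
      j <- i + 1L
      while (j <= length(lines) && !grepl("^\\[", lines[j]) && !grepl(":", lines[j])) j <- j + 1L
      block <- lines[seq.int(i + 1L, j - 1L)]
      truth[[name]] <- t(vapply(
        strsplit(trimws(block), "\\s+"),
        as.numeric,
        numeric(length(strsplit(trimws(block[1L]), "\\s+")[[1L]]))
      ))
      i <- j
    } else {
      mm <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
      if (length(mm) == 3L) {
        vals <- strsplit(trimws(mm[3L]), "\\s+")[[1L]]
        num <- suppressWarnings(as.numeric(vals))
        truth[[mm[2L]]] <- if (anyNA(num)) vals else num
      }
      i <- i + 1L
    }
  }
  truth
}

#' Write and read detector images as float TIFF with a geometry sidecar
#'
#' The image is stored as 32-bit float TIFF (masked pixels as `NaN`); the
#' geometry (beam centre, pixel size, distance, wavelength) goes to a YAML
#' sidecar `<path>.geom.yaml` so no vendor header convention is assumed.
#'
#' @param image Numeric matrix (`NA` = masked), or the list from
#'   [render_detector_image()].
#' @param path TIFF path.
#' @param geometry A [detector_geometry()] (taken from the render list if
#'   omitted).
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff` a
#'   list with `image` (masked pixels `NA`) and `geometry`.
#' @export
write_image_tiff <- function(image, path, geometry = NULL) {
  if (is.list(image) && !is.null(image$image)) {
    geometry <- geometry %||% image$geometry
    image <- image$image
  }
  stopifnot(is.matrix(image), inherits(geometry, "detector_geometry"))
  # TIFF samples live in [0, 1]: store an affine-rescaled image plus a mask
  # page, with the offset/scale recorded in the sidecar
  rng <- range(image, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  img <- (image - rng[1L]) / scale
  mask <- !is.na(image)
  img[!mask] <- 0
  tiff::writeTIFF(list(img, mask * 1), path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(
    list(
      beam_center = geometry$beam_center,
      pixel_size_mm = geometry$pixel_size_mm,
      distance_mm = geometry$distance_mm,
      wavelength_A = geometry$wavelength_A,
      shape = dim(image),
      offset = rng[1L],
      scale = scale
    ),
    paste0(path, ".geom.yaml"),
    precision = 15L
  )
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  gpath <- paste0(path, ".geom.yaml")
  if (!file.exists(gpath)) {
    stop_sxl(sprintf("missing geometry sidecar %s", gpath), "sxl_io_error")
  }
  g <- yaml::read_yaml(gpath)
  img <- pages[[1L]] * (g$scale %||% 1) + (g$offset %||% 0)
  if (length(pages) > 1L) img[pages[[2L]] < 0.5] <- NA_real_
  list(
    image = img,
    geometry = detector_geometry(
      unlist(g$beam_center), g$pixel_size_mm, g$distance_mm, g$wavelength_A
    )
  )
}
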