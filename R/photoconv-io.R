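#' Write / read a photoconversion stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered (green, red) x (t_pre, t_0, t_post) x frame, i.e.
#' `green_pre` frames 1..2, `red_pre` 1..2, `green_t0`, `red_t0`,
#' `green_post`, `red_post`.  Intensities are scaled to \[0, 1\] by a gain
#' recorded in the sidecar (the analysis is invariant to this gain); the
#' sidecar also records the pixel size and page order.  Requires the
#' `tiff` package.
#'
#' @param stack A [photoconv_stack()].
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_photoconv_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("the 'tiff' package is required for TIFF I/O")
  }
  keys <- c("green_pre", "red_pre", "green_t0", "red_t0", "green_post",
            "red_post")
  pages <- list()
  for (k in keys) {
    f <- stack[[k]]
    for (j in seq_len(dim(f)[3])) pages[[length(pages) + 1]] <- f[, , j]
  }
  offset <- min(vapply(pages, min, numeric(1)))
  gain <- max(1e-12, max(vapply(pages, max, numeric(1))) - offset)
  pages <- lapply(pages, function(p) pmin(pmax((p - offset) / gain, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size,
               t_interval_s = stack$t_interval,
               gain = gain, offset = offset,
               page_order = keys,
               frames_per_timepoint = dim(stack$green_pre)[3])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_photoconv_stack
#' @export
read_photoconv_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("the 'tiff' package is required for TIFF I/O")
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nfr <- meta$frames_per_timepoint
  arrs <- list()
  i <- 1
  for (k in meta$page_order) {
    fr <- pages[i:(i + nfr - 1)]
    arrs[[k]] <- array(unlist(fr), dim = c(dim(fr[[1]]), nfr)) * meta$gain +
      (meta$offset %||% 0)
    i <- i + nfr
  }
  photoconv_stack(arrs$green_pre, arrs$red_pre, arrs$green_t0, arrs$red_t0,
                  arrs$green_post, arrs$red_post,
                  pixel_size = meta$pixel_size_um,
                  t_interval = meta$t_interval_s)
}
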