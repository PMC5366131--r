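# Horizon-graph banding of OTU time series: median-centering with bands of
# width one median absolute deviation, negative values mirrored upwards.

#' Horizon-band transform of one time series
#'
#' Centers the series on its median `m` and assigns each value an integer
#' band index using the (unscaled) median absolute deviation `d` as band
#' width: band `= sign(x - m) * min(4, ceiling(|x - m| / d))`, 0 for values
#' at the median. If `d = 0` every off-median value saturates at band
#' `+/-4`.
#'
#' @param values numeric series (>= 3 points)
#' @return tibble (`value`, `centered`, `band`) with attributes `m`
#'   (median) and `d` (MAD)
#' @export
horizon_transform <- function(values) {
  if (length(values) < 3) stop("horizon transform needs >= 3 points", call. = FALSE)
  m <- median(values)
  d <- median(abs(values - m))
  centered <- values - m
  band <- integer(length(values))
  nz <- centered != 0
  if (d > 0) {
    band[nz] <- sign(centered[nz]) * pmin(4, ceiling(abs(centered[nz]) / d))
  } else {
    band[nz] <- sign(centered[nz]) * 4L
  }
  out <- tibble::tibble(value = values, centered = centered,
                        band = as.integer(band))
  attr(out, "m") <- m
  attr(out, "d") <- d
  out
}

#' Horizon bands for every OTU of a normalized series
#'
#' @param x an `mb_normalized` object (or samples x OTUs matrix)
#' @return tibble (`otu_id`, `sample_id`, `day`, `value`, `centered`,
#'   `band`, `m`, `d`)
#' @export
horizon_bands <- function(x) {
  m <- if (inherits(x, "mb_normalized")) x$normalized else x
  days <- if (inherits(x, "mb_normalized")) x$days else seq_len(nrow(m))
  purrr::map_dfr(colnames(m), function(o) {
    h <- horizon_transform(m[, o])
    tibble::tibble(otu_id = o, sample_id = rownames(m), day = days,
                   value = h$value, centered = h$centered, band = h$band,
                   m = attr(h, "m"), d = attr(h, "d"))
  })
}

#' Horizon-style heat panel of banded OTU trajectories
#'
#' @param object an `mb_normalized` object
#' @param ... unused
#' @return a ggplot: OTUs on the vertical axis, days on the horizontal,
#'   tiles colored by band index (warm above the median, cool below)
#' @export
autoplot.mb_normalized <- function(object, ...) {
  hb <- horizon_bands(object)
  ggplot2::ggplot(hb, ggplot2::aes(x = .data$day, y = .data$otu_id,
                                   fill = .data$band)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", limits = c(-4, 4)) +
    ggplot2::labs(x = "day", y = NULL, fill = "band",
                  title = sprintf("Horizon bands, subject %s",
                                  object$subject_id %||% "")) +
    ggplot2::theme_minimal(base_size = 9)
}
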