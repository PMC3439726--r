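# Displayed values: sample extraction, two-sample comparison statistics,
# min-value filtering, and the value -> color mapping.

#' Construct a value vector
#'
#' The displayed quantity for one sample or one two-sample comparison:
#' one finite value per entity (missing values are filtered out upstream).
#'
#' @param entity_ids Character vector.
#' @param v Numeric vector, same length, no `NA`.
#' @param label Display label for legends/titles.
#' @return An object of class `ValueVector`.
#' @export
value_vector <- function(entity_ids, v, label = "") {
  entity_ids <- as.character(entity_ids)
  v <- as.numeric(v)
  if (length(entity_ids) != length(v))
    stop2("entity_ids and v differ in length (%d vs %d)",
          length(entity_ids), length(v))
  if (anyNA(v)) stop2("value vector must not contain missing values")
  structure(list(entity_ids = entity_ids, v = v, label = as.character(label)),
            class = "ValueVector")
}

#' @export
print.ValueVector <- function(x, ...) {
  cat(sprintf("<ValueVector> '%s': %d entities", x$label, length(x$v)))
  if (length(x$v)) cat(sprintf(", range [%s, %s]",
                               fmt_val(min(x$v)), fmt_val(max(x$v))))
  cat("\n")
  invisible(x)
}

#' Extract one sample's values
#'
#' Entities missing in that sample are omitted; the original entity order is
#' preserved.
#'
#' @param ds An `ExpressionDataset`.
#' @param sample Sample id.
#' @return A `ValueVector` labelled with the sample id.
#' @export
extract_sample <- function(ds, sample) {
  if (!sample %in% ds$sample_ids)
    stop2("unknown sample '%s'; available: %s",
          sample, paste(ds$sample_ids, collapse = ", "))
  col <- ds$values[, sample]
  keep <- !is.na(col)
  if (!any(keep)) warning(sprintf("sample '%s' has no present values", sample))
  value_vector(ds$entity_ids[keep], col[keep], label = sample)
}

#' Compare two samples
#'
#' Three comparison statistics between conditions `a` (first) and `b`
#' (second), per entity with both values present:
#' * `difference`: `v_a - v_b`
#' * `fold`: `v_a / v_b`
#' * `difference_fold`: `(v_a - v_b) / v_b`
#'
#' Under `fold` and `difference_fold`, entities with `v_b == 0` are excluded
#' (keeping the color scale finite); the exclusion tally is messaged and
#' stored in the result's `n_excluded` element.
#'
#' @param ds An `ExpressionDataset`.
#' @param a,b Distinct sample ids (first and second condition).
#' @param mode One of `"difference"`, `"fold"`, `"difference_fold"`.
#' @return A `ValueVector` with an extra `n_excluded` element.
#' @export
compare_samples <- function(ds, a, b,
                            mode = c("difference", "fold", "difference_fold")) {
  mode <- match.arg(mode)
  if (identical(a, b)) stop2("the two samples to compare must differ (got '%s')", a)
  for (s in c(a, b)) if (!s %in% ds$sample_ids)
    stop2("unknown sample '%s'; available: %s",
          s, paste(ds$sample_ids, collapse = ", "))
  va <- ds$values[, a]
  vb <- ds$values[, b]
  keep <- !is.na(va) & !is.na(vb)
  n_excluded <- 0L
  if (mode != "difference") {
    zero <- keep & vb == 0
    n_excluded <- sum(zero)
    keep <- keep & !zero
    if (n_excluded > 0L)
      message(sprintf("compare_samples: excluded %d entit%s with %s = 0",
                      n_excluded, if (n_excluded == 1L) "y" else "ies", b))
  }
  va <- va[keep]; vb <- vb[keep]
  v <- switch(mode,
              difference = va - vb,
              fold = va / vb,
              difference_fold = (va - vb) / vb)
  out <- value_vector(ds$entity_ids[keep], v,
                      label = sprintf("%s vs %s (%s)", a, b, mode))
  out$n_excluded <- n_excluded
  out
}

#' Keep entities whose maximum value exceeds a threshold
#'
#' Retains exactly the entities whose maximum present value across all
#' samples is strictly greater than `threshold` ("over" the threshold);
#' entities with no present values are dropped.
#'
#' @param ds An `ExpressionDataset`.
#' @param threshold Numeric cutoff.
#' @return A filtered `ExpressionDataset`.
#' @export
filter_min_value <- function(ds, threshold) {
  mx <- suppressWarnings(apply(ds$values, 1L, max, na.rm = TRUE))
  keep <- is.finite(mx) & mx > threshold
  if (!any(keep))
    stop2("no entity has a value over %s in any sample", fmt_val(threshold))
  expression_dataset(ds$values[keep, , drop = FALSE],
                     ds$entity_ids[keep], ds$sample_ids)
}

#' Symmetric keep-over / keep-under value filters
#'
#' Restricts a displayed value vector to entities with `v > keep_over`
#' and/or `v < keep_under` (both optional; both applied when both given).
#'
#' @param v A `ValueVector`.
#' @param keep_over,keep_under Optional numeric cutoffs.
#' @return A filtered `ValueVector`.
#' @export
filter_value_range <- function(v, keep_over = NULL, keep_under = NULL) {
  keep <- rep(TRUE, length(v$v))
  if (!is.null(keep_over)) keep <- keep & v$v > keep_over
  if (!is.null(keep_under)) keep <- keep & v$v < keep_under
  value_vector(v$entity_ids[keep], v$v[keep], v$label)
}

#' Construct a color scale
#'
#' A binned sequential scale over `[vmin, vmax]` using the ColorBrewer
#' YlOrRd (light yellow - orange - dark red) palette. By default higher
#' values get darker colors; `reversed = TRUE` flips the palette.
#'
#' @param vmin,vmax Range endpoints (`vmin <= vmax`). Values outside the
#'   range saturate at the end bins.
#' @param n_bins Number of color bins (>= 2; default 9, the maximal YlOrRd
#'   class count).
#' @param palette_id Palette name (only `"YlOrRd"` is built in).
#' @param reversed Flip the light-to-dark direction.
#' @return An object of class `ColorScale`.
#' @export
color_scale <- function(vmin, vmax, n_bins = 9L, palette_id = "YlOrRd",
                        reversed = FALSE) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop2("n_bins must be >= 2 (got %d)", n_bins)
  if (!is.finite(vmin) || !is.finite(vmax) || vmin > vmax)
    stop2("need finite vmin <= vmax (got %s, %s)", fmt_val(vmin), fmt_val(vmax))
  if (palette_id != "YlOrRd")
    stop2("unknown palette '%s' (built-in: YlOrRd)", palette_id)
  structure(list(vmin = as.numeric(vmin), vmax = as.numeric(vmax),
                 n_bins = n_bins, palette_id = palette_id,
                 reversed = isTRUE(reversed)),
            class = "ColorScale")
}

#' @export
print.ColorScale <- function(x, ...) {
  cat(sprintf("<ColorScale> %s, %d bins over [%s, %s]%s\n", x$palette_id,
              x$n_bins, fmt_val(x$vmin), fmt_val(x$vmax),
              if (x$reversed) ", reversed" else ""))
  invisible(x)
}

#' Automatic color scale from the current value range
#'
#' `vmin`/`vmax` are set to the extremes of the displayed values, so the
#' full palette is always spent on the current range. A constant vector
#' yields a degenerate scale that maps every value to the middle bin.
#'
#' @param v A non-empty `ValueVector`.
#' @param n_bins Number of bins (default 9).
#' @param reversed Flip light-to-dark direction.
#' @return A `ColorScale`.
#' @export
auto_scale <- function(v, n_bins = 9L, reversed = FALSE) {
  if (length(v$v) == 0L) stop2("cannot auto-scale an empty value vector")
  color_scale(min(v$v), max(v$v), n_bins = n_bins, reversed = reversed)
}

#' Map values to color-bin indices
#'
#' Half-open equal-width bins: bin `i` covers
#' `[vmin + i*w, vmin + (i+1)*w)` with `w = (vmax - vmin)/n_bins`; the top
#' bin is closed and out-of-range values saturate at the end bins. A
#' degenerate scale (`vmin == vmax`) maps everything to `floor(n_bins/2)`.
#'
#' @param scale A `ColorScale`.
#' @param value Numeric vector.
#' @return Integer bin indices in `[0, n_bins - 1]` (0-based).
#' @export
bin_index <- function(scale, value) {
  n <- scale$n_bins
  if (scale$vmax == scale$vmin)
    return(rep.int(as.integer(floor(n / 2)), length(value)))
  idx <- floor((value - scale$vmin) / (scale$vmax - scale$vmin) * n)
  as.integer(pmin(pmax(idx, 0), n - 1L))
}

# ColorBrewer 9-class YlOrRd anchors, lightest to darkest.
ylorrd_anchors <- function() {
  c("#FFFFCC", "#FFEDA0", "#FED976", "#FEB24C", "#FD8D3C",
    "#FC4E2A", "#E31A1C", "#BD0026", "#800026")
}

hex_to_rgb <- function(hex) {
  t(vapply(hex, function(h)
    as.integer(strtoi(c(substr(h, 2, 3), substr(h, 4, 5), substr(h, 6, 7)),
                      16L)), integer(3)))
}

rgb_to_hex <- function(m) {
  sprintf("#%02X%02X%02X", m[, 1L], m[, 2L], m[, 3L])
}

# n colors linearly interpolated (per RGB channel) over the 9 anchors.
ylorrd_palette <- function(n) {
  anchors <- hex_to_rgb(ylorrd_anchors())
  at <- seq(0, 1, length.out = 9L)
  t_out <- seq(0, 1, length.out = n)
  chan <- vapply(1:3, function(j)
    stats::approx(at, anchors[, j], xout = t_out)$y, numeric(n))
  if (n == 1L) chan <- matrix(chan, nrow = 1L)
  rgb_to_hex(matrix(as.integer(round(chan)), ncol = 3L))
}

#' Color of a bin
#'
#' Deterministic hex color for bin `index` (0-based) on the scale's palette:
#' index 0 is lightest unless the scale is reversed. For `n_bins != 9` the
#' palette is linearly interpolated over the 9 YlOrRd anchors.
#'
#' @param scale A `ColorScale`.
#' @param index Integer bin index (vectorized), `0 <= index < n_bins`.
#' @return Hex color string(s) like `"#FFFFCC"`.
#' @export
palette_color <- function(scale, index) {
  index <- as.integer(index)
  if (any(index < 0L | index >= scale$n_bins))
    stop2("bin index out of range [0, %d]", scale$n_bins - 1L)
  pal <- ylorrd_palette(scale$n_bins)
  if (scale$reversed) pal <- rev(pal)
  pal[index + 1L]
}
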