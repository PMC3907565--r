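#' Generate a defect pattern along an axis
#'
#' Constructs the field `mu_N + k * projection_sd * direction` in
#' standardized space -- `mu_N` being the normal cluster's mean, the
#' anchor for every cluster's axes so patterns read as departures from
#' normality -- maps it back to dB and years, and reports the deviations
#' from the de-standardized normal-cluster mean over the 52 field points
#' together with the generated age.  Deviation values are not clipped at
#' 0 dB: they simulate a total-deviation plot, not raw thresholds.
#'
#' @param model Fitted `vim_model` with a stored standardization.
#' @param axis An oriented `axis_spec` (from [orient_axes()]).
#' @param k SD multiplier along the axis (displays typically use -2 and
#'   +2; `k = 0` gives the zero pattern).
#' @param normal_cluster_index Anchor cluster; defaults to the axis's
#'   stored `ref_cluster`.
#' @param anchor `"normal"` (default) anchors at the normal cluster's
#'   mean; `"own"` anchors at the axis's own cluster mean (exploratory).
#' @return Object of class `pattern_grid`: `layout`, `deviations` (52,
#'   dB), `age` (years), `cluster`, `axis`, `k`.
#' @export
generate_axis_pattern <- function(model, axis, k,
                                  normal_cluster_index = axis$ref_cluster,
                                  anchor = c("normal", "own")) {
  if (inherits(model, "vim_fit")) model <- model$model
  anchor <- match.arg(anchor)
  if (!isTRUE(axis$oriented)) stop("axis must be oriented first")
  ref <- if (anchor == "normal") normal_cluster_index else axis$cluster
  if (is.null(ref) || is.na(ref)) stop("no anchor cluster available")
  mu_ref <- model$clusters[[ref]]$mu_mean
  z <- mu_ref + k * axis$projection_sd * axis$direction
  std <- model$standardization
  if (is.null(std))
    std <- list(center = rep(0, model$D), scale = rep(1, model$D))
  x <- drop(destandardize(z, std))
  x0 <- drop(destandardize(mu_ref, std))
  npts <- n_points_242()
  has_age <- model$D > npts
  structure(list(
    layout = layout_242(),
    deviations = (x - x0)[seq_len(npts)],
    age = if (has_age) x[model$D] else NA_real_,
    cluster = axis$cluster, axis = axis$axis, k = k
  ), class = "pattern_grid")
}

#' Severity of a field along an oriented axis
#'
#' The signed projection of the standardized field, relative to the
#' normal-cluster mean, onto the axis direction, in units of the axis's
#' projection SD.  Larger positive values mean a more severe defect
#' (orientation convention); the pattern generated at `+k` SD scores
#' exactly `k` on its own axis.
#'
#' @param field Numeric vector in data units (52 thresholds + age, in
#'   the model's input order), or a `pattern_grid`.
#' @param axis An oriented `axis_spec`.
#' @param model The fitted `vim_model` the axis belongs to.
#' @return Signed severity in SD units.
#' @export
severity <- function(field, axis, model) {
  if (inherits(model, "vim_fit")) model <- model$model
  if (!isTRUE(axis$oriented)) stop("axis must be oriented first")
  if (inherits(field, "pattern_grid"))
    field <- pattern_field(field, model, axis$ref_cluster)
  if (length(field) != model$D)
    stop("field has length ", length(field), "; model expects ", model$D)
  std <- model$standardization
  if (is.null(std))
    std <- list(center = rep(0, model$D), scale = rep(1, model$D))
  z <- (field - std$center) / std$scale
  mu_ref <- model$clusters[[axis$ref_cluster]]$mu_mean
  sum((z - mu_ref) * axis$direction) / axis$projection_sd
}

#' Reconstruct the full field a pattern grid represents
#'
#' Adds the pattern's deviations back onto the de-standardized
#' normal-cluster mean, giving the 52 thresholds + age vector that
#' [severity()] accepts.
#'
#' @param grid A `pattern_grid`.
#' @param model The fitted `vim_model`.
#' @param normal_cluster_index Anchor used when the pattern was built.
#' @return Numeric vector of length `model$D`.
#' @export
pattern_field <- function(grid, model, normal_cluster_index) {
  if (inherits(model, "vim_fit")) model <- model$model
  std <- model$standardization
  if (is.null(std))
    std <- list(center = rep(0, model$D), scale = rep(1, model$D))
  base <- drop(destandardize(model$clusters[[normal_cluster_index]]$mu_mean,
                             std))
  npts <- n_points_242()
  out <- base
  out[seq_len(npts)] <- base[seq_len(npts)] + grid$deviations
  if (model$D > npts) out[model$D] <- grid$age
  out
}

#' @export
print.pattern_grid <- function(x, ...) {
  cat(sprintf(
    "<pattern_grid> cluster %d axis %d at %+g SD; age %.1f; range [%.1f, %.1f] dB\n",
    x$cluster, x$axis, x$k, x$age, min(x$deviations), max(x$deviations)))
  invisible(x)
}

#' Render a pattern grid as a total-deviation-style plot
#'
#' Draws the 24-2 layout with one tile per point, red for sensitivity
#' loss and green for gain, the numeric deviation printed at each
#' location and the generated age in the title.  Purely presentational;
#' nothing reads images back.
#'
#' @param grid A `pattern_grid`.
#' @param path Output image path (extension selects the device, e.g.
#'   `.png`).
#' @param limit Colour-scale limit in dB (defaults to the symmetric data
#'   range).
#' @return `path`, invisibly.
#' @export
render_pattern <- function(grid, path, limit = NULL) {
  df <- data.frame(x = grid$layout$x_deg, y = grid$layout$y_deg,
                   dev = grid$deviations,
                   lab = sprintf("%.0f", grid$deviations))
  if (is.null(limit)) limit <- max(abs(df$dev), 1)
  ttl <- sprintf("cluster %d, axis %d, %+g SD%s", grid$cluster, grid$axis,
                 grid$k,
                 if (is.na(grid$age)) "" else sprintf(" (age %.0f)", grid$age))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = dev),
                       width = 5.5, height = 5.5, colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = lab), size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "red3", mid = "white",
                                  high = "green4", midpoint = 0,
                                  limits = c(-limit, limit),
                                  name = "deviation (dB)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = ttl, x = "degrees (temporal +)",
                  y = "degrees (superior +)") +
    ggplot2::theme_minimal(base_size = 9)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(path, p, width = 5, height = 4.2, dpi = 150)
  if (!file.exists(path)) stop("failed to write ", path)
  invisible(path)
}
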