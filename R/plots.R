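# ggplot2 views of fitted models and statistic volumes.

#' Plot observed trajectories with the model-implied mean for a fitted
#' growth model
#'
#' Spaghetti plot of each subject's observed outcome across waves, overlaid
#' with model-implied mean trajectories. With a covariate-conditional model
#' the implied means are drawn at low/high values (quartiles) of the first
#' covariate, the visual convention for slope-on-covariate effects.
#'
#' @param object an `"lgm_fit"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lgm_fit <- function(object, ...) {
  spec <- object$spec
  outcomes <- spec$outcomes
  lam <- if (!is.null(spec$loadings)) spec$loadings
         else seq_along(outcomes) - 1
  long <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(object$data),
                  .subject = dplyr::row_number()),
    dplyr::all_of(outcomes), names_to = "wave", values_to = "y")
  long$time <- lam[match(long$wave, outcomes)]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$.subject),
                       alpha = 0.25, na.rm = TRUE) +
    ggplot2::labs(x = "time (wave coding)", y = "outcome")
  est <- object$params
  covs <- spec$covariates
  lat <- spec$latents
  a_i <- est[paste0(lat[1], "~1")]
  a_s <- est[paste0(lat[2], "~1")]
  if (length(covs) > 0) {
    cv <- covs[1]
    qs <- quantile(object$data[[cv]], c(0.25, 0.75), na.rm = TRUE)
    others <- if (length(covs) > 1)
      colMeans(object$data[covs[-1]], na.rm = TRUE) else numeric(0)
    lines <- lapply(seq_along(qs), function(i) {
      mu_i <- a_i + est[paste0(lat[1], "~", cv)] * qs[i] +
        sum(est[paste0(lat[1], "~", covs[-1])] * others)
      mu_s <- a_s + est[paste0(lat[2], "~", cv)] * qs[i] +
        sum(est[paste0(lat[2], "~", covs[-1])] * others)
      tibble(time = lam, mean = mu_i + lam * mu_s,
             group = paste0(cv, " = ", signif(qs[i], 3)))
    })
    p <- p + ggplot2::geom_line(
      data = dplyr::bind_rows(lines),
      ggplot2::aes(y = .data$mean, colour = .data$group), linewidth = 1.1) +
      ggplot2::labs(colour = NULL)
  } else {
    p <- p + ggplot2::geom_line(
      data = tibble(time = lam, mean = a_i + lam * a_s),
      ggplot2::aes(y = .data$mean), colour = "red", linewidth = 1.1)
  }
  p
}

#' Axial slice of a statistic volume
#'
#' @param maps a `"stat_map_set"` (or a bare 3D array).
#' @param stat which volume to draw (default the target estimate).
#' @param k slice index along the third axis (default middle).
#' @param clusters optional `"cluster_set"` whose outlines are overdrawn.
#' @return A ggplot object.
#' @export
plot_stat_slice <- function(maps, stat = "estimate", k = NULL,
                            clusters = NULL) {
  vol <- if (inherits(maps, "stat_map_set")) maps$volumes[[stat]] else maps
  if (is.null(vol)) abort(paste0("No volume named ", stat, "."))
  k <- k %||% ceiling(dim(vol)[3] / 2)
  sl <- vol[, , k]
  df <- tidyr::expand_grid(i = seq_len(nrow(sl)), j = seq_len(ncol(sl)))
  df$value <- sl[cbind(df$i, df$j)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(stat, ", slice k = ", k))
  if (!is.null(clusters)) {
    lab <- clusters$labels[, , k]
    sel <- which(lab > 0, arr.ind = TRUE)
    if (nrow(sel) > 0)
      p <- p + ggplot2::geom_tile(
        data = tibble(i = sel[, 1], j = sel[, 2]),
        ggplot2::aes(.data$i, .data$j), fill = NA, colour = "black",
        linewidth = 0.3, inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
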