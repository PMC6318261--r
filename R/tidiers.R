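#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a component set into a long tibble
#'
#' @param x A `tractica_components` object.
#' @param maps `"gm"` or `"wm"`.
#' @param ... Unused.
#' @return A tibble with `component`, `location`, `value`.
#' @method tidy tractica_components
#' @export
tidy.tractica_components <- function(x, maps = c("gm", "wm"), ...) {
  maps <- match.arg(maps)
  M <- component_maps(x, maps)
  tibble::tibble(
    component = rep(seq_len(nrow(M)), each = ncol(M)),
    location = rep(seq_len(ncol(M)), nrow(M)),
    value = as.vector(t(M))
  )
}

#' One-row summary of a mixture fit
#'
#' @param x A `tractica_ggm` object.
#' @param ... Unused.
#' @method glance tractica_ggm
#' @export
glance.tractica_ggm <- function(x, ...) {
  tibble::tibble(
    n_classes = x$n_classes,
    pi_pos = unname(x$pi["pos"] %||% 0),
    mu = x$mu, sigma = x$sigma,
    shape_pos = x$shape_pos %||% NA_real_,
    scale_pos = x$scale_pos %||% NA_real_,
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n = x$n
  )
}

#' Per-class parameters of a mixture fit
#'
#' @param x A `tractica_ggm` object.
#' @param ... Unused.
#' @method tidy tractica_ggm
#' @export
tidy.tractica_ggm <- function(x, ...) {
  rows <- list(tibble::tibble(class = "gauss", pi = unname(x$pi["gauss"]),
                              mean = x$mu, sd = x$sigma,
                              shape = NA_real_, scale = NA_real_))
  if ("pos" %in% names(x$pi))
    rows <- c(rows, list(tibble::tibble(
      class = "pos", pi = unname(x$pi["pos"]),
      mean = x$shift + x$shape_pos * x$scale_pos,
      sd = sqrt(x$shape_pos) * x$scale_pos,
      shape = x$shape_pos, scale = x$scale_pos)))
  if ("neg" %in% names(x$pi))
    rows <- c(rows, list(tibble::tibble(
      class = "neg", pi = unname(x$pi["neg"]),
      mean = x$shift - x$shape_neg * x$scale_neg,
      sd = sqrt(x$shape_neg) * x$scale_neg,
      shape = x$shape_neg, scale = x$scale_neg)))
  do.call(rbind, rows)
}

#' Tidy a split-half study
#'
#' @param x A `tractica_splithalf` object.
#' @param ... Unused.
#' @return The per-(K, component) reliability report tibble.
#' @method tidy tractica_splithalf
#' @export
tidy.tractica_splithalf <- function(x, ...) x$report

#' Per-dimensionality summary of a split-half study
#'
#' @param x A `tractica_splithalf` object.
#' @param ... Unused.
#' @method glance tractica_splithalf
#' @export
glance.tractica_splithalf <- function(x, ...) {
  out <- lapply(x$K_values, function(K) {
    r <- x$report[x$report$K == K, ]
    tibble::tibble(
      K = K,
      median_gm_r = stats::median(r$gm_r, na.rm = TRUE),
      median_wm_r = stats::median(r$wm_r, na.rm = TRUE),
      mean_dice = x$dice$mean_dice[x$dice$K == K],
      null_mean_dice = mean(x$null$null_mean_dice[x$null$K == K])
    )
  })
  do.call(rbind, out)
}

#' Reliability plot of a split-half study
#'
#' Boxplots of per-component matched correlations by dimensionality, with
#' the ICA parcellation mean Dice and the contiguous random-parcellation
#' null alongside.
#'
#' @param object A `tractica_splithalf` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tractica_splithalf
#' @export
autoplot.tractica_splithalf <- function(object, ...) {
  rep_long <- rbind(
    data.frame(K = object$report$K, r = object$report$gm_r, map = "grey matter"),
    data.frame(K = object$report$K, r = object$report$wm_r, map = "white matter")
  )
  ggplot2::ggplot(rep_long, ggplot2::aes(x = factor(.data$K), y = .data$r)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~map) +
    ggplot2::labs(x = "ICA dimensionality K",
                  y = "matched split-half |r|",
                  title = "Split-half component reliability") +
    ggplot2::ylim(0, 1)
}

#' @importFrom generics augment
#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Manhattan-style plot of an association screen
#'
#' @param object A `tractica_assoc` table with q-values ([add_fdr()]).
#' @param ... Unused.
#' @return A ggplot object: -log10 p by component, faceted by weight kind.
#' @method autoplot tractica_assoc
#' @export
autoplot.tractica_assoc <- function(object, ...) {
  df <- as.data.frame(object)
  df$neglog10p <- -log10(pmax(df$p, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$neglog10p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~weight_kind) +
    ggplot2::labs(x = "component", y = expression(-log[10](p)),
                  title = "Covariate associations of subject weights")
}

#' Density overlay of a Gaussian/gamma mixture fit
#'
#' @param object A `tractica_ggm` fit.
#' @param values The data the fit was computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tractica_ggm
#' @export
autoplot.tractica_ggm <- function(object, values, ...) {
  grid <- seq(min(values), max(values), length.out = 512)
  dens <- data.frame(x = grid, y = ggm_density(object, grid))
  ggplot2::ggplot(data.frame(x = values), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80") +
    ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$y),
                       colour = "firebrick") +
    ggplot2::labs(x = "map value", y = "density",
                  title = "Gaussian/gamma mixture fit")
}
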