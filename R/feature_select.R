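#' Fit per-class Gaussians to one descriptor
#'
#' Fits a normal distribution to the benign and the malignant values of a
#' (min-max normalized) descriptor: sample mean and (n-1) standard deviation
#' per class, plus their overlapping coefficient.
#'
#' @param values Numeric vector, one value per sample, normalized to
#'   \[0, 1\] over all samples.
#' @param labels Character/factor vector of `"benign"` / `"malignant"`.
#' @param feature_name Optional descriptor name carried in the result.
#' @return A `bus_gaussian_pair` list: `feature_name`, `mu_b`, `sd_b`,
#'   `mu_m`, `sd_m`, `overlap`.
#' @export
fit_class_gaussians <- function(values, labels, feature_name = NA_character_) {
  stopifnot(length(values) == length(labels))
  vb <- values[labels == "benign"]
  vm <- values[labels == "malignant"]
  if (length(vb) < 2L || length(vm) < 2L)
    stop("need at least two samples per class", call. = FALSE)
  sd_b <- sd(vb); sd_m <- sd(vm)
  if (sd_b == 0 || sd_m == 0)
    stop("zero within-class variance for '", feature_name,
         "'; remove this feature", call. = FALSE)
  g <- structure(list(feature_name = feature_name,
                      mu_b = mean(vb), sd_b = sd_b,
                      mu_m = mean(vm), sd_m = sd_m),
                 class = "bus_gaussian_pair")
  g$overlap <- overlap_coefficient(g)
  g
}

#' Overlapping coefficient of two Gaussians
#'
#' \eqn{OVL = \int \min(N(x;\mu_b,\sigma_b), N(x;\mu_m,\sigma_m))\,dx}: the
#' shared area under the two class density curves, in \[0, 1\]. A small
#' overlap means the descriptor separates the classes well. Equal-variance
#' pairs use the closed form \eqn{2\Phi(-|\mu_b-\mu_m|/(2\sigma))}; otherwise
#' the integral is evaluated by adaptive quadrature. Symmetric in the two
#' classes and invariant under a common affine rescaling.
#'
#' @param g A `bus_gaussian_pair` (see [fit_class_gaussians()]), or a list
#'   with fields `mu_b`, `sd_b`, `mu_m`, `sd_m`.
#' @return The overlap, a number in \[0, 1\].
#' @export
overlap_coefficient <- function(g) {
  stopifnot(g$sd_b > 0, g$sd_m > 0)
  if (isTRUE(all.equal(g$sd_b, g$sd_m, tolerance = 1e-9))) {
    return(min(2 * pnorm(-abs(g$mu_b - g$mu_m) / (2 * g$sd_b)), 1))
  }
  f <- function(x) pmin(dnorm(x, g$mu_b, g$sd_b), dnorm(x, g$mu_m, g$sd_m))
  lo <- min(g$mu_b - 10 * g$sd_b, g$mu_m - 10 * g$sd_m)
  hi <- max(g$mu_b + 10 * g$sd_b, g$mu_m + 10 * g$sd_m)
  val <- integrate(f, lo, hi, subdivisions = 500L, rel.tol = 1e-8)$value
  min(max(val, 0), 1)
}

#' Rank descriptors by inter-class Gaussian overlap
#'
#' Replaces visual inspection of per-class distribution curves with a
#' numeric criterion: every descriptor is min-max normalized over the full
#' dataset, per-class Gaussians are fitted, and descriptors are ranked by
#' ascending overlapping coefficient. Those with `overlap <= max_overlap`
#' are selected (optionally truncated to the `top_k` best).
#'
#' @param table Tibble with a `label` column (`"benign"`/`"malignant"`) and
#'   one numeric column per descriptor (`id` is ignored if present).
#' @param max_overlap Selection threshold on OVL (default 0.35).
#' @param top_k Optional cap on the number of selected descriptors.
#' @return A `bus_feature_ranking`: a tibble with columns `feature`, `mu_b`,
#'   `sd_b`, `mu_m`, `sd_m`, `overlap`, `selected`, sorted by ascending
#'   overlap. Errors (attaching the full ranking) if nothing passes.
#' @export
select_features <- function(table, max_overlap = 0.35, top_k = NULL) {
  stopifnot("label" %in% names(table))
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], "id")
  if (!length(feats)) stop("no numeric feature columns", call. = FALSE)
  ranking <- purrr::map_dfr(feats, function(f) {
    v <- table[[f]]
    rng <- range(v)
    if (diff(rng) == 0)
      stop("zero variance for '", f, "'; remove this feature", call. = FALSE)
    v <- (v - rng[1]) / diff(rng)
    g <- fit_class_gaussians(v, table$label, f)
    tibble(feature = f, mu_b = g$mu_b, sd_b = g$sd_b, mu_m = g$mu_m,
           sd_m = g$sd_m, overlap = g$overlap)
  })
  ranking <- dplyr::arrange(ranking, .data$overlap, .data$feature)
  keep <- ranking$overlap <= max_overlap
  if (!is.null(top_k)) keep <- keep & seq_len(nrow(ranking)) <= top_k
  ranking$selected <- keep
  if (!any(keep)) {
    err <- structure(
      class = c("bus_no_feature_error", "error", "condition"),
      list(message = sprintf(
             "no descriptor has overlap <= %.3g (best: %s at %.3f)",
             max_overlap, ranking$feature[1], ranking$overlap[1]),
           call = sys.call(-1), ranking = ranking))
    stop(err)
  }
  structure(ranking, class = c("bus_feature_ranking", class(ranking)))
}

#' @export
tidy.bus_feature_ranking <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' Plot the fitted class density curves of a ranking
#'
#' One panel per descriptor showing the benign and malignant Gaussian fits;
#' the shaded intersection is the overlapping coefficient used for
#' selection.
#'
#' @param object A `bus_feature_ranking`.
#' @param features Which descriptors to show (default: the selected ones).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bus_feature_ranking <- function(object,
                                         features = object$feature[object$selected],
                                         ...) {
  sub <- object[object$feature %in% features, ]
  curves <- purrr::pmap_dfr(
    list(sub$feature, sub$mu_b, sub$sd_b, sub$mu_m, sub$sd_m),
    function(f, mb, sb, mm, sm) {
      grid <- seq(min(mb - 4 * sb, mm - 4 * sm),
                  max(mb + 4 * sb, mm + 4 * sm), length.out = 200L)
      tibble(feature = f,
             x = rep(grid, 2),
             density = c(dnorm(grid, mb, sb), dnorm(grid, mm, sm)),
             class = rep(c("benign", "malignant"), each = length(grid)))
    })
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$x, .data$density,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = "normalized descriptor value", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
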