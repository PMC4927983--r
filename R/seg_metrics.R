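#' Pixel-level confusion counts between two masks
#'
#' @param S Automatic (segmented) logical mask.
#' @param G Ground-truth (reference) logical mask, same shape.
#' @return A one-row tibble with integer columns `TP`, `FP`, `FN`, `TN`
#'   (pixel counts; `TP` is the overlap area).
#' @export
pixel_confusion <- function(S, G) {
  if (!identical(dim(S), dim(G)))
    stop("masks have different shapes", call. = FALSE)
  tibble(TP = sum(S & G), FP = sum(S & !G),
         FN = sum(!S & G), TN = sum(!S & !G))
}

#' Region-based segmentation quality metrics
#'
#' The ten region-evaluation percentages comparing an automatic mask `S`
#' against the reference `G`, from pixel counts (TP = overlap):
#' \itemize{
#' \item `AOM` area overlap, \eqn{100\,TP/(TP+FP+FN)} (Jaccard);
#' \item `AUM` undersegmentation, \eqn{100\,FN/(TP+FN)};
#' \item `AVM` oversegmentation, \eqn{100\,FP/(TP+FP)};
#' \item `CP` completeness, \eqn{100\,TP/(TP+FN)};
#' \item `CR` correctness, \eqn{100\,TP/(TP+FP)};
#' \item `CM` combined measure, \eqn{(AOM+CP+CR)/3};
#' \item `Q` per-image quality, identical to AOM;
#' \item `A` pixel accuracy, `Err` its complement, `FPR` the pixel
#'   false-positive rate.
#' }
#' These satisfy `AUM + CP = 100`, `AVM + CR = 100`, `A + Err = 100` and
#' `CM = (AOM + CP + CR)/3` exactly.
#'
#' @param counts A one-row tibble/list with `TP`, `FP`, `FN`, `TN` (e.g. from
#'   [pixel_confusion()]).
#' @return A one-row tibble with columns `AOM`, `AUM`, `AVM`, `CM`, `CP`,
#'   `CR`, `Q`, `A`, `Err`, `FPR`, all percentages in \[0, 100\].
#' @export
region_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  if (TP + FN == 0 || TP + FP == 0)
    stop("empty reference or segmented region", call. = FALSE)
  total <- TP + FP + FN + TN
  AOM <- 100 * TP / (TP + FP + FN)
  CP <- 100 * TP / (TP + FN)
  CR <- 100 * TP / (TP + FP)
  tibble(
    AOM = AOM,
    AUM = 100 * FN / (TP + FN),
    AVM = 100 * FP / (TP + FP),
    CM = (AOM + CP + CR) / 3,
    CP = CP,
    CR = CR,
    Q = AOM,
    A = 100 * (TP + TN) / total,
    Err = 100 * (FP + FN) / total,
    FPR = if (FP + TN > 0) 100 * FP / (FP + TN) else 0
  )
}

#' Average per-image quality metrics
#'
#' Unweighted arithmetic mean of each metric column over images, as used for
#' per-method report rows.
#'
#' @param per_image Tibble of [region_metrics()] rows, one per image.
#' @return A one-row tibble of metric means.
#' @export
aggregate_metrics <- function(per_image) {
  if (nrow(per_image) == 0L) stop("no per-image metrics", call. = FALSE)
  dplyr::summarise(per_image, dplyr::across(dplyr::everything(), mean))
}

#' Benchmark segmentation methods on a dataset
#'
#' Runs each requested segmenter (with preprocessing and postprocessing, see
#' [segment_lesion()]) over every image of a generated dataset, scores each
#' mask against the ground truth with [region_metrics()], and averages per
#' method.
#'
#' @param dataset Tibble from [generate_dataset()] (columns `image`, `mask`).
#' @param methods Character vector of segmenter names.
#' @param cfg A [pipeline_config()].
#' @return A tibble with one row per method: `method` plus the ten metric
#'   columns.
#' @export
benchmark_segmentation <- function(dataset,
                                   methods = c("active_contour",
                                               "region_growing",
                                               "fuzzy_cmeans", "kmeans",
                                               "som"),
                                   cfg = pipeline_config()) {
  purrr::map_dfr(methods, function(m) {
    per_image <- purrr::map2_dfr(dataset$image, dataset$mask, function(im, gt) {
      S <- segment_lesion(im, method = m, cfg = cfg)
      region_metrics(pixel_confusion(S, gt))
    })
    dplyr::bind_cols(tibble(method = m), aggregate_metrics(per_image))
  })
}
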