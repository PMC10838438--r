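#' The versioned acoustic feature manifest
#'
#' The 53-feature acoustic set is fixed by a JSON manifest shipped with the
#' package: 5 jitter + 6 shimmer + 5 harmonicity + 7 fundamental-frequency
#' (F0) + 7 intensity + 2 zero-crossing-rate + 21 timing/rate features. The
#' manifest is data: an alternative composition can be supplied by path
#' without code changes.
#'
#' @param path Optional path to an alternative manifest JSON file.
#' @return A data.frame with columns `name`, `category`, `unit`.
#' @export
#' @examples
#' m <- feature_manifest()
#' nrow(m)           # 53
#' table(m$category)
feature_manifest <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "feature_manifest.json",
                        package = "bulbarvoice", mustWork = TRUE)
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.data.frame(j$features, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "category") %in% names(m)),
            !anyDuplicated(m$name))
  m
}

#' Names of manifest features in manifest order
#' @param manifest A manifest data.frame from [feature_manifest()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(manifest = feature_manifest()) manifest$name

#' Manifest feature subsets used for sex-interaction modelling
#'
#' The interaction analysis attaches sex interactions to the
#' fundamental-frequency features and to the two harmonics-to-noise-ratio
#' summaries (`hnr_mean`, `hnr_sd`), the feature groups where vocal-tract
#' physiology differs most between sexes.
#'
#' @param manifest A manifest data.frame.
#' @return Character vector of feature names in the F0 + HNR subsets.
#' @export
interaction_feature_subset <- function(manifest = feature_manifest()) {
  c(manifest$name[manifest$category == "f0"],
    intersect(c("hnr_mean", "hnr_sd"), manifest$name))
}
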