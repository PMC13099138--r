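.manifestCache <- new.env(parent = emptyenv())

#' Versioned feature manifest
#'
#' The classifier consumes a fixed, ordered set of 57 features: 7 prediction-
#' confidence features, 33 structural counting features, and 17 interface-
#' energy features. The roster is shipped as a versioned TSV so it can be
#' revised without code change; every feature table and trained model embeds
#' the version it was built against.
#'
#' @param version manifest version tag (default `"v1"`).
#' @return data.frame with columns `name` and `block`
#'   (confidence/counting/energy), in canonical column order.
#' @export
#' @examples
#' m <- featureManifest()
#' nrow(m)            # 57
#' table(m$block)
featureManifest <- function(version = "v1") {
  key <- paste0("manifest_", version)
  if (!is.null(.manifestCache[[key]])) return(.manifestCache[[key]])
  path <- system.file("extdata",
                      sprintf("feature_manifest_%s.tsv", version),
                      package = "PPIscreen")
  if (!nzchar(path))
    .err("ppiConfigError", "unknown feature manifest version '%s'", version)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(m) == 57L, !anyDuplicated(m$name))
  .manifestCache[[key]] <- m
  m
}

#' @rdname featureManifest
#' @export
featureNames <- function(version = "v1") featureManifest(version)$name
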