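#' Parcellation (atlas) metadata
#'
#' An `atlas_spec` describes a brain parcellation: how many regions it has
#' and what they are called. Feature names are built against an atlas so
#' that every regional metric maps to a fixed, 1-based region index.
#'
#' @param name Atlas label, e.g. `"BNA"` or `"WMPM"`.
#' @param n_regions Total number of regions.
#' @param n_cortical,n_subcortical Optional cortical/subcortical split;
#'   when both are given they must sum to `n_regions`.
#' @param labels Optional character vector of region labels (length
#'   `n_regions`). Defaults to `<name>_<index>_<hemisphere>` with odd
#'   indices tagged `L` and even indices `R`, the usual paired-region
#'   layout of volumetric parcellations.
#'
#' @return An object of class `atlas_spec`.
#' @seealso [bna_atlas()], [wmpm_atlas()], [build_feature_names()]
#' @export
atlas_spec <- function(name, n_regions, n_cortical = NULL,
                       n_subcortical = NULL, labels = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 1L)
    stop("`n_regions` must be a positive integer", call. = FALSE)
  if (!is.null(n_cortical) && !is.null(n_subcortical)) {
    if (n_cortical + n_subcortical != n_regions)
      stop("`n_cortical` + `n_subcortical` must equal `n_regions`",
           call. = FALSE)
  }
  if (is.null(labels)) {
    hemi <- ifelse(seq_len(n_regions) %% 2L == 1L, "L", "R")
    labels <- sprintf("%s_%03d_%s", name, seq_len(n_regions), hemi)
  }
  if (length(labels) != n_regions)
    stop("`labels` must have length `n_regions`", call. = FALSE)
  structure(
    list(name = name, n_regions = n_regions, n_cortical = n_cortical,
         n_subcortical = n_subcortical, labels = labels),
    class = "atlas_spec"
  )
}

#' @export
print.atlas_spec <- function(x, ...) {
  cat(sprintf("<atlas_spec> %s: %d regions", x$name, x$n_regions))
  if (!is.null(x$n_cortical))
    cat(sprintf(" (%d cortical + %d subcortical)",
                x$n_cortical, x$n_subcortical))
  cat("\n")
  invisible(x)
}

#' Built-in atlas specifications
#'
#' `bna_atlas()` returns the 246-region Brainnetome gray-matter
#' parcellation (210 cortical + 36 subcortical regions) used for the
#' structural and functional metrics; `wmpm_atlas()` returns the
#' 50-region white-matter parcellation map used for the diffusion
#' metrics.
#'
#' @return An [atlas_spec()].
#' @export
bna_atlas <- function() {
  atlas_spec("BNA", n_regions = 246L, n_cortical = 210L,
             n_subcortical = 36L)
}

#' @rdname bna_atlas
#' @export
wmpm_atlas <- function() {
  atlas_spec("WMPM", n_regions = 50L)
}

# Fixed modality -> metric-index and modality -> atlas mapping. Order is
# canonical and load-bearing: feature vectors and weight tables are only
# comparable across runs because this order never changes.
.modalities <- c("sMRI", "fMRI", "DTI")

.modality_indices <- list(
  sMRI = c("GMV", "WMV"),
  fMRI = c("ALFF", "ReHo", "DC"),
  DTI  = c("FA", "MD", "AD", "RD")
)

#' Metric indices available per modality
#'
#' @return Named list mapping each modality (`sMRI`, `fMRI`, `DTI`) to
#'   its regional metric indices, in canonical order.
#' @export
modality_indices <- function() .modality_indices

#' Atlas used by a modality
#'
#' Gray-matter metrics (sMRI, fMRI) are parcellated with the BNA;
#' diffusion metrics (DTI) with the WMPM.
#'
#' @param modality One of `"sMRI"`, `"fMRI"`, `"DTI"`.
#' @return An [atlas_spec()].
#' @export
modality_atlas <- function(modality) {
  modality <- match.arg(modality, .modalities)
  if (modality == "DTI") wmpm_atlas() else bna_atlas()
}

#' Build the canonical feature-name vector
#'
#' Feature columns are named `<modality>:<index>:<region>`, e.g.
#' `sMRI:GMV:001` or `DTI:FA:050`, with a fixed canonical ordering:
#' modalities in the order sMRI, fMRI, DTI; metric indices in the order
#' listed by [modality_indices()]; regions in 1-based atlas order. The
#' full three-modality layout has 2x246 + 3x246 + 4x50 = 1430 names.
#'
#' @param modalities Non-empty subset of `c("sMRI", "fMRI", "DTI")`.
#' @return Character vector of feature names in canonical order.
#' @examples
#' length(build_feature_names())          # 1430
#' length(build_feature_names("sMRI"))    # 492
#' @export
build_feature_names <- function(modalities = c("sMRI", "fMRI", "DTI")) {
  if (length(modalities) == 0L)
    stop("at least one modality is required", call. = FALSE)
  bad <- setdiff(modalities, .modalities)
  if (length(bad))
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  # canonical order, independent of the order given by the caller
  modalities <- .modalities[.modalities %in% modalities]
  unlist(lapply(modalities, function(m) {
    atlas <- modality_atlas(m)
    unlist(lapply(.modality_indices[[m]], function(idx) {
      sprintf("%s:%s:%03d", m, idx, seq_len(atlas$n_regions))
    }))
  }), use.names = FALSE)
}

#' Parse feature names into modality / index / region
#'
#' @param names Character vector of `<modality>:<index>:<region>` names.
#' @return A data.frame with columns `feature`, `modality`, `index`,
#'   `region` (integer).
#' @export
parse_feature_names <- function(names) {
  parts <- strsplit(names, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed feature name(s): ",
         paste(utils::head(names[bad], 3L), collapse = ", "),
         call. = FALSE)
  modality <- vapply(parts, `[[`, "", 1L)
  index <- vapply(parts, `[[`, "", 2L)
  region <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  for (i in seq_along(names)) {
    m <- modality[i]
    if (!m %in% .modalities)
      stop("unknown modality in feature name: ", names[i], call. = FALSE)
    if (!index[i] %in% .modality_indices[[m]])
      stop("metric index '", index[i], "' is not valid under modality '",
           m, "': ", names[i], call. = FALSE)
    if (is.na(region[i]) || region[i] < 1L ||
        region[i] > modality_atlas(m)$n_regions)
      stop("region index out of atlas range in feature name: ", names[i],
           call. = FALSE)
  }
  data.frame(feature = names, modality = modality, index = index,
             region = region, stringsAsFactors = FALSE)
}
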